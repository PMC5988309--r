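#' General structured-coalescent engine
#'
#' Simulates independent loci under a piecewise-constant multi-population
#' demography, returning derived/ancestral-coded haplotypes.  This is the
#' engine behind [sim_demography()]; it is exported so that arbitrary
#' population trees (e.g. the five-taxon configurations used by the
#' introgression-direction statistics) can be simulated directly.
#'
#' A demography is described by:
#' * `N`: diploid sizes per population at present;
#' * `splits`: data frame `(time, from, to)` - at `time` (generations,
#'   backward) all lineages of population `from` join population `to`;
#' * `size_changes`: optional data frame `(time, pop, N)` - from `time`
#'   backwards, population `pop` has size `N` (until a later change);
#' * `mig`: optional data frame `(t0, t1, from, to, rate)` - during
#'   `[t0, t1)` a lineage in `from` jumps to `to` at `rate` per generation
#'   (backward in time; a forward donor D and recipient R corresponds to
#'   `from = R, to = D`).
#'
#' @param nsam Integer vector of sampled haplotypes per population.
#' @param N Numeric vector of present-day diploid sizes per population.
#' @param splits Data frame of population mergers (see above); every
#'   population other than the final root must eventually merge.
#' @param size_changes,mig Optional data frames (see above).
#' @param n_loci Number of independent loci.
#' @param locus_length Locus length in bp.
#' @param mu Mutation rate per site per generation.
#' @param seed Integer seed; fixes all output.
#' @param pop_labels Character labels per population (recycled to samples).
#' @return List of [hap_matrix] objects, one per locus (chromosomes named
#'   `locus_1`, `locus_2`, ...).
#' @export
sim_coalescent <- function(nsam, N, splits, size_changes = NULL, mig = NULL,
                           n_loci = 1, locus_length = 10000, mu = 7.1e-9,
                           seed = 1, pop_labels = paste0("pop", seq_along(nsam))) {
  ep <- build_epochs(length(nsam), N, splits, size_changes, mig)
  set.seed(seed)
  raw <- coal_simulate_cpp(as.integer(nsam), ep$start, ep$sizes, ep$mig,
                           ep$remap, as.integer(n_loci),
                           as.integer(locus_length), mu)
  # consecutive haplotype pairs belong to the same (diploid) sample
  sample_of_hap <- unlist(lapply(seq_along(nsam), function(p)
    paste0(pop_labels[p], "_", ceiling(seq_len(nsam[p]) / 2))))
  sample_names <- unlist(lapply(seq_along(nsam), function(p)
    paste0(pop_labels[p], "_", ceiling(seq_len(nsam[p]) / 2), "_h",
           ((seq_len(nsam[p]) - 1L) %% 2L) + 1L)))
  pops <- rep(pop_labels, nsam)
  lapply(seq_along(raw), function(i) {
    l <- raw[[i]]
    G <- l$G
    colnames(G) <- sample_names
    ch <- paste0("locus_", i)
    hap_matrix(rep(ch, length(l$pos)), l$pos, G, sample_of_hap, pops,
               chrom_lengths = setNames(locus_length, ch))
  })
}

# Assemble the epoch representation consumed by the C++ engine.
build_epochs <- function(n_pops, N, splits, size_changes = NULL, mig = NULL) {
  stopifnot(length(N) == n_pops, all(N > 0))
  splits <- as.data.frame(splits)
  times <- c(0, splits$time)
  if (!is.null(size_changes)) times <- c(times, as.data.frame(size_changes)$time)
  if (!is.null(mig)) times <- c(times, as.data.frame(mig)$t0, as.data.frame(mig)$t1)
  start <- sort(unique(times))
  E <- length(start)
  sizes <- matrix(rep(N, each = E), nrow = E, ncol = n_pops)
  if (!is.null(size_changes)) {
    # apply in time order so deeper changes override shallower ones
    sc <- as.data.frame(size_changes)
    sc <- sc[order(sc$time), , drop = FALSE]
    for (k in seq_len(nrow(sc)))
      sizes[start >= sc$time[k], sc$pop[k]] <- sc$N[k]
  }
  mg <- array(0, dim = c(E, n_pops, n_pops))
  if (!is.null(mig)) {
    mm <- as.data.frame(mig)
    for (k in seq_len(nrow(mm))) {
      sel <- start >= mm$t0[k] & start < mm$t1[k]
      mg[sel, mm$from[k], mm$to[k]] <- mg[sel, mm$from[k], mm$to[k]] + mm$rate[k]
    }
  }
  remap <- matrix(rep(seq_len(n_pops), each = E), nrow = E, ncol = n_pops)
  # a split at time t takes effect for every epoch starting at or after t;
  # the C++ engine applies row e on *entry* to epoch e, so encode each merge
  # only in the first epoch at/after its time and propagate occupancy by
  # composing maps.
  comp <- seq_len(n_pops)
  sp <- splits[order(splits$time), , drop = FALSE]
  for (e in seq_len(E)) {
    due <- sp$time <= start[e] & sp$time > (if (e == 1) -Inf else start[e - 1])
    for (k in which(due)) comp[comp == sp$from[k]] <- sp$to[k]
    remap[e, ] <- comp
  }
  # zero migration involving emptied (merged-away) populations
  for (e in seq_len(E)) {
    empty <- setdiff(seq_len(n_pops), unique(remap[e, ]))
    mg[e, empty, ] <- 0
    mg[e, , empty] <- 0
  }
  list(start = start, sizes = sizes,
       mig = as.numeric(aperm(mg, c(3, 2, 1))), remap = remap - 1L)
}

# migration window equivalent to a mass-migration pulse moving `fraction`
# of population `from` (backward) into `to` at `time`
mig_pulse <- function(time, from, to, fraction, dt = 1) {
  data.frame(t0 = time, t1 = time + dt, from = from, to = to,
             rate = -log(1 - fraction) / dt)
}

#' Simulate a two-population divergence history
#'
#' Draws independent loci under a [demographic_params()] history: two
#' populations that split `T` generations ago, with optional migration
#' epochs and a bottleneck or growth phase in population 1.  Alleles are
#' coded ancestral (0) / derived (1); with `outgroup = TRUE` an outgroup
#' lineage splitting at `5 * T` is added (population label `"OUT"`) for
#' polarisation-style analyses.
#'
#' @param params A [demographic_params()] object.
#' @param spec A [locus_spec()] object; `spec$samples_per_pop` gives the
#'   haplotype counts for populations 1 and 2 (and the outgroup when
#'   present, defaulting to 2 haplotypes).
#' @param seed Integer seed; fixes all output.
#' @param outgroup Add an outgroup population?
#' @param pop_labels Labels for populations 1 and 2.
#' @param growth_steps Number of piecewise-constant steps used to represent
#'   the exponential phase of the `"growth"` variant.
#' @return List of per-locus [hap_matrix] objects.
#' @export
sim_demography <- function(params, spec, seed = 1, outgroup = FALSE,
                           pop_labels = c("JS", "PO"), growth_steps = 12) {
  params <- validate_demographic_params(params)
  n_pops <- if (outgroup) 3L else 2L
  N <- c(params$N_JS, params$N_PO, if (outgroup) params$N_ANC)
  splits <- data.frame(time = params$T, from = 2, to = 1)
  if (outgroup) splits <- rbind(splits,
                                data.frame(time = 5 * params$T, from = 3, to = 1))
  sc <- data.frame(time = params$T, pop = 1, N = params$N_ANC)
  if (params$growth == "bottleneck") {
    sc <- rbind(sc, data.frame(time = params$T_G, pop = 1, N = params$N_JSB))
  } else if (params$growth == "growth") {
    # exponential N_JS -> N_JSB over [0, T_G], as a geometric ladder
    bk <- seq(0, params$T_G, length.out = growth_steps + 1)
    mid <- (head(bk, -1) + tail(bk, -1)) / 2
    Nmid <- params$N_JS * (params$N_JSB / params$N_JS)^(mid / params$T_G)
    sc <- rbind(sc,
                data.frame(time = bk[-1], pop = 1,
                           N = c(Nmid[-1], params$N_JSB)),
                data.frame(time = params$T_G, pop = 1, N = params$N_JSB))
    sizes0 <- Nmid[1]
    N[1] <- sizes0
  }
  mig <- NULL
  wins <- migration_windows(params)
  if (nrow(wins) > 0) {
    mig <- rbind(
      data.frame(t0 = wins$t0, t1 = wins$t1, from = 1, to = 2,
                 rate = params$m12),
      data.frame(t0 = wins$t0, t1 = wins$t1, from = 2, to = 1,
                 rate = params$m21))
    mig <- mig[mig$rate > 0, , drop = FALSE]
    if (nrow(mig) == 0) mig <- NULL
  }
  nsam <- spec$samples_per_pop
  if (outgroup && length(nsam) < 3) nsam <- c(nsam[1:2], 2L)
  nsam <- nsam[seq_len(n_pops)]
  labels <- c(pop_labels, if (outgroup) "OUT")
  sim_coalescent(nsam, N, splits, size_changes = sc, mig = mig,
                 n_loci = spec$n_loci, locus_length = spec$locus_length,
                 mu = params$mu, seed = seed, pop_labels = labels)
}

# active migration intervals [t0, t1) for a scenario
migration_windows <- function(params) {
  switch(params$scenario,
         I = data.frame(t0 = numeric(), t1 = numeric()),
         IM = data.frame(t0 = 0, t1 = params$T),
         IAM = data.frame(t0 = params$T_anc_stop, t1 = params$T),
         IRM = data.frame(t0 = 0, t1 = params$T_rec_start),
         IARM = data.frame(t0 = c(0, params$T_anc_stop),
                           t1 = c(params$T_rec_start, params$T)))
}
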