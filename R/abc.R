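#' Default log-uniform priors for a divergence model
#'
#' Prior bounds (log-uniform draws): effective sizes in `[1e3, 1e6]`,
#' split time `T` in `[1e4, 1e7]` generations, migrant fractions in
#' `[1e-9, 1e-4]`, and the conditional times `T_G` in `[1e3, T]`,
#' `T_anc_stop` in `[T/100, T]`, `T_rec_start` in `[T_G/100, T_G]` (upper
#' bounds given as the name of the parent parameter).  Only parameters the
#' scenario/growth combination uses are listed.
#'
#' @param scenario,growth As in [demographic_params()].
#' @return Tibble: `param`, `dist`, `lower`, `upper` (numeric or the name
#'   of a parent parameter for conditional bounds).
#' @export
default_abc_priors <- function(scenario = "IM", growth = "constant") {
  rows <- list(
    list("N_JS", 1e3, "1e6"), list("N_PO", 1e3, "1e6"),
    list("N_ANC", 1e3, "1e6"), list("T", 1e4, "1e7"))
  if (growth %in% c("bottleneck", "growth")) {
    rows <- c(rows, list(list("N_JSB", 1e3, "1e6"),
                         list("T_G", 1e3, "T")))
  }
  if (scenario != "I")
    rows <- c(rows, list(list("m12", 1e-9, "1e-4"),
                         list("m21", 1e-9, "1e-4")))
  if (scenario %in% c("IAM", "IARM"))
    rows <- c(rows, list(list("T_anc_stop", NA, "T")))
  if (scenario %in% c("IRM", "IARM"))
    rows <- c(rows, list(list("T_rec_start", NA, "T_G")))
  tibble::tibble(
    param = vapply(rows, function(r) r[[1]], ""),
    dist = "loguniform",
    lower = vapply(rows, function(r) as.numeric(r[[2]]), 0),
    upper = vapply(rows, function(r) as.character(r[[3]]), ""))
}

#' Define an ABC model: scenario, growth variant and priors
#'
#' @param scenario,growth As in [demographic_params()].
#' @param priors Prior table as from [default_abc_priors()].
#' @param name Model label (default `scenario.growth`).
#' @return An object of class `abc_model`.
#' @export
abc_model <- function(scenario, growth = "constant",
                      priors = default_abc_priors(scenario, growth),
                      name = paste(scenario, growth, sep = ".")) {
  structure(list(scenario = scenario, growth = growth, priors = priors,
                 name = name),
            class = "abc_model")
}

# one draw from the model's priors -> named parameter vector
draw_prior <- function(model) {
  pr <- model$priors
  vals <- c()
  lu <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  for (i in seq_len(nrow(pr))) {
    up <- suppressWarnings(as.numeric(pr$upper[i]))
    if (is.na(up)) up <- vals[[pr$upper[i]]]
    lo <- pr$lower[i]
    if (is.na(lo)) lo <- up / 100   # conditional default span
    lo <- min(lo, up)
    vals[pr$param[i]] <- lu(lo, up)
  }
  vals
}

params_from_draw <- function(model, vals) {
  g <- function(nm, default = NULL) {
    if (nm %in% names(vals)) unname(vals[nm]) else default
  }
  T_ <- g("T")
  T_G <- g("T_G", T_ / 2)
  T_G <- min(T_G, T_ * 0.999)
  demographic_params(
    scenario = model$scenario, growth = model$growth,
    T = T_, T_G = T_G,
    T_anc_stop = if (!is.null(g("T_anc_stop")))
      min(g("T_anc_stop"), T_ * 0.999) else NULL,
    T_rec_start = if (!is.null(g("T_rec_start")))
      min(g("T_rec_start"), T_G * 0.999) else NULL,
    m12 = g("m12", 0), m21 = g("m21", 0),
    N_PO = g("N_PO"), N_JS = g("N_JS"),
    N_JSB = g("N_JSB", g("N_JS")), N_ANC = g("N_ANC"))
}

summary_stat_names <- function() {
  base <- c("pi1", "pi2", "thetaW1", "thetaW2", "tajd1", "tajd2", "fst",
            "shared", "private1", "private2")
  c(paste0("mean_", base), paste0("var_", base))
}

# per-locus stat matrix (n_loci x 10) -> named 20-vector of moments
moments_from_locus_stats <- function(stats) {
  mns <- colMeans(stats, na.rm = TRUE)
  vrs <- apply(stats, 2, var, na.rm = TRUE)
  vrs[is.na(vrs)] <- 0
  mns[is.nan(mns)] <- NA
  setNames(c(mns, vrs), summary_stat_names())
}

# simulate one parameter draw -> summary vector (fast C++ path)
simulate_summaries <- function(params, spec) {
  ep_model <- abc_epochs(params)
  stats <- coal_pair_summaries_cpp(
    as.integer(spec$samples_per_pop[1:2]), ep_model$start, ep_model$sizes,
    ep_model$mig, ep_model$remap, spec$n_loci, spec$locus_length,
    params$mu)
  moments_from_locus_stats(stats)
}

# epoch construction shared by sim_demography and the ABC fast path
abc_epochs <- function(params) {
  N <- c(params$N_JS, params$N_PO)
  splits <- data.frame(time = params$T, from = 2, to = 1)
  sc <- data.frame(time = params$T, pop = 1, N = params$N_ANC)
  if (params$growth == "bottleneck")
    sc <- rbind(sc, data.frame(time = params$T_G, pop = 1, N = params$N_JSB))
  if (params$growth == "growth") {
    bk <- seq(0, params$T_G, length.out = 13)
    mid <- (head(bk, -1) + tail(bk, -1)) / 2
    Nmid <- params$N_JS * (params$N_JSB / params$N_JS)^(mid / params$T_G)
    N[1] <- Nmid[1]
    sc <- rbind(sc, data.frame(time = bk[-1], pop = 1,
                               N = c(Nmid[-1], params$N_JSB)))
  }
  wins <- migration_windows(params)
  mig <- NULL
  if (nrow(wins) > 0) {
    mig <- rbind(data.frame(t0 = wins$t0, t1 = wins$t1, from = 1, to = 2,
                            rate = params$m12),
                 data.frame(t0 = wins$t0, t1 = wins$t1, from = 2, to = 1,
                            rate = params$m21))
    mig <- mig[mig$rate > 0, , drop = FALSE]
    if (nrow(mig) == 0) mig <- NULL
  }
  build_epochs(2, N, splits, size_changes = sc, mig = mig)
}

#' Build an ABC reference table
#'
#' For each model and simulation: draw parameters from the priors, run the
#' coalescent simulator for the locus design, and record the 20 summary
#' statistics (mean and variance across loci of per-population nucleotide
#' diversity, Watterson's theta, Tajima's D, plus FST and shared/private
#' polymorphism counts).
#'
#' @param models List of [abc_model()] objects.
#' @param n_sims Simulations per model.
#' @param spec A [locus_spec()]; `samples_per_pop` are haplotype counts.
#' @param seed Integer seed fixing draws and simulations.
#' @return An `abc_reference` tibble: `model`, parameter columns
#'   (`par_*`), summary columns per [summary_stat_names()].
#' @export
build_reference_table <- function(models, n_sims, spec, seed = 1) {
  if (inherits(models, "abc_model")) models <- list(models)
  set.seed(seed)
  all_pars <- unique(unlist(lapply(models, function(m) m$priors$param)))
  rows <- vector("list", length(models) * n_sims)
  k <- 0
  for (m in models) {
    for (s in seq_len(n_sims)) {
      vals <- draw_prior(m)
      params <- params_from_draw(m, vals)
      sm <- simulate_summaries(params, spec)
      k <- k + 1
      pv <- setNames(rep(NA_real_, length(all_pars)),
                     paste0("par_", all_pars))
      pv[paste0("par_", names(vals))] <- vals
      rows[[k]] <- tibble::as_tibble(c(list(model = m$name),
                                       as.list(pv), as.list(sm)))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("abc_reference", class(out))
  out
}

# standardized distances of table rows to the observed summary vector
abc_distances <- function(observed, table) {
  stat_cols <- intersect(summary_stat_names(), names(table))
  X <- as.matrix(table[, stat_cols, drop = FALSE])
  obs <- unlist(observed)[stat_cols]
  mads <- apply(X, 2, stats::mad, na.rm = TRUE)
  usable <- !is.na(mads) & mads > 0 & !is.na(obs)
  dropped <- stat_cols[!usable]
  if (length(dropped) > 0)
    warning("dropping degenerate/unusable summary columns: ",
            paste(dropped, collapse = ", "))
  X <- X[, usable, drop = FALSE]
  obs <- obs[usable]
  Z <- sweep(X, 2, mads[usable], "/")
  zo <- obs / mads[usable]
  d2 <- rowSums(sweep(Z, 2, zo, "-")^2, na.rm = TRUE)
  # rows with missing summaries are pushed to the back
  d2[!stats::complete.cases(X)] <- Inf
  sqrt(d2)
}

#' Rejection-based ABC model selection
#'
#' Accepts the `tolerance` fraction of reference simulations nearest to
#' the observed summaries (Euclidean distance on columns standardised by
#' the reference table's median absolute deviation) and estimates each
#' model's posterior probability as its share of accepted simulations.
#'
#' @param observed Named summary vector or one-row tibble (as produced by
#'   [locus_summaries()]).
#' @param table An `abc_reference` from [build_reference_table()].
#' @param tolerance Accepted fraction of simulations.
#' @return An object of class `abc_selection` with `posterior` tibble
#'   (`model`, `n_accepted`, `posterior`), `accepted` row indices,
#'   `tolerance`.  Methods: `tidy()`, `autoplot()`.
#' @export
select_model <- function(observed, table, tolerance = 0.01) {
  d <- abc_distances(observed, table)
  k <- max(1L, ceiling(tolerance * nrow(table)))
  acc <- order(d)[seq_len(k)]
  models <- sort(unique(table$model))
  cnt <- table(factor(table$model[acc], levels = models))
  post <- tibble::tibble(model = models,
                         n_accepted = as.integer(cnt),
                         posterior = as.numeric(cnt) / k)
  structure(list(posterior = post, accepted = acc, tolerance = tolerance),
            class = "abc_selection")
}

#' @export
print.abc_selection <- function(x, ...) {
  cat("<abc_selection> tolerance ", x$tolerance, ", ",
      length(x$accepted), " accepted\n", sep = "")
  print(x$posterior)
  invisible(x)
}

#' @describeIn select_model Posterior probabilities as a tibble.
#' @param x An `abc_selection`.
#' @param ... Unused.
#' @export
tidy.abc_selection <- function(x, ...) x$posterior

#' Rejection-based ABC parameter estimation
#'
#' Restricts the reference table to one model, accepts the nearest
#' `tolerance` fraction of its simulations, and summarises the accepted
#' parameter draws (rejection sampling operates on the standardised
#' summaries; parameters are summarised on the natural scale, with a
#' log10 copy retained in the draws).
#'
#' @inheritParams select_model
#' @param model Model name to restrict to (`NULL` = table already
#'   restricted).
#' @return An `abc_posterior`: `draws` tibble of accepted parameter rows,
#'   `summary` tibble (`param`, `median`, `q025`, `q975`), `tolerance`.
#' @export
estimate_parameters <- function(observed, table, model = NULL,
                                tolerance = 0.01) {
  if (!is.null(model)) table <- table[table$model == model, , drop = FALSE]
  if (nrow(table) == 0) stop("no reference simulations for model")
  d <- abc_distances(observed, table)
  k <- max(1L, ceiling(tolerance * nrow(table)))
  if (k < 20) warning("fewer than 20 accepted draws; posterior summaries ",
                      "will be unstable")
  acc <- order(d)[seq_len(k)]
  par_cols <- grep("^par_", names(table), value = TRUE)
  par_cols <- par_cols[colSums(!is.na(table[par_cols])) > 0]
  draws <- table[acc, par_cols, drop = FALSE]
  names(draws) <- sub("^par_", "", names(draws))
  summ <- dplyr::bind_rows(lapply(names(draws), function(p) {
    v <- draws[[p]]
    tibble::tibble(param = p, median = median(v, na.rm = TRUE),
                   q025 = unname(quantile(v, 0.025, na.rm = TRUE)),
                   q975 = unname(quantile(v, 0.975, na.rm = TRUE)))
  }))
  for (p in names(draws)) draws[[paste0("log10_", p)]] <- log10(draws[[p]])
  structure(list(draws = draws, summary = summ, tolerance = tolerance),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat("<abc_posterior> ", nrow(x$draws), " accepted draws\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @describeIn estimate_parameters Posterior summary as a tibble.
#' @param x An `abc_posterior`.
#' @param ... Unused.
#' @export
tidy.abc_posterior <- function(x, ...) x$summary

#' Validate ABC model selection with pseudo-observed datasets
#'
#' Draws PODs from each model's prior, runs them through [select_model()]
#' against a shared reference table, and tabulates true versus selected
#' (highest-posterior) model.
#'
#' @param models List of [abc_model()] objects.
#' @param n_pods_per_model PODs per model.
#' @param n_sims Reference simulations per model.
#' @param spec A [locus_spec()].
#' @param tolerance Rejection tolerance.
#' @param seed Integer seed.
#' @param table Optional pre-built reference table (rebuilt otherwise).
#' @return List: `confusion` (tibble true x selected counts), `accuracy`
#'   (overall diagonal fraction), `table` (the reference table).
#' @export
pod_validate <- function(models, n_pods_per_model = 20, n_sims = 1000,
                         spec, tolerance = 0.01, seed = 1, table = NULL) {
  if (inherits(models, "abc_model")) models <- list(models)
  if (length(models) < 2) stop("need at least two models")
  if (is.null(table))
    table <- build_reference_table(models, n_sims, spec, seed = seed)
  set.seed(seed + 1)
  rows <- list()
  for (m in models) {
    for (i in seq_len(n_pods_per_model)) {
      vals <- draw_prior(m)
      obs <- simulate_summaries(params_from_draw(m, vals), spec)
      sel <- select_model(obs, table, tolerance)
      top <- sel$posterior$model[which.max(sel$posterior$posterior)]
      rows[[length(rows) + 1]] <- tibble::tibble(true = m$name,
                                                 selected = top)
    }
  }
  res <- dplyr::bind_rows(rows)
  confusion <- dplyr::count(res, .data$true, .data$selected)
  list(confusion = confusion,
       accuracy = mean(res$true == res$selected),
       results = res, table = table)
}

#' Expected migrants per generation (2Nm)
#'
#' Scales a backward migrant fraction `m` by the recipient population's
#' diploid effective size: `2 * N * m` migrant individuals per generation.
#'
#' @param N Diploid effective size (> 0).
#' @param m Per-generation migrant fraction in `[0, 1)`.
#' @return Numeric.
#' @export
scaled_migration <- function(N, m) {
  stopifnot(all(N > 0), all(m >= 0 & m < 1))
  2 * N * m
}

#' Sample ABC loci from a haplotype matrix
#'
#' Tiles each chromosome with candidate loci of `locus_length` bp at
#' `spacing` bp intervals and keeps loci with at least `min_length` bp
#' inside the chromosome and with every variant site called in at least
#' `min_samples` individuals; the survivors are randomly thinned to
#' `n_target` if more are available.
#'
#' @param haps A [hap_matrix] with `chrom_lengths`.
#' @param n_target Desired number of loci (`Inf` keeps all).
#' @param locus_length,spacing,min_length Design in bp.
#' @param min_samples Minimum individuals (not haplotypes) with complete
#'   calls at every variant site of the locus.
#' @param seed Integer seed for the thinning.
#' @return List of [hap_matrix] loci (chromosome names annotated with the
#'   locus span).
#' @export
sample_abc_loci <- function(haps, n_target = Inf, locus_length = 2000,
                            spacing = 125000, min_length = 1000,
                            min_samples = 14, seed = 1) {
  stopifnot(!is.null(haps$chrom_lengths))
  samples <- unique(haps$sample_of_hap)
  loci <- list()
  for (ch in names(haps$chrom_lengths)) {
    len <- haps$chrom_lengths[[ch]]
    starts <- seq(0, max(0, len - 1), by = spacing)
    for (s in starts) {
      e <- min(s + locus_length, len)
      if (e - s < min_length) next
      rows <- window_rows(haps, ch, s, e)
      if (length(rows) > 0) {
        sub <- haps$G[rows, , drop = FALSE]
        # individual called at a site iff both its haplotypes are called
        by_sample <- sapply(samples, function(sm) {
          cols <- which(haps$sample_of_hap == sm)
          rowSums(is.na(sub[, cols, drop = FALSE])) == 0
        })
        if (min(rowSums(by_sample)) < min_samples) next
      }
      l <- if (length(rows) > 0) hap_subset(haps, rows) else
        hap_matrix(character(), integer(),
                   matrix(NA_integer_, 0, ncol(haps$G)),
                   haps$sample_of_hap, haps$pop_of_hap)
      l$chrom_lengths <- setNames(e - s, ch)
      attr(l, "span") <- c(start = s, end = e)
      loci[[length(loci) + 1]] <- l
    }
  }
  if (length(loci) == 0) stop("no loci survive the sampling filters")
  if (is.finite(n_target) && length(loci) > n_target) {
    set.seed(seed)
    loci <- loci[sort(sample(length(loci), n_target))]
  }
  loci
}

#' Summary statistics for a set of loci
#'
#' Computes the 20-statistic ABC summary vector (see
#' [build_reference_table()]) from per-locus haplotype matrices, using the
#' same definitions as the simulation fast path: per-locus totals of
#' nucleotide diversity, Watterson's theta, Tajima's D, haploid
#' Weir-Cockerham FST (ratio of sums) and shared/private polymorphism
#' counts, then means and variances across loci (undefined per-locus
#' values excluded).
#'
#' @param loci List of [hap_matrix] objects.
#' @param pop1,pop2 Population labels.
#' @return One-row tibble with the columns of [summary_stat_names()].
#' @export
locus_summaries <- function(loci, pop1, pop2) {
  if (length(loci) < 2) stop("need at least two loci")
  stats <- t(vapply(loci, function(l) locus_pair_stats(l, pop1, pop2),
                    numeric(10)))
  tibble::as_tibble(as.list(moments_from_locus_stats(stats)))
}

# R-side mirror of the C++ per-locus summary definitions
locus_pair_stats <- function(haps, pop1, pop2) {
  g1 <- haps$G[, hap_cols(haps, pop1), drop = FALSE]
  g2 <- haps$G[, hap_cols(haps, pop2), drop = FALSE]
  one <- function(g) {
    n <- ncol(g)
    nn <- rowSums(!is.na(g))
    d <- rowSums(g == 1, na.rm = TRUE)
    seg <- d > 0 & d < nn
    S <- sum(seg)
    pi_tot <- sum(2 * d[seg] * (nn[seg] - d[seg]) /
                    (nn[seg] * (nn[seg] - 1)))
    list(S = S, pi = pi_tot,
         thetaW = if (n > 1) S / sum(1 / seq_len(n - 1)) else NA_real_,
         tajd = tajd_from_counts(n, S, pi_tot),
         seg = seg)
  }
  s1 <- one(g1)
  s2 <- one(g2)
  comp <- fst_components(g1, g2)
  fst <- if (comp["den"] > 0) unname(comp["num"] / comp["den"]) else NA_real_
  shared <- sum(s1$seg & s2$seg)
  priv1 <- sum(s1$seg & !s2$seg)
  priv2 <- sum(s2$seg & !s1$seg)
  c(s1$pi, s2$pi, s1$thetaW, s2$thetaW, s1$tajd, s2$tajd, fst,
    shared, priv1, priv2)
}
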