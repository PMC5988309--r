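#' Demographic parameters for a two-population divergence model
#'
#' Describes the divergence history of a species pair (population 1 =
#' "Japan Sea"-like focal lineage, population 2 = "Pacific Ocean"-like
#' lineage) under one of five divergence scenarios crossed with three
#' population-size histories for population 1:
#'
#' * `scenario`: `"I"` strict isolation; `"IM"` continuous migration over
#'   `[0, T]`; `"IAM"` migration only in the ancient interval
#'   `[T_anc_stop, T]`; `"IRM"` migration only in the recent interval
#'   `[0, T_rec_start]`; `"IARM"` both intervals.
#' * `growth`: `"constant"`, `"growth"` (exponential change in population 1
#'   from `N_JSB` at `T_G` to `N_JS` at present) or `"bottleneck"`
#'   (population 1 has size `N_JSB` during `[T_G, T]`).
#'
#' Migration rates are backward in time: `m12` is the per-generation
#' probability that a lineage sampled in population 1 derives from
#' population 2 (i.e. the proportion of population 1 that are migrants from
#' population 2).
#'
#' @param scenario One of `"I"`, `"IM"`, `"IAM"`, `"IRM"`, `"IARM"`.
#' @param growth One of `"constant"`, `"growth"`, `"bottleneck"`.
#' @param T Split time in generations.
#' @param T_G Bottleneck/growth onset time in generations (`0 < T_G < T`).
#' @param T_anc_stop Time at which ancient migration ceased (IAM/IARM).
#' @param T_rec_start Time at which recent migration began (IRM/IARM).
#' @param m12,m21 Backward per-generation migrant fractions.
#' @param N_PO,N_JS,N_JSB,N_ANC Diploid effective sizes of population 2,
#'   population 1 (contemporary), population 1 during the
#'   bottleneck/pre-growth phase, and the ancestral population.
#' @param mu Mutation rate per site per generation.
#' @param gen_time Years per generation (used only for reporting).
#'
#' @return A validated object of class `demographic_params`.
#' @export
demographic_params <- function(scenario = c("IM", "I", "IAM", "IRM", "IARM"),
                               growth = c("constant", "growth", "bottleneck"),
                               T, T_G = T / 2, T_anc_stop = NULL,
                               T_rec_start = NULL,
                               m12 = 0, m21 = 0,
                               N_PO, N_JS, N_JSB = N_JS, N_ANC = N_PO,
                               mu = 7.1e-9, gen_time = 1) {
  scenario <- match.arg(scenario)
  growth <- match.arg(growth)
  p <- structure(list(scenario = scenario, growth = growth, T = T, T_G = T_G,
                      T_anc_stop = T_anc_stop, T_rec_start = T_rec_start,
                      m12 = m12, m21 = m21, N_PO = N_PO, N_JS = N_JS,
                      N_JSB = N_JSB, N_ANC = N_ANC, mu = mu,
                      gen_time = gen_time),
                 class = "demographic_params")
  validate_demographic_params(p)
}

validate_demographic_params <- function(p) {
  chk <- function(ok, msg) if (!ok) stop("invalid demographic parameters: ",
                                         msg, call. = FALSE)
  for (nm in c("N_PO", "N_JS", "N_JSB", "N_ANC"))
    chk(is.numeric(p[[nm]]) && p[[nm]] > 0, paste(nm, "must be > 0"))
  chk(p$mu >= 0, "mu must be >= 0")
  chk(p$m12 >= 0 && p$m12 < 1, "0 <= m12 < 1")
  chk(p$m21 >= 0 && p$m21 < 1, "0 <= m21 < 1")
  chk(p$T > 0, "T must be > 0")
  chk(p$T_G > 0 && p$T_G < p$T, "0 < T_G < T")
  if (p$scenario %in% c("IAM", "IARM")) {
    chk(!is.null(p$T_anc_stop) && p$T_anc_stop > 0 && p$T_anc_stop < p$T,
        "0 < T_anc_stop < T required for IAM/IARM")
  }
  if (p$scenario %in% c("IRM", "IARM")) {
    chk(!is.null(p$T_rec_start) && p$T_rec_start > 0 && p$T_rec_start < p$T_G,
        "0 < T_rec_start < T_G required for IRM/IARM")
  }
  if (p$scenario == "I") {
    p$m12 <- 0
    p$m21 <- 0
  }
  p
}

#' Locus sampling design for multi-locus simulation
#'
#' @param n_loci Number of independent loci.
#' @param locus_length Locus length in bp.
#' @param spacing Distance in bp between locus starts (`>= locus_length`);
#'   used when loci are laid out on a chromosome.
#' @param samples_per_pop Integer vector of haplotype counts per population.
#' @return An object of class `locus_spec`.
#' @export
locus_spec <- function(n_loci, locus_length = 2000, spacing = 125000,
                       samples_per_pop = c(20, 20)) {
  stopifnot(n_loci >= 1, locus_length > 0, spacing >= locus_length,
            all(samples_per_pop >= 1))
  structure(list(n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 spacing = as.integer(spacing),
                 samples_per_pop = as.integer(samples_per_pop)),
            class = "locus_spec")
}
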