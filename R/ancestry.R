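#' Select ancestry-informative markers (AIMs)
#'
#' Loci whose absolute allele-frequency difference between two parental
#' reference panels exceeds the threshold (strictly).  Each AIM records
#' which allele is associated with species 2: the allele more frequent in
#' species 2 ("fractional" rule for non-diagnostic AIMs).
#'
#' @param freqs Tibble with one row per locus: columns `p1`, `p2` giving
#'   the frequency of the same reference allele ("allele 1") in species 1
#'   and species 2, plus any identifier columns (kept).
#' @param min_abs_freq_diff Strict threshold on `|p1 - p2|` (default 0.8).
#' @return Tibble of selected loci with `delta` and `species2_allele`
#'   (1 if allele 1 is the species-2-associated allele, 0 otherwise).
#' @export
select_aims <- function(freqs, min_abs_freq_diff = 0.8) {
  stopifnot(min_abs_freq_diff > 0, min_abs_freq_diff <= 1)
  out <- dplyr::mutate(freqs, delta = abs(.data$p1 - .data$p2),
                       species2_allele = ifelse(.data$p2 > .data$p1, 1L, 0L))
  dplyr::filter(out, .data$delta > min_abs_freq_diff)
}

#' Hybrid index and interspecific heterozygosity
#'
#' For each individual, computes at the supplied AIMs:
#' * `h` - hybrid index: proportion of alleles assigned to species 2;
#' * `h_int` - interspecific heterozygosity: proportion of typed AIMs
#'   heterozygous for the two species-associated allele classes.
#'
#' Genotypes are allele-1 dosages (0/1/2, `NA` = untyped); missing loci
#' are excluded from both denominators.  Individuals with no typed AIM are
#' returned with missing values.
#'
#' @param genotypes Integer matrix, individuals x loci, of allele-1
#'   dosages at the AIMs (columns in the order of `aims`).
#' @param aims Tibble from [select_aims()] (uses `species2_allele`).
#' @return Tibble: `sample`, `h`, `h_int`, `n_aims_typed`.
#' @export
ancestry_indices <- function(genotypes, aims) {
  if (ncol(genotypes) != nrow(aims))
    stop("genotype columns must match the AIM table rows")
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- paste0("ind_", seq_len(nrow(genotypes)))
  # dosage of the species-2-associated allele
  s2 <- matrix(rep(aims$species2_allele, each = nrow(genotypes)),
               nrow = nrow(genotypes))
  d2 <- ifelse(s2 == 1L, genotypes, 2L - genotypes)
  typed <- !is.na(d2)
  n_typed <- rowSums(typed)
  h <- ifelse(n_typed > 0, rowSums(d2, na.rm = TRUE) / (2 * n_typed),
              NA_real_)
  het <- d2 == 1L
  h_int <- ifelse(n_typed > 0, rowSums(het, na.rm = TRUE) / n_typed,
                  NA_real_)
  tibble::tibble(sample = ids, h = h, h_int = h_int,
                 n_aims_typed = as.integer(n_typed))
}
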