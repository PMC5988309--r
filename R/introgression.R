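#' Frequency-weighted ABBA-BABA statistics (D and f_d)
#'
#' Site-pattern counts weighted by derived-allele frequencies for the
#' four-taxon tree (((P1, P2), P3), P4) with P4 the outgroup:
#' `abba = sum (1 - p1) p2 p3 (1 - p4)`,
#' `baba = sum p1 (1 - p2) p3 (1 - p4)`,
#' `D = (abba - baba) / (abba + baba)`.  The admixture-fraction estimator
#' `f_d` divides the same numerator by its value under maximal
#' introgression, replacing the donor frequency site-wise with
#' `p_D = max(p2, p3)` (dynamic donor; ties resolve to `p2`).  `f_d` is
#' reported for negative-`D` windows too; such values are not
#' interpretable as admixture proportions and can be masked with
#' `mask_negative_d`.
#'
#' @param p1,p2,p3,p4 Numeric vectors of derived-allele frequencies.
#' @param mask_negative_d Set `fd` to `NA` when `D < 0`?
#' @return One-row tibble: `abba`, `baba`, `d`, `fd`, `n_informative`.
#' @export
d_and_fd <- function(p1, p2, p3, p4, mask_negative_d = FALSE) {
  check_freqs(p1, p2, p3, p4)
  abba <- (1 - p1) * p2 * p3 * (1 - p4)
  baba <- p1 * (1 - p2) * p3 * (1 - p4)
  pD <- pmax(p2, p3)
  abbaD <- (1 - p1) * pD * pD * (1 - p4)
  babaD <- p1 * (1 - pD) * pD * (1 - p4)
  num <- sum(abba) - sum(baba)
  den <- sum(abba) + sum(baba)
  denD <- sum(abbaD) - sum(babaD)
  d <- if (den > 0) num / den else NA_real_
  fd <- if (denD != 0) num / denD else NA_real_
  if (mask_negative_d && !is.na(d) && d < 0) fd <- NA_real_
  tibble::tibble(abba = sum(abba), baba = sum(baba), d = d, fd = fd,
                 n_informative = sum(abba + baba > 0))
}

#' Partitioned five-taxon D statistics
#'
#' For the tree (((P1, P2), (P3_1, P3_2)), O), attributes derived-allele
#' sharing between P2 and the P3 pair to one or both P3 members.  With
#' frequency weights (each including the outgroup factor `1 - pO`):
#' * `D1`: derived in P3_1 only - ABBAA vs BABAA;
#' * `D2`: derived in P3_2 only - ABABA vs BAABA;
#' * `D12`: derived in both - ABBBA vs BABBA.
#'
#' A positive `D12` indicates predominance of gene flow from the P3
#' ancestor into P2.
#'
#' @param p1,p2,p31,p32,pO Frequency vectors.
#' @return One-row tibble with the three statistics and their weighted
#'   pattern sums.
#' @export
partitioned_d <- function(p1, p2, p31, p32, pO) {
  check_freqs(p1, p2, p31, p32, pO)
  w <- (1 - pO)
  abbaa <- (1 - p1) * p2 * p31 * (1 - p32) * w
  babaa <- p1 * (1 - p2) * p31 * (1 - p32) * w
  ababa <- (1 - p1) * p2 * (1 - p31) * p32 * w
  baaba <- p1 * (1 - p2) * (1 - p31) * p32 * w
  abbba <- (1 - p1) * p2 * p31 * p32 * w
  babba <- p1 * (1 - p2) * p31 * p32 * w
  dr <- function(x, y) {
    s <- sum(x) + sum(y)
    if (s > 0) (sum(x) - sum(y)) / s else NA_real_
  }
  tibble::tibble(
    abbaa = sum(abbaa), babaa = sum(babaa), d1 = dr(abbaa, babaa),
    ababa = sum(ababa), baaba = sum(baaba), d2 = dr(ababa, baaba),
    abbba = sum(abbba), babba = sum(babba), d12 = dr(abbba, babba))
}

# D_FOIL pattern groups over (P1, P2, P3, P4); "B" = derived.  DFO/DIL and
# DFI/DOL are mirror pairs under exchanging P1 with P2.
dfoil_groups <- function() {
  list(
    dfo = list(L = c("BABAA", "BBBAA", "ABABA", "AAABA"),
               R = c("BAABA", "BBABA", "ABBAA", "AABAA")),
    dil = list(L = c("ABBAA", "BBBAA", "BAABA", "AAABA"),
               R = c("ABABA", "BBABA", "BABAA", "AABAA")),
    dfi = list(L = c("BABAA", "BABBA", "ABBAA", "ABAAA"),
               R = c("ABBBA", "BAABA", "ABABA", "BAAAA")),
    dol = list(L = c("ABBAA", "ABBBA", "BABAA", "BAAAA"),
               R = c("BABBA", "ABABA", "BAABA", "ABAAA")))
}

# sign signatures of the four components for each introgression event
dfoil_sign_table <- function() {
  tibble::tribble(
    ~event,             ~dfo, ~dil, ~dfi, ~dol,
    "none",                0,    0,    0,    0,
    "ancestral P12<->P3",  1,    1,    0,    0,
    "ancestral P12<->P4", -1,   -1,    0,    0,
    "P3->P1",              1,    0,    1,   -1,
    "P1->P3",              1,    1,    1,    0,
    "P4->P1",             -1,    0,    1,   -1,
    "P1->P4",             -1,   -1,    0,   -1,
    "P3->P2",              0,    1,   -1,    1,
    "P2->P3",              1,    1,    0,    1,
    "P4->P2",              0,   -1,   -1,    1,
    "P2->P4",             -1,   -1,   -1,    0)
}

#' D_FOIL: direction-resolving five-taxon introgression test
#'
#' Computes the four frequency-weighted D_FOIL components for the
#' symmetric tree (((P1, P2), (P3, P4)), O), assuming the P1-P2 split is
#' younger than the P3-P4 split.  Each pattern weight is the product of
#' the per-taxon derived (`p`) or ancestral (`1 - p`) frequencies times
#' the outgroup factor `1 - pO` (a polymorphic outgroup contributes with
#' reduced weight rather than being dropped).  Each component is tested
#' against zero with a chi-squared goodness-of-fit on its left/right
#' weighted sums, and the signed/zero signature of the four components is
#' looked up in the event table covering all eight directed introgressions
#' between \{P1, P2\} and \{P3, P4\} plus the two ancestral exchanges.
#' Signatures matching no event (including all-zero weight) return
#' `"none"`.
#'
#' @param p1,p2,p3,p4,pO Frequency vectors.
#' @param alpha Per-component significance level for the chi-squared test.
#' @return One-row tibble: components `dfo`, `dil`, `dfi`, `dol`, their
#'   left/right sums, per-component significance flags, `n_informative`
#'   and the inferred `event`.
#' @export
dfoil <- function(p1, p2, p3, p4, pO, alpha = 0.01) {
  check_freqs(p1, p2, p3, p4, pO)
  freqs <- list(p1, p2, p3, p4)
  w_out <- 1 - pO
  pattern_weight <- function(pat) {
    w <- w_out
    for (k in 1:4)
      w <- w * (if (substr(pat, k, k) == "B") freqs[[k]] else 1 - freqs[[k]])
    w
  }
  out <- tibble::tibble(.rows = 1)
  signs <- integer(4)
  comps <- names(dfoil_groups())
  for (i in seq_along(comps)) {
    gr <- dfoil_groups()[[i]]
    L <- sum(vapply(gr$L, function(p) sum(pattern_weight(p)), 0))
    R <- sum(vapply(gr$R, function(p) sum(pattern_weight(p)), 0))
    tot <- L + R
    val <- if (tot > 0) (L - R) / tot else NA_real_
    pval <- if (tot > 0) pchisq((L - R)^2 / tot, df = 1,
                                lower.tail = FALSE) else NA_real_
    sig <- !is.na(pval) && pval < alpha
    signs[i] <- if (sig) sign(L - R) else 0L
    out[[comps[i]]] <- val
    out[[paste0(comps[i], "_left")]] <- L
    out[[paste0(comps[i], "_right")]] <- R
    out[[paste0(comps[i], "_sig")]] <- sig
  }
  tab <- dfoil_sign_table()
  hit <- tab$event[tab$dfo == signs[1] & tab$dil == signs[2] &
                     tab$dfi == signs[3] & tab$dol == signs[4]]
  out$event <- if (length(hit) == 1) hit else "none"
  out$n_informative <- sum(Reduce(`+`, lapply(
    unlist(lapply(dfoil_groups(), function(g) c(g$L, g$R))),
    pattern_weight)) > 0)
  out
}

#' Windowed site-pattern scan
#'
#' Applies [d_and_fd()], [partitioned_d()] or [dfoil()] to non-overlapping
#' windows of a per-site frequency table.
#'
#' @param freqs Tibble with columns `chrom`, `pos` and one derived-allele
#'   frequency column per population, e.g. from [pop_allele_freqs()].
#' @param mode One of `"fd"`, `"partd"`, `"dfoil"`.
#' @param pops Character vector naming the frequency columns in the role
#'   order of the chosen statistic (4 for `"fd"`, 5 ending in the outgroup
#'   for the others).
#' @param size Window size in bp (the direction statistics default to
#'   100-kb windows in chromosome-scale practice).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param ... Passed to the statistic function.
#' @return Tibble with window coordinates and the statistic's columns.
#' @export
dstat_windows <- function(freqs, mode = c("fd", "partd", "dfoil"), pops,
                          size = 100000, chrom_lengths, ...) {
  mode <- match.arg(mode)
  need <- if (mode == "fd") 4L else 5L
  stopifnot(length(pops) == need, all(pops %in% names(freqs)))
  fun <- switch(mode, fd = d_and_fd, partd = partitioned_d, dfoil = dfoil)
  res <- list()
  for (ch in names(chrom_lengths)) {
    wins <- iter_windows(chrom_lengths[[ch]], window_config(size, size, 0))
    if (nrow(wins) == 0) next
    wins$chrom <- ch
    rows <- lapply(seq_len(nrow(wins)), function(i)
      freqs$chrom == ch & freqs$pos > wins$start[i] &
        freqs$pos <= wins$end[i])
    stats <- lapply(rows, function(r) {
      args <- lapply(pops, function(p) freqs[[p]][r])
      do.call(fun, c(args, list(...)))
    })
    res[[ch]] <- dplyr::bind_cols(wins[, c("chrom", "start", "end")],
                                  dplyr::bind_rows(stats))
  }
  dplyr::bind_rows(res)
}

check_freqs <- function(...) {
  fs <- list(...)
  n <- unique(lengths(fs))
  if (length(n) != 1)
    stop("frequency vectors must have equal length", call. = FALSE)
  for (f in fs)
    if (any(f < 0 | f > 1, na.rm = TRUE))
      stop("frequencies must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}
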