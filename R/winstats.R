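#' Weir-Cockerham FST for two populations
#'
#' Multi-site Weir-Cockerham variance-component estimator combined as the
#' ratio of summed components (not the mean of per-site ratios).  On a
#' [hap_matrix] the haploid form of the estimator is used, treating each
#' haplotype as an allele drawn from its population; the estimate can be
#' slightly negative when differentiation is absent.
#'
#' @param haps A [hap_matrix].
#' @param pop1,pop2 Population labels.
#' @param chrom,start,end Optional window restriction (0-based half-open).
#' @return A single numeric value (`NA` when no usable site contributes).
#' @export
wc_fst <- function(haps, pop1, pop2, chrom = NULL, start = NULL, end = NULL) {
  rows <- if (is.null(chrom)) seq_along(haps$pos) else
    window_rows(haps, chrom, start, end)
  g1 <- haps$G[rows, hap_cols(haps, pop1), drop = FALSE]
  g2 <- haps$G[rows, hap_cols(haps, pop2), drop = FALSE]
  comp <- fst_components(g1, g2)
  if (comp["den"] <= 0) return(NA_real_)
  unname(comp["num"] / comp["den"])
}

# summed haploid Weir-Cockerham components over sites (vectorised)
fst_components <- function(g1, g2) {
  n1 <- rowSums(!is.na(g1))
  n2 <- rowSums(!is.na(g2))
  d1 <- rowSums(g1 == 1, na.rm = TRUE)
  d2 <- rowSums(g2 == 1, na.rm = TRUE)
  ok <- n1 > 0 & n2 > 0
  dtot <- d1 + d2
  ok <- ok & dtot > 0 & dtot < (n1 + n2)  # polymorphic overall
  if (!any(ok)) return(c(num = 0, den = 0))
  n1 <- n1[ok]; n2 <- n2[ok]
  p1 <- d1[ok] / n1; p2 <- d2[ok] / n2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2)
  c(num = sum(a), den = sum(a + b))
}

#' Absolute divergence and the minimum-haplotype ratio G_MIN
#'
#' `dxy` is the mean over all inter-population haplotype pairs of the
#' per-usable-site difference proportion; `dxy_min` is the minimum over
#' pairs and `gmin = dxy_min / dxy`.  Missing sites are excluded pairwise
#' (each haplotype pair has its own usable-site denominator).  A `gmin`
#' near 0 marks a pair of haplotypes far more similar than the window
#' average - the signature of a recent migrant haplotype.
#'
#' @inheritParams wc_fst
#' @param n_usable Optional denominator for per-site scaling; defaults to
#'   the number of variant sites with complete-enough data in the window.
#'   Supply the window's usable-site count (including invariant sites) to
#'   obtain per-base-pair divergence.
#' @return One-row tibble: `dxy`, `dxy_min`, `gmin`, `min_pair`,
#'   `n_usable`.  All statistics `NA` (with `gmin` flagged) if no usable
#'   sites.
#' @export
dxy_stats <- function(haps, pop1, pop2, chrom = NULL, start = NULL,
                      end = NULL, n_usable = NULL) {
  rows <- if (is.null(chrom)) seq_along(haps$pos) else
    window_rows(haps, chrom, start, end)
  i1 <- hap_cols(haps, pop1)
  i2 <- hap_cols(haps, pop2)
  g1 <- haps$G[rows, i1, drop = FALSE]
  g2 <- haps$G[rows, i2, drop = FALSE]
  dm <- pair_diff_matrix(g1, g2)
  S <- dm$sites
  nu <- if (is.null(n_usable)) S else n_usable
  # per-pair usable denominator: usable sites minus variant sites at which
  # the pair is not jointly called (invariant positions count as callable)
  pair_nu <- nu - (S - dm$denom)
  if (nu <= 0 || all(pair_nu <= 0))
    return(tibble::tibble(dxy = NA_real_, dxy_min = NA_real_,
                          gmin = NA_real_, min_pair = NA_character_,
                          n_usable = nu))
  ok <- pair_nu > 0
  dist <- matrix(NA_real_, nrow(dm$diff), ncol(dm$diff))
  dist[ok] <- dm$diff[ok] / pair_nu[ok]
  dxy <- mean(dist[ok])
  mn <- min(dist[ok])
  # lexicographically smallest pair attaining the minimum
  hit <- which(!is.na(dist) & dist == mn, arr.ind = TRUE)
  nm1 <- colnames(haps$G)[i1][hit[, 1]]
  nm2 <- colnames(haps$G)[i2][hit[, 2]]
  k <- order(nm1, nm2)[1]
  pair <- paste(nm1[k], nm2[k], sep = "|")
  tibble::tibble(dxy = dxy, dxy_min = mn,
                 gmin = if (dxy > 0) mn / dxy else NA_real_,
                 min_pair = pair, n_usable = nu)
}

# pairwise difference counts between haplotype sets with pairwise-complete
# denominators
pair_diff_matrix <- function(g1, g2) {
  a1 <- !is.na(g1); a2 <- !is.na(g2)
  x1 <- ifelse(a1, g1, 0); x2 <- ifelse(a2, g2, 0)
  diff <- t(x1) %*% (a2 * (1 - x2)) + t(a1 * (1 - x1)) %*% x2
  denom <- t(a1 * 1) %*% (a2 * 1)
  list(diff = diff, denom = denom, sites = nrow(g1),
       mean_denom = if (length(denom) > 0 && any(denom > 0))
         mean(denom[denom > 0]) else 0)
}

#' Nucleotide diversity within a population
#'
#' Mean pairwise difference per site (unbiased per-site estimator summed
#' over variant sites, divided by `n_usable`).
#'
#' @inheritParams wc_fst
#' @param pop Population label.
#' @param n_usable Optional site denominator (see [dxy_stats()]).
#' @return Numeric.
#' @export
pi_within <- function(haps, pop, chrom = NULL, start = NULL, end = NULL,
                      n_usable = NULL) {
  rows <- if (is.null(chrom)) seq_along(haps$pos) else
    window_rows(haps, chrom, start, end)
  g <- haps$G[rows, hap_cols(haps, pop), drop = FALSE]
  nn <- rowSums(!is.na(g))
  d <- rowSums(g == 1, na.rm = TRUE)
  ok <- nn > 1
  tot <- sum(2 * d[ok] * (nn[ok] - d[ok]) / (nn[ok] * (nn[ok] - 1)))
  nu <- if (is.null(n_usable)) sum(ok) else n_usable
  if (nu <= 0) return(NA_real_)
  tot / nu
}

#' Tajima's D for one population
#'
#' Standard normalised difference between mean pairwise diversity and
#' Watterson's estimator, using the canonical a1, a2, b1, b2, c1, c2, e1,
#' e2 constants.  Sites with missing haplotypes contribute through their
#' non-missing calls; the constants use the full haplotype count.
#' Windows with zero segregating sites return `NA` (flagged missing, not
#' zero).
#'
#' @inheritParams pi_within
#' @return Numeric (`NA` if fewer than 4 haplotypes or no variation).
#' @export
tajimas_d <- function(haps, pop, chrom = NULL, start = NULL, end = NULL) {
  rows <- if (is.null(chrom)) seq_along(haps$pos) else
    window_rows(haps, chrom, start, end)
  g <- haps$G[rows, hap_cols(haps, pop), drop = FALSE]
  n <- ncol(g)
  if (n < 4) return(NA_real_)
  nn <- rowSums(!is.na(g))
  d <- rowSums(g == 1, na.rm = TRUE)
  seg <- d > 0 & d < nn
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pi_tot <- sum(2 * d[seg] * (nn[seg] - d[seg]) /
                  (nn[seg] * (nn[seg] - 1)))
  tajd_from_counts(n, S, pi_tot)
}

tajd_from_counts <- function(n, S, pi_tot) {
  if (S <= 0 || n < 4) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  den <- sqrt(e1 * S + e2 * S * (S - 1))
  if (den <= 0) return(NA_real_)
  (pi_tot - S / a1) / den
}

#' Windowed divergence and diversity scan
#'
#' Computes the per-window statistic set over non-overlapping (or stepped)
#' windows of every chromosome in the haplotype matrix.  A window's usable
#' sites are all its positions minus variant sites whose call rate falls
#' below `min_call_frac` (invariant positions are assumed callable, as in
#' consensus-call data); windows with fewer than
#' `cfg$min_usable_sites` usable sites are listed with missing statistics.
#'
#' @param haps A [hap_matrix] with `chrom_lengths` set.
#' @param pop1,pop2 The two focal population labels.
#' @param cfg A [window_config()].
#' @param which Statistics to compute: subset of
#'   `c("fst", "dxy", "pi", "tajd")`.
#' @param min_call_frac Minimum fraction of called haplotypes for a variant
#'   site to count as usable.
#' @return Tibble with one row per window: `chrom`, `start`, `end`,
#'   `n_usable`, `fst`, `dxy`, `dxy_min`, `gmin`, `min_pair`, `pi_1`,
#'   `pi_2`, `tajd_1`, `tajd_2` (per the requested set).
#' @export
scan_windows <- function(haps, pop1, pop2, cfg = window_config(),
                         which = c("fst", "dxy", "pi", "tajd"),
                         min_call_frac = 0.5) {
  stopifnot(!is.null(haps$chrom_lengths))
  res <- list()
  for (ch in names(haps$chrom_lengths)) {
    wins <- iter_windows(haps$chrom_lengths[[ch]], cfg)
    if (nrow(wins) == 0) next
    wins$chrom <- ch
    on_ch <- haps$chrom == ch
    call_frac <- rowMeans(!is.na(haps$G))
    low_call <- on_ch & call_frac < min_call_frac
    rows_list <- lapply(seq_len(nrow(wins)), function(i)
      which(on_ch & haps$pos > wins$start[i] & haps$pos <= wins$end[i]))
    n_low <- vapply(seq_len(nrow(wins)), function(i)
      sum(low_call[rows_list[[i]]]), 0L)
    wins$n_usable <- as.integer(cfg$size - n_low)
    stats <- lapply(seq_len(nrow(wins)), function(i) {
      out <- tibble::tibble(.rows = 1)
      eligible <- wins$n_usable[i] >= cfg$min_usable_sites
      rows <- setdiff(rows_list[[i]], which(low_call))
      sub <- if (length(rows) > 0) hap_subset(haps, rows) else NULL
      if ("fst" %in% which)
        out$fst <- if (eligible && !is.null(sub))
          wc_fst(sub, pop1, pop2) else NA_real_
      if ("dxy" %in% which) {
        if (eligible && !is.null(sub)) {
          dd <- dxy_stats(sub, pop1, pop2, n_usable = wins$n_usable[i])
          out$dxy <- dd$dxy; out$dxy_min <- dd$dxy_min
          out$gmin <- dd$gmin; out$min_pair <- dd$min_pair
        } else {
          out$dxy <- NA_real_; out$dxy_min <- NA_real_
          out$gmin <- NA_real_; out$min_pair <- NA_character_
        }
      }
      if ("pi" %in% which) {
        out$pi_1 <- if (eligible && !is.null(sub))
          pi_within(sub, pop1, n_usable = wins$n_usable[i]) else NA_real_
        out$pi_2 <- if (eligible && !is.null(sub))
          pi_within(sub, pop2, n_usable = wins$n_usable[i]) else NA_real_
      }
      if ("tajd" %in% which) {
        out$tajd_1 <- if (eligible && !is.null(sub))
          tajimas_d(sub, pop1) else NA_real_
        out$tajd_2 <- if (eligible && !is.null(sub))
          tajimas_d(sub, pop2) else NA_real_
      }
      out
    })
    res[[ch]] <- dplyr::bind_cols(wins[, c("chrom", "start", "end",
                                           "n_usable")],
                                  dplyr::bind_rows(stats))
  }
  dplyr::bind_rows(res)
}
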