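#' Interpolate per-window recombination rates from a marker map
#'
#' Evaluates the cumulative genetic map (piecewise-linear between markers)
#' at each window's bounds and converts to a rate
#' `rho = delta_cM / (delta_bp / 1e6)` in cM/Mb.  Windows beyond the
#' terminal markers extend the terminal segment's slope (rather than a
#' zero rate).
#'
#' @param map Tibble with columns `chrom`, `pos_bp`, `cum_cM` (sorted or
#'   not; `cum_cM` must be non-decreasing in `pos_bp` per chromosome, with
#'   at least two markers per chromosome).
#' @param windows Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return `windows` with an added `rho` column (cM/Mb; `NA` when the
#'   chromosome is absent from the map).
#' @export
interpolate_window_rates <- function(map, windows) {
  out <- windows
  out$rho <- NA_real_
  for (ch in unique(windows$chrom)) {
    m <- map[map$chrom == ch, , drop = FALSE]
    sel <- windows$chrom == ch
    if (nrow(m) < 2) next
    m <- m[order(m$pos_bp), , drop = FALSE]
    if (any(diff(m$cum_cM) < 0))
      stop("cum_cM must be non-decreasing on chromosome ", ch)
    cm_at <- function(x) {
      y <- numeric(length(x))
      inside <- x >= m$pos_bp[1] & x <= m$pos_bp[nrow(m)]
      if (any(inside))
        y[inside] <- stats::approx(m$pos_bp, m$cum_cM, x[inside],
                                   ties = "ordered")$y
      lo <- x < m$pos_bp[1]
      if (any(lo)) {
        s <- (m$cum_cM[2] - m$cum_cM[1]) / (m$pos_bp[2] - m$pos_bp[1])
        y[lo] <- m$cum_cM[1] + (x[lo] - m$pos_bp[1]) * s
      }
      hi <- x > m$pos_bp[nrow(m)]
      if (any(hi)) {
        k <- nrow(m)
        s <- (m$cum_cM[k] - m$cum_cM[k - 1]) / (m$pos_bp[k] - m$pos_bp[k - 1])
        y[hi] <- m$cum_cM[k] + (x[hi] - m$pos_bp[k]) * s
      }
      y
    }
    d_cm <- cm_at(windows$end[sel]) - cm_at(windows$start[sel])
    d_mb <- (windows$end[sel] - windows$start[sel]) / 1e6
    out$rho[sel] <- pmax(d_cm / d_mb, 0)
  }
  out
}

#' Correlate recombination rate with a scan statistic
#'
#' Pearson correlation over pairwise-complete windows, with an optional
#' log10 transform of the rate (zero-rate windows are dropped under the
#' log).  The p-value uses the t approximation of [stats::cor.test()].
#'
#' @param rho Per-window recombination rates (cM/Mb).
#' @param stat Per-window statistic values, same length.
#' @param log10_rate Correlate against `log10(rho)`?
#' @return Tibble: `r`, `p_value`, `n`.
#' @export
correlate_with_stat <- function(rho, stat, log10_rate = FALSE) {
  stopifnot(length(rho) == length(stat))
  x <- rho
  if (log10_rate) {
    drop <- !is.na(x) & x <= 0
    x[drop] <- NA
    x <- log10(x)
  }
  ok <- !is.na(x) & !is.na(stat)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  ct <- cor.test(x[ok], stat[ok], method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = sum(ok))
}
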