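#' Two-state Gaussian HMM configuration for valley/peak detection
#'
#' Transition probabilities are initialised symmetric with an emphasis on
#' staying in a state (stay 0.9, switch 0.1); the chain starts in the
#' background state since outlier windows are rare.  G_MIN tracks are
#' logit transformed; f_d tracks are used untransformed.
#'
#' @param target `"valley"` (the interesting state has the lower emission
#'   mean, as for G_MIN) or `"peak"` (higher mean, as for f_d).
#' @param p_stay,p_switch Initial transition probabilities (must sum to 1).
#' @param transform `"identity"` or `"logit"`; logit inputs are clamped
#'   into (0, 1) at `eps`.
#' @param max_iter,tol Baum-Welch iteration cap and log-likelihood
#'   convergence tolerance.
#' @param eps Clamping margin for the logit transform.
#' @return An object of class `hmm_config`.
#' @export
hmm_config <- function(target = c("valley", "peak"), p_stay = 0.9,
                       p_switch = 0.1, transform = c("identity", "logit"),
                       max_iter = 500, tol = 1e-6, eps = 1e-6) {
  target <- match.arg(target)
  transform <- match.arg(transform)
  stopifnot(abs(p_stay + p_switch - 1) < 1e-12, p_stay > 0, p_switch > 0)
  structure(list(target = target, p_stay = p_stay, p_switch = p_switch,
                 transform = transform, max_iter = max_iter, tol = tol,
                 eps = eps),
            class = "hmm_config")
}

#' Classify windows into background and valley/peak states with an HMM
#'
#' Fits a two-state Gaussian hidden Markov model to a window-statistic
#' track by Baum-Welch (scaled forward-backward), then decodes the state
#' sequence with the Viterbi algorithm.  Missing-value windows are carried
#' as emission-free gaps: they contribute no emission likelihood but the
#' chain still transitions through them, and they receive a decoded state.
#' Emission means/SDs are initialised from the empirical distribution
#' (background at the median of the non-target half, target at the 5% or
#' 95% tail).
#'
#' @param values Numeric vector of the per-window statistic (may contain
#'   `NA`), in genomic order.
#' @param cfg An [hmm_config()].
#' @return An object of class `hmm_fit`: `state` (factor `background` /
#'   target per window), `params` (tibble of per-state mean/sd), the
#'   fitted transition matrix, `loglik`, `n_iter`, `converged`.  Methods:
#'   [tidy.hmm_fit()], [glance.hmm_fit()], [autoplot.hmm_fit()].
#' @export
fit_hmm_classify <- function(values, cfg = hmm_config("valley")) {
  x <- values
  if (cfg$transform == "logit") {
    x <- pmin(pmax(x, cfg$eps), 1 - cfg$eps)
    x <- log(x / (1 - x))
  }
  obs <- !is.na(x)
  if (sum(obs) < 2) stop("need at least two windows with defined values")
  n <- length(x)
  lab_target <- cfg$target
  # initial emissions from the empirical distribution
  q <- if (lab_target == "valley") quantile(x[obs], c(0.05, 0.6)) else
    quantile(x[obs], c(0.95, 0.4))
  mu <- c(background = unname(q[2]), target = unname(q[1]))
  sg <- rep(max(sd(x[obs]), 1e-8), 2)
  A <- matrix(c(cfg$p_stay, cfg$p_switch, cfg$p_switch, cfg$p_stay), 2, 2,
              byrow = TRUE)
  init <- c(1, 0)  # start in background
  emis <- function(mu, sg) {
    B <- matrix(1, n, 2)
    B[obs, 1] <- dnorm(x[obs], mu[1], sg[1])
    B[obs, 2] <- dnorm(x[obs], mu[2], sg[2])
    pmax(B, 1e-300)
  }
  loglik_old <- -Inf
  converged <- FALSE
  it <- 0
  while (it < cfg$max_iter) {
    it <- it + 1
    B <- emis(mu, sg)
    # scaled forward-backward
    alpha <- matrix(0, n, 2)
    cscale <- numeric(n)
    a <- init * B[1, ]
    cscale[1] <- sum(a)
    alpha[1, ] <- a / cscale[1]
    for (t in 2:n) {
      a <- (alpha[t - 1, ] %*% A) * B[t, ]
      cscale[t] <- sum(a)
      alpha[t, ] <- a / cscale[t]
    }
    beta <- matrix(0, n, 2)
    beta[n, ] <- 1
    for (t in (n - 1):1)
      beta[t, ] <- (A %*% (B[t + 1, ] * beta[t + 1, ])) / cscale[t + 1]
    loglik <- sum(log(cscale))
    gamma <- alpha * beta
    gamma <- gamma / rowSums(gamma)
    # transition expectations
    xi_num <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2) {
      xi_num[i, j] <- sum(alpha[-n, i] * A[i, j] * B[-1, j] *
                            beta[-1, j] / cscale[-1])
    }
    A_new <- xi_num / rowSums(xi_num)
    w <- gamma[obs, , drop = FALSE]
    mu_new <- colSums(w * x[obs]) / colSums(w)
    sg_new <- sqrt(colSums(w * (x[obs] - rep(mu_new, each = nrow(w)))^2) /
                     colSums(w))
    sg_new <- pmax(sg_new, 1e-8)
    if (is.finite(loglik) && abs(loglik - loglik_old) < cfg$tol) {
      converged <- TRUE
      loglik_old <- loglik
      break
    }
    loglik_old <- loglik
    A <- A_new
    mu <- mu_new
    sg <- sg_new
  }
  if (!converged)
    warning("Baum-Welch did not converge in ", cfg$max_iter,
            " iterations; returning last iterate")
  # Viterbi decode (log space)
  B <- emis(mu, sg)
  lA <- log(A)
  delta <- matrix(-Inf, n, 2)
  psi <- matrix(0L, n, 2)
  delta[1, ] <- log(pmax(init, 1e-300)) + log(B[1, ])
  for (t in 2:n) for (j in 1:2) {
    cand <- delta[t - 1, ] + lA[, j]
    psi[t, j] <- which.max(cand)
    delta[t, j] <- max(cand) + log(B[t, j])
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  # state 2 was initialised at the target tail; after fitting, identify the
  # target state by its mean (lower for valleys, higher for peaks).  When
  # the two fitted states have collapsed onto one emission distribution
  # there is no target state and the whole track is background.
  target_state <- if (lab_target == "valley") which.min(mu) else which.max(mu)
  degenerate <- abs(mu[1] - mu[2]) < 1e-9 * max(1, abs(mu[1]))
  state <- factor(ifelse(!degenerate & path == target_state, lab_target,
                         "background"),
                  levels = c("background", lab_target))
  structure(list(
    state = state,
    params = tibble::tibble(state = c("background", lab_target),
                            mean = mu[c(3 - target_state, target_state)],
                            sd = sg[c(3 - target_state, target_state)]),
    transition = A, loglik = loglik_old, n_iter = it,
    converged = converged, cfg = cfg, values = values),
    class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("<hmm_fit> ", length(x$state), " windows, ",
      sum(x$state != "background"), " in the ",
      levels(x$state)[2], " state\n", sep = "")
  cat("  loglik ", format(x$loglik), "; iterations ", x$n_iter,
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}

#' @describeIn fit_hmm_classify Tidy per-state emission parameters.
#' @param x,object An `hmm_fit`.
#' @param ... Unused.
#' @export
tidy.hmm_fit <- function(x, ...) x$params

#' @describeIn fit_hmm_classify One-row model summary.
#' @export
glance.hmm_fit <- function(x, ...)
  tibble::tibble(loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged,
                 n_windows = length(x$state),
                 n_target = sum(x$state != "background"))

#' Merge outlier windows into valleys or peaks
#'
#' Clusters outlier windows whose gaps are at most `gap` bp (default
#' 30 kb) into intervals spanning the first start to the last end, per
#' chromosome.  Carries the extreme statistic and, when present, the
#' haplotype pair attaining the minimum divergence.
#'
#' @param windows Tibble of outlier windows with columns `chrom`, `start`,
#'   `end` and optionally a statistic column and `min_pair`.
#' @param gap Maximum gap in bp for windows to be merged.
#' @param stat Name of the statistic column to summarise (optional).
#' @param extreme `"min"` (valleys) or `"max"` (peaks).
#' @return A `valley_set` tibble: `chrom`, `start`, `end`, `n_windows`,
#'   `length`, `stat_extreme`, `min_pair` (of the extreme window).
#' @export
cluster_outlier_windows <- function(windows, gap = 30000, stat = NULL,
                                    extreme = c("min", "max")) {
  extreme <- match.arg(extreme)
  if (nrow(windows) == 0)
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_windows = integer(),
                          length = integer(), stat_extreme = numeric(),
                          min_pair = character()))
  w <- dplyr::arrange(windows, .data$chrom, .data$start)
  res <- list()
  for (ch in unique(w$chrom)) {
    ww <- w[w$chrom == ch, , drop = FALSE]
    new_run <- c(TRUE, ww$start[-1] - ww$end[-nrow(ww)] > gap)
    run <- cumsum(new_run)
    for (r in unique(run)) {
      sub <- ww[run == r, , drop = FALSE]
      sv <- if (!is.null(stat)) sub[[stat]] else NA_real_
      k <- if (!is.null(stat) && any(!is.na(sv))) {
        if (extreme == "min") which.min(sv) else which.max(sv)
      } else 1L
      res[[length(res) + 1]] <- tibble::tibble(
        chrom = ch, start = min(sub$start), end = max(sub$end),
        n_windows = nrow(sub),
        length = max(sub$end) - min(sub$start),
        stat_extreme = if (!is.null(stat)) sv[k] else NA_real_,
        min_pair = if ("min_pair" %in% names(sub))
          sub$min_pair[k] else NA_character_)
    }
  }
  out <- dplyr::arrange(dplyr::bind_rows(res), .data$chrom, .data$start)
  class(out) <- c("valley_set", class(out))
  out
}

#' Permutation null thresholds for G_MIN valleys
#'
#' Generates a chromosome-specific null for the windowed G_MIN statistic
#' by jointly permuting the order of variant-site columns within each
#' chromosome (preserving every per-site allele configuration while
#' destroying spatial order), re-running the window scan, and pooling the
#' permuted values into usable-site bins.  The lower-tail cutoff is the
#' 1st percentile of each bin's pooled null ("lower 99 percentile" rule).
#'
#' @param haps A [hap_matrix] with `chrom_lengths`.
#' @param pop1,pop2 Population labels.
#' @param cfg A [window_config()].
#' @param n_perm Number of permutations.
#' @param bins Numeric breaks for usable-site bins; defaults to 11 bins
#'   from `cfg$min_usable_sites - 1` to `cfg$size`.
#' @param seed Integer seed.
#' @param percentile Lower-tail percentile (0.01).
#' @return Tibble: `bin_lo`, `bin_hi`, `cutoff`, `n_values`.
#' @export
permutation_threshold <- function(haps, pop1, pop2, cfg = window_config(),
                                  n_perm = 100, bins = NULL, seed = 1,
                                  percentile = 0.01) {
  if (is.null(bins))
    bins <- seq(cfg$min_usable_sites - 1, cfg$size, length.out = 12)
  set.seed(seed)
  vals <- list()
  for (k in seq_len(n_perm)) {
    perm <- haps
    for (ch in unique(haps$chrom)) {
      idx <- which(haps$chrom == ch)
      perm$G[idx, ] <- haps$G[idx[sample(length(idx))], ]
    }
    sc <- scan_windows(perm, pop1, pop2, cfg, which = "dxy")
    vals[[k]] <- sc[, c("n_usable", "gmin")]
  }
  pooled <- dplyr::bind_rows(vals)
  pooled <- pooled[!is.na(pooled$gmin), , drop = FALSE]
  out <- tibble::tibble(bin_lo = head(bins, -1), bin_hi = tail(bins, -1))
  out$cutoff <- NA_real_
  out$n_values <- 0L
  for (i in seq_len(nrow(out))) {
    sel <- pooled$n_usable > out$bin_lo[i] & pooled$n_usable <= out$bin_hi[i]
    out$n_values[i] <- sum(sel)
    if (any(sel))
      out$cutoff[i] <- unname(quantile(pooled$gmin[sel], percentile))
  }
  out
}

#' Permutation test for a difference in group means
#'
#' Label-permutation test of the difference in means between two groups of
#' window statistics, with add-one correction
#' `p = (b + 1) / (n_perm + 1)`.
#'
#' @param a,b Numeric vectors (NA dropped).
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @param alternative `"two.sided"`, `"greater"` (mean(a) > mean(b)) or
#'   `"less"`.
#' @return Tibble: `statistic` (mean(a) - mean(b)), `p_value`, `n_perm`.
#' @export
permutation_independence_test <- function(a, b, n_perm = 10000, seed = 1,
                                          alternative = c("two.sided",
                                                          "greater",
                                                          "less")) {
  alternative <- match.arg(alternative)
  if (n_perm < 1) stop("n_perm must be >= 1")
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  obs <- mean(a) - mean(b)
  pool <- c(a, b)
  na <- length(a)
  set.seed(seed)
  null <- replicate(n_perm, {
    idx <- sample(length(pool), na)
    mean(pool[idx]) - mean(pool[-idx])
  })
  extreme <- switch(alternative,
                    two.sided = sum(abs(null) >= abs(obs)),
                    greater = sum(null >= obs),
                    less = sum(null <= obs))
  tibble::tibble(statistic = obs,
                 p_value = (extreme + 1) / (n_perm + 1),
                 n_perm = n_perm)
}

#' Gene-overlap enrichment of valleys against matched random windows
#'
#' Counts the unique genes overlapping any valley by at least 1 bp and
#' compares against a null distribution built from random placements of
#' equally many, equally sized runs of non-valley windows.
#'
#' @param valleys A `valley_set` tibble (`chrom`, `start`, `end`).
#' @param genes Tibble of gene intervals (`chrom`, `start`, `end`,
#'   optional `name`), 0-based half-open.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window_size Width of the underlying scan windows.
#' @param n_draws Number of null draws.
#' @param seed Integer seed.
#' @return List: `observed`, `null` (numeric vector), `p_value`
#'   (add-one-corrected fraction of draws >= observed).
#' @export
gene_overlap_enrichment <- function(valleys, genes, chrom_lengths,
                                    window_size = 10000, n_draws = 1000,
                                    seed = 1) {
  if (is.null(genes$name)) genes$name <- paste0("gene_", seq_len(nrow(genes)))
  count_genes <- function(iv) {
    if (nrow(iv) == 0) return(0L)
    hit <- logical(nrow(genes))
    for (i in seq_len(nrow(iv))) {
      hit <- hit | (genes$chrom == iv$chrom[i] &
                      genes$start < iv$end[i] & genes$end > iv$start[i])
    }
    length(unique(genes$name[hit]))
  }
  observed <- count_genes(valleys)
  # grid of candidate (non-valley) windows per chromosome
  grid <- dplyr::bind_rows(lapply(names(chrom_lengths), function(ch) {
    w <- iter_windows(chrom_lengths[[ch]], window_config(window_size,
                                                         window_size, 0))
    w$chrom <- ch
    w
  }))
  in_valley <- logical(nrow(grid))
  for (i in seq_len(nrow(valleys)))
    in_valley <- in_valley | (grid$chrom == valleys$chrom[i] &
                                grid$start < valleys$end[i] &
                                grid$end > valleys$start[i])
  free <- grid[!in_valley, , drop = FALSE]
  lens <- pmax(1L, as.integer(round((valleys$end - valleys$start) /
                                      window_size)))
  # precompute, per required run length, the indices of `free` where a run
  # of k consecutive non-valley windows starts
  contiguous <- c(diff(free$start) == window_size &
                    free$chrom[-1] == free$chrom[-nrow(free)], FALSE)
  run_starts <- function(k) {
    n <- nrow(free)
    if (k == 1) return(seq_len(n))
    if (n < k) return(integer(0))
    which(vapply(seq_len(n - k + 1), function(j)
      all(contiguous[j:(j + k - 2)]), TRUE))
  }
  starts_by_k <- lapply(sort(unique(lens)), run_starts)
  names(starts_by_k) <- sort(unique(lens))
  if (any(lengths(starts_by_k) == 0))
    stop("insufficient non-valley territory to sample a matched run")
  set.seed(seed)
  null <- vapply(seq_len(n_draws), function(d) {
    iv <- lapply(lens, function(k) {
      ok <- starts_by_k[[as.character(k)]]
      j <- ok[sample.int(length(ok), 1)]
      tibble::tibble(chrom = free$chrom[j], start = free$start[j],
                     end = free$start[j] + k * window_size)
    })
    count_genes(dplyr::bind_rows(iv))
  }, 0L)
  list(observed = observed, null = null,
       p_value = (sum(null >= observed) + 1) / (n_draws + 1))
}
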