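# shared helpers for the test suite

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# tiny hap_matrix from a sites x haplotypes matrix
toy_haps <- function(G, pops, chrom = "chr1", pos = seq_len(nrow(G)),
                     chrom_length = NULL) {
  G <- as.matrix(G)
  samples <- paste0(pops, "_", stats::ave(seq_along(pops), pops,
                                          FUN = seq_along))
  colnames(G) <- make.unique(samples)
  cl <- if (!is.null(chrom_length)) setNames(chrom_length, chrom) else NULL
  hap_matrix(rep(chrom, nrow(G)), pos, G, samples, pops, chrom_lengths = cl)
}

# simple two-population divergence simulation on one chromosome
sim_pair_chrom <- function(T, N = 1e4, m = 0, n_loci = 50,
                           locus_length = 10000, nsam = c(8, 8), seed = 1,
                           mu = 7.1e-9, labels = c("JS", "PO")) {
  mig <- if (m > 0)
    data.frame(t0 = 0, t1 = T, from = c(1, 2), to = c(2, 1), rate = m)
  else NULL
  loci <- sim_coalescent(nsam, c(N, N),
                         data.frame(time = T, from = 2, to = 1),
                         mig = mig, n_loci = n_loci,
                         locus_length = locus_length, mu = mu, seed = seed,
                         pop_labels = labels)
  bind_loci(loci, locus_length)
}

# scalar, per-site transcription of the haploid Weir-Cockerham variance
# components (independent oracle for the vectorised implementation)
wc_oracle_site <- function(n1, n2, p1, p2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- ((n1 + n2) - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r)
  c(a = a, b = b)
}

# textbook-constants Tajima's D oracle
tajd_oracle <- function(n, S, pi_tot) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_tot - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

quiet_hmm <- function(...) suppressWarnings(fit_hmm_classify(...))
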