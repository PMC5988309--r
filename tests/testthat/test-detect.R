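test_that("HMM initialisation and trivial tracks behave as specified", {
  cfg <- hmm_config("valley", transform = "logit")
  expect_equal(cfg$p_stay, 0.9)
  expect_equal(cfg$p_switch, 0.1)
  # all-equal values: a single state throughout, no valley windows
  fit <- quiet_hmm(rep(0.8, 50), hmm_config("valley"))
  expect_equal(sum(fit$state == "valley"), 0)
  expect_error(fit_hmm_classify(c(0.5, NA), hmm_config("valley")),
               "at least two")
})

test_that("Viterbi recovers planted valleys with high accuracy", {
  set.seed(1)
  truth <- rep("background", 500)
  for (s in c(50, 200, 330, 440)) truth[s:(s + 14)] <- "valley"
  vals <- ifelse(truth == "valley",
                 inv_logit(rnorm(500, logit(0.30), 0.05)),
                 inv_logit(rnorm(500, logit(0.85), 0.05)))
  fit <- fit_hmm_classify(vals, hmm_config("valley", transform = "logit"))
  expect_gte(mean(as.character(fit$state) == truth), 0.99)
  expect_true(fit$converged)
  # peak orientation mirrors valley orientation
  fitp <- fit_hmm_classify(1 - vals, hmm_config("peak"))
  expect_gte(mean((fitp$state == "peak") == (truth == "valley")), 0.99)
  # missing windows are carried as gaps and still decoded
  vals_na <- vals
  vals_na[c(10, 205, 300)] <- NA
  fitn <- quiet_hmm(vals_na, hmm_config("valley", transform = "logit"))
  expect_length(fitn$state, 500)
  expect_false(anyNA(fitn$state))
  # broom-style accessors
  expect_named(tidy(fit), c("state", "mean", "sd"))
  expect_equal(glance(fit)$n_windows, 500)
})

test_that("30-kb clustering merges the worked interval examples exactly", {
  w <- tibble::tibble(chrom = "chr1", start = c(0L, 20000L),
                      end = c(10000L, 30000L), gmin = c(0.1, 0.2))
  v <- cluster_outlier_windows(w, gap = 30000, stat = "gmin")
  expect_equal(nrow(v), 1)
  expect_equal(c(v$start, v$end, v$length, v$n_windows),
               c(0, 30000, 30000, 2))
  expect_equal(v$stat_extreme, 0.1)
  # a 40-kb gap is not merged
  w2 <- tibble::tibble(chrom = "chr1", start = c(0L, 50000L),
                       end = c(10000L, 60000L), gmin = c(0.1, 0.2))
  expect_equal(nrow(cluster_outlier_windows(w2, gap = 30000)), 2)
  # single outlier window -> one 10-kb valley
  v3 <- cluster_outlier_windows(w2[1, ], gap = 30000)
  expect_equal(v3$length, 10000)
  # valleys never overlap and are sorted
  set.seed(2)
  st <- sort(sample(seq(0, 1e6, 1e4), 40))
  w4 <- tibble::tibble(chrom = "chr1", start = st, end = st + 1e4)
  v4 <- cluster_outlier_windows(w4, gap = 30000)
  expect_true(all(v4$start[-1] >= head(v4$end, -1)))
})

test_that("permutation independence test matches exhaustive enumeration", {
  # groups {1,2} vs {10,11}: 6 label assignments, all enumerable
  a <- c(1, 2); b <- c(10, 11)
  pool <- c(a, b)
  combs <- utils::combn(4, 2)
  null <- apply(combs, 2, function(i) mean(pool[i]) - mean(pool[-i]))
  obs <- mean(a) - mean(b)
  r <- permutation_independence_test(a, b, n_perm = 2000, seed = 1,
                                     alternative = "less")
  exact_p <- mean(null <= obs)  # 1/6
  expect_lt(abs(r$p_value - exact_p), 0.03)
  # identical groups: p cannot be small
  ri <- permutation_independence_test(c(1, 2, 3), c(1, 2, 3),
                                      n_perm = 500, seed = 2)
  expect_gte(ri$p_value, 0.5)
  # determinism and parameter validation
  r2 <- permutation_independence_test(a, b, n_perm = 2000, seed = 1,
                                      alternative = "less")
  expect_identical(r$p_value, r2$p_value)
  expect_error(permutation_independence_test(a, b, n_perm = 0), "n_perm")
})

test_that("permutation thresholds are deterministic and handle degeneracy", {
  h <- sim_pair_chrom(3e5, 1e4, m = 0, n_loci = 20, locus_length = 10000,
                      nsam = c(6, 6), seed = 3)
  cfg <- window_config(10000, 10000, 5001)
  t1 <- permutation_threshold(h, "JS", "PO", cfg, n_perm = 5,
                              bins = c(5000, 10000), seed = 7)
  t2 <- permutation_threshold(h, "JS", "PO", cfg, n_perm = 5,
                              bins = c(5000, 10000), seed = 7)
  expect_identical(t1$cutoff, t2$cutoff)
  expect_true(is.finite(t1$cutoff[1]))
  # constant-distance data (all sites identical): every permuted gmin
  # equals the observed g, so the cutoff is exactly g
  G <- matrix(c(1, 0, 1, 0), 120, 4, byrow = TRUE)
  hc <- toy_haps(G, pops = c("A", "A", "B", "B"),
                 chrom_length = nrow(G))
  cfgc <- window_config(nrow(G) / 2, nrow(G) / 2, 0)
  tc <- permutation_threshold(hc, "A", "B", cfgc, n_perm = 4,
                              bins = c(0, nrow(G)), seed = 1)
  g0 <- scan_windows(hc, "A", "B", cfgc, which = "dxy")$gmin
  expect_true(all(abs(tc$cutoff - g0[1]) < 1e-12))
})

test_that("gene-overlap enrichment matches its extreme cases", {
  chrom_lengths <- c(chr1 = 2e5)
  valleys <- tibble::tibble(chrom = "chr1", start = 0L, end = 20000L)
  # no genes anywhere near any window
  genes_none <- tibble::tibble(chrom = "chr2", start = 0L, end = 100L,
                               name = "g1")
  r0 <- gene_overlap_enrichment(valleys, genes_none, chrom_lengths,
                                n_draws = 50, seed = 1)
  expect_equal(r0$observed, 0)
  expect_equal(r0$p_value, 1)
  # genes tile valleys only: observed maximal, p at the floor
  genes_v <- tibble::tibble(chrom = "chr1", start = c(1000L, 12000L),
                            end = c(3000L, 15000L), name = c("g1", "g2"))
  r1 <- gene_overlap_enrichment(valleys, genes_v, chrom_lengths,
                                n_draws = 200, seed = 1)
  expect_equal(r1$observed, 2)
  expect_equal(r1$p_value, 1 / 201)
  # toy enumeration: 3 genes, 2 in valleys; null draws sample 2-window runs
  genes3 <- tibble::tibble(chrom = "chr1",
                           start = c(1000L, 12000L, 50000L),
                           end = c(3000L, 15000L, 52000L),
                           name = c("g1", "g2", "g3"))
  r2 <- gene_overlap_enrichment(valleys, genes3, chrom_lengths,
                                n_draws = 2000, seed = 2)
  # 17 possible 2-window runs among the 18 non-valley windows; exactly the
  # two runs covering window [50000,60000) contain a gene (g3), and no run
  # contains 2 genes
  expect_equal(r2$observed, 2)
  expect_equal(r2$p_value, 1 / 2001)
  expect_true(all(r2$null <= 1))
  expect_lt(abs(mean(r2$null == 1) - 2 / 17), 0.03)
})

test_that("HMM valleys are consistent with threshold outliers on separated tracks", {
  set.seed(9)
  truth <- rep(FALSE, 300)
  truth[c(40:44, 150:158, 260:262)] <- TRUE
  vals <- ifelse(truth, inv_logit(rnorm(300, logit(0.3), 0.03)),
                 inv_logit(rnorm(300, logit(0.85), 0.03)))
  fit <- fit_hmm_classify(vals, hmm_config("valley", transform = "logit"))
  thr_out <- vals < 0.5
  # Viterbi valleys contain the hard-threshold outliers (up to boundaries)
  expect_true(all(thr_out == (fit$state == "valley")))
})
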