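spec_small <- locus_spec(30, 2000, samples_per_pop = c(10, 10))

test_that("reference tables have the documented shape and determinism", {
  models <- list(abc_model("I", "constant"), abc_model("IM", "constant"))
  tab <- build_reference_table(models, 3, spec_small, seed = 1)
  expect_equal(nrow(tab), 6)
  expect_true(all(summary_stat_names() %in% names(tab)))
  expect_equal(as.integer(table(tab$model)), c(3L, 3L))
  tab2 <- build_reference_table(models, 3, spec_small, seed = 1)
  expect_identical(tab, tab2)
  # scenario I carries no migration parameter draws
  expect_true(all(is.na(tab$par_m12[tab$model == "I.constant"])))
  expect_true(all(!is.na(tab$par_m12[tab$model == "IM.constant"])))
})

test_that("point-mass priors give identical parameter columns", {
  pr <- default_abc_priors("I", "constant")
  pr$lower <- c(2e4, 1e4, 3e4, 1e5)
  pr$upper <- as.character(pr$lower)
  m <- abc_model("I", "constant", priors = pr)
  tab <- build_reference_table(m, 4, spec_small, seed = 2)
  expect_equal(unique(tab$par_N_JS), 2e4)
  expect_equal(unique(tab$par_T), 1e5)
})

test_that("higher migration lowers mean FST against a matched isolation model", {
  base <- default_abc_priors("I", "constant")
  base$lower <- c(2e4, 2e4, 2e4, 2e5)
  base$upper <- as.character(base$lower)
  pr_im <- default_abc_priors("IM", "constant")
  pr_im$lower <- c(2e4, 2e4, 2e4, 2e5, 5e-5, 5e-5)
  pr_im$upper <- as.character(pr_im$lower)
  tab <- build_reference_table(
    list(abc_model("I", "constant", priors = base),
         abc_model("IM", "constant", priors = pr_im)),
    40, spec_small, seed = 3)
  mfst <- tapply(tab$mean_fst, tab$model, mean, na.rm = TRUE)
  expect_lt(mfst[["IM.constant"]], mfst[["I.constant"]])
})

test_that("model selection recovers separable summary clouds", {
  models <- list(abc_model("I", "constant"), abc_model("IM", "constant"))
  tab <- build_reference_table(models, 40, spec_small, seed = 4)
  # observed identical to one simulation, tiny tolerance -> posterior 1
  obs <- tab[5, summary_stat_names()]
  sel <- suppressWarnings(select_model(obs, tab, tolerance = 1 / nrow(tab)))
  expect_equal(sel$posterior$posterior[sel$posterior$model == "I.constant"],
               1)
  expect_equal(sum(sel$posterior$posterior), 1)
  expect_named(tidy(sel), c("model", "n_accepted", "posterior"))
})

test_that("identical models split the posterior evenly", {
  m1 <- abc_model("I", "constant", name = "copy1")
  m2 <- abc_model("I", "constant", name = "copy2")
  tab <- build_reference_table(list(m1, m2), 150, spec_small, seed = 5)
  obs <- simulate_summaries(
    demographic_params("I", T = 1e5, N_PO = 5e4, N_JS = 5e4, N_ANC = 5e4),
    spec_small)
  sel <- suppressWarnings(select_model(obs, tab, tolerance = 0.2))
  p <- sel$posterior$posterior
  expect_equal(sum(p), 1)
  expect_lt(abs(p[1] - 0.5), 0.2)  # binomial band around symmetry
})

test_that("posteriors sum to one and acceptance is nested across tolerances", {
  models <- list(abc_model("I", "constant"), abc_model("IM", "constant"))
  tab <- build_reference_table(models, 100, spec_small, seed = 6)
  obs <- simulate_summaries(
    demographic_params("IM", T = 3e5, m12 = 1e-5, m21 = 1e-5,
                       N_PO = 3e4, N_JS = 3e4, N_ANC = 3e4), spec_small)
  prev <- integer(0)
  for (tol in c(0.001, 0.005, 0.01, 0.03)) {
    sel <- suppressWarnings(select_model(obs, tab, tolerance = tol))
    expect_equal(sum(sel$posterior$posterior), 1)
    expect_true(all(prev %in% sel$accepted))
    prev <- sel$accepted
  }
})

test_that("parameter estimation honours point masses and tolerance monotonicity", {
  pr <- default_abc_priors("I", "constant")
  pr$lower <- c(2e4, 1e4, 3e4, 1e5)
  pr$upper <- as.character(pr$lower)
  m <- abc_model("I", "constant", priors = pr)
  tab <- build_reference_table(m, 60, spec_small, seed = 7)
  obs <- simulate_summaries(params_from_draw(m, sticklescan:::draw_prior(m)),
                            spec_small)
  est <- suppressWarnings(estimate_parameters(obs, tab, tolerance = 0.5))
  expect_equal(est$summary$median[est$summary$param == "N_JS"], 2e4)
  expect_true("log10_T" %in% names(est$draws))
  expect_named(tidy(est), c("param", "median", "q025", "q975"))
})

test_that("scaled migration is plain arithmetic", {
  expect_equal(scaled_migration(5e5, 1e-6), 1.0)
  expect_equal(scaled_migration(1e4, 0), 0)
  expect_error(scaled_migration(-1, 0.1))
  expect_error(scaled_migration(10, 1))
})

test_that("locus sampling applies the design filters", {
  h <- sim_pair_chrom(3e5, 1e4, n_loci = 50, locus_length = 10000,
                      nsam = c(8, 8), seed = 13)
  # 500 kb chromosome, 125 kb spacing -> 4 candidate loci
  loci <- sample_abc_loci(h, locus_length = 2000, spacing = 125000,
                          min_length = 1000, min_samples = 2)
  expect_lte(length(loci), 4)
  # spacing beyond chromosome length -> at most one locus
  loci1 <- sample_abc_loci(h, locus_length = 2000, spacing = 1e6,
                           min_length = 1000, min_samples = 2)
  expect_equal(length(loci1), 1)
  # a locus shorter than min_length at the chromosome end is excluded
  h2 <- h
  h2$chrom_lengths <- setNames(125999, "chr1")
  loci2 <- sample_abc_loci(h2, locus_length = 2000, spacing = 125000,
                           min_length = 1000, min_samples = 2)
  expect_equal(length(loci2), 1)   # second candidate has only 999 bp
  # the individual-completeness rule excludes loci with missing calls
  h3 <- sim_pair_chrom(3e5, 1e4, n_loci = 5, locus_length = 2000,
                       nsam = c(8, 8), seed = 14)
  h3$chrom_lengths <- setNames(5 * 2000, "chr1")
  drop <- h3$pos <= 4000                # damage loci 1-2
  h3$G[drop, 1:14] <- NA_integer_       # 7 of 8 samples incomplete there
  loci3 <- sample_abc_loci(h3, locus_length = 2000, spacing = 2000,
                           min_length = 1000, min_samples = 4)
  expect_equal(length(loci3), 3)
  expect_error(sample_abc_loci(h3, locus_length = 2000, spacing = 2000,
                               min_length = 1000, min_samples = 9),
               "no loci survive")
})

test_that("R and C++ per-locus statistic definitions agree exactly", {
  p <- demographic_params("IM", T = 2e5, m12 = 1e-5, m21 = 1e-5,
                          N_PO = 2e4, N_JS = 2e4, N_ANC = 2e4)
  spec <- locus_spec(25, 2000, samples_per_pop = c(10, 10))
  loci <- sim_demography(p, spec, seed = 21, pop_labels = c("p1", "p2"))
  for (l in loci[1:10]) {
    r_stats <- sticklescan:::locus_pair_stats(l, "p1", "p2")
    c_stats <- sticklescan:::locus_stats_matrix_cpp(l$G, 10L, 10L)
    expect_equal(unname(r_stats), unname(c_stats), tolerance = 1e-12)
  }
  # moments assemble the summary vector in the fixed order
  slow <- locus_summaries(loci, "p1", "p2")
  per_locus <- t(vapply(loci, function(l)
    sticklescan:::locus_stats_matrix_cpp(l$G, 10L, 10L), numeric(10)))
  expect_equal(unname(unlist(slow)),
               unname(sticklescan:::moments_from_locus_stats(per_locus)),
               tolerance = 1e-12)
  # identical loci -> zero variances
  two <- list(loci[[1]], loci[[1]])
  s2 <- locus_summaries(two, "p1", "p2")
  expect_true(all(abs(unlist(s2[grep("var_", names(s2))])) < 1e-12))
})

test_that("POD validation separates isolation from strong migration", {
  pr_i <- default_abc_priors("I", "constant")
  pr_i$lower <- c(1e4, 1e4, 1e4, 5e5); pr_i$upper <- c("5e4", "5e4", "5e4", "2e6")
  pr_im <- default_abc_priors("IM", "constant")
  pr_im$lower <- c(1e4, 1e4, 1e4, 5e5, 3e-5, 3e-5)
  pr_im$upper <- c("5e4", "5e4", "5e4", "2e6", "1e-4", "1e-4")
  models <- list(abc_model("I", "constant", priors = pr_i),
                 abc_model("IM", "constant", priors = pr_im))
  pv <- suppressWarnings(pod_validate(models, n_pods_per_model = 10,
                                      n_sims = 400, spec = spec_small,
                                      tolerance = 0.02, seed = 8))
  expect_gte(pv$accuracy, 0.7)
  pv2 <- suppressWarnings(pod_validate(models, n_pods_per_model = 10,
                                       n_sims = 400, spec = spec_small,
                                       tolerance = 0.02, seed = 8,
                                       table = pv$table))
  expect_identical(pv$confusion, pv2$confusion)
})
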