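test_that("windowed FST equals the component-by-component oracle", {
  # fixed difference, n = 20 haplotypes per population, one site
  G <- cbind(matrix(0, 1, 20), matrix(1, 1, 20))
  h <- toy_haps(G, pops = rep(c("A", "B"), each = 20))
  o <- wc_oracle_site(20, 20, 0, 1)
  expect_equal(wc_fst(h, "A", "B"), unname(o["a"] / (o["a"] + o["b"])),
               tolerance = 1e-12)

  # 5 tabulated sites combined as ratio of summed components
  d1 <- c(3, 10, 0, 7, 1)   # derived counts in A (n = 10)
  d2 <- c(9, 2, 5, 7, 0)    # derived counts in B (n = 12)
  G <- do.call(rbind, lapply(1:5, function(s)
    c(rep(1, d1[s]), rep(0, 10 - d1[s]), rep(1, d2[s]), rep(0, 12 - d2[s]))))
  h <- toy_haps(G, pops = rep(c("A", "B"), c(10, 12)))
  comp <- vapply(1:5, function(s) wc_oracle_site(10, 12, d1[s] / 10,
                                                 d2[s] / 12), c(a = 0, b = 0))
  poly <- (d1 + d2) > 0 & (d1 + d2) < 22
  expected <- sum(comp["a", poly]) / sum(comp["a", poly] + comp["b", poly])
  expect_equal(wc_fst(h, "A", "B"), expected, tolerance = 1e-12)
  # not the mean of per-site ratios
  per_site <- comp["a", poly] / (comp["a", poly] + comp["b", poly])
  expect_false(isTRUE(all.equal(wc_fst(h, "A", "B"), mean(per_site))))
})

test_that("FST is near zero without differentiation and NA without sites", {
  set.seed(8)
  G <- matrix(rbinom(200 * 40, 1, 0.4), 200, 40)
  h <- toy_haps(G, pops = rep(c("A", "B"), each = 20))
  expect_lt(abs(wc_fst(h, "A", "B")), 0.05)
  h0 <- toy_haps(matrix(integer(0), 0, 4), pops = rep(c("A", "B"), each = 2))
  expect_true(is.na(wc_fst(h0, "A", "B")))
})

test_that("dxy statistics match full pair enumeration", {
  # A = {00, 01}, B = {11, 10}: distances {1, 0.5, 0.5, 1}
  G <- cbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0))
  h <- toy_haps(G, pops = c("A", "A", "B", "B"))
  d <- dxy_stats(h, "A", "B")
  expect_equal(d$dxy, 0.75, tolerance = 1e-12)
  expect_equal(d$dxy_min, 0.5, tolerance = 1e-12)
  expect_equal(d$gmin, 2 / 3, tolerance = 1e-12)

  # single pair fully diverged
  h2 <- toy_haps(cbind(rep(0, 4), rep(1, 4)), pops = c("A", "B"))
  d2 <- dxy_stats(h2, "A", "B")
  expect_equal(d2$dxy, 1)
  expect_equal(d2$gmin, 1)

  # a B haplotype identical to an A haplotype: recent-migrant signature
  G3 <- cbind(c(0, 0, 1), c(1, 1, 1), c(0, 0, 1), c(1, 0, 0))
  h3 <- toy_haps(G3, pops = c("A", "A", "B", "B"))
  d3 <- dxy_stats(h3, "A", "B")
  expect_equal(d3$dxy_min, 0)
  expect_equal(d3$gmin, 0)
  expect_match(d3$min_pair, "^A_1")
})

test_that("gmin is invariant to haplotype relabeling", {
  set.seed(3)
  G <- matrix(rbinom(50 * 8, 1, 0.3), 50, 8)
  h <- toy_haps(G, pops = rep(c("A", "B"), each = 4))
  g1 <- dxy_stats(h, "A", "B")$gmin
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  h2 <- toy_haps(G[, perm], pops = rep(c("A", "B"), each = 4))
  expect_equal(dxy_stats(h2, "A", "B")$gmin, g1, tolerance = 1e-12)
})

test_that("dxy is additive over concatenated windows", {
  set.seed(4)
  G <- matrix(rbinom(60 * 6, 1, 0.4), 60, 6)
  h <- toy_haps(G, pops = rep(c("A", "B"), each = 3), pos = 1:60)
  d_all <- dxy_stats(h, "A", "B", n_usable = 60)$dxy
  d1 <- dxy_stats(toy_haps(G[1:25, ], rep(c("A", "B"), each = 3)),
                  "A", "B", n_usable = 25)$dxy
  d2 <- dxy_stats(toy_haps(G[26:60, ], rep(c("A", "B"), each = 3)),
                  "A", "B", n_usable = 35)$dxy
  expect_equal(d_all, (25 * d1 + 35 * d2) / 60, tolerance = 1e-12)
})

test_that("Tajima's D matches the textbook-constants oracle", {
  # n = 4 haplotypes, 3 segregating sites with derived counts 1, 2, 3
  G <- rbind(c(1, 0, 0, 0), c(1, 1, 0, 0), c(1, 1, 1, 0))
  h <- toy_haps(G, pops = rep("A", 4))
  pi_tot <- sum(2 * c(1, 2, 3) * c(3, 2, 1) / (4 * 3))
  expect_equal(tajimas_d(h, "A"), tajd_oracle(4, 3, pi_tot),
               tolerance = 1e-12)
  # monomorphic window flagged missing, not zero
  h0 <- toy_haps(matrix(0, 5, 10), pops = rep("A", 10))
  expect_true(is.na(tajimas_d(h0, "A")))
})

test_that("population expansion drives Tajima's D negative", {
  # strong recent expansion: star-like genealogies, excess singletons
  N <- 1e5
  loci <- sim_coalescent(
    15, N, data.frame(time = numeric(), from = integer(), to = integer()),
    size_changes = data.frame(time = 2000, pop = 1, N = 500),
    n_loci = 100, locus_length = 5000, mu = 1e-7, seed = 6)
  h <- bind_loci(loci, 5000)
  td <- scan_windows(h, "pop1", "pop1", window_config(5000, 5000, 0),
                     which = "tajd")$tajd_1
  expect_lt(mean(td, na.rm = TRUE), 0)
})

test_that("window eligibility follows the strict usable-site rule", {
  # 10-kb window; low-call variant sites reduce n_usable below the bound
  n_low <- 5000
  G <- rbind(matrix(NA_integer_, n_low, 4),
             matrix(c(0, 1, 1, 0), n_low + 10, 4, byrow = TRUE))
  h <- toy_haps(G, pops = c("A", "A", "B", "B"),
                pos = seq_len(nrow(G)), chrom_length = 10000)
  sc <- scan_windows(h, "A", "B", window_config(10000, 10000, 5001))
  expect_equal(sc$n_usable, 5000L)
  expect_true(is.na(sc$fst) && is.na(sc$gmin))  # listed but not computed
  # one fewer missing site -> 5001 usable -> computed
  h2 <- toy_haps(G[-1, , drop = FALSE], pops = c("A", "A", "B", "B"),
                 pos = seq_len(nrow(G) - 1), chrom_length = 10000)
  sc2 <- scan_windows(h2, "A", "B", window_config(10000, 10000, 5001))
  expect_equal(sc2$n_usable, 5001L)
  expect_false(is.na(sc2$gmin))
})

test_that("per-window scan values equal single-window calls on the slice", {
  h <- sim_pair_chrom(3e5, 2e4, m = 1e-6, n_loci = 6, locus_length = 10000,
                      nsam = c(6, 6), seed = 9)
  sc <- scan_windows(h, "JS", "PO", window_config(10000, 10000, 0))
  i <- 3
  rows <- which(h$pos > sc$start[i] & h$pos <= sc$end[i])
  sub <- hap_matrix(h$chrom[rows], h$pos[rows], h$G[rows, ],
                    h$sample_of_hap, h$pop_of_hap)
  expect_equal(sc$fst[i], wc_fst(sub, "JS", "PO"), tolerance = 1e-12)
  dd <- dxy_stats(sub, "JS", "PO", n_usable = sc$n_usable[i])
  expect_equal(sc$dxy[i], dd$dxy, tolerance = 1e-12)
  expect_equal(sc$gmin[i], dd$gmin, tolerance = 1e-12)
  expect_equal(sc$tajd_1[i], tajimas_d(sub, "JS"), tolerance = 1e-12)
})
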