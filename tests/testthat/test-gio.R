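# build a small VCF on disk for reader/filter tests
write_toy_vcf <- function(lines, .env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = .env)
  hdr <- c("##fileformat=VCFv4.2", "##contig=<ID=chr1>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "s1", "s2", "s3", sep = "\t"))
  writeLines(c(hdr, lines), path)
  path
}

write_toy_popmap <- function(samples = c("s1", "s2", "s3"),
                             pops = c("A", "A", "B"),
                             .env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = .env)
  writeLines(paste(samples, pops, sep = "\t"), path)
  path
}

rec <- function(pos, qual, alt, gts, dps = c(30, 30, 30)) {
  paste("chr1", pos, ".", "A", alt, qual, "PASS", ".", "GT:DP",
        paste(gts, dps, sep = ":", collapse = "\t"), sep = "\t")
}

test_that("VCF reading preserves genotypes, missingness and metadata", {
  vcf <- write_toy_vcf(c(
    rec(100, 50, "T", c("0|1", "1|1", "./.")),
    rec(200, 50, "T", c("0/0", "0/1", "1/1"))))
  st <- read_genotypes(vcf, write_toy_popmap())
  expect_s3_class(st$sites, "tbl_df")
  expect_equal(st$sites$pos, c(100L, 200L))
  expect_identical(unname(st$a1[1, ]), c(0L, 1L, NA))
  expect_identical(unname(st$a2[1, ]), c(1L, 1L, NA))
  expect_true(st$phased[1, 1] && !st$phased[2, 2])
  expect_identical(unname(st$pops), c("A", "A", "B"))
})

test_that("an empty VCF body gives an empty store without error", {
  vcf <- write_toy_vcf(character(0))
  st <- read_genotypes(vcf, write_toy_popmap())
  expect_equal(nrow(st$sites), 0)
})

test_that("a popmap missing a sample names it in the error", {
  vcf <- write_toy_vcf(rec(100, 50, "T", c("0|1", "1|1", "0|0")))
  pm <- write_toy_popmap(samples = c("s1", "s2"), pops = c("A", "A"))
  expect_error(read_genotypes(vcf, pm), "s3")
})

test_that("site filters remove the enumerated toy records per filter", {
  # 6 records: 2 fail QUAL (<=10), 1 triallelic, 1 fails depth entirely,
  # 2 survive
  vcf <- write_toy_vcf(c(
    rec(100, 5, "T", c("0|1", "0|0", "0|0")),
    rec(200, 10, "T", c("0|1", "0|0", "0|0")),
    rec(300, 50, "T,G", c("0|1", "0|2", "0|0")),
    rec(400, 50, "T", c("0|1", "0|1", "0|0"), dps = c(300, 300, 300)),
    rec(500, 50, "T", c("0|1", "0|0", "1|1")),
    rec(600, 99, "T", c("0|1", "1|1", "0|0"))))
  st <- read_genotypes(vcf, write_toy_popmap())
  res <- filter_sites(st, site_filter_config(
    min_qual = 10, min_depth = 10, max_depth = 200, biallelic_only = TRUE))
  expect_equal(nrow(res$store$sites), 2)
  expect_equal(res$store$sites$pos, c(500L, 600L))
  cnt <- setNames(res$counts$removed, res$counts$filter)
  expect_identical(cnt[c("qual", "biallelic", "depth")],
                   c(qual = 2L, biallelic = 1L, depth = 1L))
})

test_that("disabled thresholds are the identity and filtering is idempotent", {
  vcf <- write_toy_vcf(c(
    rec(100, 5, "T", c("0|1", "0|0", "./.")),
    rec(200, 50, "T", c("0|1", "0|1", "1|1"))))
  st <- read_genotypes(vcf, write_toy_popmap())
  res <- filter_sites(st, site_filter_config())
  expect_equal(nrow(res$store$sites), 2)
  expect_true(all(res$counts$removed == 0))
  cfg <- site_filter_config(min_qual = 10, min_maf = 0.1,
                            min_call_rate = 0.5)
  once <- filter_sites(st, cfg)$store
  twice <- filter_sites(once, cfg)$store
  expect_identical(once$sites, twice$sites)
  expect_identical(once$a1, twice$a1)
})

test_that("MAF and call-rate boundaries are inclusive", {
  vcf <- write_toy_vcf(c(
    rec(100, 50, "T", c("0|1", "0|1", "0|1")),   # maf = 0.5
    rec(200, 50, "T", c("0|1", "./.", "./."))))  # call rate = 1/3
  st <- read_genotypes(vcf, write_toy_popmap())
  keep_maf <- filter_sites(st, site_filter_config(min_maf = 0.5))
  expect_true(100 %in% keep_maf$store$sites$pos)
  keep_cr <- filter_sites(st, site_filter_config(min_call_rate = 1 / 3))
  expect_equal(nrow(keep_cr$store$sites), 2)
})

test_that("pseudo-phasing conserves alleles and is seed-deterministic", {
  vcf <- write_toy_vcf(c(
    rec(100, 50, "T", c("0|1", "0|1", "0|1")),
    rec(200, 50, "T", c("0|0", "1|1", "./.")),
    rec(300, 50, "T", c("0|1", "1|0", "0|1"))))
  st <- read_genotypes(vcf, write_toy_popmap())
  h1 <- pseudo_phase(st, seed = 1)
  h1b <- pseudo_phase(st, seed = 1)
  expect_identical(h1$G, h1b$G)
  # per-site per-sample allele multisets preserved
  for (s in 1:3) {
    obs <- h1$G[, (2 * s - 1):(2 * s)]
    expect_identical(
      unname(apply(obs, 1, sort, na.last = TRUE)),
      unname(apply(cbind(st$a1[, s], st$a2[, s]), 1, sort, na.last = TRUE)))
  }
  # homozygous samples have identical haplotypes
  expect_identical(unname(h1$G[2, 1]), unname(h1$G[2, 2]))
  # different seeds eventually differ on a heterozygous site
  diffs <- vapply(2:40, function(sd)
    !identical(pseudo_phase(st, seed = sd)$G, h1$G), TRUE)
  expect_true(any(diffs))
})

test_that("window tiling is exact and drops trailing partials", {
  cfg <- window_config(10000, 10000, 5001)
  w <- iter_windows(35000, cfg)
  expect_equal(nrow(w), 3)
  expect_equal(max(w$end), 30000)
  expect_equal(nrow(iter_windows(10000, cfg)), 1)
  expect_equal(nrow(iter_windows(9999, cfg)), 0)
  # non-overlapping tiling covers [0, floor(L/size)*size) exactly once
  w2 <- iter_windows(53000, cfg)
  expect_identical(w2$start, seq(0L, 40000L, 10000L))
  expect_true(all(w2$end - w2$start == 10000))
})

test_that("population allele frequencies use non-missing denominators", {
  G <- rbind(c(1, 1, 0, NA, 0, 0),
             c(0, 0, 0, 0, 0, 0),
             c(NA, NA, NA, NA, 1, 0))
  h <- toy_haps(G, pops = c("A", "A", "A", "A", "B", "B"))
  fr <- pop_allele_freqs(h, c("A", "B"))
  expect_equal(fr$A[1], 2 / 3)
  expect_equal(fr$A[2], 0)
  expect_true(is.na(fr$A[3]) && !fr$usable[3])  # fully missing pop masked
  expect_true(fr$usable[1])
  expect_error(pop_allele_freqs(h, "Z"), "unknown population")
})
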