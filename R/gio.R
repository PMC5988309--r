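#' Read a multi-sample VCF and population map
#'
#' Parses a VCF (via \pkg{vcfR}) together with a two-column
#' `sample<TAB>population` map into a diploid genotype store used by the
#' filtering, phasing and windowing steps.  Missing genotypes are kept as
#' missing; every VCF sample must appear in the population map.
#'
#' @param vcf Path to a VCF 4.x file.
#' @param popmap Path to a headerless TSV with columns sample, population.
#' @return A `geno_store`: list with elements `sites` (tibble: chrom, pos,
#'   ref, alt, qual, n_alt_alleles), allele matrices `a1`/`a2` (sites x
#'   samples, 0 = REF, 1... = ALT index, `NA` = missing), `phased` logical
#'   matrix, `dp` depth matrix (or `NULL`), `samples`, and `pops` (named
#'   character, sample -> population).
#' @export
read_genotypes <- function(vcf, popmap) {
  pm <- utils::read.table(popmap, header = FALSE, sep = "\t",
                          col.names = c("sample", "pop"),
                          stringsAsFactors = FALSE)
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_sites <- nrow(v@gt)
  samples <- colnames(v@gt)[-1]
  missing <- setdiff(samples, pm$sample)
  if (length(missing) > 0)
    stop("samples in VCF absent from popmap: ",
         paste(missing, collapse = ", "), call. = FALSE)
  pops <- setNames(pm$pop, pm$sample)[samples]
  if (n_sites == 0) {
    sites <- tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            qual = numeric(), n_alt_alleles = integer())
    emp <- matrix(NA_integer_, 0, length(samples),
                  dimnames = list(NULL, samples))
    return(structure(list(sites = sites, a1 = emp, a2 = emp,
                          phased = matrix(NA, 0, length(samples)),
                          dp = NULL, samples = samples, pops = pops),
                     class = "geno_store"))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- ""
  sites <- tibble::tibble(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = alt,
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    n_alt_alleles = ifelse(alt == "" | alt == ".", 0L,
                           lengths(strsplit(alt, ",", fixed = TRUE))))
  phased <- grepl("|", gt, fixed = TRUE)
  dim(phased) <- dim(gt)
  parts <- strsplit(gsub("\\|", "/", gt), "/", fixed = FALSE)
  to_int <- function(k) {
    x <- vapply(parts, function(p) if (length(p) >= k) p[k] else NA_character_,
                character(1))
    x[x == "."] <- NA
    matrix(suppressWarnings(as.integer(x)), nrow = n_sites,
           dimnames = dimnames(gt))
  }
  a1 <- to_int(1)
  a2 <- to_int(2)
  dp <- NULL
  if (any(grepl("DP", v@gt[, 1])))
    dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP",
                                            as.numeric = TRUE))
  structure(list(sites = sites, a1 = a1, a2 = a2, phased = phased,
                 dp = dp, samples = samples, pops = pops),
            class = "geno_store")
}

#' @export
print.geno_store <- function(x, ...) {
  cat("<geno_store> ", nrow(x$sites), " sites x ", length(x$samples),
      " samples (", length(unique(x$pops)), " populations)\n", sep = "")
  invisible(x)
}

#' Site-filter configuration
#'
#' Thresholds follow the conventions of consensus-call variant filtering:
#' QUAL must exceed `min_qual` (strict), per-genotype depth must lie inside
#' `[min_depth, max_depth]` (inclusive; failing genotypes are set missing),
#' sites may be restricted to at most two alleles, and minor-allele
#' frequency and call rate are inclusive lower bounds (a site with MAF
#' exactly `min_maf` is retained).
#'
#' @param min_qual Phred site-quality threshold (`NULL` disables); strict.
#' @param min_depth,max_depth Per-genotype depth bounds (`NULL` disables).
#' @param biallelic_only Keep only sites with a single ALT allele?
#' @param min_maf Minimum minor-allele frequency in `[0, 0.5]` (`NULL`
#'   disables).
#' @param min_call_rate Minimum fraction of genotyped samples (`NULL`
#'   disables).
#' @return An object of class `site_filter_config`.
#' @export
site_filter_config <- function(min_qual = NULL, min_depth = NULL,
                               max_depth = NULL, biallelic_only = FALSE,
                               min_maf = NULL, min_call_rate = NULL) {
  if (!is.null(min_maf) && (min_maf < 0 || min_maf > 0.5))
    stop("min_maf must lie in [0, 0.5]")
  if (!is.null(min_call_rate) && (min_call_rate < 0 || min_call_rate > 1))
    stop("min_call_rate must lie in [0, 1]")
  if (!is.null(min_depth) && !is.null(max_depth) && min_depth > max_depth)
    stop("min_depth must not exceed max_depth")
  structure(list(min_qual = min_qual, min_depth = min_depth,
                 max_depth = max_depth, biallelic_only = biallelic_only,
                 min_maf = min_maf, min_call_rate = min_call_rate),
            class = "site_filter_config")
}

#' Filter sites of a genotype store
#'
#' Applies the enabled filters of a [site_filter_config()] in the order
#' QUAL, biallelic, depth, MAF, call rate; each removed site is charged to
#' the first filter it fails.  Depth bounds act on individual genotypes
#' (out-of-range genotypes become missing) and a site is charged to the
#' depth filter when no genotype survives.
#'
#' @param store A `geno_store` from [read_genotypes()].
#' @param cfg A [site_filter_config()].
#' @return List with elements `store` (filtered) and `counts`, a tibble of
#'   per-filter removal counts (`qual`, `biallelic`, `depth`, `maf`,
#'   `call_rate`).
#' @export
filter_sites <- function(store, cfg) {
  stopifnot(inherits(cfg, "site_filter_config"))
  n <- nrow(store$sites)
  keep <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  fail <- function(bad, why) {
    new <- bad & keep
    reason[new] <<- why
    keep[new] <<- FALSE
  }
  if (!is.null(cfg$min_qual))
    fail(!(store$sites$qual > cfg$min_qual) | is.na(store$sites$qual), "qual")
  if (isTRUE(cfg$biallelic_only))
    fail(store$sites$n_alt_alleles > 1, "biallelic")
  if (!is.null(cfg$min_depth) || !is.null(cfg$max_depth)) {
    if (!is.null(store$dp)) {
      lo <- if (is.null(cfg$min_depth)) -Inf else cfg$min_depth
      hi <- if (is.null(cfg$max_depth)) Inf else cfg$max_depth
      bad_gt <- !is.na(store$dp) & (store$dp < lo | store$dp > hi)
      store$a1[bad_gt] <- NA_integer_
      store$a2[bad_gt] <- NA_integer_
      fail(rowSums(!is.na(store$a1)) == 0, "depth")
    }
  }
  called <- !is.na(store$a1)
  n_called <- rowSums(called)
  if (!is.null(cfg$min_maf)) {
    cnt1 <- rowSums(store$a1 == 1, na.rm = TRUE) +
      rowSums(store$a2 == 1, na.rm = TRUE)
    tot <- rowSums(!is.na(store$a1)) + rowSums(!is.na(store$a2))
    f <- ifelse(tot > 0, cnt1 / tot, NA)
    maf <- pmin(f, 1 - f)
    fail(!is.na(maf) & maf < cfg$min_maf, "maf")
  }
  if (!is.null(cfg$min_call_rate))
    fail(n_called / length(store$samples) < cfg$min_call_rate, "call_rate")
  counts <- tibble::tibble(filter = c("qual", "biallelic", "depth", "maf",
                                      "call_rate"))
  counts$removed <- vapply(counts$filter,
                           function(f) sum(reason == f, na.rm = TRUE), 0L)
  store$sites <- store$sites[keep, , drop = FALSE]
  store$a1 <- store$a1[keep, , drop = FALSE]
  store$a2 <- store$a2[keep, , drop = FALSE]
  store$phased <- store$phased[keep, , drop = FALSE]
  if (!is.null(store$dp)) store$dp <- store$dp[keep, , drop = FALSE]
  list(store = store, counts = counts)
}

#' Pseudo-phase a diploid genotype store
#'
#' Produces two haplotypes per sample by randomly assigning the two alleles
#' of each heterozygous genotype to the haplotypes, independently per site.
#' Homozygous and missing genotypes are carried through unchanged, so the
#' per-site allele multiset of every sample is preserved.  Long-range
#' haplotype structure is intentionally destroyed; haplotype-based window
#' statistics are robust to this randomisation when within-window linkage
#' carries the signal of interest.
#'
#' @param store A `geno_store`.
#' @param seed Integer seed; fixes the assignment.
#' @return A [hap_matrix] with two haplotypes per sample (`_h1`, `_h2`).
#' @export
pseudo_phase <- function(store, seed = 1) {
  set.seed(seed)
  a1 <- store$a1
  a2 <- store$a2
  het <- !is.na(a1) & !is.na(a2) & a1 != a2
  flip <- matrix(runif(length(a1)) < 0.5, nrow = nrow(a1))
  sw <- het & flip
  h1 <- ifelse(sw, a2, a1)
  h2 <- ifelse(sw, a1, a2)
  n_s <- length(store$samples)
  G <- matrix(NA_integer_, nrow = nrow(a1), ncol = 2 * n_s)
  G[, seq(1, 2 * n_s, 2)] <- h1
  G[, seq(2, 2 * n_s, 2)] <- h2
  colnames(G) <- paste0(rep(store$samples, each = 2), "_h", 1:2)
  hap_matrix(store$sites$chrom, store$sites$pos, G,
             rep(store$samples, each = 2),
             rep(unname(store$pops), each = 2))
}

#' Window configuration
#'
#' @param size Window size in bp.
#' @param step Step between window starts (equal to `size` for
#'   non-overlapping scans).
#' @param min_usable_sites Minimum usable-site count for a window's
#'   haplotype statistics to be computed (inclusive); the default 5,001
#'   encodes the "more than half of a 10-kb window" rule.
#' @return An object of class `window_config`.
#' @export
window_config <- function(size = 10000, step = size,
                          min_usable_sites = 5001) {
  stopifnot(size > 0, step > 0, min_usable_sites <= size)
  structure(list(size = as.integer(size), step = as.integer(step),
                 min_usable_sites = as.integer(min_usable_sites)),
            class = "window_config")
}

#' Tile a chromosome with windows
#'
#' Generates 0-based half-open windows `[0, size)`, `[step, step + size)`,
#' ...; a trailing partial window is dropped.
#'
#' @param chrom_length Chromosome length in bp.
#' @param cfg A [window_config()].
#' @return Tibble with columns `start`, `end`.
#' @export
iter_windows <- function(chrom_length, cfg) {
  stopifnot(chrom_length > 0)
  starts <- seq(0L, by = cfg$step, length.out =
                  max(0L, (chrom_length - cfg$size) %/% cfg$step + 1L))
  if (chrom_length < cfg$size) starts <- integer(0)
  tibble::tibble(start = as.integer(starts),
                 end = as.integer(starts + cfg$size))
}

#' Per-population derived-allele frequencies
#'
#' Computes per-site derived (ALT) allele frequencies for each population
#' from a haplotype matrix, dividing by the non-missing haplotype count.
#' Sites at which any requested population is entirely missing are flagged
#' unusable.
#'
#' @param haps A [hap_matrix].
#' @param pops Character vector of population labels (default: all).
#' @param chrom,start,end Optional window restriction (0-based half-open).
#' @return Tibble: `chrom`, `pos`, one frequency column per population, and
#'   `usable`.
#' @export
pop_allele_freqs <- function(haps, pops = unique(haps$pop_of_hap),
                             chrom = NULL, start = NULL, end = NULL) {
  rows <- seq_along(haps$pos)
  if (!is.null(chrom)) rows <- window_rows(haps, chrom, start, end)
  out <- tibble::tibble(chrom = haps$chrom[rows], pos = haps$pos[rows])
  usable <- rep(TRUE, length(rows))
  for (p in pops) {
    cols <- hap_cols(haps, p)
    sub <- haps$G[rows, cols, drop = FALSE]
    cnt <- rowSums(sub == 1, na.rm = TRUE)
    nn <- rowSums(!is.na(sub))
    out[[p]] <- ifelse(nn > 0, cnt / nn, NA_real_)
    usable <- usable & nn > 0
  }
  out$usable <- usable
  out
}
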