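#' Write a self-contained synthetic dataset to disk
#'
#' Simulates a two-population divergence history, lays the loci out on a
#' single chromosome and writes the four files the scan pipeline consumes:
#' a phased multi-sample VCF, a `sample<TAB>population` map, a linear
#' recombination-map table and a BED of synthetic "genes" tiling a subset
#' of windows.  All files are plain text and round-trip through
#' [read_genotypes()].
#'
#' @param params A [demographic_params()] object.
#' @param spec A [locus_spec()] object (haplotype counts must be even, two
#'   haplotypes per diploid sample).
#' @param seed Integer seed; fixes every file byte-for-byte.
#' @param outdir Output directory (created if needed).
#' @param chrom Chromosome name used in all files.
#' @param gene_every Place a synthetic 2-kb gene at the start of every
#'   `gene_every`-th 10-kb window.
#' @param cm_per_mb Constant recombination rate used for the marker table.
#' @return A list manifest: file paths plus the simulated [hap_matrix].
#' @export
make_fixture_dataset <- function(params, spec, seed = 1, outdir,
                                 chrom = "chr1", gene_every = 3,
                                 cm_per_mb = 5) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (any(spec$samples_per_pop %% 2 != 0))
    stop("samples_per_pop must be even (two haplotypes per diploid sample)")
  loci <- sim_demography(params, spec, seed = seed)
  haps <- bind_loci(loci, spec$locus_length, spec$spacing, chrom = chrom)
  chrom_len <- unname(haps$chrom_lengths[chrom])

  vcf_path <- file.path(outdir, "variants.vcf")
  popmap_path <- file.path(outdir, "popmap.tsv")
  map_path <- file.path(outdir, "recomb_map.tsv")
  bed_path <- file.path(outdir, "genes.bed")

  write_hap_vcf(haps, vcf_path)

  sm <- hap_sample_table(haps)
  writeLines(paste(sm$sample, sm$pop, sep = "\t"), popmap_path)

  marker_pos <- seq(0, chrom_len, by = 250000)
  if (marker_pos[length(marker_pos)] != chrom_len)
    marker_pos <- c(marker_pos, chrom_len)
  map <- data.frame(chrom = chrom, pos_bp = marker_pos,
                    cum_cM = marker_pos / 1e6 * cm_per_mb)
  write.table(format(map, scientific = FALSE, trim = TRUE), map_path,
              sep = "\t", quote = FALSE, row.names = FALSE)

  win_starts <- seq(0, chrom_len - 10000, by = 10000)
  gene_starts <- win_starts[seq(1, length(win_starts), by = gene_every)]
  bed <- data.frame(chrom = chrom, start = gene_starts,
                    end = gene_starts + 2000,
                    name = paste0("gene_", seq_along(gene_starts)))
  write.table(format(bed, scientific = FALSE, trim = TRUE), bed_path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  list(vcf = vcf_path, popmap = popmap_path, recomb_map = map_path,
       genes = bed_path, haps = haps, chrom_length = chrom_len,
       n_sites = nrow(haps$G))
}

# sample table (sample, pop) in haplotype order
hap_sample_table <- function(haps) {
  keep <- !duplicated(haps$sample_of_hap)
  data.frame(sample = haps$sample_of_hap[keep], pop = haps$pop_of_hap[keep])
}

# Write a hap_matrix as a minimal phased VCF 4.2 (pairs of haplotype
# columns form diploid samples; synthetic REF/ALT, constant QUAL/DP).
write_hap_vcf <- function(haps, path, qual = 99, dp = 30) {
  n_hap <- ncol(haps$G)
  if (n_hap %% 2 != 0) stop("need an even number of haplotypes")
  sm <- hap_sample_table(haps)
  # haplotypes must come in sample pairs
  if (!all(haps$sample_of_hap[seq(1, n_hap, 2)] ==
           haps$sample_of_hap[seq(2, n_hap, 2)])) {
    # derive diploid samples by pairing consecutive haplotypes per population
    stop("haplotype columns must be ordered in sample pairs")
  }
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", unique(haps$chrom), ">"),
           '##INFO=<ID=NS,Number=1,Type=Integer,Description="Number of samples">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sm$sample), collapse = "\t"))
  a1 <- haps$G[, seq(1, n_hap, 2), drop = FALSE]
  a2 <- haps$G[, seq(2, n_hap, 2), drop = FALSE]
  gt <- matrix(paste0(ifelse(is.na(a1), ".", a1), "|",
                      ifelse(is.na(a2), ".", a2), ":", dp),
               nrow = nrow(haps$G))
  body <- apply(cbind(haps$chrom, haps$pos, ".", "A", "T", qual, "PASS",
                      paste0("NS=", n_hap / 2), "GT:DP", gt), 1,
                paste, collapse = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
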