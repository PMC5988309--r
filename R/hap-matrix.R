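#' Haplotype matrix container
#'
#' The substrate of all haplotype-based statistics: a sites x haplotypes
#' matrix of allele codes (0 = ancestral/REF, 1 = derived/ALT, `NA` =
#' missing), together with site coordinates and the sample and population
#' each haplotype belongs to.
#'
#' @param chrom Character vector of chromosome identifiers, one per site.
#' @param pos Integer vector of 1-based site positions, strictly increasing
#'   within each chromosome.
#' @param G Integer matrix, sites x haplotypes, values in \{0, 1, `NA`\}.
#' @param sample_of_hap Character vector mapping each haplotype column to a
#'   sample identifier.
#' @param pop_of_hap Character vector mapping each haplotype column to a
#'   population label.
#' @param chrom_lengths Optional named numeric vector of chromosome lengths
#'   in bp (used to define windows and usable-site counts).
#'
#' @return An object of class `hap_matrix`.
#' @export
hap_matrix <- function(chrom, pos, G, sample_of_hap, pop_of_hap,
                       chrom_lengths = NULL) {
  G <- as.matrix(G)
  stopifnot(length(chrom) == nrow(G), length(pos) == nrow(G),
            length(sample_of_hap) == ncol(G), length(pop_of_hap) == ncol(G))
  bad <- !(G %in% c(0L, 1L, NA))
  if (any(bad)) stop("allele codes must be 0, 1 or NA")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (is.null(colnames(G)))
    colnames(G) <- make.unique(paste0(sample_of_hap, "_h"), sep = "")
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos), G = G,
         sample_of_hap = as.character(sample_of_hap),
         pop_of_hap = as.character(pop_of_hap),
         chrom_lengths = chrom_lengths),
    class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat("<hap_matrix> ", nrow(x$G), " sites x ", ncol(x$G), " haplotypes\n", sep = "")
  cat("  chromosomes: ", paste(unique(x$chrom), collapse = ", "), "\n", sep = "")
  cat("  populations: ", paste(sprintf("%s (%d)", names(table(x$pop_of_hap)),
                                       table(x$pop_of_hap)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.hap_matrix <- function(x) dim(x$G)

# haplotype column indices for a population label
hap_cols <- function(haps, pop) {
  idx <- which(haps$pop_of_hap == pop)
  if (length(idx) == 0L)
    stop("unknown population label: ", pop, call. = FALSE)
  idx
}

# site row indices within a 0-based half-open window on one chromosome
window_rows <- function(haps, chrom, start, end) {
  which(haps$chrom == chrom & haps$pos > start & haps$pos <= end)
}

# subset sites of a hap_matrix
hap_subset <- function(haps, rows) {
  hap_matrix(haps$chrom[rows], haps$pos[rows],
             haps$G[rows, , drop = FALSE],
             haps$sample_of_hap, haps$pop_of_hap, haps$chrom_lengths)
}

#' Concatenate independently simulated loci onto one chromosome
#'
#' Lays out a list of single-locus [hap_matrix] objects along a single
#' chromosome, locus `i` starting at offset `(i - 1) * spacing`.  With
#' `spacing` equal to the locus length this produces a contiguous chromosome
#' made of independent genealogical blocks, a simple stand-in for
#' recombination along a chromosome.
#'
#' @param loci List of `hap_matrix` objects with identical haplotype layout.
#' @param spacing Distance in bp between locus starts; must be at least the
#'   locus length.
#' @param locus_length Length of each locus in bp.
#' @param chrom Chromosome name for the combined object.
#' @return A single [hap_matrix] whose `chrom_lengths` spans all loci.
#' @export
bind_loci <- function(loci, locus_length, spacing = locus_length, chrom = "chr1") {
  stopifnot(length(loci) > 0L, spacing >= locus_length)
  G <- do.call(rbind, lapply(loci, function(l) l$G))
  pos <- unlist(lapply(seq_along(loci), function(i)
    loci[[i]]$pos + (i - 1L) * as.integer(spacing)))
  len <- length(loci) * spacing
  hap_matrix(rep(chrom, length(pos)), pos, G,
             loci[[1L]]$sample_of_hap, loci[[1L]]$pop_of_hap,
             chrom_lengths = setNames(len, chrom))
}
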