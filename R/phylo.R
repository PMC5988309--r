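#' Neighbour-joining tree for a genomic window
#'
#' Builds a rooted tree over haplotypes from the pairwise per-site
#' difference matrix of a window (pairwise-complete denominators),
#' neighbour joining, rooted on the outgroup haplotypes; negative branch
#' lengths are clamped to zero.  A distance-based method is used in place
#' of per-window maximum-likelihood search: it is consistent on additive
#' distances and orders of magnitude faster, and the downstream topology
#' classification is method-agnostic.
#'
#' @param haps A [hap_matrix] including outgroup haplotypes.
#' @param outgroup Population label of the outgroup.
#' @param chrom,start,end Optional window restriction.
#' @return An [ape::phylo] rooted tree; attribute `star` is `TRUE` when
#'   all haplotypes were identical (zero distances).
#' @export
window_tree <- function(haps, outgroup, chrom = NULL, start = NULL,
                        end = NULL) {
  rows <- if (is.null(chrom)) seq_along(haps$pos) else
    window_rows(haps, chrom, start, end)
  if (length(rows) == 0) stop("no usable sites in window")
  G <- haps$G[rows, , drop = FALSE]
  dm <- pair_diff_matrix(G, G)
  d <- dm$diff / pmax(dm$denom, 1)
  rownames(d) <- colnames(d) <- colnames(haps$G)
  og_tips <- colnames(haps$G)[haps$pop_of_hap == outgroup]
  if (length(og_tips) == 0) stop("unknown outgroup population: ", outgroup)
  star <- all(d == 0)
  if (star) d <- d + 1e-9 * (1 - diag(nrow(d)))  # nj needs non-degenerate input
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr <- ape::root(tr, outgroup = og_tips, resolve.root = TRUE)
  attr(tr, "star") <- star
  tr
}

#' Classify a window tree into species / geography / ancestral classes
#'
#' Given a rooted tree whose tips carry lineage labels, assigns:
#' * `species` - each of the three ingroup lineages is monophyletic;
#' * `geography` - otherwise, the two sympatric lineages (first two of
#'   `lineages`) together form a monophyletic group;
#' * `ancestral` - otherwise, the focal lineage groups with the allopatric
#'   lineage (first and third together monophyletic);
#' * `unresolved` - none of the above, or a lineage has no tips.
#'
#' Precedence is species > geography > ancestral.
#'
#' @param tree Rooted [ape::phylo].
#' @param tip_lineage Named character vector tip label -> lineage.
#' @param lineages Length-3 character vector, e.g. `c("JS", "PO", "AT")`:
#'   focal, sympatric-partner, allopatric.
#' @return Character scalar topology class.
#' @export
classify_topology <- function(tree, tip_lineage,
                              lineages = c("JS", "PO", "AT")) {
  groups <- lapply(lineages, function(l)
    intersect(tree$tip.label, names(tip_lineage)[tip_lineage == l]))
  if (any(lengths(groups) == 0)) return("unresolved")
  mono <- function(tips) {
    if (length(tips) == length(tree$tip.label)) return(TRUE)
    ape::is.monophyletic(tree, tips)
  }
  if (all(vapply(groups, mono, TRUE))) return("species")
  if (mono(c(groups[[1]], groups[[2]]))) return("geography")
  if (mono(c(groups[[1]], groups[[3]]))) return("ancestral")
  "unresolved"
}

#' Genealogical sorting index
#'
#' Quantifies the degree of exclusive ancestry of a group of tips on a
#' rooted tree, normalised to `[0, 1]` with 1 attained exactly at
#' monophyly.  Let `I_obs` be the number of internal nodes on the union of
#' paths from the group's tips to their most recent common ancestor
#' (inclusive); for a monophyletic group of `n` tips on a binary tree
#' `I_obs = n - 1`, and any intruding lineage inflates it.  With `M` the
#' total number of internal nodes:
#' `gsi = (1/I_obs - 1/M) / (1/(n-1) - 1/M)`.
#' Relabeling tips outside the group's spanning subtree leaves the index
#' unchanged; moving a group tip deeper into foreign territory can only
#' decrease it.
#'
#' @param tree Rooted binary [ape::phylo].
#' @param tips Character vector of group tip labels (non-empty).
#' @return Numeric in `[0, 1]`; defined as 1 when the group contains all
#'   tips.
#' @export
gsi <- function(tree, tips) {
  stopifnot(length(tips) >= 1)
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("unknown tip labels: ",
                       paste(tips[is.na(idx)], collapse = ", "))
  n <- length(idx)
  n_tips <- length(tree$tip.label)
  if (n == n_tips) return(1)
  if (n == 1) return(1)  # a single tip is trivially exclusive
  M <- tree$Nnode
  parent <- integer(n_tips + M)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  # ascend from each tip, recording visit counts until paths join at mrca
  anc_path <- function(v) {
    path <- integer(0)
    while (v != root) {
      v <- parent[v]
      path <- c(path, v)
    }
    path
  }
  paths <- lapply(idx, anc_path)
  # mrca = deepest node common to all paths
  common <- Reduce(intersect, paths)
  mrca <- common[1]  # paths list ancestors tip->root; first common is mrca
  nodes <- unique(unlist(lapply(paths, function(p)
    p[seq_len(match(mrca, p))])))
  I_obs <- length(nodes)
  lo <- 1 / M
  hi <- 1 / (n - 1)
  if (hi == lo) return(1)
  g <- (1 / I_obs - lo) / (hi - lo)
  min(max(g, 0), 1)
}

#' Per-window tree scan with topology classes and gsi
#'
#' @param haps A [hap_matrix] with `chrom_lengths` and an outgroup
#'   population.
#' @param outgroup Outgroup population label.
#' @param lineages Length-3 lineage vector as in [classify_topology()].
#' @param cfg A [window_config()].
#' @param min_sites Minimum variant sites for a window tree.
#' @return Tibble: window coordinates, `n_sites`, `topo_class`, one
#'   `gsi_*` column per lineage, and a `tree` list-column.
#' @export
window_trees <- function(haps, outgroup, lineages = c("JS", "PO", "AT"),
                         cfg = window_config(), min_sites = 1) {
  stopifnot(!is.null(haps$chrom_lengths))
  tip_lineage <- setNames(haps$pop_of_hap, colnames(haps$G))
  res <- list()
  for (ch in names(haps$chrom_lengths)) {
    wins <- iter_windows(haps$chrom_lengths[[ch]], cfg)
    if (nrow(wins) == 0) next
    for (i in seq_len(nrow(wins))) {
      rows <- window_rows(haps, ch, wins$start[i], wins$end[i])
      row <- tibble::tibble(chrom = ch, start = wins$start[i],
                            end = wins$end[i], n_sites = length(rows))
      if (length(rows) < min_sites) {
        row$topo_class <- "unresolved"
        for (l in lineages) row[[paste0("gsi_", l)]] <- NA_real_
        row$tree <- list(NULL)
      } else {
        tr <- window_tree(haps, outgroup, ch, wins$start[i], wins$end[i])
        row$topo_class <- classify_topology(tr, tip_lineage, lineages)
        for (l in lineages) {
          tps <- names(tip_lineage)[tip_lineage == l]
          row[[paste0("gsi_", l)]] <- if (length(tps) >= 1)
            gsi(tr, tps) else NA_real_
        }
        row$tree <- list(tr)
      }
      res[[length(res) + 1]] <- row
    }
  }
  dplyr::bind_rows(res)
}
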