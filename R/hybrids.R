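#' Simulate hybrid-class diploid genotypes
#'
#' Draws diploid genotypes for pedigree-defined hybrid classes between two
#' parental species A and B with per-locus allele frequencies `p_A` and
#' `p_B` (frequency of the same reference allele, "allele 1", in each
#' parental gene pool).  Gametes are drawn independently per locus (free
#' recombination):
#'
#' * `parentA` / `parentB`: two gametes from the same parental pool;
#' * `F1`: one gamete from each pool;
#' * `F2`: two gametes from F1 parents (each F1 gamete is an A- or B-pool
#'   draw with probability 1/2 per locus);
#' * `BC_A` / `BC_B`: one F1 gamete plus one pure parental gamete.
#'
#' @param p_A,p_B Numeric vectors of allele-1 frequencies, equal length.
#' @param cls One of `"parentA"`, `"parentB"`, `"F1"`, `"F2"`, `"BC_A"`,
#'   `"BC_B"`.
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return Integer matrix `n x n_loci` of allele-1 dosages (0, 1, 2).
#' @export
simulate_hybrid_genotypes <- function(p_A, p_B,
                                      cls = c("parentA", "parentB", "F1",
                                              "F2", "BC_A", "BC_B"),
                                      n = 1, seed = 1) {
  cls <- match.arg(cls)
  if (length(p_A) != length(p_B))
    stop("p_A and p_B must have the same number of loci")
  if (any(p_A < 0 | p_A > 1 | p_B < 0 | p_B > 1))
    stop("allele frequencies must lie in [0, 1]")
  L <- length(p_A)
  set.seed(seed)
  gamete <- function(pool) {
    # pool: "A", "B" or "F1"; returns n x L matrix of 0/1 alleles
    if (pool == "A") matrix(rbinom(n * L, 1, rep(p_A, each = n)), n, L)
    else if (pool == "B") matrix(rbinom(n * L, 1, rep(p_B, each = n)), n, L)
    else {
      # F1 gamete: per locus, the transmitted allele traces to the A or B
      # grandparental gamete with probability 1/2
      pick <- matrix(runif(n * L) < 0.5, n, L)
      a <- gamete("A"); b <- gamete("B")
      ifelse(pick, a, b)
    }
  }
  g <- switch(cls,
              parentA = gamete("A") + gamete("A"),
              parentB = gamete("B") + gamete("B"),
              F1 = gamete("A") + gamete("B"),
              F2 = gamete("F1") + gamete("F1"),
              BC_A = gamete("F1") + gamete("A"),
              BC_B = gamete("F1") + gamete("B"))
  storage.mode(g) <- "integer"
  colnames(g) <- paste0("locus_", seq_len(L))
  g
}
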