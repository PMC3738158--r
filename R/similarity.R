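#' Pairwise shared-allele similarity
#'
#' Counts shared alleles locus by locus with multiset semantics: at one locus
#' the contribution is the size of the multiset intersection of the two
#' genotypes, so a homozygote matched against an identical homozygote counts 2
#' and (1,2) against (1,1) counts 1. Any locus at which either individual
#' dropped out contributes 0. Summed over loci, 0 <= s_xy <= 2m.
#'
#' @param x,y single-individual \code{Population}s (e.g. \code{pop[3]}) with
#'   the same locus count.
#' @return integer shared-allele count.
#' @examples
#' pop <- Population(c("x", "y"),
#'   matrix(c(1L, 1L,  2L, 2L,  1L, 2L), 2),
#'   matrix(c(2L, 1L,  2L, 2L,  3L, 3L), 2))
#' pairSimilarity(pop[1], pop[2])  # 4
#' @export
pairSimilarity <- function(x, y) {
  stopifnot(is(x, "Population"), is(y, "Population"),
            nInd(x) == 1L, nInd(y) == 1L)
  if (nLoci(x) != nLoci(y)) stop("individuals have mismatched locus counts")
  sum(.locusScores(x@alleleA[1, ], x@alleleB[1, ], y@alleleA[1, ], y@alleleB[1, ]))
}

# per-locus multiset intersection size of canonical (a<=b) genotypes
.locusScores <- function(a1, b1, a2, b2) {
  s <- integer(length(a1))
  both <- !is.na(a1) & !is.na(a2)
  eq2 <- both & a1 == a2 & b1 == b2
  eq1 <- both & !eq2 & (a1 == a2 | a1 == b2 | b1 == a2 | b1 == b2)
  s[eq2] <- 2L; s[eq1] <- 1L
  s
}

#' Similarity matrix of a population
#'
#' The n x n symmetric matrix S with S[x, y] = [pairSimilarity()] of
#' individuals x and y, computed in O(n^2 m). Diagonal entries are the
#' self-similarities, 2 x (number of non-missing loci).
#'
#' @param pop a \code{Population}.
#' @return integer matrix with individual ids as dimnames.
#' @export
similarityMatrix <- function(pop) {
  n <- nInd(pop)
  A <- pop@alleleA; B <- pop@alleleB
  S <- matrix(0L, n, n, dimnames = list(pop@ids, pop@ids))
  for (i in seq_len(n)) {
    ai <- A[i, ]; bi <- B[i, ]
    both <- !is.na(A) & !rep(is.na(ai), each = n) # n x m
    # recycle row i across all rows
    Ai <- matrix(ai, n, length(ai), byrow = TRUE)
    Bi <- matrix(bi, n, length(bi), byrow = TRUE)
    eq2 <- both & A == Ai & B == Bi
    eq1 <- both & !eq2 & (A == Ai | A == Bi | B == Ai | B == Bi)
    S[, i] <- as.integer(rowSums(eq2, na.rm = TRUE) * 2L +
                         rowSums(eq1, na.rm = TRUE))
  }
  S
}

#' Export a similarity matrix as TSV
#'
#' @param S matrix from [similarityMatrix()].
#' @param path output path; ids form the header row and first column.
#' @export
writeSimilarity <- function(S, path) {
  utils::write.table(data.frame(id = rownames(S), S, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}
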