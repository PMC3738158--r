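#' Simulate a half-sibling population with ground truth
#'
#' Forward simulator for the regime the reconstruction targets: n/f mothers and
#' n/f fathers each receive two independent uniform alleles from {0..k-1} at
#' every locus. Children are generated from mother-father pairs: each mother
#' raises one brood of f offspring with a single father drawn uniformly at
#' random with replacement from the father pool, so fathers are polygamous
#' (several broods) with variable half-sib family sizes while maternal
#' families are full-sib blocks of size f. Every offspring inherits one
#' uniformly chosen allele from each parent per locus. Deterministic given
#' \code{seed}.
#'
#' @param k alleles per locus (>= 2).
#' @param m number of loci (>= 1).
#' @param n population size; rounded down to a multiple of \code{f} with a
#'   warning if needed.
#' @param f maternal half-sib family size (>= 1).
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @return a \code{SimTruth} with the offspring population, the true maternal
#'   and paternal partitions, and the parental genotypes.
#' @examples
#' st <- simulatePopulation(k = 6, m = 6, n = 40, f = 5, seed = 1)
#' table(tabulate(st@truth@maternal))  # eight maternal families of five
#' @export
simulatePopulation <- function(k = 6, m = 6, n = 40, f = 5, seed = NULL) {
  stopifnot(k >= 2, m >= 1, f >= 1, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  nf <- n %/% f
  if (nf < 1L) stop("population smaller than one family")
  if (nf * f != n) {
    warning("population size ", n, " rounded down to ", nf * f,
            " (multiple of family size ", f, ")")
    n <- nf * f
  }
  drawParents <- function(prefix) {
    Population(paste0(prefix, seq_len(nf)),
               matrix(sample.int(k, nf * m, replace = TRUE) - 1L, nf, m),
               matrix(sample.int(k, nf * m, replace = TRUE) - 1L, nf, m))
  }
  mothers <- drawParents("M")
  fathers <- drawParents("F")
  mom <- rep(seq_len(nf), each = f)
  dad <- rep(sample.int(nf, nf, replace = TRUE), each = f)
  pickM <- matrix(sample(c(TRUE, FALSE), n * m, replace = TRUE), n, m)
  pickF <- matrix(sample(c(TRUE, FALSE), n * m, replace = TRUE), n, m)
  fromM <- ifelse(pickM, mothers@alleleA[mom, , drop = FALSE],
                         mothers@alleleB[mom, , drop = FALSE])
  fromF <- ifelse(pickF, fathers@alleleA[dad, , drop = FALSE],
                         fathers@alleleB[dad, , drop = FALSE])
  pop <- Population(paste0("ind", seq_len(n)), fromM, fromF)
  new("SimTruth", pop = pop,
      truth = SibPartition(pop@ids, mom, dad),
      mothers = mothers, fathers = fathers)
}

#' Inject allelic dropout
#'
#' Sets each (individual, locus) cell fully missing independently with the
#' given probability, emulating allelic dropout.
#'
#' @param x a \code{Population} or \code{SimTruth}.
#' @param rate dropout probability in [0, 1).
#' @param seed optional integer seed.
#' @return object of the same class with dropout applied (ground truth in a
#'   \code{SimTruth} is unchanged).
#' @export
injectDropout <- function(x, rate, seed = NULL) {
  stopifnot(rate >= 0, rate < 1)
  if (is(x, "SimTruth")) {
    x@pop <- injectDropout(x@pop, rate, seed)
    return(x)
  }
  stopifnot(is(x, "Population"))
  if (!is.null(seed)) set.seed(seed)
  drop <- matrix(stats::runif(nInd(x) * nLoci(x)) < rate, nInd(x), nLoci(x))
  a <- x@alleleA; b <- x@alleleB
  a[drop] <- NA_integer_; b[drop] <- NA_integer_
  Population(x@ids, a, b, x@locusNames)
}

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nInd(object@pop), "offspring of", nInd(object@mothers),
      "mothers and", nInd(object@fathers), "fathers\n")
})
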