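# Closed-form / enumerative expectations behind the shared-allele similarity
# measure, and the single-locus triplet-compatibility fractions.
#
# Throughout, an individual's single-locus genotype is two i.i.d. uniform
# draws from a k-allele pool, which induces weight 2 on each heterozygote and
# 1 on each homozygote (total weight k^2 per individual).

.analyticsCache <- new.env(parent = emptyenv())

# all unordered genotypes over 1..k with their sampling weights
.genotypePool <- function(k) {
  g <- t(utils::combn(k, 2L))
  g <- rbind(g, cbind(seq_len(k), seq_len(k)))
  list(a = g[, 1], b = g[, 2], w = c(rep(2, k * (k - 1) / 2), rep(1, k)))
}

# multiset intersection size of genotype pairs, vectorised
.sharedCount <- function(a1, b1, a2, b2) {
  lo1 <- pmin(a1, b1); hi1 <- pmax(a1, b1)
  lo2 <- pmin(a2, b2); hi2 <- pmax(a2, b2)
  eq2 <- lo1 == lo2 & hi1 == hi2
  eq1 <- !eq2 & (lo1 == lo2 | lo1 == hi2 | hi1 == lo2 | hi1 == hi2)
  2 * eq2 + eq1
}

# exact enumeration of E[X | relationship] at one locus for small k.
# full: two shared parents; half: one shared parent, the other contribution is
# a uniform allele (marginal of an independent parent); unrelated: four
# independent uniform alleles.
.enumExpectedShared <- function(relationship, k) {
  switch(relationship,
    unrelated = {
      g <- .genotypePool(k)
      i <- rep(seq_along(g$a), each = length(g$a))
      j <- rep(seq_along(g$a), times = length(g$a))
      sum(g$w[i] * g$w[j] *
            .sharedCount(g$a[i], g$b[i], g$a[j], g$b[j])) / k^4
    },
    half = {
      par <- expand.grid(u = seq_len(k), v = seq_len(k),
                         c1 = seq_len(k), c2 = seq_len(k))
      tot <- 0
      for (h1 in 1:2) for (h2 in 1:2) {
        a1 <- if (h1 == 1) par$u else par$v
        a2 <- if (h2 == 1) par$u else par$v
        tot <- tot + sum(.sharedCount(a1, par$c1, a2, par$c2))
      }
      tot / (4 * k^4)
    },
    full = {
      par <- expand.grid(m1 = seq_len(k), m2 = seq_len(k),
                         p1 = seq_len(k), p2 = seq_len(k))
      tot <- 0
      for (i1 in 1:2) for (j1 in 1:2) for (i2 in 1:2) for (j2 in 1:2) {
        a1 <- if (i1 == 1) par$m1 else par$m2
        b1 <- if (j1 == 1) par$p1 else par$p2
        a2 <- if (i2 == 1) par$m1 else par$m2
        b2 <- if (j2 == 1) par$p1 else par$p2
        tot <- tot + sum(.sharedCount(a1, b1, a2, b2))
      }
      tot / (16 * k^4)
    })
}

# E[X] * 16 * k^4 is an integer polynomial in k of degree <= 4 (enumeration
# states scale as k^4 with denominators 1, 4 or 16). Interpolate it exactly
# from small-k enumerations so large k is evaluated in closed form.
.sharedPolynomial <- function(relationship) {
  key <- paste0("poly_", relationship)
  if (!is.null(.analyticsCache[[key]])) return(.analyticsCache[[key]])
  ks <- 2:8
  vals <- vapply(ks, function(k) .enumExpectedShared(relationship, k) * 16 * k^4, 0)
  V <- outer(ks, 0:(length(ks) - 1), "^")
  coef <- solve(V, vals)
  stopifnot(max(abs(coef - round(coef))) < 1e-6,
            all(abs(round(coef[6:7])) == 0))  # degree really is <= 4
  coef <- round(coef)[1:5]
  .analyticsCache[[key]] <- coef
  coef
}

#' Expected shared alleles at one locus
#'
#' Exact expectation of the number of shared alleles X between two individuals
#' at a single locus with k equally frequent alleles, for full siblings (both
#' parents shared), half siblings (one shared parent) or unrelated pairs. For
#' small k the value is computed by exhaustive enumeration over parental
#' draws and Mendelian inheritance; for large k the same quantity is evaluated
#' through an exactly interpolated polynomial in k (the two agree wherever
#' both apply). As k grows the expectations tend to 1, 1/2 and 0, and the
#' unrelated case has the closed form (4k^2 - 4k + 2) / k^3.
#'
#' @param relationship "full", "half" or "unrelated".
#' @param k number of alleles (>= 2).
#' @param method "auto" (default: enumeration for k <= 25, polynomial beyond),
#'   "enumeration" or "closed" (polynomial / closed form).
#' @return numeric in [0, 2].
#' @examples
#' expectedSharedAlleles("unrelated", 2)  # 1.25
#' @export
expectedSharedAlleles <- function(relationship = c("full", "half", "unrelated"),
                                  k, method = c("auto", "enumeration", "closed")) {
  relationship <- match.arg(relationship)
  method <- match.arg(method)
  stopifnot(k >= 2)
  if (method == "auto")
    method <- if (k <= 25) "enumeration" else "closed"
  if (method == "enumeration") return(.enumExpectedShared(relationship, k))
  if (relationship == "unrelated") return((4 * k^2 - 4 * k + 2) / k^3)
  coef <- .sharedPolynomial(relationship)
  # evaluate sum(coef[d+1] k^d) / (16 k^4) in powers of 1/k for stability
  sum(coef * (1 / k)^(4:0)) / 16
}

#' Hoeffding bound on mean similarity deviation
#'
#' For m independent loci with per-locus shared-allele counts in [0, 2], the
#' probability that the mean shared-allele count deviates from its expectation
#' by at least t is bounded by 2 exp(-t^2 m / 2). This is why the pairwise
#' measure separates relationship classes once m (or k) is moderately large.
#'
#' @param t deviation (>= 0).
#' @param m number of loci (>= 1).
#' @return the bound (may exceed 1 for small t).
#' @export
hoeffdingDeviationBound <- function(t, m) {
  stopifnot(t >= 0, m >= 1)
  2 * exp(-t^2 * m / 2)
}

#' Fraction of random triplets compatible as half or full siblings
#'
#' Probability that three individuals, each with two i.i.d. uniform alleles
#' from a k-allele pool at one locus, pass the half-sibship property
#' ([halfSibCompatible()]) or the full-sibling 4-allele + 2-allele properties
#' ([fullSibCompatible()]). Computed by exact weighted enumeration over all
#' genotype triples, using the same compatibility predicates as the
#' clustering. Triples are grouped by their allele-labelling pattern, so each
#' distinct pattern is tested once.
#'
#' These fractions quantify why half-sib incompatibility is a weak signal:
#' with five alleles most random triplets are half-sib compatible.
#'
#' @param relationship "half" or "full".
#' @param k number of alleles (>= 2).
#' @return probability in [0, 1].
#' @examples
#' round(tripletCompatibilityFraction("half", 5), 4)  # 0.9662
#' @export
tripletCompatibilityFraction <- function(relationship = c("half", "full"), k) {
  relationship <- match.arg(relationship)
  stopifnot(k >= 2)
  key <- paste0("trip_", relationship, "_", k)
  if (!is.null(.analyticsCache[[key]])) return(.analyticsCache[[key]])
  g <- .genotypePool(k)
  ng <- length(g$a)
  trip <- expand.grid(i = seq_len(ng), j = seq_len(ng), t = seq_len(ng))
  X <- cbind(g$a[trip$i], g$b[trip$i], g$a[trip$j], g$b[trip$j],
             g$a[trip$t], g$b[trip$t])
  w <- g$w[trip$i] * g$w[trip$j] * g$w[trip$t]
  # canonical pattern: relabel alleles by order of first appearance
  pat <- apply(X, 1L, function(r) paste(match(r, unique(r)), collapse = ""))
  patW <- rowsum(w, pat)
  pred <- if (relationship == "half") halfSibCompatible else fullSibCompatible
  ok <- vapply(rownames(patW), function(p) {
    r <- as.integer(strsplit(p, "")[[1]])
    pop <- Population(c("t1", "t2", "t3"),
                      matrix(r[c(1, 3, 5)], 3), matrix(r[c(2, 4, 6)], 3))
    pred(pop, 1:3)
  }, NA)
  res <- sum(patW[ok]) / as.numeric(k)^6
  .analyticsCache[[key]] <- res
  res
}

#' Tabulated similarity analytics
#'
#' @param k number of alleles.
#' @return data.frame of expected shared alleles per relationship and the
#'   half/full triplet compatibility fractions at this k.
#' @export
similarityAnalytics <- function(k) {
  data.frame(
    relationship = c("full", "half", "unrelated"),
    expectedShared = c(expectedSharedAlleles("full", k),
                       expectedSharedAlleles("half", k),
                       expectedSharedAlleles("unrelated", k)),
    tripletCompatible = c(tripletCompatibilityFraction("full", k),
                          tripletCompatibilityFraction("half", k), NA))
}
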