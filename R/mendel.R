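# Genotype codes: an unordered pair (a <= b) of alleles < 2^15 is stored as
# a * 2^15 + b. Codes only exist inside ParentSet algebra and never leak into
# output.
.CODE_BASE <- 32768L

genotypeCode <- function(a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  stopifnot(all(hi < .CODE_BASE))
  as.numeric(lo) * .CODE_BASE + as.numeric(hi)
}

genotypeDecode <- function(code) {
  lo <- floor(code / .CODE_BASE)
  rbind(as.integer(lo), as.integer(code - lo * .CODE_BASE))
}

#' Initial feasible parent set of one individual
#'
#' At a non-missing locus with genotype (a, b), the shared parent of any
#' half-sibship containing this individual must carry a or b, so the feasible
#' set is every unordered genotype over the locus allele set A_l containing a
#' or b — at most 2k - 1 genotypes, i.e. O(k). Dropout loci place no
#' restriction on the parent and are UNRESTRICTED (\code{NULL}).
#'
#' @param pop a \code{Population}.
#' @param i individual index or id.
#' @param sets optional precomputed [alleleSets()] of the population.
#' @return a \code{ParentSet}.
#' @export
initialParentSet <- function(pop, i, sets = alleleSets(pop)) {
  if (is.character(i)) i <- match(i, pop@ids)
  m <- nLoci(pop)
  out <- vector("list", m)
  for (l in seq_len(m)) {
    a <- pop@alleleA[i, l]
    if (is.na(a)) { out[l] <- list(NULL); next }
    b <- pop@alleleB[i, l]
    A <- sets[[l]]
    out[[l]] <- sort(unique(c(genotypeCode(A, a), genotypeCode(A, b))))
  }
  new("ParentSet", sets = out)
}

#' Intersect two parent sets
#'
#' Per-locus set intersection; UNRESTRICTED (\code{NULL}) is the identity. An
#' empty set at any locus means no single parent can explain the combined
#' group, so a proposed join must be rejected.
#'
#' @param p,q \code{ParentSet}s over the same loci.
#' @return a \code{ParentSet}.
#' @export
intersectParentSets <- function(p, q) {
  if (length(p@sets) != length(q@sets)) stop("parent sets have mismatched locus counts")
  out <- vector("list", length(p@sets))
  for (l in seq_along(out)) {
    ps <- p@sets[[l]]; qs <- q@sets[[l]]
    out[l] <- if (is.null(ps)) list(qs) else if (is.null(qs)) list(ps)
              else list(intersect(ps, qs))
  }
  new("ParentSet", sets = out)
}

#' @describeIn intersectParentSets TRUE iff the set is non-empty at every locus
#'   (an UNRESTRICTED locus counts as non-empty).
#' @export
parentSetNonEmpty <- function(p)
  all(vapply(p@sets, function(s) is.null(s) || length(s) > 0L, NA))

setMethod("show", "ParentSet", function(object) {
  sz <- vapply(object@sets, function(s) if (is.null(s)) NA_integer_ else length(s), 0L)
  cat("ParentSet over", length(sz), "loci; sizes:",
      paste(ifelse(is.na(sz), "*", sz), collapse = " "), "\n")
})

#' Half-sibship compatibility of a group
#'
#' A group can be a half-sib family iff at every locus there is an unordered
#' allele pair (the shared parent's genotype) such that every non-missing
#' member carries at least one of the two alleles. Equivalent to non-emptiness
#' of the intersection of the members' initial parent sets.
#'
#' @param pop a \code{Population}.
#' @param members indices or ids of the group (non-empty).
#' @return logical.
#' @examples
#' sext <- Population(paste0("s", 1:6),
#'                    matrix(c(1L,1L,1L,2L,2L,3L), 6),
#'                    matrix(c(2L,3L,4L,3L,4L,4L), 6))
#' halfSibCompatible(sext, 1:6)  # FALSE: the parent would need 3 alleles
#' halfSibCompatible(sext, 1:5)  # TRUE
#' @export
halfSibCompatible <- function(pop, members) {
  if (is.character(members)) members <- match(members, pop@ids)
  stopifnot(length(members) > 0L)
  for (l in seq_len(nLoci(pop))) {
    a <- pop@alleleA[members, l]; b <- pop@alleleB[members, l]
    keep <- !is.na(a)
    a <- a[keep]; b <- b[keep]
    if (length(a) <= 2L) next  # any two genotypes' left alleles cover them
    obs <- unique(c(a, b))
    ok <- FALSE
    for (u in seq_along(obs)) {
      for (v in u:length(obs)) {
        if (all(a == obs[u] | a == obs[v] | b == obs[u] | b == obs[v])) {
          ok <- TRUE; break
        }
      }
      if (ok) break
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Full-sibling compatibility of a group
#'
#' Checks the 4-allele property (at most four alleles per locus across the
#' group) and the 2-allele property: there must exist two parent genotypes
#' such that every member's genotype takes one allele from each. The parent
#' pair is found by exhaustive enumeration over the at most four observed
#' alleles (at most 10 x 10 candidate genotype pairs per locus), which is
#' exact. Dropout loci are skipped.
#'
#' @inheritParams halfSibCompatible
#' @return logical.
#' @export
fullSibCompatible <- function(pop, members) {
  if (is.character(members)) members <- match(members, pop@ids)
  stopifnot(length(members) > 0L)
  for (l in seq_len(nLoci(pop))) {
    a <- pop@alleleA[members, l]; b <- pop@alleleB[members, l]
    keep <- !is.na(a)
    a <- a[keep]; b <- b[keep]
    if (length(a) <= 1L) next  # a single child is explained by its own parents
    obs <- unique(c(a, b))
    if (length(obs) > 4L) return(FALSE)
    het <- if (length(obs) >= 2L) t(utils::combn(obs, 2L)) else NULL
    cand <- rbind(het, cbind(obs, obs), deparse.level = 0)
    ok <- FALSE
    for (im in seq_len(nrow(cand))) {
      for (ip in seq_len(nrow(cand))) {
        M <- cand[im, ]; P <- cand[ip, ]
        split1 <- (a %in% M) & (b %in% P)
        split2 <- (b %in% M) & (a %in% P)
        if (all(split1 | split2)) { ok <- TRUE; break }
      }
      if (ok) break
    }
    if (!ok) return(FALSE)
  }
  TRUE
}
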