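# Accuracy metrics for comparing half-sib partitionings: variation of
# information (VI), the sex-symmetric normalized half-sibling VI, partition
# distance via maximum-weight bipartite matching, and a combined report.

.membership <- function(p) {
  if (is(p, "SibPartition")) stop("pass one side of a SibPartition, not the object")
  as.integer(factor(p))
}

#' Variation of information between two partitionings
#'
#' VI(P, Q) = H(P) + H(Q) - 2 I(P, Q) under the empirical joint
#' block-membership distribution, in nats. VI is a metric on partitions: it is
#' 0 iff the partitions are identical and at most log(n).
#'
#' @param p,q partitionings of the same universe, given as membership vectors
#'   (cluster label per individual, any label type).
#' @return non-negative numeric.
#' @examples
#' variationOfInformation(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 2 log 2
#' @export
variationOfInformation <- function(p, q) {
  if (length(p) != length(q)) stop("partitionings cover different universes")
  n <- length(p)
  joint <- table(p, q) / n
  pi <- rowSums(joint); qj <- colSums(joint)
  H <- function(w) { w <- w[w > 0]; -sum(w * log(w)) }
  nz <- joint > 0
  I <- sum(joint[nz] * log(joint[nz] / outer(pi, qj)[nz]))
  max(0, H(pi) + H(qj) - 2 * I)
}

#' Normalized half-sibling variation of information
#'
#' Half-sib reconstructions come as a maternal/paternal pair whose sex labels
#' are arbitrary, so the score averages the two per-side VIs under both
#' possible sex pairings, keeps the smaller, and normalizes by log(n):
#' \deqn{HSVI = \min\{(VI(M,M') + VI(P,P'))/2,\ (VI(M,P') + VI(P,M'))/2\} / \log n}
#' The result lies in [0, 1]; 0 means perfect recovery up to sex labels.
#'
#' @param truth,inferred \code{SibPartition}s over the same individuals (the
#'   inferred partition is matched to the truth's id order).
#' @return numeric in [0, 1].
#' @export
hsvi <- function(truth, inferred) {
  stopifnot(is(truth, "SibPartition"), is(inferred, "SibPartition"))
  ord <- match(truth@ids, inferred@ids)
  if (anyNA(ord)) stop("partitions cover different individuals")
  n <- length(truth@ids)
  M <- truth@maternal; P <- truth@paternal
  Mi <- inferred@maternal[ord]; Pi <- inferred@paternal[ord]
  if (n < 2) return(0)  # single-individual partitions are always identical
  v1 <- (variationOfInformation(M, Mi) + variationOfInformation(P, Pi)) / 2
  v2 <- (variationOfInformation(M, Pi) + variationOfInformation(P, Mi)) / 2
  min(v1, v2) / log(n)
}

#' Partition distance
#'
#' The minimum number of individuals that must be removed so that the two
#' partitionings become identical: n minus the maximum-weight matching between
#' blocks of P and blocks of Q, weighted by intersection sizes.
#'
#' @inheritParams variationOfInformation
#' @return non-negative integer.
#' @export
partitionDistance <- function(p, q) {
  if (length(p) != length(q)) stop("partitionings cover different universes")
  n <- length(p)
  tab <- table(p, q)
  nb1 <- nrow(tab); nb2 <- ncol(tab)
  idx <- which(tab > 0, arr.ind = TRUE)
  edges <- rbind(idx[, 1], nb1 + idx[, 2])
  g <- igraph::make_bipartite_graph(rep(c(FALSE, TRUE), c(nb1, nb2)),
                                    as.vector(edges))
  mw <- igraph::max_bipartite_match(g, weights = tab[idx])$matching_weight
  as.integer(n - mw)
}

#' Compare an inferred half-sib reconstruction with the truth
#'
#' @inheritParams hsvi
#' @return list with per-side VIs under the best sex pairing, the normalized
#'   \code{hsvi}, per-side partition distances, \code{misplaced} (the ids
#'   outside the maximum-weight block matching on either side, i.e. a minimum
#'   set whose removal reconciles the partitions), and \code{falsePositives},
#'   the larger of the two per-side removal counts.
#' @export
evaluatePartition <- function(truth, inferred) {
  stopifnot(is(truth, "SibPartition"), is(inferred, "SibPartition"))
  ord <- match(truth@ids, inferred@ids)
  if (anyNA(ord)) stop("partitions cover different individuals")
  M <- truth@maternal; P <- truth@paternal
  Mi <- inferred@maternal[ord]; Pi <- inferred@paternal[ord]
  v1 <- c(variationOfInformation(M, Mi), variationOfInformation(P, Pi))
  v2 <- c(variationOfInformation(M, Pi), variationOfInformation(P, Mi))
  if (mean(v2) < mean(v1)) { tmp <- Mi; Mi <- Pi; Pi <- tmp; v1 <- v2 }
  pd <- c(maternal = partitionDistance(M, Mi), paternal = partitionDistance(P, Pi))
  mis <- union(.unmatchedIds(truth@ids, M, Mi), .unmatchedIds(truth@ids, P, Pi))
  list(viMaternal = v1[1], viPaternal = v1[2],
       hsvi = hsvi(truth, inferred),
       partitionDistance = pd,
       misplaced = mis,
       falsePositives = max(pd))
}

# ids outside the maximum-weight matching between blocks of p and q
.unmatchedIds <- function(ids, p, q) {
  tab <- table(p, q)
  nb1 <- nrow(tab); nb2 <- ncol(tab)
  idx <- which(tab > 0, arr.ind = TRUE)
  g <- igraph::make_bipartite_graph(rep(c(FALSE, TRUE), c(nb1, nb2)),
                                    as.vector(rbind(idx[, 1], nb1 + idx[, 2])))
  mt <- igraph::max_bipartite_match(g, weights = tab[idx])$matching
  pf <- as.integer(factor(p)); qf <- as.integer(factor(q))
  keep <- !is.na(mt[pf]) & mt[pf] == nb1 + qf
  ids[!keep]
}
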