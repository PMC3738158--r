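# SibJoin: Mendelian-constrained single-linkage agglomeration.
#
# State lives in a mutable environment: 2n clusters (two per individual, one
# per parental side), each with a member set and a feasible parent set; a
# cluster-level single-linkage similarity matrix; and the bipartite cluster
# graph, kept as an adjacency-count matrix in which every individual is an
# edge between its two clusters.

#' Single-linkage similarity between two clusters
#'
#' max s_xy over cross pairs x in Ci, y in Cj, from a precomputed
#' [similarityMatrix()].
#'
#' @param membersI,membersJ integer indices of the two clusters' members.
#' @param S similarity matrix of the population.
#' @return integer.
#' @export
clusterSimilarity <- function(membersI, membersJ, S)
  max(S[membersI, membersJ, drop = FALSE])

.sjInit <- function(pop, S) {
  n <- nInd(pop)
  e <- new.env(parent = emptyenv())
  e$pop <- pop
  e$n <- n
  sets <- alleleSets(pop)
  ips <- lapply(seq_len(n), function(i) initialParentSet(pop, i, sets))
  e$members <- c(lapply(seq_len(n), identity), lapply(seq_len(n), identity))
  e$parentSet <- c(ips, ips)
  e$live <- rep(TRUE, 2L * n)
  e$clusterOf <- cbind(seq_len(n), n + seq_len(n))
  e$adj <- matrix(0L, 2L * n, 2L * n)
  e$adj[cbind(seq_len(n), n + seq_len(n))] <- 1L
  e$adj[cbind(n + seq_len(n), seq_len(n))] <- 1L
  e$CS <- rbind(cbind(S, S), cbind(S, S))  # 2n x 2n single-linkage matrix
  diag(e$CS) <- -1L
  e$size <- rep(1L, 2L * n)
  e$minId <- c(pop@ids, pop@ids)
  e
}

# 2-coloring of the live cluster graph; returns integer colors (0/1) or NULL
# if not bipartite (an individual's own two clusters merging shows up as a
# self-loop, which also fails).
.sjColoring <- function(e) {
  if (any(diag(e$adj) > 0L)) return(NULL)
  color <- rep(NA_integer_, length(e$live))
  for (s in which(e$live)) {
    if (!is.na(color[s])) next
    color[s] <- 0L; queue <- s
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      for (v in which(e$adj[u, ] > 0L)) {
        if (is.na(color[v])) { color[v] <- 1L - color[u]; queue <- c(queue, v) }
        else if (color[v] == color[u]) return(NULL)
      }
    }
  }
  color
}

# full-sib families implied if clusters ci and cj merge: members of the merged
# cluster grouped by their other-side cluster.
.sjImpliedFamilies <- function(e, ci, cj) {
  mem <- c(e$members[[ci]], e$members[[cj]])
  own <- rep(c(ci, cj), c(length(e$members[[ci]]), length(e$members[[cj]])))
  other <- ifelse(e$clusterOf[mem, 1] == own, e$clusterOf[mem, 2], e$clusterOf[mem, 1])
  split(mem, other)
}

# Attempt join(ci <- cj); mutates e on accept only.
.sjTryJoin <- function(e, ci, cj) {
  stopifnot(e$live[ci], e$live[cj])
  if (ci == cj || e$adj[ci, cj] > 0L) return("reject:self")
  ps <- intersectParentSets(e$parentSet[[ci]], e$parentSet[[cj]])
  if (!parentSetNonEmpty(ps)) return("reject:empty-parent-set")
  for (fam in .sjImpliedFamilies(e, ci, cj))
    if (length(fam) >= 2L && !fullSibCompatible(e$pop, fam))
      return("reject:full-sib")
  # tentatively contract cj into ci and 2-color
  rowI <- e$adj[ci, ]; rowJ <- e$adj[cj, ]
  e$adj[ci, ] <- e$adj[ci, ] + e$adj[cj, ]
  e$adj[, ci] <- e$adj[, ci] + e$adj[, cj]
  e$adj[cj, ] <- 0L; e$adj[, cj] <- 0L
  e$adj[ci, ci] <- rowI[cj] + rowJ[ci]  # shared individuals become self-loops
  e$live[cj] <- FALSE
  if (is.null(.sjColoring(e))) {
    e$adj[ci, ] <- rowI; e$adj[, ci] <- rowI
    e$adj[cj, ] <- rowJ; e$adj[, cj] <- rowJ
    e$adj[ci, cj] <- rowI[cj]; e$adj[cj, ci] <- rowI[cj]
    e$live[cj] <- TRUE
    return("reject:bipartite")
  }
  e$clusterOf[e$clusterOf == cj] <- ci
  e$members[[ci]] <- c(e$members[[ci]], e$members[[cj]])
  e$members[[cj]] <- integer(0)
  e$parentSet[[ci]] <- ps
  e$CS[ci, ] <- pmax(e$CS[ci, ], e$CS[cj, ])
  e$CS[, ci] <- pmax(e$CS[, ci], e$CS[, cj])
  e$CS[ci, ci] <- -1L
  e$CS[cj, ] <- -1L; e$CS[, cj] <- -1L
  e$size[ci] <- e$size[ci] + e$size[cj]
  e$minId[ci] <- min(e$minId[ci], e$minId[cj])
  "accept"
}

#' Reconstruct half-sibling partitions with SibJoin
#'
#' Constrained single-linkage agglomeration. The algorithm starts from 2n
#' singleton clusters (one maternal-side and one paternal-side cluster per
#' individual) and sweeps candidate similarity levels s from 2m down to 1. At
#' each level every live cluster pair with single-linkage similarity s is a
#' candidate; pairs whose merge would create or extend a full-sib family are
#' attempted first, then the rest, breaking ties by larger combined size and
#' then by smallest member id. A join is accepted only if (a) the intersected
#' feasible parent set is non-empty at every locus, (b) the cluster graph
#' stays bipartite (each individual keeps one parent of each sex), and (c)
#' every implied full-sib family M intersect P passes the 4-allele/2-allele
#' check. After an accepted join the sweep restarts at the current level,
#' since new joins can enable others at the same similarity. The algorithm is
#' deterministic given the input order; \code{seed} is kept in the interface
#' for future randomized tie-breaking but is unused.
#'
#' @param pop a \code{Population}.
#' @param mode \code{"both"} reconstructs maternal and paternal partitions;
#'   \code{"single"} runs the same algorithm but reports the side with the
#'   larger mean cluster size as the (single) reconstructed parent, leaving
#'   the other side as singletons — for data where only one sex is polygamous
#'   or sampled.
#' @param seed unused; retained in the interface.
#' @param audit if TRUE (default), assert the structural invariants on the
#'   final state (non-empty parent sets, bipartiteness, half-sib validity of
#'   every cluster, full-sib validity of every implied family).
#' @return a \code{SibPartition}.
#' @examples
#' st <- simulatePopulation(k = 6, m = 20, n = 40, f = 5, seed = 7)
#' sp <- sibJoin(st@pop)
#' hsvi(st@truth, sp)
#' @export
sibJoin <- function(pop, mode = c("both", "single"), seed = NULL, audit = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is(pop, "Population"))
  S <- similarityMatrix(pop)
  e <- .sjInit(pop, S)
  s <- 2L * nLoci(pop)
  while (s >= 1L) {
    lv <- which(e$live)
    cand <- which(e$CS[lv, lv, drop = FALSE] == s, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ci <- lv[cand[, 1]]; cj <- lv[cand[, 2]]
    adjacent <- e$adj[cbind(ci, cj)] > 0L
    ci <- ci[!adjacent]; cj <- cj[!adjacent]
    if (length(ci) == 0L) { s <- s - 1L; next }
    common <- e$adj %*% e$adj  # two-step connections: merge forms a full family
    fullFirst <- common[cbind(ci, cj)] > 0
    combined <- e$size[ci] + e$size[cj]
    lex <- pmin(e$minId[ci], e$minId[cj])
    accepted <- FALSE
    for (t in order(!fullFirst, -combined, lex)) {
      if (.sjTryJoin(e, ci[t], cj[t]) == "accept") { accepted <- TRUE; break }
    }
    # a merge can raise other pairs' single-linkage similarity above the
    # current level and can unblock previously rejected pairs, so an accepted
    # join restarts the sweep from the top
    s <- if (accepted) 2L * nLoci(pop) else s - 1L
  }
  if (audit) .sjAudit(e)
  color <- .sjColoring(e)
  colOf1 <- color[e$clusterOf[, 1]]
  maternal <- ifelse(colOf1 == 0L, e$clusterOf[, 1], e$clusterOf[, 2])
  paternal <- ifelse(colOf1 == 0L, e$clusterOf[, 2], e$clusterOf[, 1])
  maternal <- as.integer(factor(maternal))
  paternal <- as.integer(factor(paternal))
  if (mode == "single") {
    m1 <- mean(tabulate(maternal)[maternal])
    m2 <- mean(tabulate(paternal)[paternal])
    if (m2 > m1) maternal <- paternal
    paternal <- seq_along(paternal)
  }
  SibPartition(pop@ids, maternal, paternal)
}

# invariant audit of the final clustering state
.sjAudit <- function(e) {
  stopifnot(!is.null(.sjColoring(e)))
  for (cl in which(e$live)) {
    stopifnot(length(e$members[[cl]]) > 0L,
              parentSetNonEmpty(e$parentSet[[cl]]),
              halfSibCompatible(e$pop, e$members[[cl]]))
  }
  counts <- tabulate(as.vector(e$clusterOf), nbins = length(e$live))
  stopifnot(all(counts[e$live] == lengths(e$members)[e$live]),
            sum(counts) == 2L * e$n)
  for (fam in split(seq_len(e$n), paste(e$clusterOf[, 1], e$clusterOf[, 2])))
    if (length(fam) >= 2L) stopifnot(fullSibCompatible(e$pop, fam))
  invisible(TRUE)
}
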