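# The minimum-individual-removal 0/1 integer program: given a population and a
# candidate half-sib partitioning, find the smallest set of individuals whose
# removal leaves a Mendelian-valid structure (a genotype can be assigned to
# every family's shared parent so that each remaining child inherits one
# allele from each of its two families' parents).

#' Build a removal problem from a population and partitioning
#'
#' Assembles the family multiset C (maternal families first, then paternal),
#' the maps pi0/pi1 from each individual to its two family indices, and the
#' maps lambda0/lambda1 from each individual's two alleles to indices in the
#' per-locus allele set K. Dropout loci get NA lambda entries and generate no
#' constraints: a missing locus cannot force an incompatibility.
#'
#' @param pop a \code{Population}.
#' @param partition a \code{SibPartition} covering the same individuals.
#' @return a \code{RemovalProblem}.
#' @export
buildRemovalProblem <- function(pop, partition) {
  stopifnot(is(pop, "Population"), is(partition, "SibPartition"))
  ord <- match(pop@ids, partition@ids)
  if (anyNA(ord)) stop("partition does not cover the population")
  n <- nInd(pop); m <- nLoci(pop)
  mat <- as.integer(factor(partition@maternal[ord]))
  pat <- as.integer(factor(partition@paternal[ord]))
  nM <- max(mat)
  famMembers <- c(split(seq_len(n), mat), split(seq_len(n), pat))
  names(famMembers) <- NULL
  sets <- alleleSets(pop)
  lam0 <- matrix(NA_integer_, n, m); lam1 <- matrix(NA_integer_, n, m)
  for (l in seq_len(m)) {
    lam0[, l] <- match(pop@alleleA[, l], sets[[l]])
    lam1[, l] <- match(pop@alleleB[, l], sets[[l]])
  }
  new("RemovalProblem", pop = pop, partition = partition,
      famMembers = famMembers,
      famSide = rep(c(0L, 1L), c(nM, length(famMembers) - nM)),
      pi0 = mat, pi1 = nM + pat,
      lambda0 = lam0, lambda1 = lam1, alleleSets = sets)
}

setMethod("show", "RemovalProblem", function(object) {
  cat("RemovalProblem:", nInd(object@pop), "individuals,",
      length(object@famMembers), "families,", nLoci(object@pop), "loci\n")
})

#' Build the 0/1 integer program of a removal problem
#'
#' Emits the five constraint families of the removal program. Writing y[j,k,l]
#' for "family j's parent carries allele k at locus l", x0/x1 for the two
#' inheritance orientations of child i at locus l and xl for locus
#' incompatibility:
#' \enumerate{
#'   \item sum_k y[j,k,l] <= 2 (a parent has at most two alleles);
#'   \item x0[i,l] + (y[pi0(i),lambda0(i),l] + y[pi1(i),lambda1(i),l])/2 >= 1;
#'   \item x1[i,l] + (y[pi0(i),lambda1(i),l] + y[pi1(i),lambda0(i),l])/2 >= 1;
#'   \item x0[i,l] + x1[i,l] - xl[i,l] <= 1 (both orientations failing marks
#'     the locus incompatible);
#'   \item x_i - xl[i,l] >= 0 (an individual with any incompatible locus must
#'     be removed).
#' }
#' The objective minimises sum_i x_i. Constraints 2-3 are scaled by 2 for
#' integer coefficients. For homozygous children the two orientation
#' constraints coincide and are kept as printed. The model has O(m n)
#' constraints.
#'
#' @param problem a \code{RemovalProblem}.
#' @return a \code{RemovalModel}.
#' @export
buildRemovalModel <- function(problem) {
  stopifnot(is(problem, "RemovalProblem"))
  n <- nInd(problem@pop); m <- nLoci(problem@pop)
  nfam <- length(problem@famMembers)
  ks <- vapply(problem@alleleSets, length, 0L)
  cumks <- c(0L, cumsum(ks))
  sumk <- cumks[m + 1L]
  # variable layout: x (1..n), then y blocks (family-major, locus, allele),
  # then x0/x1/xl triples per non-missing (individual, locus)
  xVar <- seq_len(n)
  yIdx <- function(j, l, k) n + (j - 1L) * sumk + cumks[l] + k
  pairs <- which(!is.na(problem@lambda0))  # (i, l) linear indices, column-major
  pi_i <- ((pairs - 1L) %% n) + 1L
  pi_l <- ((pairs - 1L) %/% n) + 1L
  npair <- length(pairs)
  auxBase <- n + nfam * sumk
  x0Var <- auxBase + 3L * (seq_len(npair) - 1L) + 1L
  x1Var <- x0Var + 1L
  xlVar <- x0Var + 2L
  nvar <- auxBase + 3L * npair
  k0 <- problem@lambda0[pairs]; k1 <- problem@lambda1[pairs]
  yM0 <- yIdx(problem@pi0[pi_i], pi_l, k0); yP1 <- yIdx(problem@pi1[pi_i], pi_l, k1)
  yM1 <- yIdx(problem@pi0[pi_i], pi_l, k1); yP0 <- yIdx(problem@pi1[pi_i], pi_l, k0)
  # (1) parent allele cardinality: one <= 2 row per family and non-empty locus
  lNon <- which(ks > 0L)
  c1j <- unlist(lapply(seq_len(nfam), function(j)
    unlist(lapply(lNon, function(l) yIdx(j, l, seq_len(ks[l]))))),
    use.names = FALSE)
  c1i <- rep(seq_len(nfam * length(lNon)), times = rep(ks[lNon], nfam))
  ncon1 <- nfam * length(lNon)
  # (2)-(5) per (individual, locus): orientation, incompatibility, removal link
  base <- ncon1
  r2 <- base + seq_len(npair); r3 <- r2 + npair
  r4 <- r3 + npair; r5 <- r4 + npair
  ci <- c(c1i,
          rep(r2, 3L), rep(r3, 3L), rep(r4, 3L), rep(r5, 2L))
  cj <- c(c1j,
          x0Var, yM0, yP1,
          x1Var, yM1, yP0,
          x0Var, x1Var, xlVar,
          xVar[pi_i], xlVar)
  cx <- c(rep(1L, length(c1j)),
          rep(c(2L, 1L, 1L), each = npair),
          rep(c(2L, 1L, 1L), each = npair),
          rep(c(1L, 1L, -1L), each = npair),
          rep(c(1L, -1L), each = npair))
  sense <- c(rep(-1L, ncon1),
             rep(1L, npair), rep(1L, npair), rep(-1L, npair), rep(1L, npair))
  rhs <- c(rep(2L, ncon1),
           rep(2L, npair), rep(2L, npair), rep(1L, npair), rep(0L, npair))
  vt <- data.frame(
    type = c(rep("x", n), rep("y", nfam * sumk),
             rep(c("x0", "x1", "xl"), npair)),
    ind = c(seq_len(n), rep(NA_integer_, nfam * sumk), rep(pi_i, each = 3L)),
    fam = c(rep(NA_integer_, n), rep(seq_len(nfam), each = sumk),
            rep(NA_integer_, 3L * npair)),
    locus = c(rep(NA_integer_, n), rep(rep(seq_len(m), times = ks), nfam),
              rep(pi_l, each = 3L)),
    allele = c(rep(NA_integer_, n),
               rep(unlist(lapply(ks, seq_len)), nfam),
               rep(NA_integer_, 3L * npair)))
  obj <- integer(nvar)
  obj[xVar] <- 1L
  # Branch on removals first (preferring to keep individuals), then parent
  # alleles grouped by locus: loci are independent given the removal set, so
  # locus-major ordering keeps backtracking local to one locus. Within a
  # family and locus, alleles are tried in decreasing child support (how many
  # of the family's children carry them), preferring presence for supported
  # alleles: for a valid partition this descends straight to the true parents.
  yAll <- n + seq_len(nfam * sumk)
  yLocus <- rep(rep(seq_len(m), times = ks), nfam)
  yFam <- rep(seq_len(nfam), each = sumk)
  support <- integer(nfam * sumk)
  for (j in seq_len(nfam)) {
    kids <- problem@famMembers[[j]]
    for (l in which(ks > 0L)) {
      cnt <- vapply(seq_len(ks[l]), function(k)
        sum(problem@lambda0[kids, l] == k | problem@lambda1[kids, l] == k,
            na.rm = TRUE), 0L)
      support[(j - 1L) * sumk + cumks[l] + seq_len(ks[l])] <- cnt
    }
  }
  ord <- order(yLocus, yFam, -support)
  preferred <- integer(nvar)
  preferred[yAll] <- as.integer(support > 0L)
  new("RemovalModel", nvar = as.integer(nvar), obj = obj,
      ci = as.integer(ci), cj = as.integer(cj), cx = as.integer(cx),
      sense = as.integer(sense), rhs = as.integer(rhs),
      varTable = vt, decision = as.integer(c(xVar, yAll[ord])),
      preferred = preferred, problem = problem)
}

setMethod("show", "RemovalModel", function(object) {
  cat("RemovalModel:", object@nvar, "binary variables,",
      length(object@rhs), "constraints\n")
})

#' Solve the minimum-removal program exactly
#'
#' Branch-and-bound with constraint propagation over the binary variables
#' (removals first, then parent alleles; orientation indicators are
#' propagated). Returns the optimum, or the best incumbent with its gap if the
#' time limit strikes first.
#'
#' When no removal budget is given, the solver first climbs budgets
#' iteratively (is the partition valid as is? with one removal? ...), which
#' proves optimality bottom-up, and falls back to a plain incumbent-driven
#' search with the remaining time so that a time-out still reports the best
#' solution found and its gap.
#'
#' @param model a \code{RemovalModel}.
#' @param timeLimit wall-clock limit in seconds (default 300).
#' @param maxRemovals optional removal budget: adds sum x_i <= maxRemovals, so
#'   status "cutoff" proves the optimum exceeds the budget (used to decide
#'   "is this partitioning valid as is?" with \code{maxRemovals = 0}).
#' @return a \code{RemovalSolution}.
#' @export
solveMinRemoval <- function(model, timeLimit = 300, maxRemovals = NA) {
  stopifnot(is(model, "RemovalModel"))
  if (is.na(maxRemovals)) {
    n <- sum(model@varTable$type == "x")
    deadline <- Sys.time() + 0.6 * timeLimit
    lb <- 0
    for (r in 0:n) {
      left <- as.numeric(difftime(deadline, Sys.time(), units = "secs"))
      if (left <= 0) break
      sol <- solveMinRemoval(model, timeLimit = left, maxRemovals = r)
      if (sol@status == "optimal") return(sol)
      if (sol@status == "time-limited") break
      lb <- r + 1
    }
    # deepening inconclusive: plain search for an incumbent with the rest
    sol <- solveMinRemoval(model, timeLimit = max(0.4 * timeLimit, 1),
                           maxRemovals = n)
    sol@status <- if (sol@objective <= lb) "optimal" else "time-limited"
    sol@gap <- if (is.finite(sol@objective)) sol@objective - lb else Inf
    return(sol)
  }
  ci <- model@ci; cj <- model@cj; cx <- model@cx
  sense <- model@sense; rhs <- model@rhs
  if (!is.na(maxRemovals)) {
    xs <- which(model@varTable$type == "x")
    row <- length(rhs) + 1L
    ci <- c(ci, rep(row, length(xs))); cj <- c(cj, xs)
    cx <- c(cx, rep(1L, length(xs)))
    sense <- c(sense, -1L); rhs <- c(rhs, as.integer(maxRemovals))
  }
  # normalise <= rows to >= by negation, then to CSR ordered by constraint
  flip <- sense[ci] == -1L
  cx[flip] <- -cx[flip]
  rhs2 <- ifelse(sense == -1L, -rhs, rhs)
  ord <- order(ci)
  ci <- ci[ord]; cj <- cj[ord]; cx <- cx[ord]
  conStart <- c(0L, cumsum(tabulate(ci, nbins = length(rhs2))))
  res <- .pbSolve(model@nvar, model@obj, conStart, cj - 1L, cx,
                  as.integer(rhs2), model@decision - 1L, model@preferred,
                  timeLimit)
  vt <- model@varTable
  if (is.finite(res$objective)) {
    xs <- which(vt$type == "x" & res$solution[seq_len(model@nvar)] == 1L)
    removed <- model@problem@pop@ids[vt$ind[xs]]
    pg <- .parentGenotypesFromY(model, res$solution)
  } else {
    removed <- character(0); pg <- list()
  }
  gap <- if (res$status == "time-limited") res$objective else 0
  new("RemovalSolution", removed = removed, objective = res$objective,
      status = res$status, gap = gap, parentGenotypes = pg)
}

# reconstruct per-family parent genotypes from the y solution
.parentGenotypesFromY <- function(model, sol) {
  problem <- model@problem
  vt <- model@varTable
  m <- nLoci(problem@pop)
  ys <- which(vt$type == "y" & sol == 1L)
  out <- lapply(problem@famMembers, function(.) {
    g <- matrix(NA_integer_, 2, m)
    rownames(g) <- c("a", "b")
    g
  })
  for (v in ys) {
    j <- vt$fam[v]; l <- vt$locus[v]
    allele <- problem@alleleSets[[l]][vt$allele[v]]
    g <- out[[j]]
    slot <- if (is.na(g[1, l])) 1L else 2L
    g[slot, l] <- allele
    out[[j]] <- g
  }
  # a parent with fewer than two chosen alleles is homozygous/unconstrained
  lapply(out, function(g) { g[2, is.na(g[2, ]) & !is.na(g[1, ])] <-
                              g[1, is.na(g[2, ]) & !is.na(g[1, ])]; g })
}

setMethod("show", "RemovalSolution", function(object) {
  cat("RemovalSolution:", object@status, "| objective", object@objective, "\n")
  if (length(object@removed))
    cat("removed:", paste(object@removed, collapse = ", "), "\n")
})

#' Verify a parental genotype assignment
#'
#' Polynomial-time certificate check of a proposed assignment of shared-parent
#' genotypes: a child is valid at a locus iff its two alleles can be oriented
#' so that each parent's genotype contains the allele attributed to it. A
#' parent genotype identical to the child's forces nothing; a differing parent
#' genotype forces which allele the child inherited from it — both cases are
#' captured by the orientation test. NA parent entries are unconstrained.
#' Dropout loci are skipped.
#'
#' @param problem a \code{RemovalProblem}.
#' @param parentGenotypes list over families of 2 x m allele matrices.
#' @param removed ids to exclude from the check.
#' @return data.frame of violations (id, locus); zero rows means valid.
#' @export
verifyAssignment <- function(problem, parentGenotypes, removed = character(0)) {
  stopifnot(is(problem, "RemovalProblem"),
            length(parentGenotypes) == length(problem@famMembers))
  pop <- problem@pop
  bad_id <- character(0); bad_locus <- integer(0)
  carries <- function(g, l, allele)
    is.na(g[1, l]) || g[1, l] == allele || (!is.na(g[2, l]) && g[2, l] == allele)
  for (i in seq_len(nInd(pop))) {
    if (pop@ids[i] %in% removed) next
    gm <- parentGenotypes[[problem@pi0[i]]]
    gp <- parentGenotypes[[problem@pi1[i]]]
    for (l in seq_len(nLoci(pop))) {
      a <- pop@alleleA[i, l]
      if (is.na(a)) next
      b <- pop@alleleB[i, l]
      ok <- (carries(gm, l, a) && carries(gp, l, b)) ||
            (carries(gm, l, b) && carries(gp, l, a))
      if (!ok) { bad_id <- c(bad_id, pop@ids[i]); bad_locus <- c(bad_locus, l) }
    }
  }
  data.frame(id = bad_id, locus = bad_locus)
}

# is there a valid parent-genotype assignment once `removedIdx` are dropped?
# Loci are independent given the removal set; per locus, backtracking over
# families with candidate genotypes drawn from the family's remaining child
# alleles (any parent allele that matters is inherited by some child).
.removalFeasible <- function(problem, removedIdx) {
  pop <- problem@pop
  keep <- setdiff(seq_len(nInd(pop)), removedIdx)
  if (length(keep) == 0L) return(TRUE)
  for (l in seq_len(nLoci(pop))) {
    childA <- pop@alleleA[, l]; childB <- pop@alleleB[, l]
    present <- keep[!is.na(childA[keep])]
    if (length(present) == 0L) next
    fams <- sort(unique(c(problem@pi0[present], problem@pi1[present])))
    famKids <- lapply(fams, function(j)
      intersect(problem@famMembers[[j]], present))
    cand <- lapply(famKids, function(kids) {
      al <- unique(c(childA[kids], childB[kids]))
      cbind(rep(al, each = length(al)), al)[rep(al, each = length(al)) <= al, ,
                                            drop = FALSE]
    })
    ordF <- order(-lengths(famKids))
    assign <- vector("list", length(fams))
    childOK <- function(i) {
      j0 <- match(problem@pi0[i], fams); j1 <- match(problem@pi1[i], fams)
      g0 <- assign[[j0]]; g1 <- assign[[j1]]
      if (is.null(g0) || is.null(g1)) return(TRUE)  # defer until both set
      a <- childA[i]; b <- childB[i]
      (a %in% g0 && b %in% g1) || (b %in% g0 && a %in% g1)
    }
    bt <- function(t) {
      if (t > length(ordF)) return(TRUE)
      j <- ordF[t]
      for (r in seq_len(nrow(cand[[j]]))) {
        assign[[j]] <<- cand[[j]][r, ]
        if (all(vapply(famKids[[j]], childOK, NA)) && bt(t + 1L)) return(TRUE)
      }
      assign[j] <<- list(NULL)
      FALSE
    }
    if (!bt(1L)) return(FALSE)
  }
  TRUE
}

#' Brute-force minimum removal (test oracle)
#'
#' Exhaustive search over removal subsets in increasing size; a subset is
#' accepted when a parent-genotype assignment exists for every locus
#' (enumerated by backtracking, checked with the same orientation rule as
#' [verifyAssignment()]). Independent of the integer program; intended as its
#' oracle on small instances.
#'
#' @param problem a \code{RemovalProblem}.
#' @param maxRemovals optional search budget; status "cutoff" if exceeded.
#' @param limits size guard, by default at most 12 individuals, 5 alleles and
#'   2 loci (override knowingly for structured instances).
#' @return a \code{RemovalSolution} (without parent genotypes).
#' @export
bruteForceMinRemoval <- function(problem, maxRemovals = NA,
                                 limits = c(ind = 12, k = 5, m = 2)) {
  stopifnot(is(problem, "RemovalProblem"))
  n <- nInd(problem@pop)
  if (n > limits["ind"] || nLoci(problem@pop) > limits["m"] ||
      max(c(0, vapply(problem@alleleSets, length, 0L))) > limits["k"])
    stop("instance too large for brute force; raise `limits` knowingly")
  top <- if (is.na(maxRemovals)) n else min(n, maxRemovals)
  for (r in 0:top) {
    for (rem in if (r == 0) list(integer(0)) else
         asplit(utils::combn(n, r), 2)) {
      if (.removalFeasible(problem, rem))
        return(new("RemovalSolution",
                   removed = problem@pop@ids[rem], objective = r,
                   status = "optimal", gap = 0, parentGenotypes = list()))
    }
  }
  new("RemovalSolution", removed = character(0), objective = Inf,
      status = "cutoff", gap = 0, parentGenotypes = list())
}
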