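# MONOTONE ONE-IN-THREE SAT -> VALID HALF-SIBLING PARTITIONING reduction.
# Three gadgets turn clauses over positive literals into single-locus families:
#   selection   - one maternal family per clause with six children (two copies
#                 of each allele pair from the clause); picking the mother's
#                 genotype picks which literal is true (the absent allele).
#   mapping     - six paternal families per clause that receive the selection
#                 children and tie the chosen mother to fresh clause alleles
#                 s_p through forced inheritance.
#   enforcement - one maternal family per pair of clauses sharing a literal,
#                 consuming (s_p, y_i) mapping children so a literal set true
#                 in one clause stays true in every clause.
# Individuals carrying the shared allele z get a singleton family on their
# unassigned side, adding no further restrictions.

#' Construct a MONOTONE ONE-IN-THREE SAT instance
#'
#' @param clauses list of character vectors of length 3 (distinct positive
#'   literals).
#' @return a \code{SatInstance}.
#' @examples
#' satInstance(list(c("x1", "x2", "x3"), c("x1", "x4", "x5")))
#' @export
satInstance <- function(clauses) {
  clauses <- lapply(clauses, as.character)
  new("SatInstance", variables = unique(unlist(clauses)), clauses = clauses)
}

setMethod("show", "SatInstance", function(object) {
  cat("SatInstance:", length(object@variables), "variables,",
      length(object@clauses), "clauses\n")
})

#' Exhaustive one-in-three satisfiability check
#'
#' @param instance a \code{SatInstance} (small: at most ~20 variables).
#' @return the first satisfying assignment as a named logical vector, or NULL
#'   if no assignment sets exactly one literal per clause true.
#' @export
satBruteForce <- function(instance) {
  vars <- instance@variables
  nv <- length(vars)
  stopifnot(nv <= 20)
  for (mask in 0:(2^nv - 1)) {
    truth <- as.logical(bitwAnd(bitwShiftR(mask, seq_len(nv) - 1L), 1L))
    names(truth) <- vars
    if (all(vapply(instance@clauses, function(cl) sum(truth[cl]) == 1L, NA)))
      return(truth)
  }
  NULL
}

#' Reduce a SAT instance to a half-sibling validity instance
#'
#' Builds the single-locus population and candidate partitioning whose
#' Mendelian validity (minimum removal 0) holds iff the SAT instance has a
#' one-in-three satisfying assignment. Allele codes: literal i maps to allele
#' i, clause p (0-based) to s_p = nVars + 1 + p, and the shared mapping allele
#' z = nVars + nClauses + 2. Each mapping family carrying literal allele y_i
#' at clause p holds max(1, k_i - 1) fresh copies of the (s_p, y_i) child,
#' where k_i counts the clauses containing x_i: one copy for each enforcement
#' pair involving clause p, so no individual is reused across maternal
#' families.
#'
#' @param instance a \code{SatInstance}.
#' @return a \code{SibReduction}.
#' @export
reduceSat <- function(instance) {
  stopifnot(is(instance, "SatInstance"))
  vars <- instance@variables
  nv <- length(vars); nc <- length(instance@clauses)
  stopifnot(nc >= 1)
  lit <- seq_len(nv); names(lit) <- vars
  sAll <- nv + 1L + seq_len(nc) - 1L   # s_p, p = 1..nc
  z <- nv + nc + 2L
  kcount <- vapply(vars, function(v)
    sum(vapply(instance@clauses, function(cl) v %in% cl, NA)), 0L)

  ids <- character(0); a1 <- integer(0); a2 <- integer(0)
  mat <- character(0); pat <- character(0)
  addInd <- function(id, x, y, mfam, pfam) {
    ids <<- c(ids, id); a1 <<- c(a1, x); a2 <<- c(a2, y)
    mat <<- c(mat, mfam); pat <<- c(pat, pfam)
  }
  # pools of unconsumed (s_p, y_i) copies per (clause, literal, mapping side)
  mapCopies <- list()

  for (p in seq_len(nc)) {
    cl <- instance@clauses[[p]]
    y <- lit[cl]  # alleles y_i, y_j, y_k
    sel <- sprintf("Msel_%d", p)
    sp <- sAll[p]
    # selection children: two copies of each pair, maternal = selection family
    pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
    selIds <- list()
    for (q in seq_along(pairs)) {
      for (cp in 0:1) {
        id <- sprintf("sel_%d_%d%d_%d", p, pairs[[q]][1], pairs[[q]][2], cp)
        selIds[[paste(q, cp)]] <- id
        addInd(id, y[pairs[[q]][1]], y[pairs[[q]][2]], sel, NA_character_)
      }
    }
    # six mapping (paternal) families: (selection child, copies of (s_p, y),
    # one fresh (s_p, z), one fresh (y', z))
    mapSpec <- list(  # carried literal index, selection child key, trailing y'
      list(carry = 1L, sel = "1 0", tail = 2L),
      list(carry = 1L, sel = "2 0", tail = 3L),
      list(carry = 2L, sel = "1 1", tail = 1L),
      list(carry = 2L, sel = "3 0", tail = 3L),
      list(carry = 3L, sel = "2 1", tail = 1L),
      list(carry = 3L, sel = "3 1", tail = 2L))
    for (fidx in seq_along(mapSpec)) {
      ms <- mapSpec[[fidx]]
      fam <- sprintf("Pmap_%d_%d", p, fidx)
      pat[ids == selIds[[ms$sel]]] <- fam
      v <- cl[ms$carry]
      ncopies <- max(1L, kcount[v] - 1L)
      copyIds <- character(ncopies)
      for (cp in seq_len(ncopies)) {
        id <- sprintf("map_%d_%d_%s_%d", p, fidx, v, cp)
        copyIds[cp] <- id
        addInd(id, sp, lit[v], NA_character_, fam)
      }
      mapCopies[[sprintf("%d_%s_%d", p, v, fidx %% 2L)]] <- copyIds
      addInd(sprintf("mapz_%d_%d", p, fidx), sp, z, NA_character_, fam)
      addInd(sprintf("tailz_%d_%d", p, fidx), y[ms$tail], z, NA_character_, fam)
    }
  }
  # enforcement maternal families per variable and clause pair
  enfZ <- 0L
  for (v in vars) {
    inCl <- which(vapply(instance@clauses, function(cl) v %in% cl, NA))
    if (length(inCl) < 2L) next
    prs <- utils::combn(inCl, 2L)
    used <- integer(length(inCl)); names(used) <- as.character(inCl)
    for (t in seq_len(ncol(prs))) {
      p <- prs[1, t]; q <- prs[2, t]
      fam <- sprintf("Menf_%s_%d_%d", v, p, q)
      for (pp in c(p, q)) {
        used[as.character(pp)] <- used[as.character(pp)] + 1L
        for (side in 0:1) {
          pool <- mapCopies[[sprintf("%d_%s_%d", pp, v, side)]]
          id <- pool[used[as.character(pp)]]
          stopifnot(!is.na(id))
          mat[ids == id] <- fam
        }
        enfZ <- enfZ + 1L
        addInd(sprintf("enfz_%s_%d_%d_%d", v, p, q, enfZ),
               sAll[pp], z, fam, NA_character_)
      }
    }
  }
  # singleton families for unassigned sides
  mat[is.na(mat)] <- paste0("Msing_", seq_len(sum(is.na(mat))))
  pat[is.na(pat)] <- paste0("Psing_", seq_len(sum(is.na(pat))))
  pop <- Population(ids, matrix(a1, ncol = 1), matrix(a2, ncol = 1), "L1")
  partition <- SibPartition(ids, as.integer(factor(mat)), as.integer(factor(pat)))
  selFams <- vapply(seq_len(nc), function(p)
    partition@maternal[match(sprintf("sel_%d_12_0", p), ids)], 0L)
  new("SibReduction", instance = instance, pop = pop, partition = partition,
      literalAllele = lit, clauseAllele = sAll, zAllele = z,
      selectionFamily = selFams)
}

setMethod("show", "SibReduction", function(object) {
  cat("SibReduction:", length(object@instance@variables), "variables,",
      length(object@instance@clauses), "clauses ->",
      nInd(object@pop), "individuals,",
      length(unique(object@partition@maternal)), "maternal +",
      length(unique(object@partition@paternal)), "paternal families\n")
})

#' Decode a truth assignment from reconstructed parents
#'
#' Given shared-parent genotypes that validate the reduced instance (e.g. from
#' [solveMinRemoval()]), reads each clause's selection-family mother: the
#' clause allele absent from the mother's genotype marks the literal set true.
#' Checks that exactly one literal per clause is true and that the assignment
#' is consistent across clauses.
#'
#' @param reduction a \code{SibReduction}.
#' @param parentGenotypes per-family genotype list, ordered as in the
#'   \code{RemovalProblem} built from \code{reduction} (maternal families
#'   first, in factor order of the partition labels).
#' @return named logical vector over the instance's variables.
#' @export
decodeParentChoice <- function(reduction, parentGenotypes) {
  stopifnot(is(reduction, "SibReduction"))
  truth <- setNames(rep(FALSE, length(reduction@instance@variables)),
                    reduction@instance@variables)
  for (p in seq_along(reduction@instance@clauses)) {
    cl <- reduction@instance@clauses[[p]]
    g <- parentGenotypes[[reduction@selectionFamily[p]]]
    mother <- c(g[1, 1], g[2, 1])
    absent <- cl[!(reduction@literalAllele[cl] %in% mother)]
    if (length(absent) != 1L)
      stop("selection mother of clause ", p,
           " does not single out one literal; not a valid certificate")
    truth[absent] <- TRUE
  }
  bad <- vapply(reduction@instance@clauses,
                function(cl) sum(truth[cl]) != 1L, NA)
  if (any(bad))
    stop("decoded assignment violates one-in-three on clause ", which(bad)[1])
  truth
}
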