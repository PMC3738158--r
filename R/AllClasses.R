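#' @import methods
NULL

#' Diploid microsatellite population
#'
#' A \code{Population} holds unordered diploid genotypes for \code{n}
#' individuals at \code{m} microsatellite loci. Alleles are arbitrary
#' non-negative integer repeat counts; a fully missing locus (allelic dropout)
#' is stored as a pair of \code{NA}s. Genotypes are canonicalised so that the
#' first allele is never larger than the second, which makes unordered
#' equality a plain elementwise comparison.
#'
#' @slot ids character vector of individual identifiers (unique).
#' @slot locusNames character vector of locus names.
#' @slot alleleA integer matrix (individuals x loci), smaller allele of each
#'   genotype, \code{NA} at dropout loci.
#' @slot alleleB integer matrix, larger allele, \code{NA} exactly where
#'   \code{alleleA} is \code{NA}.
#'
#' @seealso [Population()], [readPopulation()], [alleleSummary()]
#' @export
setClass("Population",
  representation(ids = "character", locusNames = "character",
                 alleleA = "matrix", alleleB = "matrix"))

setValidity("Population", function(object) {
  n <- length(object@ids); m <- length(object@locusNames)
  a <- object@alleleA; b <- object@alleleB
  if (!is.integer(a) || !is.integer(b))
    return("allele matrices must be integer")
  if (!all(dim(a) == c(n, m)) || !all(dim(b) == c(n, m)))
    return("allele matrix dimensions must be n x m")
  if (n < 1) return("a population needs at least one individual")
  if (anyDuplicated(object@ids)) return("individual ids must be unique")
  if (any(is.na(a) != is.na(b)))
    return("alleles must be missing in pairs (full-locus dropout only)")
  ok <- !is.na(a)
  if (any(a[ok] < 0L) || any(b[ok] < 0L)) return("alleles must be non-negative")
  if (any(a[ok] > b[ok])) return("genotypes must be stored with alleleA <= alleleB")
  TRUE
})

#' Per-locus feasible shared-parent genotype sets
#'
#' For a cluster of putative half-siblings, the set of unordered genotypes the
#' shared parent could carry, per locus. A locus where no restriction applies
#' (e.g. all members dropped out) is \code{NULL}, the UNRESTRICTED element,
#' which is the identity under intersection. Restricted loci store genotypes as
#' sorted integer codes (see \code{genotypeCode}).
#'
#' @slot sets list of length \code{m}; each element \code{NULL} or a sorted
#'   numeric vector of genotype codes.
#' @export
setClass("ParentSet", representation(sets = "list"))

#' Maternal and paternal half-sib partitions
#'
#' The output structure of half-sibling reconstruction: every individual is a
#' member of exactly one maternal and one paternal cluster. Cluster labels are
#' arbitrary integers; they carry no sex information beyond the side they are
#' stored on (microsatellites cannot tell which parent is the mother).
#'
#' @slot ids character vector of individual identifiers.
#' @slot maternal integer vector of maternal cluster labels, parallel to ids.
#' @slot paternal integer vector of paternal cluster labels.
#' @export
setClass("SibPartition",
  representation(ids = "character", maternal = "integer", paternal = "integer"))

setValidity("SibPartition", function(object) {
  n <- length(object@ids)
  if (length(object@maternal) != n || length(object@paternal) != n)
    return("maternal/paternal labels must be parallel to ids")
  if (anyDuplicated(object@ids)) return("ids must be unique")
  if (anyNA(object@maternal) || anyNA(object@paternal))
    return("every individual needs a maternal and a paternal cluster")
  TRUE
})

#' Simulated population with ground truth
#'
#' @slot pop simulated offspring \code{Population}.
#' @slot truth true \code{SibPartition} (maternal families are the sibship
#'   blocks; paternal families follow the drawn fathers).
#' @slot mothers,fathers parental \code{Population}s used to generate offspring.
#' @export
setClass("SimTruth",
  representation(pop = "Population", truth = "SibPartition",
                 mothers = "Population", fathers = "Population"))

#' Minimum-removal problem instance
#'
#' Pairs a population with a candidate half-sib partitioning and precomputes
#' the index maps used by the 0/1 integer program: the family multiset C
#' (maternal blocks then paternal blocks), the maps pi0/pi1 from individual to
#' its maternal/paternal family index in C, and the maps lambda0/lambda1 from
#' an individual's two alleles to indices in the per-locus allele set K.
#'
#' @slot pop the \code{Population}.
#' @slot partition the candidate \code{SibPartition}.
#' @slot famMembers list over C of integer member indices.
#' @slot famSide integer vector over C: 0 maternal, 1 paternal.
#' @slot pi0,pi1 integer vectors: family index in C per individual.
#' @slot lambda0,lambda1 integer matrices (n x m): allele index in K per locus,
#'   \code{NA} at dropout loci.
#' @slot alleleSets list over loci of the sorted allele set K.
#' @export
setClass("RemovalProblem",
  representation(pop = "Population", partition = "SibPartition",
    famMembers = "list", famSide = "integer",
    pi0 = "integer", pi1 = "integer",
    lambda0 = "matrix", lambda1 = "matrix", alleleSets = "list"))

#' 0/1 integer program for minimum individual removal
#'
#' Sparse representation of the removal IP. Binary variables: \code{x_i}
#' (remove individual i), \code{y[j,k,l]} (parent of family j carries the k-th
#' allele of locus l), \code{x0[i,l]}/\code{x1[i,l]} (failure of the two
#' inheritance orientations) and \code{xl[i,l]} (locus incompatibility). The
#' objective minimises the number of removed individuals.
#'
#' @slot nvar number of binary variables.
#' @slot obj integer objective coefficients.
#' @slot ci,cj,cx constraint triplets (constraint row, variable, coefficient).
#' @slot sense integer per constraint: +1 for >=, -1 for <=.
#' @slot rhs integer right-hand sides.
#' @slot varTable data.frame describing each variable (type, ind, fam, locus,
#'   allele).
#' @slot decision integer indices of branching variables (x then y, with y
#'   grouped by locus and ordered by child support).
#' @slot preferred preferred branch value per variable (0/1).
#' @slot problem the originating \code{RemovalProblem}.
#' @export
setClass("RemovalModel",
  representation(nvar = "integer", obj = "integer",
    ci = "integer", cj = "integer", cx = "integer",
    sense = "integer", rhs = "integer",
    varTable = "data.frame", decision = "integer", preferred = "integer",
    problem = "RemovalProblem"))

#' Solution of the minimum-removal program
#'
#' @slot removed character vector of removed individual ids.
#' @slot objective number of removed individuals (or the best incumbent).
#' @slot status "optimal", "time-limited" or "cutoff" (no solution within the
#'   removal budget).
#' @slot gap absolute gap between incumbent and proven lower bound.
#' @slot parentGenotypes list over families of 2 x m integer matrices, the
#'   reconstructed shared-parent genotypes (NA where unconstrained).
#' @export
setClass("RemovalSolution",
  representation(removed = "character", objective = "numeric",
    status = "character", gap = "numeric", parentGenotypes = "list"))

#' MONOTONE ONE-IN-THREE SAT instance
#'
#' Clauses of exactly three distinct positive literals; the decision problem
#' asks for an assignment making exactly one literal per clause true.
#'
#' @slot variables character vector of variable names.
#' @slot clauses list of character triples.
#' @export
setClass("SatInstance",
  representation(variables = "character", clauses = "list"))

setValidity("SatInstance", function(object) {
  for (cl in object@clauses) {
    if (length(cl) != 3L) return("every clause must have exactly 3 literals")
    if (anyDuplicated(cl)) return("clause literals must be distinct")
    if (!all(cl %in% object@variables)) return("clause uses unknown variable")
  }
  if (anyDuplicated(object@variables)) return("variable names must be unique")
  TRUE
})

#' Output of the SAT-to-half-sibship reduction
#'
#' A single-locus population plus a candidate half-sib partitioning whose
#' Mendelian validity encodes satisfiability of the source MONOTONE
#' ONE-IN-THREE SAT instance.
#'
#' @slot instance the source \code{SatInstance}.
#' @slot pop the constructed single-locus \code{Population}.
#' @slot partition the constructed \code{SibPartition}.
#' @slot literalAllele named integer: allele y for each variable.
#' @slot clauseAllele integer vector: allele s_p for each clause.
#' @slot zAllele the shared allele z of the mapping families.
#' @slot selectionFamily integer vector: maternal cluster label of the
#'   selection family of each clause.
#' @export
setClass("SibReduction",
  representation(instance = "SatInstance", pop = "Population",
    partition = "SibPartition", literalAllele = "integer",
    clauseAllele = "integer", zAllele = "integer",
    selectionFamily = "integer"))
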