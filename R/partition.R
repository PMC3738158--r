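#' Construct a SibPartition
#'
#' @param ids character vector of individual identifiers.
#' @param maternal,paternal cluster labels (coerced to integer codes), one per
#'   individual.
#' @return a \code{SibPartition}.
#' @export
SibPartition <- function(ids, maternal, paternal) {
  new("SibPartition", ids = as.character(ids),
      maternal = as.integer(maternal), paternal = as.integer(paternal))
}

setMethod("show", "SibPartition", function(object) {
  cat("SibPartition of", length(object@ids), "individuals:",
      length(unique(object@maternal)), "maternal and",
      length(unique(object@paternal)), "paternal clusters\n")
})

#' Cluster membership of a partition side
#'
#' @param partition a \code{SibPartition}.
#' @return \code{maternalBlocks}/\code{paternalBlocks}: list of character
#'   vectors of member ids; \code{familyBlocks}: the implied full-sib families
#'   F = M intersect P (non-empty intersections of a maternal and a paternal
#'   cluster).
#' @export
maternalBlocks <- function(partition)
  split(partition@ids, partition@maternal)

#' @rdname maternalBlocks
#' @export
paternalBlocks <- function(partition)
  split(partition@ids, partition@paternal)

#' @rdname maternalBlocks
#' @export
familyBlocks <- function(partition)
  split(partition@ids, paste(partition@maternal, partition@paternal, sep = "/"))
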