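#' Construct a Population
#'
#' Genotypes are canonicalised: within each locus the two alleles are sorted,
#' and a half-missing genotype (one allele read, one missing) is normalised to
#' full-locus dropout with a warning, since dropout is only defined for whole
#' loci.
#'
#' @param ids character vector of unique individual identifiers.
#' @param alleleA,alleleB integer matrices (individuals x loci) of allele
#'   repeat counts; \code{NA} marks dropout.
#' @param locusNames optional locus names (default \code{L1..Lm}).
#' @return a \code{Population} object.
#' @examples
#' pop <- Population(c("a", "b"),
#'                   matrix(c(1L, 2L), 2), matrix(c(2L, 2L), 2))
#' alleleSummary(pop)
#' @export
Population <- function(ids, alleleA, alleleB, locusNames = NULL) {
  a <- as.matrix(alleleA); b <- as.matrix(alleleB)
  storage.mode(a) <- "integer"; storage.mode(b) <- "integer"
  if (is.null(locusNames))
    locusNames <- if (ncol(a) > 0) paste0("L", seq_len(ncol(a))) else character(0)
  half <- is.na(a) != is.na(b)
  if (any(half)) {
    warning(sum(half), " half-missing genotype(s) normalised to full-locus dropout")
    a[half] <- NA_integer_; b[half] <- NA_integer_
  }
  swap <- !is.na(a) & a > b
  if (any(swap)) { tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp }
  dimnames(a) <- dimnames(b) <- NULL
  new("Population", ids = as.character(ids), locusNames = as.character(locusNames),
      alleleA = a, alleleB = b)
}

#' @describeIn Population number of individuals
#' @param pop,object a \code{Population}.
#' @export
nInd <- function(pop) length(pop@ids)

#' @describeIn Population number of loci
#' @export
nLoci <- function(pop) length(pop@locusNames)

#' @describeIn Population individual identifiers
#' @export
popIds <- function(pop) pop@ids

setMethod("show", "Population", function(object) {
  cat("Population of", nInd(object), "individuals at", nLoci(object), "loci\n")
  ks <- vapply(alleleSets(object), length, 0L)
  if (length(ks)) cat("alleles per locus:", paste(ks, collapse = " "), "\n")
  miss <- mean(is.na(object@alleleA))
  if (!is.nan(miss) && miss > 0) cat(sprintf("dropout fraction: %.3f\n", miss))
})

#' @export
setMethod("[", "Population", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("Population", ids = x@ids[i], locusNames = x@locusNames,
      alleleA = x@alleleA[i, , drop = FALSE], alleleB = x@alleleB[i, , drop = FALSE])
})

#' Per-locus observed allele sets
#'
#' @param pop a \code{Population}.
#' @return list over loci of sorted integer vectors: the observed (non-missing)
#'   alleles A_l. Loci where every individual dropped out give an empty set.
#' @export
alleleSets <- function(pop) {
  lapply(seq_len(nLoci(pop)), function(l) {
    v <- c(pop@alleleA[, l], pop@alleleB[, l])
    sort(unique(v[!is.na(v)]))
  })
}

#' Summarise allele content per locus
#'
#' @param pop a \code{Population}.
#' @return data.frame with one row per locus: locus name, number of distinct
#'   observed alleles \code{k}, dropout count, and the sorted allele set in the
#'   list column \code{alleles}. Missing genotypes never contribute alleles.
#' @export
alleleSummary <- function(pop) {
  sets <- alleleSets(pop)
  data.frame(locus = pop@locusNames,
             k = vapply(sets, length, 0L),
             dropouts = colSums(is.na(pop@alleleA[, seq_len(nLoci(pop)), drop = FALSE])),
             alleles = I(sets), row.names = NULL)
}

#' Read a genotype table
#'
#' Canonical dialect: tab-separated, one header line \code{id <locus>.1
#' <locus>.2 ...} (two allele columns per locus) and one row per individual.
#' \code{*} is the dropout sentinel.
#'
#' @param path file path.
#' @param dialect currently only \code{"tsv"}.
#' @return a \code{Population}.
#' @export
readPopulation <- function(path, dialect = "tsv") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty genotype file: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  nallele <- length(header) - 1L
  if (nallele %% 2L != 0L)
    stop("format error: header declares an odd number of allele columns")
  m <- nallele %/% 2L
  locusNames <- sub("\\.1$", "", header[1L + 2L * seq_len(m) - 1L])
  body <- lines[-1]
  body <- body[nzchar(body)]
  n <- length(body)
  if (n == 0L) stop("genotype file has no individuals: ", path)
  a <- matrix(NA_integer_, n, m); b <- matrix(NA_integer_, n, m)
  ids <- character(n)
  for (r in seq_len(n)) {
    f <- strsplit(body[[r]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 1L + nallele)
      stop("parse error at row ", r, ": expected ", 1L + nallele,
           " columns, found ", length(f))
    ids[r] <- f[1]
    toks <- f[-1]
    bad <- toks != "*" & is.na(suppressWarnings(as.integer(toks)))
    if (any(bad))
      stop("parse error at row ", r, ", column ", which(bad)[1] + 1L,
           ": non-integer allele token '", toks[which(bad)[1]], "'")
    v <- suppressWarnings(as.integer(toks))
    a[r, ] <- v[2L * seq_len(m) - 1L]
    b[r, ] <- v[2L * seq_len(m)]
  }
  Population(ids, a, b, locusNames)
}

#' Write a genotype table
#'
#' Inverse of [readPopulation()]: emits the canonical tab-separated dialect
#' with \code{*} as the dropout sentinel. Round-trips bit-exactly.
#'
#' @param pop a \code{Population}.
#' @param path output file path.
#' @export
writePopulation <- function(pop, path) {
  m <- nLoci(pop)
  header <- c("id", if (m > 0)
    as.vector(rbind(paste0(pop@locusNames, ".1"), paste0(pop@locusNames, ".2"))))
  fmt <- function(x) ifelse(is.na(x), "*", as.character(x))
  rows <- vapply(seq_len(nInd(pop)), function(r) {
    cells <- if (m > 0)
      as.vector(rbind(fmt(pop@alleleA[r, ]), fmt(pop@alleleB[r, ]))) else character(0)
    paste(c(pop@ids[r], cells), collapse = "\t")
  }, "")
  writeLines(c(paste(header, collapse = "\t"), rows), path)
}

#' Read/write half-sib partition tables
#'
#' Partition tables are tab-separated with columns \code{id},
#' \code{maternal_cluster}, \code{paternal_cluster}.
#'
#' @param path file path.
#' @return \code{readPartition}: a \code{SibPartition}.
#' @export
readPartition <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", colClasses = "character")
  SibPartition(d$id, as.integer(factor(d$maternal_cluster)),
               as.integer(factor(d$paternal_cluster)))
}

#' @rdname readPartition
#' @param partition a \code{SibPartition}.
#' @export
writePartition <- function(partition, path) {
  d <- data.frame(id = partition@ids,
                  maternal_cluster = partition@maternal,
                  paternal_cluster = partition@paternal)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
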