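# Shared fixtures, all built in code.

# The six-individual, one-locus group over four alleles in which every five
# form a valid half-sibship but all six together would need a three-allele
# parent.
sextetPopulation <- function() {
  Population(paste0("s", 1:6),
             matrix(c(1L, 1L, 1L, 2L, 2L, 3L), 6),
             matrix(c(2L, 3L, 4L, 3L, 4L, 4L), 6))
}

# the worked similarity pair: x = [(1,2),(2,2),(1,3)], y = [(1,1),(2,2),(2,3)]
workedPair <- function() {
  Population(c("x", "y"),
             matrix(c(1L, 1L, 2L, 2L, 1L, 2L), 2),
             matrix(c(2L, 1L, 2L, 2L, 3L, 3L), 2))
}

randomPopulation <- function(n, m, k, missing = 0) {
  pop <- Population(paste0("i", seq_len(n)),
                    matrix(sample.int(k, n * m, TRUE), n, m),
                    matrix(sample.int(k, n * m, TRUE), n, m))
  if (missing > 0) pop <- injectDropout(pop, missing)
  pop
}

randomPartition <- function(ids, maxBlocks = max(2L, length(ids) %/% 3L)) {
  SibPartition(ids, sample.int(maxBlocks, length(ids), TRUE),
               sample.int(maxBlocks, length(ids), TRUE))
}

# monogamous forward simulation: mother i mates only with father i, so true
# full families, maternal and paternal partitions all coincide
simulateMonogamous <- function(k, m, n, f, seed) {
  set.seed(seed)
  nf <- n %/% f
  draw <- function() matrix(sample.int(k, nf * m, TRUE) - 1L, nf, m)
  mA <- draw(); mB <- draw(); fA <- draw(); fB <- draw()
  mom <- rep(seq_len(nf), each = f)
  pickM <- matrix(sample(c(TRUE, FALSE), nf * f * m, TRUE), nf * f, m)
  pickF <- matrix(sample(c(TRUE, FALSE), nf * f * m, TRUE), nf * f, m)
  pop <- Population(paste0("i", seq_len(nf * f)),
                    ifelse(pickM, mA[mom, , drop = FALSE], mB[mom, , drop = FALSE]),
                    ifelse(pickF, fA[mom, , drop = FALSE], fB[mom, , drop = FALSE]))
  list(pop = pop, family = mom)
}

# blocks of a membership vector as a canonical sorted signature
blockSignature <- function(ids, membership)
  sort(vapply(split(ids, membership), function(b) paste(sort(b), collapse = ","), ""))

# exhaustive partition distance: smallest removal set after which the two
# partitions coincide
bruteForcePartitionDistance <- function(p, q) {
  n <- length(p)
  for (r in 0:n) {
    for (rem in if (r == 0) list(integer(0)) else asplit(utils::combn(n, r), 2)) {
      keep <- setdiff(seq_len(n), rem)
      if (setequal(blockSignature(keep, p[keep]), blockSignature(keep, q[keep])))
        return(r)
    }
  }
  n
}

# mean normalized HSVI of SibJoin over seeded simulation trials
meanHsvi <- function(k, m, n, f, seeds) {
  mean(vapply(seeds, function(s) {
    st <- simulatePopulation(k, m, n, f, seed = s)
    hsvi(st@truth, sibJoin(st@pop))
  }, 0))
}

# all monotone one-in-three instances with <= nv variables and <= ncl clauses
allSmallSatInstances <- function(nv = 5, ncl = 3) {
  vars <- paste0("v", seq_len(nv))
  pool <- utils::combn(vars, 3, simplify = FALSE)
  out <- list()
  for (r in seq_len(ncl))
    for (cc in utils::combn(seq_along(pool), r, simplify = FALSE))
      out[[length(out) + 1L]] <- satInstance(pool[cc])
  out
}

# minimum-removal objective of a population/partition pair via the IP
ipObjective <- function(pop, partition, timeLimit = 60, maxRemovals = NA) {
  sol <- solveMinRemoval(buildRemovalModel(buildRemovalProblem(pop, partition)),
                         timeLimit = timeLimit, maxRemovals = maxRemovals)
  sol@objective
}

# force a family's parent genotype by appending y >= 1 rows to a removal model
pinParent <- function(mod, pr, famIdx, alleles) {
  sets <- pr@alleleSets[[1]]
  for (al in alleles) {
    v <- which(mod@varTable$type == "y" & mod@varTable$fam == famIdx &
                 mod@varTable$allele == match(al, sets))
    row <- length(mod@rhs) + 1L
    mod@ci <- c(mod@ci, row); mod@cj <- c(mod@cj, as.integer(v))
    mod@cx <- c(mod@cx, 1L)
    mod@sense <- c(mod@sense, 1L); mod@rhs <- c(mod@rhs, 1L)
  }
  mod
}
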