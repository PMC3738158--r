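psGenotypes <- function(ps, l) {
  codes <- ps@sets[[l]]
  if (is.null(codes)) return(NULL)
  m <- SibJoinR:::genotypeDecode(codes)
  sort(paste(m[1, ], m[2, ], sep = "/"))
}

test_that("initial parent sets enumerate genotypes carrying a child allele", {
  pop <- Population("x", matrix(1L), matrix(2L))
  ps <- initialParentSet(pop, 1, sets = list(c(1L, 2L, 3L)))
  expect_equal(psGenotypes(ps, 1), c("1/1", "1/2", "1/3", "2/2", "2/3"))
  hom <- Population("h", matrix(2L), matrix(2L))
  ps2 <- initialParentSet(hom, 1, sets = list(c(1L, 2L)))
  expect_equal(psGenotypes(ps2, 1), c("1/2", "2/2"))
  # at most 2k - 1 genotypes per locus
  expect_lte(length(ps@sets[[1]]), 2 * 3 - 1)
})

test_that("dropout loci are unrestricted and identity under intersection", {
  pop <- Population(c("x", "y"), matrix(c(NA, 1L), 2), matrix(c(NA, 2L), 2))
  ps <- initialParentSet(pop, 1)
  expect_null(ps@sets[[1]])
  other <- initialParentSet(pop, 2)
  both <- intersectParentSets(ps, other)
  expect_identical(both@sets, other@sets)
  expect_true(parentSetNonEmpty(ps))
})

test_that("parent-set intersection is commutative and associative", {
  set.seed(3)
  pop <- randomPopulation(9, 3, 4)
  sets <- alleleSets(pop)
  ps <- lapply(1:9, function(i) initialParentSet(pop, i, sets))
  for (rep in 1:20) {
    idx <- sample(9, 3)
    a <- ps[[idx[1]]]; b <- ps[[idx[2]]]; c <- ps[[idx[3]]]
    ab_c <- intersectParentSets(intersectParentSets(a, b), c)
    a_bc <- intersectParentSets(a, intersectParentSets(b, c))
    ba <- intersectParentSets(b, a)
    expect_identical(ab_c@sets, a_bc@sets)
    expect_identical(intersectParentSets(a, b)@sets, ba@sets)
  }
})

test_that("the sextet is incompatible but all its five-subsets are not", {
  sext <- sextetPopulation()
  expect_false(halfSibCompatible(sext, 1:6))
  for (drop in 1:6)
    expect_true(halfSibCompatible(sext, setdiff(1:6, drop)))
  # any pair is always half-sib compatible
  set.seed(9)
  pop <- randomPopulation(12, 4, 6)
  for (rep in 1:20)
    expect_true(halfSibCompatible(pop, sample(12, 2)))
})

test_that("half-sib compatibility equals non-empty folded parent sets, exhaustively", {
  # all one-locus genotypes over four alleles, all groups of size <= 4
  g <- expand.grid(a = 1:4, b = 1:4)
  g <- g[g$a <= g$b, ]
  pop <- Population(paste0("g", seq_len(nrow(g))), matrix(g$a), matrix(g$b))
  sets <- alleleSets(pop)
  ps <- lapply(seq_len(nrow(g)), function(i) initialParentSet(pop, i, sets))
  for (size in 1:4) {
    for (grp in utils::combn(nrow(g), size, simplify = FALSE)) {
      fold <- Reduce(intersectParentSets, ps[grp])
      expect_identical(halfSibCompatible(pop, grp), parentSetNonEmpty(fold))
    }
  }
})

test_that("full-sib compatibility honours the 4-allele and 2-allele properties", {
  one <- function(rows) {
    pop <- Population(paste0("i", seq_along(rows)),
                      matrix(vapply(rows, `[`, 0L, 1)),
                      matrix(vapply(rows, `[`, 0L, 2)))
    fullSibCompatible(pop, seq_along(rows))
  }
  expect_true(one(list(c(1L, 2L), c(3L, 4L))))           # parents (1,3) x (2,4)
  expect_false(one(list(c(1L, 2L), c(3L, 4L), c(5L, 6L))))  # 5+ alleles
  expect_false(one(list(c(1L, 2L), c(3L, 4L), c(1L, 3L), c(2L, 3L), c(1L, 4L))))
  expect_true(one(list(c(1L, 3L), c(2L, 4L), c(1L, 4L), c(2L, 3L))))
})

test_that("full siblings are always half siblings and compatibility is monotone", {
  set.seed(21)
  for (rep in 1:40) {
    pop <- randomPopulation(10, 2, 4)
    grp <- sample(10, sample(2:5, 1))
    if (fullSibCompatible(pop, grp)) expect_true(halfSibCompatible(pop, grp))
    sub <- grp[-1]
    if (!halfSibCompatible(pop, sub)) expect_false(halfSibCompatible(pop, grp))
    if (!fullSibCompatible(pop, sub)) expect_false(fullSibCompatible(pop, grp))
  }
  # simulator full families satisfy the full-sib predicate by construction
  st <- simulatePopulation(k = 4, m = 5, n = 20, f = 4, seed = 5)
  for (fam in familyBlocks(st@truth))
    expect_true(fullSibCompatible(st@pop, fam))
})
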