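test_that("cluster similarity is the single-linkage maximum", {
  set.seed(12)
  pop <- randomPopulation(12, 4, 5)
  S <- similarityMatrix(pop)
  expect_identical(clusterSimilarity(3L, 7L, S), S[3, 7])
  for (rep in 1:10) {
    a <- sample(12, 4); b <- setdiff(sample(12, 8), a)
    brute <- max(vapply(a, function(x) max(S[x, b]), 0L))
    expect_identical(clusterSimilarity(a, b, S), brute)
    # monotone under union
    expect_gte(clusterSimilarity(c(a, b[1]), b[-1], S),
               clusterSimilarity(a, b[-1], S))
  }
})

test_that("joins are rejected for incompatible groups and self-pairs", {
  sext <- sextetPopulation()
  S <- similarityMatrix(sext)
  e <- SibJoinR:::.sjInit(sext, S)
  # merge the six left-slot singletons pairwise up to two clusters of 3: fine
  expect_equal(SibJoinR:::.sjTryJoin(e, 1L, 2L), "accept")
  expect_equal(SibJoinR:::.sjTryJoin(e, 1L, 3L), "accept")
  expect_equal(SibJoinR:::.sjTryJoin(e, 4L, 5L), "accept")
  expect_equal(SibJoinR:::.sjTryJoin(e, 4L, 6L), "accept")
  # the union would be the sextet: empty parent set
  expect_equal(SibJoinR:::.sjTryJoin(e, 1L, 4L), "reject:empty-parent-set")
  # an individual's own two clusters can never merge (self-loop)
  e2 <- SibJoinR:::.sjInit(sext, S)
  expect_equal(SibJoinR:::.sjTryJoin(e2, 1L, 7L), "reject:self")
})

test_that("reconstruction is deterministic and structurally valid", {
  st <- simulatePopulation(6, 6, 40, 5, seed = 31)
  sp1 <- sibJoin(st@pop)
  sp2 <- sibJoin(st@pop)
  expect_identical(sp1@maternal, sp2@maternal)
  expect_identical(sp1@paternal, sp2@paternal)
  # every individual in exactly one cluster per side; families full-sib valid;
  # clusters half-sib valid
  expect_equal(length(sp1@maternal), 40)
  for (cl in maternalBlocks(sp1)) expect_true(halfSibCompatible(st@pop, cl))
  for (cl in paternalBlocks(sp1)) expect_true(halfSibCompatible(st@pop, cl))
  for (fam in familyBlocks(sp1)) expect_true(fullSibCompatible(st@pop, fam))
})

test_that("structural invariants hold across a randomized sweep with dropout", {
  set.seed(44)
  for (rep in 1:6) {
    k <- sample(c(3, 6, 10), 1); m <- sample(c(2, 5, 8), 1)
    st <- simulatePopulation(k, m, 30, 5, seed = sample.int(1e6, 1))
    pop <- if (rep %% 2 == 0) injectDropout(st@pop, 0.1) else st@pop
    sp <- sibJoin(pop)  # audit = TRUE asserts bipartiteness internally
    expect_setequal(sp@ids, pop@ids)
    for (fam in familyBlocks(sp)) expect_true(fullSibCompatible(pop, fam))
    score <- hsvi(st@truth, sp)
    expect_gte(score, 0); expect_lte(score, 1)
  }
})

test_that("accuracy improves with more loci and more alleles", {
  mScores <- vapply(c(2, 6, 20), function(m) meanHsvi(6, m, 40, 5, 1:10), 0)
  expect_true(all(diff(mScores) < 0))
  expect_true(all(is.finite(mScores)))
  kScores <- vapply(c(2, 6, 20), function(k) meanHsvi(k, 6, 40, 5, 1:10), 0)
  expect_true(all(diff(kScores) < 0))
})

test_that("a monogamous population is fully recovered with enough loci", {
  for (s in 1:10) {
    sim <- simulateMonogamous(6, 15, 40, 5, seed = s)
    sp <- sibJoin(sim$pop)
    expect_identical(blockSignature(sim$pop@ids, sp@maternal),
                     blockSignature(sim$pop@ids, sim$family))
    expect_identical(blockSignature(sim$pop@ids, sp@paternal),
                     blockSignature(sim$pop@ids, sim$family))
  }
})

test_that("two dissimilar individuals stay in singleton clusters", {
  pop <- Population(c("a", "b"), matrix(c(1L, 3L, 1L, 3L), 2),
                    matrix(c(2L, 4L, 2L, 4L), 2))
  expect_identical(pairSimilarity(pop[1], pop[2]), 0L)
  sp <- sibJoin(pop)
  expect_equal(length(unique(sp@maternal)), 2)
  expect_equal(length(unique(sp@paternal)), 2)
})

test_that("single-parent mode reports one reconstructed side", {
  st <- simulatePopulation(6, 10, 40, 5, seed = 3)
  sp <- sibJoin(st@pop, mode = "single")
  expect_equal(length(unique(sp@paternal)), 40)  # unreported side: singletons
  vi1 <- variationOfInformation(st@truth@maternal, sp@maternal)
  vi2 <- variationOfInformation(st@truth@paternal, sp@maternal)
  expect_lt(min(vi1, vi2) / log(40), 0.2)
})
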