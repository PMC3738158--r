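test_that("problem construction populates the family multiset and index maps", {
  set.seed(1)
  pop <- randomPopulation(8, 2, 4, missing = 0.15)
  part <- SibPartition(pop@ids, 1:8, rep(1:2, 4))  # singleton maternal families
  pr <- buildRemovalProblem(pop, part)
  expect_equal(length(pr@famMembers), 8 + 2)
  expect_true(all(pr@pi0 != pr@pi1))
  hom <- !is.na(pop@alleleA) & pop@alleleA == pop@alleleB
  expect_identical(pr@lambda0[hom], pr@lambda1[hom])
  expect_identical(is.na(pr@lambda0), is.na(pop@alleleA))
})

test_that("the model carries the five constraint families within O(mn) rows", {
  set.seed(2)
  for (rep in 1:5) {
    n <- sample(6:14, 1); m <- sample(1:3, 1)
    pop <- randomPopulation(n, m, 4)
    pr <- buildRemovalProblem(pop, randomPartition(pop@ids))
    mod <- buildRemovalModel(pr)
    # per non-missing (i,l): 4 rows; per family-locus: 1 cardinality row
    expect_lte(length(mod@rhs), 4 * n * m + 2 * n * m)
    expect_equal(sum(mod@obj), n)  # objective counts individuals
    expect_setequal(unique(mod@varTable$type), c("x", "y", "x0", "x1", "xl"))
  }
})

test_that("a consistent single-child trio solves with no removals", {
  pop <- Population("kid", matrix(1L), matrix(2L))
  part <- SibPartition("kid", 1L, 1L)
  expect_equal(ipObjective(pop, part), 0)
})

test_that("the sextet as one family requires exactly one removal", {
  sext <- sextetPopulation()
  part <- SibPartition(sext@ids, 1:6, rep(1L, 6))
  pr <- buildRemovalProblem(sext, part)
  sol <- solveMinRemoval(buildRemovalModel(pr))
  expect_equal(sol@objective, 1)
  expect_equal(sol@status, "optimal")
  expect_length(sol@removed, 1)
  expect_equal(bruteForceMinRemoval(pr)@objective, 1)
  expect_equal(nrow(verifyAssignment(pr, sol@parentGenotypes,
                                     removed = sol@removed)), 0)
})

test_that("the IP optimum matches brute force on random small instances", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(4:10, 1); m <- sample(1:2, 1); k <- sample(2:5, 1)
    pop <- randomPopulation(n, m, k, missing = if (rep %% 5 == 0) 0.1 else 0)
    part <- randomPartition(pop@ids)
    pr <- buildRemovalProblem(pop, part)
    expect_equal(solveMinRemoval(buildRemovalModel(pr))@objective,
                 bruteForceMinRemoval(pr)@objective)
  }
})

test_that("simulated truths are valid and objective is monotone in family growth", {
  for (s in 1:3) {
    st <- simulatePopulation(6, 6, 40, 5, seed = s)
    expect_equal(ipObjective(st@pop, st@truth), 0)
  }
  # merging families can only raise the minimum removal
  set.seed(7)
  for (rep in 1:8) {
    pop <- randomPopulation(9, 2, 4)
    part <- randomPartition(pop@ids, maxBlocks = 4L)
    merged <- part
    merged@maternal[merged@maternal == 2L] <- 1L
    o1 <- ipObjective(pop, part); o2 <- ipObjective(pop, merged)
    expect_gte(o2, o1)
  }
})

test_that("verifyAssignment applies the forced-allele orientation rule", {
  pop <- Population("kid", matrix(1L), matrix(2L))
  pr <- buildRemovalProblem(pop, SibPartition("kid", 1L, 1L))
  g <- function(a, b) matrix(c(a, b), 2, 1)
  # mother (1,3), father (2,4): orientation 1<-M, 2<-F works
  expect_equal(nrow(verifyAssignment(pr, list(g(1L, 3L), g(2L, 4L)))), 0)
  # neither parent carries allele 2
  expect_equal(nrow(verifyAssignment(pr, list(g(1L, 3L), g(1L, 4L)))), 1)
  # a parent identical to the child forces nothing
  expect_equal(nrow(verifyAssignment(pr, list(g(1L, 2L), g(2L, 5L)))), 0)
  # unconstrained (NA) parents never violate
  expect_equal(nrow(verifyAssignment(pr, list(g(NA_integer_, NA_integer_),
                                              g(NA_integer_, NA_integer_)))), 0)
})

test_that("y-derived parent genotypes always satisfy the verifier at optimum zero", {
  set.seed(19)
  for (rep in 1:5) {
    st <- simulatePopulation(5, 3, 20, 4, seed = rep)
    pr <- buildRemovalProblem(st@pop, st@truth)
    sol <- solveMinRemoval(buildRemovalModel(pr))
    expect_equal(sol@objective, 0)
    expect_equal(nrow(verifyAssignment(pr, sol@parentGenotypes)), 0)
  }
})

test_that("a removal budget below the optimum reports cutoff", {
  sext <- sextetPopulation()
  part <- SibPartition(sext@ids, 1:6, rep(1L, 6))
  pr <- buildRemovalProblem(sext, part)
  sol <- solveMinRemoval(buildRemovalModel(pr), maxRemovals = 0)
  expect_equal(sol@status, "cutoff")
  expect_false(is.finite(sol@objective))
  expect_equal(bruteForceMinRemoval(pr, maxRemovals = 0)@status, "cutoff")
})

test_that("oversized instances are refused by the brute-force guard", {
  set.seed(3)
  pop <- randomPopulation(20, 2, 4)
  pr <- buildRemovalProblem(pop, randomPartition(pop@ids))
  expect_error(bruteForceMinRemoval(pr), "too large")
})

test_that("removal IP flags misplaced individuals with higher precision than recall", {
  # reconstruct simulated populations, validate the inferred partitions, and
  # compare the removed sets against the truly misplaced individuals
  tp <- 0; removed <- 0; misplaced <- 0
  for (s in 1:10) {
    st <- simulatePopulation(6, 6, 20, 5, seed = s)
    sp <- sibJoin(st@pop)
    sol <- solveMinRemoval(buildRemovalModel(buildRemovalProblem(st@pop, sp)),
                           timeLimit = 45)
    ev <- evaluatePartition(st@truth, sp)
    tp <- tp + length(intersect(sol@removed, ev$misplaced))
    removed <- removed + length(sol@removed)
    misplaced <- misplaced + length(ev$misplaced)
  }
  expect_gt(misplaced, 0)
  expect_gt(removed, 0)
  expect_gt(tp / removed, tp / misplaced)  # precision exceeds recall
})
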