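exampleInstance <- function()
  satInstance(list(c("x1", "x2", "x3"), c("x1", "x4", "x5")))

test_that("clauses must hold three distinct known literals", {
  expect_error(satInstance(list(c("a", "a", "b"))), "distinct")
  expect_error(satInstance(list(c("a", "b"))), "3 literals")
})

test_that("the worked two-clause reduction has the published gadget structure", {
  red <- reduceSat(exampleInstance())
  expect_equal(red@literalAllele, setNames(1:5, paste0("x", 1:5)))
  expect_equal(red@clauseAllele, 6:7)
  expect_equal(red@zAllele, 9L)
  expect_equal(nInd(red@pop), 50)
  # two selection families of six children each
  msizes <- table(red@partition@maternal)
  selSizes <- msizes[as.character(red@selectionFamily)]
  expect_true(all(selSizes == 6))
  # twelve mapping families of four children each on the paternal side
  psizes <- table(red@partition@paternal)
  expect_equal(sum(psizes == 4), 12)
  # one enforcement family (x1 is the only shared literal): children
  # (s0,1) x2, (s1,1) x2, (s0,z), (s1,z)
  enf <- which(msizes == 6 & !(names(msizes) %in% as.character(red@selectionFamily)))
  expect_length(enf, 1)
  mem <- which(red@partition@maternal == as.integer(names(enf)))
  gts <- sort(paste(red@pop@alleleA[mem, 1], red@pop@alleleB[mem, 1]))
  expect_equal(gts, sort(c("1 6", "1 6", "1 7", "1 7", "6 9", "7 9")))
  # every z-carrying individual has a singleton family on its unassigned side
  zInd <- which(red@pop@alleleB[, 1] == red@zAllele)
  mSize <- table(red@partition@maternal); pSize <- table(red@partition@paternal)
  expect_true(all(mSize[as.character(red@partition@maternal[zInd])] == 1 |
                  pSize[as.character(red@partition@paternal[zInd])] == 1))
})

test_that("the published certificate (mothers (1,3) and (1,5)) decodes to x2, x4", {
  red <- reduceSat(exampleInstance())
  pr <- buildRemovalProblem(red@pop, red@partition)
  mod <- buildRemovalModel(pr)
  mod <- pinParent(mod, pr, red@selectionFamily[1], c(1L, 3L))
  mod <- pinParent(mod, pr, red@selectionFamily[2], c(1L, 5L))
  sol <- solveMinRemoval(mod, maxRemovals = 0)
  expect_equal(sol@objective, 0)
  expect_equal(nrow(verifyAssignment(pr, sol@parentGenotypes)), 0)
  truth <- decodeParentChoice(red, sol@parentGenotypes)
  expect_equal(truth, setNames(c(FALSE, TRUE, FALSE, TRUE, FALSE),
                               paste0("x", 1:5)))
})

test_that("satisfiability is preserved on canonical small cases", {
  one <- satInstance(list(c("a", "b", "c")))
  red <- reduceSat(one)
  expect_equal(ipObjective(red@pop, red@partition, maxRemovals = 0), 0)
  unsat <- satInstance(list(c("a", "b", "c"), c("a", "b", "d"),
                            c("a", "c", "d"), c("b", "c", "d")))
  expect_null(satBruteForce(unsat))
  redu <- reduceSat(unsat)
  expect_false(is.finite(ipObjective(redu@pop, redu@partition, maxRemovals = 0)))
})

test_that("decoded assignments satisfy one-in-three on random satisfiable instances", {
  set.seed(10)
  pool <- utils::combn(paste0("v", 1:5), 3, simplify = FALSE)
  found <- 0
  while (found < 6) {
    ins <- satInstance(sample(pool, sample(1:3, 1)))
    if (is.null(satBruteForce(ins))) next
    found <- found + 1
    red <- reduceSat(ins)
    pr <- buildRemovalProblem(red@pop, red@partition)
    sol <- solveMinRemoval(buildRemovalModel(pr), maxRemovals = 0)
    expect_equal(sol@objective, 0)
    truth <- decodeParentChoice(red, sol@parentGenotypes)
    for (cl in ins@clauses) expect_equal(sum(truth[cl]), 1)
  }
})

test_that("encoding a known satisfying assignment decodes back to it", {
  set.seed(30)
  pool <- utils::combn(paste0("v", 1:5), 3, simplify = FALSE)
  found <- 0
  while (found < 5) {
    ins <- satInstance(sample(pool, 2))
    truth <- satBruteForce(ins)
    if (is.null(truth)) next
    found <- found + 1
    red <- reduceSat(ins)
    # selection mothers carry the two false literals of each clause
    pg <- vector("list", length(red@partition@maternal))
    for (p in seq_along(ins@clauses)) {
      fal <- red@literalAllele[ins@clauses[[p]][!truth[ins@clauses[[p]]]]]
      pg[[red@selectionFamily[p]]] <- matrix(as.integer(fal), 2, 1)
    }
    expect_equal(decodeParentChoice(red, pg), truth)
  }
})

test_that("reduction size grows with the proof's polynomial bounds", {
  set.seed(50)
  pool <- utils::combn(paste0("v", 1:6), 3, simplify = FALSE)
  for (rep in 1:5) {
    ins <- satInstance(sample(pool, sample(1:4, 1)))
    red <- reduceSat(ins)
    nc <- length(ins@clauses)
    kc <- vapply(ins@variables, function(v)
      sum(vapply(ins@clauses, function(cl) v %in% cl, NA)), 0L)
    expected <- 6 * nc +                                   # selection children
      sum(vapply(ins@clauses, function(cl)
        sum(pmax(1, kc[cl] - 1)) * 2, 0)) +                # (s_p, y) copies
      12 * nc +                                            # (s_p,z), (y,z)
      2 * sum(choose(kc, 2))                               # enforcement z pairs
    expect_equal(nInd(red@pop), expected)
    # every individual has one family per side
    expect_equal(length(red@partition@maternal), nInd(red@pop))
  }
})
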