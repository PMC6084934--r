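test_that("random codes are valid under their generating model", {
  set.seed(31)
  for (model in c("DEG", "BLO", "NUM", "GEN")) {
    for (r in 1:50) {
      code <- randomCode(model)
      expect_true(validateCode(code, model)$valid)
    }
  }
})

test_that("NUM draws reproduce the standard count profile exactly", {
  set.seed(37)
  for (r in 1:200) {
    idx <- codonEvolve:::.random_raw("NUM")
    expect_identical(tabulate(idx, nbins = 20L), codonEvolve:::.SGC_COUNTS)
  }
})

test_that("GEN draws are surjective with near-uniform codon counts", {
  set.seed(41)
  n <- 2000L
  counts <- matrix(0L, n, 20L)
  for (r in seq_len(n)) {
    idx <- codonEvolve:::.random_raw("GEN")
    expect_length(unique(idx), 20L)
    counts[r, ] <- tabulate(idx, nbins = 20L)
  }
  # 61 codons over 20 amino acids: the mean is 3.05 by construction and
  # the spread of counts is small (random codes are nearly uniform)
  expect_equal(mean(counts), 3.05)
  expect_lt(sd(counts), 2)
})

test_that("mutation preserves the model constraints and involutes", {
  sgc <- standardCode()
  set.seed(43)
  for (model in c("DEG", "BLO", "NUM", "GEN")) {
    code <- randomCodeOf(model)
    m <- mutateCode(code, model)
    expect_true(validateCode(m, model)$valid)
    expect_false(identical(m@assignment, code@assignment))
  }
  # DEG mutation keeps the degeneracy profile
  m <- mutateCode(sgc, "DEG")
  expect_identical(degeneracyProfile(m), degeneracyProfile(sgc))
  # NUM mutation keeps per-amino-acid counts
  m <- mutateCode(sgc, "NUM")
  expect_identical(tabulate(codonEvolve:::.idx_of_code(m), 20L),
                   codonEvolve:::.SGC_COUNTS)
  # repeating the same codon exchange restores the original
  idx <- codonEvolve:::.idx_of_code(sgc)
  idx2 <- idx
  idx2[c(1L, 10L)] <- idx2[c(10L, 1L)]
  idx3 <- idx2
  idx3[c(1L, 10L)] <- idx3[c(10L, 1L)]
  expect_identical(idx3, idx)
})

test_that("position-based crossover follows the documented fill rule", {
  posx <- codonEvolve:::pos_crossover_pair_cpp
  one <- rep(1L, 3)   # single exchange class
  p1 <- c(1L, 2L, 3L)
  p2 <- c(2L, 3L, 1L)
  # keeping only amino acid 1: offspring equal their parents
  off <- posx(p1, p2, one, c(TRUE, FALSE, FALSE))
  expect_identical(off[[1]], p1)
  expect_identical(off[[2]], p2)
  # keeping only amino acid 2 (hand-traced): O1 = (3,2,1), O2 = (2,1,3)
  off <- posx(p1, p2, one, c(FALSE, TRUE, FALSE))
  expect_identical(off[[1]], c(3L, 2L, 1L))
  expect_identical(off[[2]], c(2L, 1L, 3L))
  # with every amino acid kept there is nothing to recombine
  off <- posx(p1, p2, one, c(TRUE, TRUE, TRUE))
  expect_identical(off[[1]], p1)
  expect_identical(off[[2]], p2)
})

test_that("crossover is closed and identical parents reproduce themselves", {
  set.seed(47)
  for (model in c("DEG", "BLO", "NUM", "GEN")) {
    p1 <- randomCodeOf(model)
    off <- crossoverCodes(p1, p1, model)
    expect_identical(off[[1]]@assignment, p1@assignment)
    expect_identical(off[[2]]@assignment, p1@assignment)
    p2 <- randomCodeOf(model)
    off <- crossoverCodes(p1, p2, model)
    for (o in off) expect_true(validateCode(o, model)$valid)
  }
})

test_that("NUM crossover restores the standard count profile", {
  set.seed(53)
  for (r in 1:200) {
    a <- codonEvolve:::.random_raw("NUM")
    b <- codonEvolve:::.random_raw("NUM")
    off <- codonEvolve:::crossover_codon_pair_cpp(a, b, 20L, TRUE)
    for (o in off)
      expect_identical(tabulate(o, nbins = 20L), codonEvolve:::.SGC_COUNTS)
  }
})

test_that("operators reject structurally invalid inputs", {
  broken <- standardCode()@assignment
  broken["TTT"] <- "L"
  code <- new("GeneticCode", assignment = broken)
  expect_error(mutateCode(code, "BLO"), "not valid under the BLO")
  expect_error(crossoverCodes(code, standardCode(), "DEG"), "not valid")
})
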