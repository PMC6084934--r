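test_that("global distance interpolates, extrapolates and rejects", {
  expect_equal(globalDistance(5, 5, 10), 0)
  expect_equal(globalDistance(10, 5, 10), 100)
  expect_equal(globalDistance(4, 5, 10), -20)   # below the best: negative
  expect_equal(globalDistance(7.5, 5, 10), 50)
  expect_error(globalDistance(1, 2, 2), "degenerate")
  # invariant under positive rescaling of the objective
  set.seed(73)
  f <- sort(runif(3, 1, 100))
  for (c in c(0.5, 4, 1000))
    expect_equal(globalDistance(c * f[2], c * f[1], c * f[3]),
                 globalDistance(f[2], f[1], f[3]))
  # doubling the pair-counting convention doubles every F, so GD is fixed
  expect_equal(globalDistance(2 * f[2], 2 * f[1], 2 * f[3]),
               globalDistance(f[2], f[1], f[3]))
})

test_that("cross-position GD matches its defining arithmetic", {
  sgc <- standardCode()
  # a best-code set containing the reference itself gives 0 everywhere
  for (j in 1:3)
    expect_equal(crossPositionGD(list(sgc), j, 5, 10), 0)
  # manual recomputation on an arbitrary code set
  set.seed(79)
  codes <- replicate(4, randomCodeOf("BLO"), simplify = FALSE)
  f2 <- vapply(codes, polarityCost, numeric(1), position = 2)
  got <- crossPositionGD(codes, 2, 344.70, 1063.46)
  want <- 100 * (polarityCost(sgc, position = 2) - min(f2)) /
    (1063.46 - 344.70)
  expect_equal(got, want)
  expect_error(crossPositionGD(list(), 1, 0, 1), "empty")
  expect_error(crossPositionGD(list(sgc), 1, 2, 2), "degenerate")
})

test_that("euclideanToSet takes the minimum distance over the set", {
  expect_equal(euclideanToSet(c(0, 0, 0), rbind(c(1, 2, 2))), 3)
  expect_equal(euclideanToSet(c(1, 2, 2), rbind(c(1, 2, 2), c(9, 9, 9))), 0)
  expect_equal(euclideanToSet(c(0, 0, 0), rbind(c(1, 2, 2), c(3, 0, 0))), 3)
  # decomposes over unions
  set.seed(83)
  v <- runif(3)
  S <- matrix(runif(15), ncol = 3)
  T2 <- matrix(runif(9), ncol = 3)
  expect_equal(euclideanToSet(v, rbind(S, T2)),
               min(euclideanToSet(v, S), euclideanToSet(v, T2)))
  expect_error(euclideanToSet(c(0, 0, 0), matrix(0, 0, 3)), "empty")
})

test_that("structure distance is a scaled Hamming metric", {
  sgc <- standardCode()
  expect_equal(structureDistance(sgc, sgc)$sd, 0)
  # the worked single-swap example: 4 flipped bits, 3.3% at one decimal
  sw <- swapAminoAcids(sgc, "M", "W")
  d <- structureDistance(sgc, sw)
  expect_equal(d$hamming, 4L)
  expect_equal(round(d$sd, 1), 3.3)
  # a code sharing no assignment with the standard code: exactly 100%
  shifted <- codonEvolve:::.code_from_idx(
    (codonEvolve:::.idx_of_code(sgc) %% 20L) + 1L)
  expect_equal(structureDistance(sgc, shifted)$sd, 100)
  expect_equal(structureDistance(sgc, shifted)$hamming, 122L)
  # metric axioms on random triples from all models
  set.seed(89)
  for (r in 1:150) {
    model <- sample(c("DEG", "BLO", "NUM", "GEN"), 1)
    a <- randomCodeOf(model); b <- randomCodeOf(model)
    cc <- randomCodeOf(model)
    dab <- structureDistance(a, b)$sd
    dba <- structureDistance(b, a)$sd
    dac <- structureDistance(a, cc)$sd
    dcb <- structureDistance(cc, b)$sd
    expect_identical(dab, dba)
    expect_true(dab %% 1 >= 0)
    expect_lte(dab, dac + dcb + 1e-12)
    expect_equal(structureDistance(a, a)$sd, 0)
    expect_true(structureDistance(a, b)$hamming %% 2 == 0)
  }
})

test_that("rank correlation handles the canonical cases", {
  expect_equal(rankCorrelation(1:5, 2 * (1:5) + 3), 1)
  expect_equal(rankCorrelation(1:5, -(1:5)), -1)
  expect_equal(rankCorrelation(c(1, 2, 3), c(3, 1, 2)), -0.5)
  expect_error(rankCorrelation(1:4, 1:5), "length mismatch")
  expect_error(rankCorrelation(1:2, 1:2), "at least 3")
})

test_that("the CA export is the stacked assignment matrix", {
  sgc <- standardCode()
  sw <- swapAminoAcids(sgc, "M", "W")
  m <- caMatrix(list(sgc, sw, sgc), labels = c("sgc", "swap", "dup"))
  expect_identical(dim(m), c(3L, 1220L))
  expect_true(all(rowSums(m) == 61L))
  expect_equal(sum(m["sgc", ] != m["swap", ]), 4L)
  expect_identical(m["sgc", ], m["dup", ])
  expect_error(caMatrix(list(sgc)), "at least 2")
  path <- tempfile(fileext = ".csv")
  writeCaMatrix(m, path)
  back <- utils::read.csv(path, row.names = 1)
  expect_equal(unname(as.matrix(back)), unname(m))
})

test_that("random baselines sit where the code models put them", {
  set.seed(97)
  # DEG randomized codes are roughly equidistant from the extremes of the
  # summed cost (extremes frozen from an independent exhaustive-restart
  # local search); GEN randomized codes lean toward the best codes
  deg <- randomBaseline("DEG", "sum", 3000, 1218.65, 2493.05)
  expect_gt(deg$gdRand, 40)
  expect_lt(deg$gdRand, 62)
  gen <- randomBaseline("GEN", "sum", 3000, 503.96, 9694.02)
  expect_lt(gen$gdRand, 40)
  expect_gt(gen$gdRand, 15)
  expect_gte(deg$dispF, 0)
  # ED summaries appear when extreme sets are supplied
  bset <- rbind(c(300, 900, 10))
  wset <- rbind(c(900, 1500, 400))
  out <- randomBaseline("BLO", "sum", 200, 879.21, 4271.92,
                        bestSet = bset, worstSet = wset)
  expect_true(all(c("meanEDbest", "meanEDworst", "dispEDbest",
                    "dispEDworst") %in% names(out)))
  expect_gte(out$meanEDbest, 0)
  expect_error(randomBaseline("DEG", "sum", 10, 5, 5), "degenerate")
})

test_that("pdm compares the reference to the random mean", {
  expect_equal(pdm(5, 10, 0), 50)
  expect_equal(pdm(10, 10, 5), 0)
  expect_equal(pdm(5, 10, 5), 100)
  expect_error(pdm(1, 3, 3), "degenerate")
})
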