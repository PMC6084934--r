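test_that("trajectories are monotone and runs are seed-deterministic", {
  for (model in c("DEG", "GEN")) {
    cfg <- eaConfig(model, "sum", "min", generations = 40, runs = 2,
                    popSize = 60, archiveSize = 30, seed = 7)
    res <- runEA(cfg)
    for (r in res) {
      expect_length(r@trajectory, 40L)
      expect_true(all(diff(r@trajectory) <= 0))
      expect_equal(r@bestValue, min(r@trajectory))
      expect_true(validateCode(r@bestCode, model)$valid)
    }
    res2 <- runEA(cfg)
    expect_identical(res[[1]]@trajectory, res2[[1]]@trajectory)
    expect_identical(res[[1]]@bestCode@assignment,
                     res2[[1]]@bestCode@assignment)
    expect_identical(res[[1]]@archive, res2[[1]]@archive)
  }
  # maximization trajectories are non-decreasing
  cfg <- eaConfig("BLO", "pos1", "max", generations = 30, runs = 1,
                  popSize = 60, archiveSize = 30, seed = 9)
  r <- runEA(cfg)[[1]]
  expect_true(all(diff(r@trajectory) >= 0))
  expect_gte(r@bestValue, polarityCost(standardCode(), position = 1))
})

test_that("binary tournament has the closed-form selection pressure", {
  # archive of one: the pool is n copies of it
  expect_identical(binaryTournament(c(5), 7, "min"), rep(1L, 7))
  expect_error(binaryTournament(numeric(0), 3), "empty archive")
  # probability that the best of m=10 wins a slot is 1-(1-1/m)^2 = 0.19
  set.seed(61)
  vals <- sample(10)
  idx <- binaryTournament(vals, 2e5, "min")
  pBest <- mean(vals[idx] == 1)
  expect_equal(pBest, 1 - (1 - 1 / 10)^2, tolerance = 0.02)
  # direction symmetry: max selects the complementary extreme
  idxMax <- binaryTournament(vals, 2e5, "max")
  expect_equal(mean(vals[idxMax] == 10), 1 - (1 - 1 / 10)^2,
               tolerance = 0.02)
})

test_that("bestOverRuns returns the extremum and all tying codes", {
  cfg <- eaConfig("DEG", "pos3", "min", generations = 30, runs = 3,
                  popSize = 100, archiveSize = 50, seed = 17)
  res <- runEA(cfg)
  vals <- vapply(res, function(r) r@bestValue, numeric(1))
  out <- bestOverRuns(res, "min")
  expect_equal(out$value, min(vals))
  expect_gte(length(out$codes), 1L)
  for (cc in out$codes)
    expect_equal(polarityCost(cc, position = 3), out$value)
  # distinct codes only
  keys <- vapply(out$codes, function(cc)
    paste(cc@assignment, collapse = ""), character(1))
  expect_false(anyDuplicated(keys) > 0)
  expect_error(bestOverRuns(list()), "no runs")
})

test_that("the EA dominates random search on every model and criterion", {
  set.seed(71)
  for (model in c("DEG", "BLO", "NUM", "GEN")) {
    A <- t(vapply(seq_len(5000), function(i)
      codonEvolve:::.random_raw(model), integer(61L)))
    for (crit in c("pos1", "pos2", "pos3", "sum")) {
      pd <- codonEvolve:::.pair_idx(crit)
      randBest <- min(codonEvolve:::eval_pop_cpp(
        A, unname(scaleValues(woesePolarity())), pd$i, pd$j))
      cfg <- eaConfig(model, crit, "min", generations = 200, runs = 1,
                      popSize = 300, archiveSize = 150,
                      seed = 1000 + match(crit, c("pos1", "pos2", "pos3",
                                                  "sum")))
      ea <- runEA(cfg)[[1]]
      expect_lte(ea@bestValue, randBest)
    }
  }
})

test_that("degenerate budgets work: one generation, tiny populations", {
  cfg <- eaConfig("NUM", "sum", "min", generations = 1, runs = 1,
                  popSize = 20, archiveSize = 10, seed = 3)
  r <- runEA(cfg)[[1]]
  expect_length(r@trajectory, 1L)
  expect_true(validateCode(r@bestCode, "NUM")$valid)
  expect_equal(nrow(r@archive), 10L)
  expect_identical(archiveCode(r, 1L)@assignment, r@bestCode@assignment)
})

test_that("invalid configurations are rejected before any computation", {
  expect_error(eaConfig("DEG", "sum", "min", pMut = 1.5), "\\[0, 1\\]")
  expect_error(eaConfig("DEG", "bad"), "criterion")
  expect_error(eaConfig("DEG", "sum", "sideways"), "direction")
  expect_error(eaConfig("BLO", classes = list(1:20)), "DEG")
})
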