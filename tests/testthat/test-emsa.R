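test_that("noiseless titrations refit to their generating parameters", {
  for (r in seq_len(nrow(TABLE1))) {
    truthKd <- TABLE1$kd[r]
    truthB <- TABLE1$hill[r]
    sim <- simulateTitration(0, 1, truthKd, truthB, logConcGrid())
    fit <- fit4PL(sim)
    expect_true(fit@converged)
    est <- estimates(fit)
    expect_lt(abs(est["kd"] - truthKd) / truthKd, 1e-6)
    expect_lt(abs(est["b"] - truthB) / truthB, 1e-6)
  }
})

test_that("the 4PL forward model has its midpoint and monotone shape", {
  expect_equal(fourPL(98, a = 0, d = 1, kd = 98, b = 4.4), 0.5)
  expect_equal(fourPL(50, a = 0.2, d = 0.9, kd = 50, b = 1.7),
               (0.2 + 0.9) / 2)
  grid <- logConcGrid(1, 1000, 40)
  y <- fourPL(grid, 0, 1, 98, 4.4)
  expect_true(all(diff(y) > 0))
  ## noiseless residuals on self-generated data are ~0
  fit <- fit4PL(simulateTitration(0, 1, 109, 2.2, logConcGrid()))
  expect_lt(sum(fit@residuals^2), 1e-12)
})

test_that("noisy parameter recovery stays within the assay uncertainties", {
  nSeeds <- 100
  for (r in seq_len(nrow(TABLE1))) {
    kdErr <- bErr <- numeric(nSeeds)
    for (s in seq_len(nSeeds)) {
      sim <- simulateTitration(0, 1, TABLE1$kd[r], TABLE1$hill[r],
                               logConcGrid(), noiseSd = 0.03, seed = s)
      est <- estimates(fit4PL(sim))
      kdErr[s] <- abs(est["kd"] - TABLE1$kd[r])
      bErr[s] <- abs(est["b"] - TABLE1$hill[r])
    }
    expect_lt(median(kdErr), TABLE1$kdErr[r])
    expect_lt(median(bErr), TABLE1$hillErr[r])
  }
})

test_that("titration simulation is seeded and unbiased", {
  grid <- logConcGrid()
  exact <- simulateTitration(0, 1, 98, 4.4, grid)
  expect_equal(exact$boundFraction, fourPL(grid, 0, 1, 98, 4.4))

  s1 <- simulateTitration(0, 1, 98, 4.4, grid, noiseSd = 0.05, seed = 7)
  s2 <- simulateTitration(0, 1, 98, 4.4, grid, noiseSd = 0.05, seed = 7)
  expect_identical(s1$boundFraction, s2$boundFraction)
  expect_error(simulateTitration(0, 1, 98, 4.4, grid, noiseSd = -1),
               "noiseSd")

  ## law of large numbers at one concentration
  sd <- 0.05
  reps <- vapply(1:10000, function(s)
    simulateTitration(0, 1, 98, 4.4, c(50, 100, 200), noiseSd = sd,
                      seed = s)$boundFraction[2], numeric(1))
  expect_lt(abs(mean(reps) - fourPL(100, 0, 1, 98, 4.4)), 3 * sd / 100)
})

test_that("fit preconditions are enforced", {
  flat <- titrationSeries(logConcGrid(), rep(0.5, 12))
  expect_error(fit4PL(flat), "flat")
  short <- titrationSeries(c(10, 50, 100), c(0.1, 0.4, 0.9))
  expect_error(fit4PL(short), "at least 5")
  expect_error(titrationSeries(c(10, 5, 100), c(0.1, 0.4, 0.9)),
               "increasing")
  expect_error(titrationSeries(c(-1, 5, 100), c(0.1, 0.4, 0.9)),
               "positive")
  ## the 4PL assumes DNA well below Kd
  lowKd <- simulateTitration(0, 1, 20, 2, logConcGrid(), dnaConc = 9)
  expect_warning(fit4PL(lowKd), "Kd/5")
})

test_that("kinetic back-calculation applies the stated formulas", {
  expect_equal(koffFromHalfLife(log(2)), 1.0)
  expect_equal(koffFromHalfLife(600), log(2) / 600)
  expect_equal(koffFromHalfLife(600), 1.155e-3, tolerance = 1e-3)
  expect_equal(koffFromHalfLife(60), 1.155e-2, tolerance = 1e-3)
  expect_equal(konFromKdKoff(1e-9, 1e-3), 1e6)
  expect_equal(konFromKdKoff(98e-9, 1.155e-3), 1.18e4,
               tolerance = 5e-3)
  ## round trip: kd = koff / kon exactly
  kin <- kineticEstimate(600, 98e-9)
  expect_identical(kin$kOff / kin$kOn, 98e-9)
  expect_error(koffFromHalfLife(0), "positive")
  expect_error(konFromKdKoff(0, 1), "positive")
})

test_that("band patterns classify dimerizing vs non-dimerizing variants", {
  expect_identical(classifyDimerization(
    c(free = 0.5, single_occupied = 0, double_occupied = 0.5)),
    "dimerizing")
  expect_identical(classifyDimerization(
    c(free = 0.4, single_occupied = 0.35, double_occupied = 0.25)),
    "non_dimerizing")
  expect_identical(classifyDimerization(
    c(free = 1, single_occupied = 0, double_occupied = 0)),
    "indeterminate")
  ## invariant to overall intensity scaling
  raw <- c(free = 1200, single_occupied = 30, double_occupied = 900)
  expect_identical(classifyDimerization(raw),
                   classifyDimerization(raw / 1000))
  expect_error(classifyDimerization(c(free = 1)), "must name")
})

test_that("titration tables round-trip through delimited text", {
  sim <- simulateTitration(0, 1, 98, 4.4, logConcGrid(), noiseSd = 0.02,
                           seed = 3)
  tf <- tempfile(fileext = ".csv")
  write.csv(data.frame(conc_nM = sim$proteinConc,
                       bound_fraction = sim$boundFraction),
            tf, row.names = FALSE)
  back <- readTitration(tf)
  expect_equal(back$proteinConc, sim$proteinConc)
  expect_equal(back$boundFraction, sim$boundFraction)
})
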