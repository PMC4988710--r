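test_that("AIR effective distance matches its closed form", {
  one <- effectiveDistance(rbind(c(0, 0, 0)), rbind(c(5, 0, 0)))
  expect_equal(one, 5)
  two <- effectiveDistance(rbind(c(0, 0, 0)),
                           rbind(c(5, 0, 0), c(0, 5, 0)))
  expect_equal(two, 5 * 2^(-1 / 6))
  near <- effectiveDistance(rbind(c(0, 0, 0)),
                            rbind(c(3, 0, 0), c(100, 0, 0)))
  expect_equal(near, 3, tolerance = 1e-4)
  expect_equal(effectiveDistance(rbind(c(0, 0, 0)), rbind(c(0, 0, 0))),
               0)

  ## d_eff <= min pairwise distance, equality iff one pair dominates
  set.seed(310)
  for (rep in 1:10) {
    A <- matrix(rnorm(9, 0, 4), 3)
    B <- matrix(rnorm(15, 2, 4), 5)
    deff <- effectiveDistance(A, B)
    expect_lte(deff, min(soxdimer:::crossDist(A, B)))
  }
  ## monotone non-increasing as a pair approaches
  B2 <- rbind(c(6, 0, 0), c(0, 8, 0))
  prev <- effectiveDistance(rbind(c(0, 0, 0)), B2)
  B2[1, 1] <- 4
  expect_lt(effectiveDistance(rbind(c(0, 0, 0)), B2), prev)
})

test_that("flat-bottom evaluation follows the energy formula", {
  m <- coarseModel("A", 1:2, rbind(c(0, 0, 0), c(7, 0, 0)))
  r <- distanceRestraint("A:1:CA", "A:2:CA", target = 5, lowerPad = 0.5,
                         upperPad = 0.5, k = 2)
  expect_equal(evaluateRestraints(r, m)$total, 2 * 1.5^2)

  inside <- coarseModel("A", 1:2, rbind(c(0, 0, 0), c(5.3, 0, 0)))
  expect_equal(evaluateRestraints(r, inside)$total, 0)

  ## hbond restraints only penalize the upper side
  hb <- hbondRestraint("A:1:CA", "A:2:CA", target = 5, upperPad = 0.5)
  tight <- coarseModel("A", 1:2, rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(evaluateRestraints(hb, tight)$total, 0)
  expect_equal(evaluateRestraints(hb, m)$total, 1.5^2)

  bad <- distanceRestraint("A:1:CA", "A:9:CA", target = 5)
  expect_error(evaluateRestraints(bad, m), "A:9:CA")

  ## energies are non-negative for arbitrary geometry
  set.seed(311)
  mm <- coarseModel("A", 1:6, matrix(rnorm(18, 0, 6), 6))
  rs <- c(distanceRestraint("A:1:CA", "A:4:CA", 4),
          hbondRestraint("A:2:CA", "A:5:CA", 5),
          torsionRestraint(paste0("A:", 1:4, ":CA"), 50),
          planarityRestraint(paste0("A:", 1:5, ":CA"), 0.2))
  ev <- evaluateRestraints(rs, mm)
  expect_true(all(ev$energies >= 0))
  expect_equal(ev$total, sum(ev$energies))
  ## violations are sorted by energy, descending
  expect_true(all(diff(ev$violations$energy) <= 0))
})

test_that("restraint energy is rigid-motion invariant", {
  fix <- dockedFixture()
  rs <- c(fix$prob$airs,
          sampleContactRestraints(fix$pair, c("A", "B"), n = 20,
                                  seed = 5))
  e0 <- evaluateRestraints(rs, fix$pair)$total
  set.seed(312)
  moved <- transformModel(fix$pair, soxdimer:::randomRotation(),
                          rnorm(3, 0, 15))
  expect_equal(evaluateRestraints(rs, moved)$total, e0,
               tolerance = 1e-9)
})

test_that("helix restraint synthesis counts windows and is satisfiable", {
  region <- proteinRegion("SIREAVSQVLSGY", 72)
  rs <- helixRestraints(region, "A")
  tb <- restraintTable(rs)
  expect_equal(sum(tb$type == "torsion"), 10L)
  expect_equal(sum(tb$type == "hbond" & tb$target == 5.1), 10L)
  expect_equal(sum(tb$type == "hbond" & tb$target == 6.2), 9L)

  ideal <- idealHelix("SIREAVSQVLSGY", 72, "A")
  expect_lt(evaluateRestraints(rs, ideal)$total, 1e-6)

  extended <- coarseModel("A", 72:84, cbind(3.8 * (0:12), 0, 0))
  expect_gt(evaluateRestraints(rs, extended)$total, 100)

  expect_error(helixRestraints(proteinRegion("SIRE", 72), "A"),
               "length >= 5")
})

test_that("mutagenesis AIR synthesis builds the experimental groups", {
  airs <- makeAIRs()
  expect_equal(length(airs), 6L)
  tb <- restraintTable(airs)
  expect_true(all(tb$type == "air"))
  for (i in 1:6)
    expect_equal(length(soxdimer:::splitSel(tb$selB[i])), 8L)
  expect_setequal(soxdimer:::splitSel(tb$selA[1]), "A:73:CA")
  ## bead-level target carries the documented calibration offset
  expect_equal(unique(tb$target), 5.0)

  single <- makeAIRs(activeA = 10, activeB = 20, passiveB = integer(),
                     chainA = "A", chainB = "B")
  expect_equal(length(single), 1L)
  expect_error(makeAIRs(activeA = integer()), "non-empty")
  expect_error(makeAIRs(activeA = 119, activeB = 119,
                        passiveB = integer(), chainA = "A", chainB = "A"),
               "overlap")
})

test_that("contact restraint sampling is seeded and self-consistent", {
  fix <- dockedFixture()
  rs <- sampleContactRestraints(fix$pair, c("A", "B"), n = 50,
                                cutoff = 10, seed = 9)
  expect_equal(length(rs), 50L)
  expect_equal(evaluateRestraints(rs, fix$pair)$total, 0)

  again <- sampleContactRestraints(fix$pair, c("A", "B"), n = 50,
                                   cutoff = 10, seed = 9)
  expect_identical(restraintTable(rs), restraintTable(again))

  expect_error(sampleContactRestraints(fix$pair, c("A", "B"), n = 5000,
                                       cutoff = 6, seed = 1),
               "cross-chain pairs within")
})

test_that("restraint sets round-trip losslessly through TSV", {
  fix <- dockedFixture()
  rs <- c(fix$prob$airs,
          helixRestraints(proteinRegion("SIREAVSQVLSGY", 72), "A"),
          deriveDNARestraints(buildBDNA("ACGTACGTAC")),
          sampleContactRestraints(fix$pair, c("A", "B"), n = 10,
                                  seed = 2))
  tf <- tempfile(fileext = ".tsv")
  writeRestraints(rs, tf)
  back <- readRestraints(tf)
  expect_equal(restraintTable(back), restraintTable(rs))
})
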