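test_that("annealing schedules validate their parameters", {
  expect_error(annealSchedule(startT = 1, endT = 2), "startT > endT")
  expect_error(annealSchedule(endT = 0), "endT > 0")
  expect_error(annealSchedule(nStages = 0), ">= 1")
  sch <- annealSchedule(startT = 10, endT = 1, nStages = 4)
  expect_true(all(diff(sch$temps) < 0))
})

test_that("annealing satisfies a feasible restraint set from a jitter", {
  ## the target conformation is a witness that the set is satisfiable
  h <- idealHelix(13, 72, "A")
  xyz <- coords(h); keys <- beadKeys(h)
  sets <- list()
  for (i in 1:12) for (off in 1:4) if (i + off <= 13)
    sets[[length(sets) + 1]] <- distanceRestraint(
      keys[i], keys[i + off],
      target = soxdimer:::vecNorm(xyz[i, ] - xyz[i + off, ]),
      lowerPad = 0.5, upperPad = 0.5)
  rs <- do.call(c, sets)

  jit <- h
  set.seed(320)
  coords(jit) <- xyz + matrix(rnorm(39, 0, 1.5), 13, 3)
  e0 <- evaluateRestraints(rs, jit)$total
  expect_gt(e0, 1)
  ann <- annealModel(jit, rs, annealSchedule(startT = 3, endT = 0.1,
                                             nStages = 4,
                                             stepsPerStage = 2500,
                                             seed = 2))
  e1 <- evaluateRestraints(rs, ann$model)$total
  expect_lt(e1, 0.01 * e0)

  ## same seed, same trajectory endpoint
  ann2 <- annealModel(jit, rs, annealSchedule(startT = 3, endT = 0.1,
                                              nStages = 4,
                                              stepsPerStage = 2500,
                                              seed = 2))
  expect_identical(coords(ann$model), coords(ann2$model))

  ## unresolvable restraints fail before any move
  bad <- c(rs, distanceRestraint("Z:1:CA", "A:72:CA", 5))
  expect_error(annealModel(jit, bad, annealSchedule(seed = 1)), "Z:1:CA")
})

test_that("annealing with no restraints keeps bonded geometry", {
  m <- coarseModel("A", 1:8, cbind(3.8 * (0:7), 0, 0))
  ann <- annealModel(m, soxdimer:::emptyRestraints(),
                     annealSchedule(startT = 1, endT = 0.2, nStages = 2,
                                    stepsPerStage = 400, seed = 3))
  d <- sqrt(rowSums(diff(coords(ann$model))^2))
  expect_true(all(d > 2.8 & d < 4.8))
})

test_that("HMG placement is self-consistent and dyad-symmetric", {
  probe <- scanMotif(bundledProbes()$CC36, "CACAAAG")
  hits <- siteHits(probe)
  dna <- buildBDNA(topStrand(probe))

  plA <- placeHmgOnDna(toyHMG(chain = "A"), dna, hits[1, ])
  comb <- combineModels(plA$model, dnaBeads(dna))
  expect_equal(evaluateRestraints(plA$restraints, comb)$total, 0)
  expect_gte(min(soxdimer:::crossDist(coords(plA$model),
                                      coords(dnaBeads(dna)))), 4.5)

  ## the two placements on a palindromic probe are related by the
  ## duplex 2-fold axis (computed independently by superposing the DNA
  ## beads onto their palindrome-mapped image)
  plB <- placeHmgOnDna(toyHMG(chain = "B"), dna, hits[2, ])
  b <- dnaBeads(dna); xyz <- coords(b); n <- nbp(dna)
  top <- xyz[1:n, ]; bot <- xyz[n + 1:n, ]
  dyad <- soxdimer:::kabsch(rbind(top, bot),
                            rbind(bot[n:1, ], top[n:1, ]))
  mapped <- soxdimer:::transformCoords(coords(plA$model), dyad$R, dyad$t)
  expect_lt(soxdimer:::rmsd(mapped, coords(plB$model)), 1)

  outOfRange <- data.frame(start = 33, end = 40, strand = "+")
  expect_error(placeHmgOnDna(toyHMG(), dna, outOfRange), "outside")
})

test_that("linker threading bridges anchors at bonded spacing", {
  p0 <- c(0, 0, 0); p1 <- c(40, 0, 0)
  lx <- soxdimer:::threadLinker(p0, p1, 15, awayFrom = c(20, -30, 0))
  path <- rbind(p0, lx, p1)
  d <- sqrt(rowSums(diff(path)^2))
  expect_true(all(d > 2.8 & d < 4.8))
  expect_error(soxdimer:::threadLinker(p0, c(90, 0, 0), 15,
                                       awayFrom = c(0, 0, 0)),
               "too far")
})

test_that("model validation reports the planted defects", {
  ## hand-built: two beads 15 apart under a 5-angstrom restraint
  m <- combineModels(coarseModel("A", 86:100,
                                 cbind(3.8 * (0:14), 0, 0)),
                     coarseModel("B", 86:100,
                                 cbind(3.8 * (0:14), 40, 0)))
  r <- distanceRestraint(beadKeys(m)[1], beadKeys(m)[16], target = 25,
                         lowerPad = 0.5, upperPad = 0.5)
  ## deviation = |observed - target| = |40 something|...
  obs <- soxdimer:::vecNorm(coords(m)[1, ] - coords(m)[16, ])
  probe <- scanMotif(bundledProbes()$CC36, "CACAAAG")
  cx <- new("ComplexModel",
            proteins = list(soxdimer:::subsetBeads(m, 1:15),
                            soxdimer:::subsetBeads(m, 16:30)),
            dna = buildBDNA(topStrand(probe)),
            restraints = distanceRestraint(beadKeys(m)[1],
                                           beadKeys(m)[16],
                                           target = obs - 10,
                                           lowerPad = 0.5,
                                           upperPad = 0.5),
            provenance = list())
  rep <- validateModel(cx)
  expect_equal(rep$maxViolation, 10, tolerance = 1e-9)
  expect_equal(rep$bendDeg, 0, tolerance = 1e-6)   # straight DNA
  expect_equal(rep$clashCount, 0L)
  expect_equal(unname(rep$linkerSpans), rep(14 * 3.8, 2))
})

test_that("a reduced assembly runs end to end with the trans topology", {
  cfg <- assemblyConfig(nTrials = 60,
                        schedule = annealSchedule(stepsPerStage = 400,
                                                  seed = 5),
                        seed = 5)
  res <- assembleDimer(cfg)
  rep <- res$report
  expect_equal(rep$bendDeg, 108, tolerance = 5)
  expect_equal(rep$clashCount, 0L)
  expect_true(all(rep$alpha0CrossContacts > 0))
  expect_true(all(rep$linkerSpans <= 15 * 3.8))
  expect_true(rep$alpha0Docked)
  ## energy decreases across the quench stages
  qe <- tail(res$trace$energy, 3)
  expect_true(all(diff(qe) <= 0))

  ## without dimerization AIRs the helix is left undocked and flagged
  noAir <- assemblyConfig(airActiveA = integer(),
                          schedule = annealSchedule(stepsPerStage = 50,
                                                    seed = 5),
                          seed = 5)
  res0 <- assembleDimer(noAir)
  expect_false(res0$report$alpha0Docked)
  expect_match(res0$report$note, "not docked")

  expect_error(assemblyConfig(bogus = 1), "unknown config")
  expect_error(assembleDimer(assemblyConfig(motif = "AAAA")),
               "exactly two")
})
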