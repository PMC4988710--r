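test_that("B-DNA building propagates frames from step parameters", {
  cc36 <- topStrand(bundledProbes()$CC36)
  dna <- buildBDNA(cc36)
  expect_equal(nbp(dna), 36L)
  ## straight axis: end-to-end distance is 35 steps of 3.4 angstrom
  expect_equal(soxdimer:::vecNorm(dna@origins[36, ] - dna@origins[1, ]),
               35 * 3.4)

  two <- buildBDNA("AT")
  expect_equal(two@origins[2, ], c(0, 0, 3.4))
  expect_equal(two@triads[, , 2], soxdimer:::rotZ(soxdimer:::deg2rad(36)),
               tolerance = 1e-12)

  frozen <- buildBDNA("ACGTACGT", stepParams(twist = 0))
  for (i in 2:8)
    expect_equal(frozen@triads[, , i], diag(3), tolerance = 1e-12)

  expect_error(buildBDNA("ACGU"), "invalid base")
  expect_error(buildBDNA("A"), "length >= 2")
  expect_error(stepParams(rise = 0), "rise")
  expect_error(stepParams(roll = 95), "-90, 90")
})

test_that("bend measurement matches single-rotation oracles", {
  cc36 <- topStrand(bundledProbes()$CC36)
  expect_equal(measureBend(buildBDNA(cc36)), 0, tolerance = 1e-6)

  ## a single 30-degree roll step in the middle bends the axis by 30
  steps <- rep(list(stepParams()), 35)
  steps[[18]] <- stepParams(roll = 30)
  expect_equal(measureBend(buildBDNA(cc36, steps)), 30, tolerance = 1e-6)

  expect_error(measureBend(buildBDNA("ACGTACGTAC")), "too short")
})

test_that("site bends phase coplanarly and compose additively", {
  cc36 <- topStrand(bundledProbes()$CC36)
  dna <- buildBDNA(cc36)

  one <- applySiteBend(dna, bendSpec(list(c(9, 16)), 30))
  expect_equal(measureBend(one), 30, tolerance = 0.5)

  unbent <- applySiteBend(dna, bendSpec(list(c(9, 16)), 0))
  expect_equal(unbent@origins, dna@origins)

  both <- applySiteBend(dna, bendSpec(list(c(9, 16), c(20, 27)), 54))
  expect_equal(measureBend(both), 108, tolerance = 5)

  expect_error(bendSpec(list(c(9, 16), c(14, 21)), 54), "overlap")
  expect_error(applySiteBend(dna, bendSpec(list(c(30, 40)), 54)),
               "outside")
})

test_that("derived DNA restraints are self-consistent and counted", {
  dna <- applySiteBend(buildBDNA(topStrand(bundledProbes()$CC36)),
                       bendSpec(list(c(9, 16), c(20, 27)), 54))
  rs <- deriveDNARestraints(dna)
  tb <- restraintTable(rs)
  ## 36 inter-strand + 2 x (35 + 34) intra-strand + 35 planarity
  expect_equal(sum(tb$type == "distance"), 36 + 2 * (35 + 34))
  expect_equal(sum(tb$type == "planarity"), 35)
  expect_equal(length(rs), 209L)

  beads <- dnaBeads(dna)
  expect_equal(evaluateRestraints(rs, beads)$total, 0)

  ## random sequences stay self-consistent (construction invariant)
  set.seed(304)
  for (rep in 1:3) {
    d <- buildBDNA(randomDnaString(12))
    expect_equal(evaluateRestraints(deriveDNARestraints(d),
                                    dnaBeads(d))$total, 0)
  }

  ## jittered beads violate the flat bottoms
  jit <- beads
  set.seed(305)
  coords(jit) <- coords(beads) + matrix(rnorm(72 * 3), 72, 3)
  expect_gt(evaluateRestraints(rs, jit)$total, 0)
})

test_that("rigid motion changes neither restraint energy nor bend", {
  dna <- applySiteBend(buildBDNA(topStrand(bundledProbes()$CC36)),
                       bendSpec(list(c(9, 16), c(20, 27)), 54))
  rs <- deriveDNARestraints(dna)
  beads <- dnaBeads(dna)
  set.seed(306)
  R <- soxdimer:::randomRotation()
  t <- rnorm(3, 0, 20)
  moved <- transformModel(beads, R, t)
  expect_equal(evaluateRestraints(rs, moved)$total, 0, tolerance = 1e-9)

  movedDna <- dna
  movedDna@origins <- soxdimer:::transformCoords(dna@origins, R, t)
  for (i in seq_len(nbp(dna)))
    movedDna@triads[, , i] <- R %*% dna@triads[, , i]
  expect_equal(measureBend(movedDna), measureBend(dna),
               tolerance = 1e-9)

  ## reversing the frame order (reading the duplex from the other end)
  ## gives the same bend angle
  rev <- dna
  n <- nbp(dna)
  rev@origins <- dna@origins[n:1, ]
  flip <- diag(c(1, -1, -1))   # keep triads right-handed, z reversed
  for (i in seq_len(n)) rev@triads[, , i] <- dna@triads[, , n + 1 - i] %*% flip
  expect_equal(measureBend(rev), measureBend(dna), tolerance = 1e-9)
})

test_that("strand beads derive exactly from the frames", {
  dna <- buildBDNA("ACGTACGTACGT")
  beads <- dnaBeads(dna)
  expect_equal(nrow(coords(beads)), 24L)
  expect_setequal(unique(chainIds(beads)), c("C", "D"))
  i <- 5L
  expect_equal(coords(beads)[i, ],
               dna@origins[i, ] + 4.5 * dna@triads[, 2, i])
  expect_equal(coords(beads)[12L + i, ],
               dna@origins[i, ] - 4.5 * dna@triads[, 2, i])
  ## unbent steps: consecutive origins within the B-DNA rise window
  d <- sqrt(rowSums(diff(dna@origins)^2))
  expect_true(all(d > 3.2 & d < 3.6))
})
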