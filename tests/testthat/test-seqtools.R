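test_that("motif scanning finds the probe binding sites", {
  probes <- bundledProbes()

  cc36 <- scanMotif(probes$CC36, "CACAAAG")
  hits <- siteHits(cc36)
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$strand, c("+", "-"))
  expect_equal(hits$start, c(9L, 20L))

  s9 <- scanMotif(probes$S9WT, "AACAATG")
  expect_equal(nrow(siteHits(s9)), 1L)
  expect_equal(siteHits(s9)$strand, "+")

  polyA <- duplexProbe("pA", strrep("A", 20))
  expect_equal(nrow(siteHits(scanMotif(polyA, "CACAAAG"))), 0L)

  ## the CC36 sites carry C (not A/T) at pattern position 1, so the
  ## degenerate consensus needs one mismatch to match them
  expect_equal(nrow(siteHits(scanMotif(probes$CC36, "WWCAAWG", 0))), 0L)
  expect_equal(nrow(siteHits(scanMotif(probes$CC36, "WWCAAWG", 1))), 2L)

  expect_error(scanMotif(probes$CC36, "CACAXAG"), "IUPAC")
  ## motif longer than probe: empty result, not an error
  short <- duplexProbe("s", "ACGT")
  expect_equal(nrow(siteHits(scanMotif(short, "ACGTACGTA"))), 0L)
})

test_that("scanMotif agrees with a brute-force oracle on random probes", {
  set.seed(301)
  pats <- c("CACAAAG", "WWCAAWG", "RYSWKM", "AACNTG", "TTT")
  for (rep in 1:12) {
    top <- randomDnaString(50)
    probe <- duplexProbe("r", top)
    pat <- sample(pats, 1)
    mm <- sample(0:2, 1)
    got <- siteHits(scanMotif(probe, pat, mm))
    want <- bruteScan(top, pat, mm)
    expect_equal(got$start, want$start,
                 info = sprintf("pattern %s mm %d on %s", pat, mm, top))
    expect_equal(got$strand, want$strand)
  }
})

test_that("palindrome detection matches reverse-complement identity", {
  probes <- bundledProbes()
  expect_true(checkPalindrome(probes$CC36))
  expect_false(checkPalindrome(probes$S9WT))
  expect_true(checkPalindrome(duplexProbe("at", "AT")))

  set.seed(302)
  for (rep in 1:10) {
    top <- randomDnaString(sample(10:40, 1))
    p1 <- duplexProbe("x", top)
    p2 <- duplexProbe("y", reverseComplementStr(top))
    expect_identical(checkPalindrome(p1), checkPalindrome(p2))
  }

  ## strand symmetry of hits on a palindromic probe
  cc36 <- scanMotif(bundledProbes()$CC36, "CACAAAG")
  hits <- siteHits(cc36)
  L <- nbp(cc36); len <- 7L
  plus <- hits$start[hits$strand == "+"]
  minus <- hits$start[hits$strand == "-"]
  expect_setequal(minus, L - plus - len)
})

test_that("site spacing counts base pairs between inverted footprints", {
  cc36 <- scanMotif(bundledProbes()$CC36, "CACAAAG")
  expect_identical(siteSpacing(cc36), 4L)
  expect_identical(siteSpacing(siteHits(cc36)[2:1, ]), 4L)  # symmetric

  abut <- data.frame(start = c(0L, 7L), end = c(7L, 14L),
                     strand = c("+", "-"))
  expect_identical(siteSpacing(abut), 0L)
  apart <- data.frame(start = c(0L, 11L), end = c(7L, 18L),
                      strand = c("+", "-"))
  expect_identical(siteSpacing(apart), 4L)

  same <- data.frame(start = c(0L, 11L), end = c(7L, 18L),
                     strand = c("+", "+"))
  expect_error(siteSpacing(same), "opposite strands")
  expect_error(siteSpacing(siteHits(cc36)[1, , drop = FALSE]),
               "exactly two")
})

test_that("helical wheel projects the dimerization region amphipathically", {
  region <- proteinRegion("SIREAVSQVLSGY", 72, "alpha0")
  wheel <- wheelProjection(region)
  expect_equal(wheel$angle, ((0:12) * 100) %% 360)
  ## geometry is invariant to residue relabelling
  shifted <- wheelProjection(proteinRegion("SIREAVSQVLSGY", 172))
  expect_equal(wheel$angle, shifted$angle)

  face <- hydrophobicFace(region)
  expect_setequal(face$residues$resno, c(73, 76, 77, 80, 81, 84))
  expect_equal(face$arcStart, 40)
  expect_equal(face$arcEnd, 180)
  expect_equal(face$arcSpan, 140)
  expect_true(face$cleanSeparation)

  ## no polar residue to separate from: not a clean amphipathic call
  allLeu <- hydrophobicFace(proteinRegion(strrep("L", 10), 1))
  expect_false(allLeu$cleanSeparation)
  expect_true(allLeu$arcDefined)

  ## alternating pattern: no arc excludes all polar residues
  altLS <- hydrophobicFace(proteinRegion(strrep("LS", 6), 1))
  expect_false(altLS$cleanSeparation)

  ## all-polar region: arc undefined, flagged
  pol <- hydrophobicFace(proteinRegion("SSSSQQQQ", 1))
  expect_false(pol$arcDefined)
  expect_equal(nrow(pol$residues), 0L)
})

test_that("smallest enclosing arc matches a brute-force search", {
  set.seed(303)
  for (rep in 1:20) {
    angles <- (sample(0:17, sample(2:8, 1)) * 20)
    got <- soxdimer:::smallestEnclosingArc(angles)
    want <- bruteArc(angles)
    expect_equal(got$span, want$span)
    expect_equal(got$start, want$start)
  }
})

test_that("phenotype prediction follows the mutagenesis map", {
  expect_identical(predictPhenotype("V77E"), "loss")
  expect_identical(predictPhenotype("A119E"), "loss")
  expect_identical(predictPhenotype("L142Q"), "loss")
  expect_identical(predictPhenotype("S78A"), "retained")
  expect_identical(predictPhenotype("A118E"), "retained")
  expect_identical(predictPhenotype("L145E"), "retained")
  expect_identical(predictPhenotype("Q100W"), "unknown")
  expect_identical(predictPhenotype(84L), "loss")
  expect_error(predictPhenotype("XYZ"), "residue number")
})
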