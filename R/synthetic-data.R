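## Synthetic fixtures: ideal alpha helices, a toy L-shaped three-helix HMG
## fold with the experimentally relevant residue numbering, the probe
## sequences used throughout, and planted docking problems with a known
## answer pose. The toy fold is explicitly NOT a homology model: its
## contract is topological (three packed helices, residues 101-184, an
## exposed alpha1/alpha2 outward face), which is what the restraint and
## docking machinery needs.

HELIX_RISE <- 1.5     # angstrom per residue
HELIX_TURN <- 100     # degrees per residue
HELIX_RADIUS <- 2.3   # Calpha radius, angstrom

## Dimerization region of the solubility-optimized Group E construct
## (residues 71-85; includes the C72S and K82S substitutions).
ALPHA0_SEQ <- "VSIREAVSQVLSGYD"
ALPHA0_START <- 71L

## Synthetic HMG sequence for residues 101-184: serine background with the
## mutagenesis-relevant identities placed at their positions.
toyHMGSequence <- function() {
  aa <- rep("S", 84)
  fix <- c("115" = "W", "118" = "A", "119" = "A", "123" = "L",
           "130" = "L", "138" = "T", "139" = "L", "142" = "L",
           "145" = "L", "146" = "T")
  aa[as.integer(names(fix)) - 100L] <- fix
  paste(aa, collapse = "")
}

#' Ideal alpha-helix bead model
#'
#' Calpha beads on the canonical helix: 1.5 angstrom rise per residue,
#' 100 degrees per residue, 2.3 angstrom radius, axis along +z.
#'
#' @param sequence amino-acid string, or an integer length.
#' @param startResidue residue number of the first bead.
#' @param chain chain id.
#' @param phase angular offset of the first residue (degrees); rotating
#'   the phase spins the helix about its own axis.
#' @return a [CoarseModel-class].
#' @examples
#' h <- idealHelix("SIREAVSQVLSGY", 72)
#' @export
idealHelix <- function(sequence, startResidue = 1L, chain = "A",
                       phase = 0) {
  if (is.numeric(sequence))
    sequence <- paste(rep("A", sequence), collapse = "")
  n <- nchar(sequence)
  if (n < 4L) stop("helix must have length >= 4")
  i <- seq_len(n) - 1L
  ang <- deg2rad(phase + i * HELIX_TURN)
  xyz <- cbind(HELIX_RADIUS * cos(ang), HELIX_RADIUS * sin(ang),
               HELIX_RISE * i)
  coarseModel(chain, startResidue + i, xyz,
              meta = list(sequence = sequence))
}

#' Toy fold specification for the three-helix HMG domain
#'
#' @param spans named list of `c(first, last)` residue intervals for
#'   helices `a1`, `a2`, `a3` (within 101-184, disjoint and ordered).
#' @param angles inter-helix angles: `a1a2` between helix 1 and 2 (they
#'   pack roughly antiparallel in the fold's long arm) and `a1a3` between
#'   helix 1 and the cross-arm helix 3 (degrees, in (0, 180)).
#' @return list of class `ToyFoldSpec`.
#' @export
toyFoldSpec <- function(spans = list(a1 = c(106, 125), a2 = c(131, 145),
                                     a3 = c(151, 176)),
                        angles = c(a1a2 = 170, a1a3 = 75)) {
  iv <- do.call(rbind, spans)
  if (any(iv[, 1] < 101) || any(iv[, 2] > 184))
    stop("helix spans must lie within residues 101-184")
  if (any(diff(as.vector(t(iv))) <= 0))
    stop("helix spans must be disjoint and ordered")
  if (any(angles <= 0 | angles >= 180))
    stop("inter-helix angles must lie in (0, 180)")
  structure(list(spans = spans, angles = angles), class = "ToyFoldSpec")
}

#' Toy three-helix HMG fold
#'
#' Builds an idealized, L-shaped stand-in for the HMG domain: helices
#' alpha1 and alpha2 packed side by side (the long arm), helix alpha3
#' crossing at the spec angle (the short arm), loops as extended beads.
#' Residues are numbered 101-184 so the experimentally derived residue
#' lists (W115, A119, L142, ...) resolve directly. Helix phases are set
#' so the platform residues A119 and L142 point away from alpha3 -- the
#' solvent-exposed outward face that receives the dimerization helix.
#'
#' @param spec a [toyFoldSpec()].
#' @param chain chain id.
#' @return a [CoarseModel-class] with `meta$sequence`, `meta$spans`.
#' @examples
#' hmg <- toyHMG()
#' range(residueNumbers(hmg))
#' @export
toyHMG <- function(spec = toyFoldSpec(), chain = "B") {
  seqHMG <- toyHMGSequence()
  res <- 101:184
  xyz <- matrix(NA_real_, length(res), 3)
  rownames(xyz) <- res
  place <- function(span, R, t, phase) {
    n <- span[2] - span[1] + 1L
    h <- idealHelix(n, startResidue = span[1], phase = phase)
    transformCoords(coords(h), R, t)
  }
  sp <- spec$spans
  ## alpha1 along +z at the origin; phase chosen so residue 119 points +y
  ph1 <- 90 - (119 - sp$a1[1]) * HELIX_TURN
  xyz[as.character(sp$a1[1]:sp$a1[2]), ] <-
    place(sp$a1, diag(3), c(0, 0, 0), ph1)
  ## alpha2 packed beside alpha1 (offset in x), near-antiparallel: rotate
  ## by (180 - a1a2) off exact antiparallel about x, run back down in z;
  ## phase chosen so residue 142 points +y
  a2len <- sp$a2[2] - sp$a2[1] + 1L
  R2 <- rotX(deg2rad(180 - spec$angles["a1a2"])) %*% rotY(pi)
  ph2 <- 90 - (142 - sp$a2[1]) * HELIX_TURN  # rotY(pi) preserves +y
  top1 <- (sp$a1[2] - sp$a1[1]) * HELIX_RISE
  xyz[as.character(sp$a2[1]:sp$a2[2]), ] <-
    place(sp$a2, R2, c(9, 0, top1 - 2), ph2)
  ## alpha3 crossing underneath at a1a3 degrees to alpha1, displaced -y
  ## (the opposite side from the exposed 119/142 face)
  R3 <- rotY(deg2rad(spec$angles["a1a3"]))
  xyz[as.character(sp$a3[1]:sp$a3[2]), ] <-
    place(sp$a3, R3, c(4.5, -9.5, -6), 0)
  ## loops: linear interpolation between flanking helix ends, plus short
  ## extended tails at the termini
  fillGap <- function(fromRes, toRes) {
    if (fromRes + 1L > toRes - 1L) return()
    gap <- (fromRes + 1L):(toRes - 1L)
    p0 <- xyz[as.character(fromRes), ]
    p1 <- xyz[as.character(toRes), ]
    ## arc outward (away from the fold centroid) so consecutive beads
    ## keep near-bonded spacing even across short gaps
    away <- colMeans(xyz[!is.na(xyz[, 1]), , drop = FALSE])
    xyz[as.character(gap), ] <<- threadLinker(p0, p1, length(gap), away)
  }
  fillGap(sp$a1[2], sp$a2[1])
  fillGap(sp$a2[2], sp$a3[1])
  ## N-terminal tail 101..(a1 start - 1): extended along -z from alpha1
  nt <- 101:(sp$a1[1] - 1L)
  for (j in rev(seq_along(nt)))
    xyz[as.character(nt[j]), ] <-
      xyz[as.character(sp$a1[1]), ] +
      c(0, 0, -3.5 * (length(nt) - j + 1L))
  ## C-terminal tail after alpha3: extended along the alpha3 axis
  ct <- (sp$a3[2] + 1L):184L
  if (sp$a3[2] < 184L) {
    ax <- unitVec(xyz[as.character(sp$a3[2]), ] -
                  xyz[as.character(sp$a3[1]), ])
    for (j in seq_along(ct))
      xyz[as.character(ct[j]), ] <-
        xyz[as.character(sp$a3[2]), ] + 3.5 * j * ax
  }
  if (diff(range(spec$angles)) == 0 || spec$angles["a1a3"] < 5)
    warning("near-collinear helices: degenerate toy fold")
  coarseModel(chain, res, xyz,
              meta = list(sequence = seqHMG, spans = sp,
                          synthetic = TRUE))
}

#' Bundled duplex probe fixtures
#'
#' The two probes assayed in the study, verbatim: CC36, the 36-bp
#' palindromic double-site probe (two CACAAAG sites spaced 4 bp apart),
#' and S9WT, the engineered high-affinity single-site probe (one
#' canonical AACAATG site).
#'
#' @return named list of two [DuplexProbe-class] objects.
#' @examples
#' probes <- bundledProbes()
#' checkPalindrome(probes$CC36)
#' @export
bundledProbes <- function() {
  list(CC36 = duplexProbe("CC36",
         "GGGATCCTACACAAAGCCGGCTTTGTGTAGGATCCC"),
       S9WT = duplexProbe("S9WT", "GGGTTAACGAACAATGGAATCTGGTAGA"))
}

#' Planted rigid-body docking problem
#'
#' Generates a ground-truth docking task: the toy HMG receptor plus an
#' ideal dimerization helix placed in contact at a random orientation
#' against the alpha1/alpha2 outward face, with AIRs generated from the
#' true cross-chain contacts. The true pose is returned (and withheld
#' from the docking run by construction).
#'
#' @param seed integer seed; the same seed reproduces the same problem.
#' @param contactCutoff residue-contact cutoff used to derive the AIRs
#'   (angstrom).
#' @param shellWidth thickness of the closest-contact shell defining
#'   each AIR's partner group (angstrom).
#' @return list with `receptor` and `mobile` (`CoarseModel`s; the mobile
#'   is in its reference placement, centred at the origin), `truePose`
#'   (`list(R, t)`), `trueCoords` (mobile coordinates in the planted
#'   pose) and `airs` (a `RestraintSet`).
#' @export
plantedDockingProblem <- function(seed = 1, contactCutoff = 8,
                                  shellWidth = 0.5) {
  receptor <- toyHMG(chain = "B")
  helix <- idealHelix(ALPHA0_SEQ, ALPHA0_START, chain = "A")
  ref <- coords(helix)
  ref <- sweep(ref, 2, colMeans(ref))   # centred reference
  mobile <- helix
  coords(mobile) <- ref
  rec <- coords(receptor)
  spans <- receptor@meta$spans
  rres <- residueNumbers(receptor)
  a1Idx <- match(spans$a1[1]:spans$a1[2], rres)
  a2Idx <- match(spans$a2[1]:spans$a2[2], rres)
  ## groove between alpha1 and alpha2: candidate anchors are midpoints of
  ## close alpha1/alpha2 bead pairs, so the planted patch engages both
  ## helices and the answer pose is identifiable from its contacts
  pairD <- crossDist(rec[a1Idx, , drop = FALSE],
                     rec[a2Idx, , drop = FALSE])
  cand <- which(pairD <= 13, arr.ind = TRUE)
  grooveAxis <- principalAxis(rec[a1Idx, , drop = FALSE])
  core <- colMeans(rec[c(a1Idx, a2Idx), , drop = FALSE])
  best <- NULL
  withSeed(seed, {
    for (attempt in 1:300) {
      pick <- cand[sample.int(nrow(cand), 1), ]
      anchor <- (rec[a1Idx[pick[1]], ] + rec[a2Idx[pick[2]], ]) / 2
      dirOut <- unitVec(anchor - core)
      ## helix axis roughly along the groove, with a random tilt of up
      ## to ~25 degrees, a random flip, and a random spin about its own
      ## axis: a random but identifiable surface placement
      ax0 <- grooveAxis * sample(c(-1, 1), 1)
      tiltAx <- stats::rnorm(3); tiltAx <- unitVec(tiltAx)
      Rt <- rotAxis(tiltAx, stats::runif(1, 0, deg2rad(25)))
      axTarget <- unitVec(as.numeric(Rt %*% ax0))
      axTarget <- unitVec(axTarget - sum(axTarget * dirOut) * dirOut)
      rotTo <- crossProd3(c(0, 0, 1), axTarget)
      Rbase <- if (vecNorm(rotTo) > 1e-8)
        rotAxis(rotTo, acos(max(-1, min(1, axTarget[3])))) else diag(3)
      R <- Rbase %*% rotZ(stats::runif(1, 0, 2 * pi))
      ## slide the rotated helix along dirOut until minimum cross-chain
      ## distance reaches a contact separation
      posed <- ref %*% t(R)
      lo <- 0; hi <- 60
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        dmin <- min(crossDist(sweep(posed, 2, anchor + mid * dirOut,
                                    "+"), rec))
        if (dmin < 4.1) lo <- mid else hi <- mid
      }
      t <- anchor + hi * dirOut
      trueCoords <- sweep(posed, 2, t, "+")
      ## quality gate: most of the helix in contact and both receptor
      ## helices engaged; among admissible placements keep the one with
      ## the most near-contact pairs (the most identifiable patch)
      Dq <- crossDist(trueCoords, rec)
      activeM <- which(apply(Dq, 1, min) <= contactCutoff)
      contacted <- which(apply(Dq, 2, min) <= contactCutoff)
      score <- sum(apply(Dq, 1, min) <= 5.0) +
        sum(apply(Dq, 2, min) <= 5.0)
      if (length(activeM) >= 8 && diff(range(activeM)) >= 9 &&
          sum(contacted %in% a1Idx) >= 3 &&
          sum(contacted %in% a2Idx) >= 3 &&
          (is.null(best) || score > best$score))
        best <- list(score = score, R = R, t = t,
                     trueCoords = trueCoords)
    }
  })
  if (is.null(best))
    stop("could not plant an identifiable docking problem for seed ",
         seed)
  R <- best$R; t <- best$t; trueCoords <- best$trueCoords
  ## AIRs from true contacts: every mobile residue with a receptor bead
  ## within the cutoff becomes an active residue restrained to the set of
  ## receptor residues it contacts
  D <- crossDist(trueCoords, rec)
  sets <- list()
  ## AIRs from the true contact map, in both directions (every contacting
  ## residue of either chain is an active residue restrained to its
  ## closest-shell partner set), with target = the true-pose effective
  ## distance so each emitted AIR is exactly satisfied at the planted
  ## answer and the answer is sharply identifiable
  ## two scales of AIR: a broad set (all contacts within contactCutoff)
  ## that identifies the binding patch globally, and a tight set (pairs
  ## just above the soft-sphere clash diameter) whose targets sandwich
  ## each close pair between the clash floor and its upper bound,
  ## pinning the pose locally
  shell <- function(dRow, cutoff, width) {
    m <- min(dRow)
    if (m > cutoff) integer() else which(dRow <= min(cutoff, m + width))
  }
  emit <- function(cutoff, width) {
    for (i in seq_len(nrow(trueCoords))) {
      near <- shell(D[i, ], cutoff, width)
      if (!length(near)) next
      trueDeff <- effectiveDistance(trueCoords[i, , drop = FALSE],
                                    rec[near, , drop = FALSE])
      sets[[length(sets) + 1L]] <<- ambiguousRestraint(
        beadKey("A", residueNumbers(mobile)[i]),
        beadKey("B", residueNumbers(receptor)[near]),
        target = trueDeff, stage = "planted")
    }
    for (j in seq_len(nrow(rec))) {
      near <- shell(D[, j], cutoff, width)
      if (!length(near)) next
      trueDeff <- effectiveDistance(rec[j, , drop = FALSE],
                                    trueCoords[near, , drop = FALSE])
      sets[[length(sets) + 1L]] <<- ambiguousRestraint(
        beadKey("B", residueNumbers(receptor)[j]),
        beadKey("A", residueNumbers(mobile)[near]),
        target = trueDeff, stage = "planted")
    }
  }
  emit(contactCutoff, 1.0)
  emit(5.0, shellWidth)
  if (!length(sets))
    stop("planted problem has no contacts; try another seed")
  list(receptor = receptor, mobile = mobile,
       truePose = list(R = R, t = t), trueCoords = trueCoords,
       airs = do.call(c, sets))
}
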