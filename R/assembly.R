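## Assembly of the dimeric protein-DNA complex: HMG placement on the bent
## tandem site, kinematic construction of the dimerization helices at
## their docked poses, linker threading, and Metropolis simulated
## annealing under the amalgamated restraints with a final greedy quench.

ASSEMBLY_CLASH_SIGMA <- 3.5  # soft-sphere diameter for cross-chain beads
BOND_TARGET <- 3.8           # consecutive Calpha distance, angstrom
BOND_PAD <- 0.2
BOND_K <- 10
CLASH_COUNT_CUTOFF <- 2.5    # a cross-chain pair closer than this is a clash
CONTACT_CUTOFF <- 8          # cross-chain contact distance for reporting

#' Simulated-annealing schedule
#'
#' Geometric temperature ladder in reduced energy units. The default
#' (50 -> 0.5 over 8 stages, 2000 Metropolis steps per stage) is sized so
#' a full default assembly runs in minutes on one CPU; `quench` appends a
#' greedy-descent stage (the T -> 0 limit of the acceptance rule).
#'
#' @param startT,endT start and end temperatures (start > end > 0).
#' @param nStages number of geometric stages.
#' @param stepsPerStage Metropolis steps per stage.
#' @param moveSd single-bead move amplitude at `startT` (angstrom); the
#'   amplitude shrinks with the square root of temperature.
#' @param quench append a greedy quench stage after the ladder.
#' @param seed integer seed.
#' @return list of class `AnnealSchedule`.
#' @export
annealSchedule <- function(startT = 50, endT = 0.5, nStages = 8,
                           stepsPerStage = 2000, moveSd = 0.3,
                           quench = TRUE, seed = 1) {
  if (!(startT > endT && endT > 0)) stop("need startT > endT > 0")
  if (nStages < 1 || stepsPerStage < 1) stop("counts must be >= 1")
  structure(list(temps = exp(seq(log(startT), log(endT),
                                 length.out = nStages)),
                 stepsPerStage = as.integer(stepsPerStage),
                 moveSd = moveSd, quench = quench,
                 seed = as.integer(seed)),
            class = "AnnealSchedule")
}

## Bonded terms (consecutive-residue tethers) for every protein chain of
## a bead model, as compiled term entries.
bondedTerms <- function(model) {
  terms <- list()
  for (ch in unique(chainIds(model))) {
    idx <- which(chainIds(model) == ch & beadRoles(model) == "CA")
    if (!length(idx)) next
    idx <- idx[order(residueNumbers(model)[idx])]
    rn <- residueNumbers(model)[idx]
    consec <- which(diff(rn) == 1L)
    for (j in consec)
      terms[[length(terms) + 1L]] <- list(
        type = "distance", ia = idx[j], ib = idx[j + 1L],
        target = BOND_TARGET, lowerPad = BOND_PAD, upperPad = BOND_PAD,
        k = BOND_K)
  }
  terms
}

## Precompiled annealing system: restraint + bonded terms with per-bead
## indices, and per-chain cross-chain clash partner lists.
compileSystem <- function(model, restraints) {
  terms <- c(compileRestraints(restraints, model), bondedTerms(model))
  n <- nrow(coords(model))
  beadTerms <- vector("list", n)
  for (tid in seq_along(terms)) {
    for (i in unique(c(terms[[tid]]$ia, terms[[tid]]$ib)))
      beadTerms[[i]] <- c(beadTerms[[i]], tid)
  }
  chains <- chainIds(model)
  othersByChain <- lapply(unique(chains), function(ch)
    which(chains != ch))
  names(othersByChain) <- unique(chains)
  list(model = model, terms = terms, beadTerms = beadTerms,
       chains = chains, othersByChain = othersByChain)
}

termEnergy <- function(term, xyz) unname(evalTerm(term, xyz)["energy"])

clashBead <- function(xyz, i, others, sigma = ASSEMBLY_CLASH_SIGMA) {
  if (!length(others)) return(0)
  dv <- xyz[others, , drop = FALSE]
  d <- sqrt((dv[, 1] - xyz[i, 1])^2 + (dv[, 2] - xyz[i, 2])^2 +
            (dv[, 3] - xyz[i, 3])^2)
  v <- sigma - d
  sum(v[v > 0]^2)
}

totalClash <- function(xyz, chains, sigma = ASSEMBLY_CLASH_SIGMA) {
  chs <- unique(chains)
  e <- 0
  if (length(chs) < 2) return(0)
  for (a in seq_len(length(chs) - 1L)) for (b in seq(a + 1L, length(chs))) {
    D <- crossDist(xyz[chains == chs[a], , drop = FALSE],
                   xyz[chains == chs[b], , drop = FALSE])
    v <- sigma - D[D < sigma]
    if (length(v)) e <- e + sum(v^2)
  }
  e
}

systemEnergy <- function(sys, xyz) {
  sum(vapply(sys$terms, termEnergy, numeric(1), xyz = xyz)) +
    totalClash(xyz, sys$chains)
}

## Energy of the terms touching a bead set, plus their clash against all
## beads outside the set (set-internal clash pairs are excluded and must
## be unchanged by the proposed move).
localEnergy <- function(sys, xyz, beadSet, termIds) {
  e <- 0
  for (tid in termIds) e <- e + termEnergy(sys$terms[[tid]], xyz)
  for (i in beadSet) {
    others <- setdiff(sys$othersByChain[[sys$chains[i]]], beadSet)
    e <- e + clashBead(xyz, i, others)
  }
  e
}

#' Metropolis simulated annealing of a bead model under restraints
#'
#' Single-bead Gaussian moves (and, when `segments` are given, occasional
#' rigid-segment rotation/translation moves) accepted by the Metropolis
#' rule under total energy = restraint energy + bonded terms + soft-core
#' cross-chain clash. At temperature -> 0 the acceptance rule reduces to
#' greedy descent, which the optional quench stage exploits. Reproducible
#' under the schedule seed.
#'
#' @param model a `CoarseModel` holding every chain (use [complexBeads()]
#'   for a complex).
#' @param restraints a `RestraintSet`; all referenced beads must resolve
#'   (an unresolvable bead is an error before any move).
#' @param schedule an [annealSchedule()].
#' @param mobile integer indices (or logical mask) of beads allowed to
#'   move; defaults to all beads.
#' @param segments optional list of integer index vectors moved as rigid
#'   bodies (each within one chain).
#' @param segmentProb probability that a step is a segment move.
#' @return list with `model` (annealed), `trace` (per-stage energies) and
#'   `energy` (final total).
#' @export
annealModel <- function(model, restraints, schedule,
                        mobile = NULL, segments = list(),
                        segmentProb = 0.05) {
  stopifnot(inherits(schedule, "AnnealSchedule"))
  sys <- compileSystem(model, restraints)   # errors early if unresolvable
  xyz <- coords(model)
  n <- nrow(xyz)
  if (is.null(mobile)) mobile <- seq_len(n)
  if (is.logical(mobile)) mobile <- which(mobile)
  if (!length(mobile)) stop("no mobile beads")
  segTerms <- lapply(segments, function(seg)
    unique(unlist(sys$beadTerms[seg])))
  temps <- schedule$temps
  ## the quench is a staged greedy descent (the T -> 0 limit of the
  ## Metropolis rule) at decreasing move amplitudes
  quenchAmps <- if (schedule$quench) c(0.5, 0.3, 0.15, 0.08) else
    numeric()
  temps <- c(temps, rep(1e-9, length(quenchAmps)))
  trace <- data.frame(stage = seq_along(temps), temp = temps,
                      energy = NA_real_)
  nLadder <- length(schedule$temps)
  withSeed(schedule$seed, {
    for (s in seq_along(temps)) {
      temp <- temps[s]
      amp <- if (s > nLadder) quenchAmps[s - nLadder] else
        max(0.05, schedule$moveSd * sqrt(temp / temps[1]))
      nSteps <- if (s > nLadder) 2L * schedule$stepsPerStage else
        schedule$stepsPerStage
      for (step in seq_len(nSteps)) {
        segP <- if (s > nLadder) min(1, 3 * segmentProb) else segmentProb
        useSeg <- length(segments) > 0 && stats::runif(1) < segP
        if (useSeg) {
          k <- sample.int(length(segments), 1L)
          seg <- segments[[k]]
          tids <- segTerms[[k]]
          e0 <- localEnergy(sys, xyz, seg, tids)
          cen <- colMeans(xyz[seg, , drop = FALSE])
          ax <- stats::rnorm(3); ax <- ax / vecNorm(ax)
          R <- rotAxis(ax, stats::rnorm(1, 0, 0.05 * amp))
          shift <- stats::rnorm(3, 0, amp / 2)
          new <- sweep(sweep(xyz[seg, , drop = FALSE], 2, cen) %*% t(R),
                       2, cen + shift, "+")
          xyz2 <- xyz; xyz2[seg, ] <- new
          e1 <- localEnergy(sys, xyz2, seg, tids)
        } else {
          i <- mobile[sample.int(length(mobile), 1L)]
          tids <- sys$beadTerms[[i]]
          e0 <- localEnergy(sys, xyz, i, tids)
          xyz2 <- xyz
          xyz2[i, ] <- xyz[i, ] + stats::rnorm(3, 0, amp)
          e1 <- localEnergy(sys, xyz2, i, tids)
        }
        dE <- e1 - e0
        if (dE <= 0 || stats::runif(1) < exp(-dE / temp)) xyz <- xyz2
      }
      trace$energy[s] <- systemEnergy(sys, xyz)
    }
  })
  out <- model
  coords(out) <- xyz
  list(model = out, trace = trace, energy = trace$energy[nrow(trace)])
}

#' Place an HMG domain onto a DNA binding site
#'
#' Positions the domain deterministically against the minor-groove side
#' of the site's centre base-pair frame (the domain's DNA-binding face --
#' the concave side of the L, opposite the exposed alpha1/alpha2 platform
#' -- toward the DNA), at a separation giving near-contact without
#' clashes. For a minus-strand site the placement frame is flipped about
#' the frame x axis (the duplex dyad), so the two placements on a
#' palindromic tandem site are related by the palindrome's 2-fold axis.
#' Interface distance restraints pinning all protein-DNA bead pairs
#' within 10 angstrom at their placed distances are emitted; they
#' evaluate to zero on the returned pose.
#'
#' @param hmg an HMG-domain `CoarseModel` (e.g. [toyHMG()]).
#' @param dna a `DNAModel`.
#' @param site one site-hit row (`data.frame` with `start`, `end`,
#'   `strand`) in 0-based half-open bp coordinates.
#' @param contactDist target minimum protein-DNA bead separation
#'   (angstrom).
#' @return list with `model` (the placed chain) and `restraints`
#'   (`RestraintSet`, stage `stage3_interface`).
#' @export
placeHmgOnDna <- function(hmg, dna, site, contactDist = 5) {
  n <- nbp(dna)
  if (site$start[1] < 0 || site$end[1] > n)
    stop("site footprint outside the DNA")
  centre <- floor((site$start[1] + site$end[1] - 1) / 2) + 1L
  G <- dna@triads[, , centre]
  o <- dna@origins[centre, ]
  if (site$strand[1] == "-") G <- G %*% diag(c(1, -1, -1))
  ## maps the domain's binding direction (-y) onto +x (toward the DNA)
  ## and its alpha1 N-terminal end toward the partner site (-z), so the
  ## two placements of a tandem dimer face each other
  M <- rotZ(pi / 2) %*% rotY(pi)
  R <- G %*% M
  xyz <- coords(hmg)
  cen <- colMeans(xyz)
  rot <- sweep(xyz, 2, cen) %*% t(R)
  dnaXyz <- coords(dnaBeads(dna))
  ## slide outward along the frame's minor-groove direction (-x) until
  ## the minimum protein-DNA separation reaches contactDist
  dirOut <- as.numeric(G %*% c(-1, 0, 0))
  lo <- 0; hi <- 80
  for (it in 1:48) {
    mid <- (lo + hi) / 2
    dmin <- min(crossDist(sweep(rot, 2, o + mid * dirOut, "+"), dnaXyz))
    if (dmin < contactDist) lo <- mid else hi <- mid
  }
  placed <- hmg
  coords(placed) <- sweep(rot, 2, o + hi * dirOut, "+")
  ## interface restraints from the placed geometry
  comb <- combineModels(placed, dnaBeads(dna))
  keys <- beadKeys(comb)
  np <- nrow(coords(placed))
  D <- crossDist(coords(placed), dnaXyz)
  pairs <- which(D <= 10, arr.ind = TRUE)
  sets <- lapply(seq_len(nrow(pairs)), function(j)
    distanceRestraint(keys[pairs[j, 1]], keys[np + pairs[j, 2]],
                      target = D[pairs[j, 1], pairs[j, 2]],
                      lowerPad = 0.5, upperPad = 0.5, k = 1,
                      stage = "stage3_interface"))
  if (!length(sets)) stop("no protein-DNA contacts at placement")
  list(model = placed, restraints = do.call(c, sets))
}

#' Default assembly configuration
#'
#' Names every input of [assembleDimer()]: probe and motif, per-site DNA
#' bend, dimerization-helix span and linker, toy-fold spec, AIR residue
#' lists, docking and annealing parameters, and seeds. The defaults are
#' the study conditions: the CC36 tandem probe, 54 degrees of bend per
#' site (108 for the dimer), trans docking of each dimerization helix
#' onto the partner HMG domain, 400 docking trials / top 20 / 50 sampled
#' contact restraints.
#'
#' @param ... overrides of the default entries.
#' @return list of class `AssemblyConfig`.
#' @export
assemblyConfig <- function(...) {
  cfg <- list(
    probe = bundledProbes()$CC36,
    motif = "CACAAAG",
    perSiteBend = 54,
    bendPhasing = "coplanar",
    alpha0Seq = ALPHA0_SEQ,
    alpha0Start = ALPHA0_START,       # region 71-85
    helixSpan = c(72, 84),            # restrained helical span
    linkerSpan = c(86, 100),          # left unrestrained (bonded only)
    foldSpec = toyFoldSpec(),
    airActiveA = c(73, 76, 77, 80, 81, 84),
    airActiveB = c(119, 142),
    airPassiveB = c(115, 123, 130, 138, 139, 146),
    trans = TRUE,                     # helix docks the partner HMG
    nTrials = 400,
    top = 20,
    nContacts = 50,
    contactCutoff = 10,
    schedule = annealSchedule(),
    seed = 11)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "AssemblyConfig")
}

## Thread linker beads from anchor p0 (residue before the linker) to p1
## (residue after) along a circular arc bowed away from `awayFrom`, with
## total arc length ~ (nInterior + 1) * 3.4 so bonded terms start near
## their flat bottom.
threadLinker <- function(p0, p1, nInterior, awayFrom) {
  nSeg <- nInterior + 1L
  chord <- vecNorm(p1 - p0)
  if (chord > nSeg * (BOND_TARGET + 2 * BOND_PAD))
    stop("linker anchors too far apart to bridge: ", round(chord, 1),
         " angstrom")
  S <- max(chord * 1.001, nSeg * 3.4)
  ## circular arc: solve S = chord * phi / (2 sin(phi/2)) for phi
  f <- function(phi) phi / (2 * sin(phi / 2)) - S / chord
  phi <- tryCatch(stats::uniroot(f, c(1e-6, 2 * pi - 1e-6))$root,
                  error = function(e) NA_real_)
  mid <- (p0 + p1) / 2
  outDir <- mid - awayFrom
  outDir <- outDir - sum(outDir * unitVec(p1 - p0)) * unitVec(p1 - p0)
  if (vecNorm(outDir) < 1e-6) outDir <- crossProd3(unitVec(p1 - p0),
                                                   c(0, 0, 1))
  outDir <- unitVec(outDir)
  ts <- seq_len(nInterior) / nSeg
  if (is.na(phi)) {   # nearly straight
    xyz <- t(vapply(ts, function(f) p0 + f * (p1 - p0), numeric(3)))
    return(xyz)
  }
  Rarc <- chord / (2 * sin(phi / 2))
  sag <- Rarc * (1 - cos(phi / 2))
  xyz <- t(vapply(ts, function(fr) {
    a <- (fr - 0.5) * phi
    along <- Rarc * sin(a) / chord + 0.5     # fractional along-chord
    h <- Rarc * cos(a) - (Rarc - sag)
    p0 + along * (p1 - p0) + h * outDir
  }, numeric(3)))
  xyz
}

#' Assemble the dimeric protein-DNA complex
#'
#' Runs the modelling stages end to end: (2) bent tandem-site DNA with
#' self-consistent DNA restraints; (3) two HMG domains placed on the two
#' inverted sites with interface restraints; (4) the dimerization
#' helices built at ideal helical geometry (satisfying their stage-4
#' helix restraints) and (5) positioned by AIR-driven rigid-body docking
#' onto the partner HMG (or their own, with `trans = FALSE`), from whose
#' representative pose 50 contact restraints are sampled; linkers are
#' threaded between helix and domain; (6) all restraints amalgamated and
#' the protein beads refined by Metropolis simulated annealing with the
#' linker unrestrained (bonded terms only), followed by a greedy quench.
#'
#' When the AIR lists are empty the helices are left extended and
#' undocked; the report then flags `alpha0Docked = FALSE`.
#'
#' @param config an [assemblyConfig()].
#' @return list with `complex` (a [ComplexModel-class]), `report` (see
#'   [validateModel()]; plus per-stage energies) and `trace`.
#' @export
assembleDimer <- function(config = assemblyConfig()) {
  stopifnot(inherits(config, "AssemblyConfig"))
  prov <- list()
  ## stage 2: bent DNA + restraints -------------------------------------
  probe <- scanMotif(config$probe, config$motif)
  hits <- siteHits(probe)
  if (nrow(hits) != 2L)
    stop("stage2: expected exactly two binding sites on the probe, got ",
         nrow(hits))
  dnaStraight <- buildBDNA(topStrand(probe))
  spec <- bendSpec(list(c(hits$start[1], hits$end[1]),
                        c(hits$start[2], hits$end[2])),
                   perSiteBend = config$perSiteBend,
                   phasing = config$bendPhasing)
  dna <- applySiteBend(dnaStraight, spec)
  dnaRes <- deriveDNARestraints(dna)
  prov$stage2 <- list(bend = measureBend(dna))
  ## stage 3: place the HMG domains -------------------------------------
  hmgA <- toyHMG(config$foldSpec, chain = "A")
  hmgB <- toyHMG(config$foldSpec, chain = "B")
  siteA <- hits[hits$strand == "+", ][1, ]
  siteB <- hits[hits$strand == "-", ][1, ]
  plA <- placeHmgOnDna(hmgA, dna, siteA)
  plB <- placeHmgOnDna(hmgB, dna, siteB)
  if (min(crossDist(coords(plA$model), coords(plB$model))) <
      CLASH_COUNT_CUTOFF)
    stop("stage3: overlapping HMG placements (clash)")
  ifaceRes <- c(plA$restraints, plB$restraints)
  prov$stage3 <- list(interfaceRestraints = length(ifaceRes))
  ## stages 4+5: dimerization helices, docked or extended ---------------
  docked <- length(config$airActiveA) > 0
  helixRegion <- proteinRegion(config$alpha0Seq, config$alpha0Start)
  alpha0 <- list()
  contactRes <- emptyRestraints()
  helixRes <- emptyRestraints()
  if (docked) {
    for (side in 1:2) {
      chSelf <- c("A", "B")[side]
      chPartner <- if (config$trans) c("B", "A")[side] else chSelf
      receptor <- if (chPartner == "A") plA$model else plB$model
      mobile <- idealHelix(config$alpha0Seq, config$alpha0Start,
                           chain = chSelf)
      airs <- makeAIRs(config$airActiveA, config$airActiveB,
                       config$airPassiveB, chainA = chSelf,
                       chainB = chPartner)
      ens <- dockTrials(mobile, receptor, airs,
                        nTrials = config$nTrials,
                        seed = config$seed + side)
      sel <- rankSelect(ens, config$top)
      bins <- clusterByOrientation(sel)
      ## candidate must be bridgeable: its helix C terminus has to reach
      ## the chain's own HMG N terminus through the 15-residue linker
      ownHmg <- if (chSelf == "A") plA$model else plB$model
      own101 <- coords(ownHmg)[match(config$linkerSpan[2] + 1L,
                                     residueNumbers(ownHmg)), ]
      maxReach <- (config$linkerSpan[2] - config$linkerSpan[1] + 2L) *
        BOND_TARGET * 0.92
      candOrder <- unlist(lapply(bins, function(b)
        b$members[order(energies(sel)[b$members])]))
      rep <- NULL
      for (ci in candOrder) {
        cc <- poseCoords(sel, ci)
        reach <- vecNorm(cc[nrow(cc), ] - own101)
        if (reach <= maxReach) {
          rep <- list(index = ci, energy = energies(sel)[ci],
                      coords = cc)
          break
        }
      }
      if (is.null(rep))
        stop("stage5: no linker-compatible docking candidate for chain ",
             chSelf)
      a0 <- mobile
      coords(a0) <- rep$coords
      alpha0[[chSelf]] <- a0
      pair <- combineModels(a0, receptor)
      contactRes <- c(contactRes,
        sampleContactRestraints(pair, c(chSelf, chPartner),
                                n = config$nContacts,
                                cutoff = config$contactCutoff,
                                seed = config$seed + 10 + side))
      prov[[paste0("stage5_", chSelf)]] <-
        list(trials = config$nTrials, bins = vapply(bins, function(b)
          length(b$members), integer(1)), energy = rep$energy)
    }
    hs <- config$helixSpan
    sub <- substr(config$alpha0Seq, hs[1] - config$alpha0Start + 1L,
                  hs[2] - config$alpha0Start + 1L)
    helixRes <- c(helixRestraints(proteinRegion(sub, hs[1]), "A"),
                  helixRestraints(proteinRegion(sub, hs[1]), "B"))
  } else {
    ## no AIRs: leave the extension extended, pointing away from the DNA
    for (chSelf in c("A", "B")) {
      hmg <- if (chSelf == "A") plA$model else plB$model
      p101 <- coords(hmg)[match(101L, residueNumbers(hmg)), ]
      away <- unitVec(p101 - colMeans(coords(dnaBeads(dna))))
      res <- config$alpha0Start:(config$alpha0Start +
                                 nchar(config$alpha0Seq) - 1L)
      ## extended at 3.5 A per residue back from residue 101
      xyz <- t(vapply(seq_along(res), function(j)
        p101 + (101L - res[j]) * 3.5 * away, numeric(3)))
      alpha0[[chSelf]] <- coarseModel(chSelf, res, xyz,
                                      meta = list(sequence =
                                                    config$alpha0Seq))
    }
  }
  ## linkers ------------------------------------------------------------
  ls <- config$linkerSpan
  nInt <- ls[2] - ls[1] + 1L
  chains <- list()
  for (chSelf in c("A", "B")) {
    hmg <- if (chSelf == "A") plA$model else plB$model
    a0 <- alpha0[[chSelf]]
    a0End <- coords(a0)[match(ls[1] - 1L, residueNumbers(a0)), ]
    hmgStart <- coords(hmg)[match(ls[2] + 1L, residueNumbers(hmg)), ]
    away <- colMeans(rbind(coords(plA$model), coords(plB$model),
                           coords(dnaBeads(dna))))
    lxyz <- threadLinker(a0End, hmgStart, nInt, away)
    linker <- coarseModel(chSelf, ls[1]:ls[2], lxyz)
    chains[[chSelf]] <- combineModels(a0, linker, hmg)
  }
  ## stage 6: amalgamated refinement ------------------------------------
  allRes <- c(dnaRes, ifaceRes, helixRes, contactRes)
  complexM <- new("ComplexModel", proteins = chains, dna = dna,
                  restraints = allRes, provenance = prov)
  beads <- complexBeads(complexM)
  mobileIdx <- which(beadRoles(beads) == "CA")   # DNA frames stay fixed
  segA <- which(chainIds(beads) == "A" &
                residueNumbers(beads) <= ls[1] - 1L)
  segB <- which(chainIds(beads) == "B" &
                residueNumbers(beads) <= ls[1] - 1L)
  ann <- annealModel(beads, allRes, config$schedule,
                     mobile = mobileIdx,
                     segments = list(segA, segB))
  refined <- ann$model
  for (chSelf in c("A", "B")) {
    idx <- which(chainIds(refined) == chSelf)
    m <- chains[[chSelf]]
    coords(m) <- coords(refined)[idx, , drop = FALSE]
    chains[[chSelf]] <- m
  }
  prov$stage6 <- list(energyTrace = ann$trace, seed = config$seed)
  complexM@proteins <- chains
  complexM@provenance <- prov
  report <- validateModel(complexM)
  report$alpha0Docked <- docked &&
    all(report$alpha0CrossContacts > 0)
  if (!docked) report$note <- "no dimerization AIRs: alpha0 not docked"
  list(complex = complexM, report = report, trace = ann$trace)
}

#' Validation metrics for an assembled complex
#'
#' Deterministic quality report: overall DNA bend, worst restraint
#' violation, cross-chain clash count (bead pairs closer than 2.5
#' angstrom), restraint satisfaction fraction, linker end-to-end spans,
#' and the number of cross-chain contacts the dimerization helix of each
#' chain makes with the partner HMG domain.
#'
#' @param complex a [ComplexModel-class].
#' @param linkerSpan residue interval of the unrestrained linker.
#' @return named list of metrics.
#' @export
validateModel <- function(complex, linkerSpan = c(86, 100)) {
  beads <- complexBeads(complex)
  xyz <- coords(beads)
  chains <- chainIds(beads)
  ev <- evaluateRestraints(complex@restraints, beads)
  chs <- unique(chains)
  clashes <- 0L
  for (a in seq_len(length(chs) - 1L)) for (b in seq(a + 1L, length(chs))) {
    D <- crossDist(xyz[chains == chs[a], , drop = FALSE],
                   xyz[chains == chs[b], , drop = FALSE])
    clashes <- clashes + sum(D < CLASH_COUNT_CUTOFF)
  }
  linkerSpanOf <- function(ch) {
    i0 <- which(chains == ch & residueNumbers(beads) == linkerSpan[1])
    i1 <- which(chains == ch & residueNumbers(beads) == linkerSpan[2])
    if (!length(i0) || !length(i1)) return(NA_real_)
    vecNorm(xyz[i1, ] - xyz[i0, ])
  }
  crossContacts <- function(chSelf, chPartner) {
    ia <- which(chains == chSelf & residueNumbers(beads) < linkerSpan[1])
    ib <- which(chains == chPartner &
                residueNumbers(beads) > linkerSpan[2])
    if (!length(ia) || !length(ib)) return(0L)
    sum(crossDist(xyz[ia, , drop = FALSE],
                  xyz[ib, , drop = FALSE]) <= CONTACT_CUTOFF)
  }
  list(bendDeg = measureBend(complex@dna),
       totalRestraintEnergy = ev$total,
       maxViolation = if (length(ev$energies))
         max(abs(ev$violations$deviation)) else 0,
       satisfaction = restraintSatisfaction(complex@restraints, beads),
       clashCount = as.integer(clashes),
       linkerSpans = c(A = linkerSpanOf("A"), B = linkerSpanOf("B")),
       alpha0CrossContacts = c(A = crossContacts("A", "B"),
                               B = crossContacts("B", "A")))
}
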