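## Stage-5 rigid-body docking of the dimerization helix onto the HMG
## alpha1/alpha2 surface: random-start trials minimized under AIR energy
## plus a soft-sphere clash penalty, energy ranking, greedy orientation
## clustering, and representative selection.

CLASH_SIGMA <- 4.0   # soft-sphere diameter between cross-chain beads, A

## Compile AIRs referencing mobile (chain of `mobile`) and receptor beads
## into index lists against the two coordinate blocks.
compileDockingAirs <- function(airs, mobile, receptor) {
  mkeys <- beadKeys(mobile); rkeys <- beadKeys(receptor)
  tb <- restraintTable(airs)
  tb <- tb[tb$type == "air", , drop = FALSE]
  lapply(seq_len(nrow(tb)), function(i) {
    ka <- splitSel(tb$selA[i]); kb <- splitSel(tb$selB[i])
    ia <- match(ka, mkeys); ib <- match(kb, rkeys)
    swapped <- FALSE
    if (anyNA(ia) || anyNA(ib)) {   # groups may be given receptor-first
      ia2 <- match(kb, mkeys); ib2 <- match(ka, rkeys)
      if (anyNA(ia2) || anyNA(ib2))
        stop("AIR ", i, " references beads outside the two chains")
      ia <- ia2; ib <- ib2; swapped <- TRUE
    }
    list(ia = ia, ib = ib, target = tb$target[i],
         upperPad = tb$upperPad[i], k = tb$k[i], swapped = swapped)
  })
}

## Docking energy: AIR flat-bottom upper bounds + soft-sphere clash, from
## the cross-chain distance matrix D (mobile rows x receptor cols).
dockEnergyFromD <- function(D, cairs) {
  e <- 0
  for (a in cairs) {
    d6 <- D[a$ia, a$ib]^-6
    deff <- if (any(!is.finite(d6))) 0 else sum(d6)^(-1 / 6)
    v <- max(0, deff - a$target - a$upperPad)
    e <- e + a$k * v * v
  }
  cl <- D[D < CLASH_SIGMA]
  if (length(cl)) e <- e + sum((CLASH_SIGMA - cl)^2)
  e
}

## Reference (vectorized R) docking energy, used for cross-checking the
## compiled implementation and for reporting.
dockEnergy <- function(mobileXyz, receptorXyz, cairs) {
  dockEnergyFromD(crossDist(mobileXyz, receptorXyz), cairs)
}

## Deterministic coordinate-wise rigid-body minimization: sweep the six
## degrees of freedom (rotations about x/y/z, translations along x/y/z)
## trying +/- the current step; shrink both steps x0.7 after a sweep with
## no improvement; stop below 1e-3 or after `maxSweeps` sweeps. The hot
## loop is compiled (src/dock.cpp).
minimizePose <- function(ref, receptorXyz, cairs, R, t,
                         stepRot = 0.35, stepTrans = 2.0,
                         maxSweeps = 200) {
  .minimizePoseCpp(ref, receptorXyz, cairs, R, t, stepRot, stepTrans,
                   as.integer(maxSweeps), CLASH_SIGMA)
}

#' Rigid-body docking trials under ambiguous restraints
#'
#' Each trial starts the mobile chain at a uniformly random rotation and
#' a random point on a shell around the receptor interface (the centroid
#' of the AIR-restrained receptor residues), then locally minimizes
#' AIR energy + soft-sphere clash by a deterministic coordinate-wise
#' rigid-body search. Reproducible under `seed`.
#'
#' @param mobile mobile-chain `CoarseModel` (its reference coordinates
#'   are re-centred internally).
#' @param receptor receptor `CoarseModel`, held fixed.
#' @param airs `RestraintSet` of AIRs referencing only these two chains.
#' @param nTrials number of trials (>= 1).
#' @param seed integer seed.
#' @return a [DockEnsemble-class] of `nTrials` results.
#' @examples
#' prob <- plantedDockingProblem(seed = 7)
#' ens <- dockTrials(prob$mobile, prob$receptor, prob$airs,
#'                   nTrials = 20, seed = 7)
#' @export
dockTrials <- function(mobile, receptor, airs, nTrials = 400, seed = 1) {
  if (nTrials < 1) stop("nTrials must be >= 1")
  ref <- coords(mobile)
  refCentred <- sweep(ref, 2, colMeans(ref))
  rec <- coords(receptor)
  cairs <- compileDockingAirs(airs, mobile, receptor)
  ifaceIdx <- sort(unique(unlist(lapply(cairs, `[[`, "ib"))))
  ifaceC <- colMeans(rec[ifaceIdx, , drop = FALSE])
  ifaceR <- max(crossDist(rec[ifaceIdx, , drop = FALSE],
                          matrix(ifaceC, 1)))
  mobR <- max(crossDist(refCentred, matrix(0, 1, 3)))
  shell <- ifaceR + mobR + 5
  poses <- vector("list", nTrials)
  energies <- numeric(nTrials)
  withSeed(seed, {
    for (i in seq_len(nTrials)) {
      R0 <- randomRotation()
      u <- stats::rnorm(3); u <- u / vecNorm(u)
      t0 <- ifaceC + shell * u
      m <- minimizePose(refCentred, rec, cairs, R0, t0)
      poses[[i]] <- list(R = m$R, t = m$t)
      energies[i] <- m$energy
    }
  })
  new("DockEnsemble", poses = poses, energies = energies,
      trial = seq_len(nTrials), seed = as.numeric(seed),
      mobileRef = {
        mc <- mobile; coords(mc) <- refCentred; mc
      },
      receptor = receptor)
}

#' @rdname energies
#' @export
setMethod("energies", "DockEnsemble", function(object) object@energies)

setMethod("show", "DockEnsemble", function(object) {
  cat(sprintf("DockEnsemble: %d poses, energy range [%.3g, %.3g]\n",
              length(object@poses), min(object@energies),
              max(object@energies)))
})

#' Mobile-chain coordinates of one pose
#'
#' @param ens a `DockEnsemble`.
#' @param i trial index (position in the ensemble).
#' @return n x 3 coordinate matrix of the posed mobile chain.
#' @export
poseCoords <- function(ens, i) {
  p <- ens@poses[[i]]
  transformCoords(coords(ens@mobileRef), p$R, p$t)
}

#' Select the lowest-energy docking results
#'
#' Stable selection: ties are broken by trial index. Requesting more than
#' available returns everything with a warning.
#'
#' @param ens a `DockEnsemble`.
#' @param top number of results to keep (default 20).
#' @return the subset `DockEnsemble`, sorted by energy.
#' @export
rankSelect <- function(ens, top = 20) {
  n <- length(ens@poses)
  if (n < 1) stop("empty ensemble")
  if (top > n) {
    warning("requested top ", top, " of ", n, " results; returning all")
    top <- n
  }
  ord <- order(ens@energies, ens@trial)[seq_len(top)]
  new("DockEnsemble", poses = ens@poses[ord],
      energies = ens@energies[ord], trial = ens@trial[ord],
      seed = ens@seed, mobileRef = ens@mobileRef,
      receptor = ens@receptor)
}

## Orientation descriptor of a pose: interhelical angle between the posed
## mobile helix axis and the receptor alpha1 axis (degrees), plus a
## topology flag for whether the mobile N terminus sits nearer the alpha1
## N terminus than the mobile C terminus does to the alpha2 C terminus.
orientationDescriptor <- function(ens, i) {
  mob <- poseCoords(ens, i)
  rec <- coords(ens@receptor)
  spans <- ens@receptor@meta$spans
  rres <- residueNumbers(ens@receptor)
  if (!is.null(spans)) {
    a1Idx <- which(rres >= spans$a1[1] & rres <= spans$a1[2])
    a2Idx <- which(rres >= spans$a2[1] & rres <= spans$a2[2])
  } else {  # generic receptor: split in half along the chain
    half <- ceiling(length(rres) / 2)
    a1Idx <- seq_len(half)
    a2Idx <- seq(half + 1L, length(rres))
  }
  axMob <- principalAxis(mob)
  axA1 <- principalAxis(rec[a1Idx, , drop = FALSE])
  angle <- vecAngleDeg(axMob, axA1)
  dNN <- vecNorm(mob[1, ] - rec[a1Idx[1], ])
  dCC <- vecNorm(mob[nrow(mob), ] - rec[a2Idx[length(a2Idx)], ])
  list(angle = angle, nnDistance = dNN, nTopology = dNN <= dCC)
}

#' Cluster selected poses by orientation
#'
#' Greedy leader clustering on the orientation descriptor: poses are
#' visited in energy order; a pose joins the first existing bin whose
#' leader is within `angleBinWidth` degrees of interhelical angle and
#' shares its terminus-proximity topology, otherwise it founds a new bin.
#' The number of bins is emergent. Bins are returned sorted by size
#' (descending), ties by leader angle.
#'
#' @param ens a (typically rank-selected) `DockEnsemble`.
#' @param angleBinWidth angular bin half-width (degrees).
#' @return list of bins; each bin is a list with `members` (positions in
#'   `ens`), `representative` (lowest-energy member), `angle` (leader
#'   orientation angle) and `nnDistance`.
#' @export
clusterByOrientation <- function(ens, angleBinWidth = 45) {
  n <- length(ens@poses)
  if (n < 1) stop("empty ensemble")
  desc <- lapply(seq_len(n), function(i) orientationDescriptor(ens, i))
  ord <- order(ens@energies, ens@trial)
  bins <- list()
  for (i in ord) {
    placed <- FALSE
    for (b in seq_along(bins)) {
      lead <- desc[[bins[[b]]$leader]]
      if (abs(desc[[i]]$angle - lead$angle) <= angleBinWidth &&
          desc[[i]]$nTopology == lead$nTopology) {
        bins[[b]]$members <- c(bins[[b]]$members, i)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      bins[[length(bins) + 1L]] <- list(leader = i, members = i)
  }
  bins <- lapply(bins, function(b) {
    mem <- b$members
    rep <- mem[order(ens@energies[mem], ens@trial[mem])][1]
    list(members = mem, representative = rep,
         angle = desc[[b$leader]]$angle,
         nnDistance = desc[[b$leader]]$nnDistance,
         nTopology = desc[[b$leader]]$nTopology)
  })
  sizes <- vapply(bins, function(b) length(b$members), integer(1))
  angles <- vapply(bins, function(b) b$angle, numeric(1))
  bins[order(-sizes, angles)]
}

#' Representative pose of a clustered ensemble
#'
#' The lowest-energy member of the predominant (largest) bin; ties
#' between equal-size bins go to the smaller orientation angle, then the
#' lower trial index.
#'
#' @param bins bin list from [clusterByOrientation()].
#' @param ens the `DockEnsemble` the bins index into.
#' @return list with `index` (position in `ens`), `pose`, `energy`,
#'   `coords` (posed mobile coordinates).
#' @export
pickRepresentative <- function(bins, ens) {
  if (!length(bins)) stop("no bins")
  idx <- bins[[1]]$representative
  list(index = idx, pose = ens@poses[[idx]],
       energy = ens@energies[idx], coords = poseCoords(ens, idx))
}
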