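## Coarse-grained B-DNA: one orthonormal frame per base pair, propagated
## from helicoidal step parameters (twist/roll/tilt/rise), with two beads
## per base pair at approximate phosphate positions. Site-directed bends
## are imposed as lab-frame-axis rotations distributed across a binding
## footprint, and the overall bend is measured from the terminal helix
## axes.

DNA_RISE <- 3.4       # angstrom per step
DNA_TWIST <- 36       # degrees per step
DNA_BEAD_OFFSET <- 4.5  # bead distance from the frame origin along +/- y

#' Default base-pair step parameters
#'
#' @param twist twist per step (degrees).
#' @param rise rise per step (angstrom, > 0).
#' @param roll roll per step (degrees).
#' @param tilt tilt per step (degrees).
#' @return list of class `StepParams`.
#' @export
stepParams <- function(twist = DNA_TWIST, rise = DNA_RISE, roll = 0,
                       tilt = 0) {
  if (rise <= 0) stop("rise must be positive")
  if (abs(roll) >= 90 || abs(tilt) >= 90)
    stop("roll and tilt must lie in (-90, 90) degrees")
  structure(list(twist = twist, rise = rise, roll = roll, tilt = tilt),
            class = "StepParams")
}

#' Build straight (or uniformly wound) coarse B-DNA from sequence
#'
#' Frames are propagated per step by composing the twist, roll and tilt
#' rotations in the local frame and translating by `rise` along the local
#' helix axis. With default parameters the result is straight B-DNA:
#' consecutive origins 3.4 angstrom apart, 36 degrees of twist per step.
#'
#' @param sequence top-strand A/C/G/T sequence (length >= 2).
#' @param steps a single `StepParams` applied uniformly, or a list of
#'   per-step `StepParams` of length `nchar(sequence) - 1`.
#' @return a [DNAModel-class].
#' @examples
#' dna <- buildBDNA("GGGATCCTACACAAAGCCGGCTTTGTGTAGGATCCC")
#' measureBend(dna)
#' @export
buildBDNA <- function(sequence, steps = stepParams()) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("invalid base in sequence (A/C/G/T only)")
  n <- nchar(sequence)
  if (n < 2L) stop("sequence must have length >= 2")
  if (inherits(steps, "StepParams")) steps <- rep(list(steps), n - 1L)
  if (length(steps) != n - 1L)
    stop("need one StepParams per step (", n - 1L, ")")
  origins <- matrix(0, n, 3)
  triads <- array(0, c(3, 3, n))
  Tcur <- diag(3)
  triads[, , 1] <- Tcur
  for (i in seq_len(n - 1L)) {
    sp <- steps[[i]]
    origins[i + 1L, ] <- origins[i, ] + Tcur %*% c(0, 0, sp$rise)
    Tcur <- Tcur %*% rotZ(deg2rad(sp$twist)) %*%
      rotY(deg2rad(sp$roll)) %*% rotX(deg2rad(sp$tilt))
    triads[, , i + 1L] <- Tcur
  }
  new("DNAModel", sequence = sequence, origins = origins, triads = triads)
}

#' @rdname nbp
#' @export
setMethod("nbp", "DNAModel", function(x) nchar(x@sequence))

setMethod("show", "DNAModel", function(object) {
  cat(sprintf("DNAModel: %d bp, bend %.1f deg\n  %s\n", nbp(object),
              tryCatch(measureBend(object), error = function(e) NA),
              object@sequence))
})

#' Strand beads of a DNA model
#'
#' Two beads per base pair at +/- 4.5 angstrom from the frame origin
#' along the frame y axis (approximate phosphate positions): chain `C`
#' carries the top-strand bead, chain `D` the bottom-strand bead, both
#' numbered by base-pair index 1..n.
#'
#' @param x a `DNAModel`.
#' @return a [CoarseModel-class] with role `"P"` beads.
#' @export
dnaBeads <- function(x) {
  n <- nbp(x)
  top <- bot <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    y <- x@triads[, 2, i]
    top[i, ] <- x@origins[i, ] + DNA_BEAD_OFFSET * y
    bot[i, ] <- x@origins[i, ] - DNA_BEAD_OFFSET * y
  }
  new("CoarseModel",
      chain = rep(c("C", "D"), each = n),
      resno = rep(seq_len(n), 2L),
      role = rep("P", 2L * n),
      coords = rbind(top, bot),
      meta = list(sequence = x@sequence))
}

#' Specify site-directed bends
#'
#' @param footprints list of `c(start, end)` 0-based half-open bp
#'   intervals (the binding-site footprints), non-overlapping.
#' @param perSiteBend bend magnitude per site (degrees), distributed
#'   uniformly across each footprint's internal steps.
#' @param phasing `"coplanar"` (all sites bend about one common axis, the
#'   major-groove bend axis at the first site's centre, so site bends add)
#'   or `"per_site"` (each site bends about its own centre-frame axis).
#' @return list of class `BendSpec`.
#' @export
bendSpec <- function(footprints, perSiteBend = 54, phasing = "coplanar") {
  footprints <- lapply(footprints, as.integer)
  if (length(footprints) > 1L) {
    iv <- do.call(rbind, footprints)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] < iv[-nrow(iv), 2]))
      stop("bend footprints must not overlap")
  }
  phasing <- match.arg(phasing, c("coplanar", "per_site"))
  structure(list(footprints = footprints, perSiteBend = perSiteBend,
                 phasing = phasing), class = "BendSpec")
}

#' Impose per-site bends on a DNA model
#'
#' Rebuilds the frames, inserting at every internal step of each
#' footprint an additional rotation of `perSiteBend / nsteps` degrees
#' about a fixed bend axis, so the bend is phased toward the major groove
#' at the site centre. With `"coplanar"` phasing all sites share one
#' bend axis and their bend angles compose additively (two 54-degree
#' sites give a 108-degree overall bend); with `"per_site"` phasing each
#' site uses its own centre frame and the composition depends on the
#' helical phase between sites.
#'
#' @param model a `DNAModel` (typically straight, from [buildBDNA()]).
#' @param spec a [bendSpec()].
#' @return the bent `DNAModel`.
#' @examples
#' dna <- buildBDNA(topStrand(bundledProbes()$CC36))
#' bent <- applySiteBend(dna, bendSpec(list(c(9, 16), c(20, 27)), 54))
#' measureBend(bent)
#' @export
applySiteBend <- function(model, spec) {
  stopifnot(is(model, "DNAModel"), inherits(spec, "BendSpec"))
  n <- nbp(model)
  for (fp in spec$footprints)
    if (fp[1] < 0 || fp[2] > n) stop("footprint outside sequence")
  if (spec$perSiteBend == 0) return(model)
  ## per-step bend increments (degrees), indexed by step i = bp i -> i+1
  bendPerStep <- numeric(n - 1L)
  siteOfStep <- integer(n - 1L)
  for (s in seq_along(spec$footprints)) {
    fp <- spec$footprints[[s]]
    stepIdx <- seq(fp[1] + 1L, fp[2] - 1L)  # 1-based internal steps
    bendPerStep[stepIdx] <- spec$perSiteBend / length(stepIdx)
    siteOfStep[stepIdx] <- s
  }
  ## bend axes: major-groove bend axis (frame y) at each site's centre bp
  ## of the *input* model; coplanar phasing shares the first site's axis.
  axes <- lapply(spec$footprints, function(fp) {
    centre <- floor((fp[1] + fp[2] - 1) / 2) + 1L
    model@triads[, 2, centre]
  })
  if (spec$phasing == "coplanar") axes <- rep(axes[1], length(axes))
  ## re-propagate frames with the same twist/rise, adding the bend as a
  ## lab-frame rotation expressed in local coordinates
  origins <- matrix(0, n, 3)
  triads <- array(0, c(3, 3, n))
  origins[1, ] <- model@origins[1, ]
  Tcur <- model@triads[, , 1]
  triads[, , 1] <- Tcur
  for (i in seq_len(n - 1L)) {
    ## local step of the input model (twist/roll/tilt/rise as built)
    S <- t(model@triads[, , i]) %*% model@triads[, , i + 1L]
    rise <- vecNorm(model@origins[i + 1L, ] - model@origins[i, ])
    origins[i + 1L, ] <- origins[i, ] + Tcur %*% c(0, 0, rise)
    Tnext <- Tcur %*% S
    if (bendPerStep[i] != 0) {
      u <- axes[[siteOfStep[i]]]
      Tnext <- rotAxis(u, deg2rad(bendPerStep[i])) %*% Tnext
    }
    Tcur <- Tnext
    triads[, , i + 1L] <- Tcur
  }
  new("DNAModel", sequence = model@sequence, origins = origins,
      triads = triads,
      bendSpec = list(footprints = spec$footprints,
                      perSiteBend = spec$perSiteBend,
                      phasing = spec$phasing))
}

#' @rdname measureBend
#' @export
setMethod("measureBend", "DNAModel", function(x, endWindow = 5L) {
  n <- nbp(x)
  if (n < 2L * endWindow + 2L)
    stop("model too short for endWindow = ", endWindow)
  zFirst <- rowMeans(sapply(seq_len(endWindow), function(i)
    x@triads[, 3, i]))
  zLast <- rowMeans(sapply(seq(n - endWindow + 1L, n), function(i)
    x@triads[, 3, i]))
  vecAngleDeg(zFirst, zLast)
})

#' @rdname measureBend
#' @export
setMethod("measureBend", "ComplexModel", function(x, endWindow = 5L)
  measureBend(x@dna, endWindow = endWindow))

#' Derive self-consistent DNA restraints from a model
#'
#' Emits (i) two-sided distance restraints between each bead and its
#' intra-strand i+1 and i+2 neighbours and its inter-strand partner, with
#' targets equal to the current model distances, and (ii) one planarity
#' restraint per stacked base-pair step (the 4 beads of two adjacent base
#' pairs). Every restraint evaluates to zero energy on the source model
#' by construction. Flat-bottom half-widths are +/- 0.5 angstrom.
#'
#' @param model a `DNAModel`.
#' @param pad flat-bottom half-width (angstrom).
#' @param k force constant (reduced energy per square angstrom).
#' @return a [RestraintSet-class] tagged `stage2_dna`.
#' @export
deriveDNARestraints <- function(model, pad = 0.5, k = 1) {
  beads <- dnaBeads(model)
  xyz <- coords(beads)
  keys <- beadKeys(beads)
  n <- nbp(model)
  topIdx <- seq_len(n)
  botIdx <- n + seq_len(n)
  rows <- list()
  addDist <- function(i, j) {
    d <- vecNorm(xyz[i, ] - xyz[j, ])
    rows[[length(rows) + 1L]] <<- data.frame(
      type = "distance", selA = keys[i], selB = keys[j], target = d,
      lowerPad = pad, upperPad = pad, k = k, stage = "stage2_dna",
      stringsAsFactors = FALSE)
  }
  for (strand in list(topIdx, botIdx)) {
    for (off in 1:2)
      for (i in seq_len(n - off)) addDist(strand[i], strand[i + off])
  }
  for (i in seq_len(n)) addDist(topIdx[i], botIdx[i])
  for (i in seq_len(n - 1L)) {
    quad <- c(topIdx[i], botIdx[i], topIdx[i + 1L], botIdx[i + 1L])
    rms <- planeRms(xyz[quad, ])
    rows[[length(rows) + 1L]] <- data.frame(
      type = "planarity", selA = paste(keys[quad], collapse = "+"),
      selB = "", target = rms + pad, lowerPad = 0, upperPad = 0, k = k,
      stage = "stage2_dna", stringsAsFactors = FALSE)
  }
  new("RestraintSet", table = do.call(rbind, rows))
}
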