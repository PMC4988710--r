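## Synthesis of the modelling restraints: alpha-helix pseudo-torsion and
## hydrogen-bond restraints for the dimerization helix, mutagenesis-derived
## ambiguous interaction restraints (AIRs), and contact restraints sampled
## from a docked pose.

HELIX_TORSION_TARGET <- 50    # Calpha pseudo-dihedral of an alpha helix, deg
HELIX_TORSION_HW <- 10        # flat-bottom half-width, deg
HELIX_I3_TARGET <- 5.1        # Calpha i -> i+3 distance, angstrom
HELIX_I4_TARGET <- 6.2        # Calpha i -> i+4 distance, angstrom

#' Alpha-helix restraints for a protein region
#'
#' Synthesizes, for every residue window of the region, the standard
#' coarse-grained helix restraints: a Calpha pseudo-torsion restraint per
#' 4-residue window (target 50 degrees, half-width 10) and i->i+3
#' (5.1 angstrom) plus i->i+4 (6.2 angstrom) hydrogen-bond-style distance
#' restraints (upper-bound, pad 0.5). A region of n residues yields
#' (n-3) torsions, (n-3) i+3 and (n-4) i+4 restraints.
#'
#' @param region a [proteinRegion()] (or any list with `start` and
#'   `sequence`).
#' @param chain chain id carrying the region's beads.
#' @param torsionTarget,torsionHalfWidth pseudo-torsion target and
#'   half-width (degrees).
#' @param k force constant.
#' @return a [RestraintSet-class] tagged `stage4_helix`.
#' @examples
#' helixRestraints(proteinRegion("SIREAVSQVLSGY", 72), "A")
#' @export
helixRestraints <- function(region, chain,
                            torsionTarget = HELIX_TORSION_TARGET,
                            torsionHalfWidth = HELIX_TORSION_HW, k = 1) {
  n <- nchar(region$sequence)
  if (n < 5L) stop("helix region must have length >= 5")
  res <- region$start + seq_len(n) - 1L
  sets <- list()
  for (i in seq_len(n - 3L)) {
    sets[[length(sets) + 1L]] <- torsionRestraint(
      beadKey(chain, res[i + 0:3]), target = torsionTarget,
      halfWidth = torsionHalfWidth, k = k, stage = "stage4_helix")
    sets[[length(sets) + 1L]] <- hbondRestraint(
      beadKey(chain, res[i]), beadKey(chain, res[i + 3L]),
      target = HELIX_I3_TARGET, upperPad = 0.5, k = k,
      stage = "stage4_helix")
  }
  for (i in seq_len(n - 4L))
    sets[[length(sets) + 1L]] <- hbondRestraint(
      beadKey(chain, res[i]), beadKey(chain, res[i + 4L]),
      target = HELIX_I4_TARGET, upperPad = 0.5, k = k,
      stage = "stage4_helix")
  do.call(c, sets)
}

#' Mutagenesis-derived ambiguous interaction restraints
#'
#' One AIR per active residue on side A (the dimerization helix), each
#' satisfiable by any residue of the active + passive set on side B (the
#' HMG-domain platform and its surrounding hydrophobic surface). The
#' 2.0-angstrom atom-surface AIR target is applied to Calpha beads with a
#' +3.0-angstrom calibration offset (beads cannot approach to 2 angstrom).
#'
#' Defaults are the experimentally derived sets: active A
#' \{73, 76, 77, 80, 81, 84\}, active B \{119, 142\}, passive B
#' \{115, 123, 130, 138, 139, 146\}.
#'
#' @param activeA residue numbers of the active side-A residues.
#' @param activeB residue numbers of the active side-B residues.
#' @param passiveB residue numbers of the passive side-B residues.
#' @param chainA,chainB chain ids of the two sides.
#' @param target bead-level effective-distance upper bound (angstrom).
#' @param k force constant.
#' @return a [RestraintSet-class] tagged `stage5_air` with
#'   `length(activeA)` AIRs.
#' @examples
#' airs <- makeAIRs()
#' length(airs)   # 6
#' @export
makeAIRs <- function(activeA = c(73, 76, 77, 80, 81, 84),
                     activeB = c(119, 142),
                     passiveB = c(115, 123, 130, 138, 139, 146),
                     chainA = "A", chainB = "B",
                     target = 2.0 + AIR_BEAD_OFFSET, k = 1) {
  if (!length(activeA) || !length(activeB))
    stop("active residue lists must be non-empty")
  groupB <- beadKey(chainB, sort(unique(c(activeB, passiveB))))
  if (identical(chainA, chainB) &&
      length(intersect(activeA, c(activeB, passiveB))))
    stop("active A residues overlap the B-side residue set")
  sets <- lapply(activeA, function(r)
    ambiguousRestraint(beadKey(chainA, r), groupB, target = target,
                       k = k, stage = "stage5_air"))
  do.call(c, sets)
}

#' Sample contact restraints from a docked pose
#'
#' Draws `n` distinct cross-chain bead pairs uniformly among all pairs
#' within `cutoff`, and pins each at its current distance (two-sided,
#' pad 0.5 angstrom), so the emitted set evaluates to zero on the source
#' pose. The eligible pair list is sorted lexicographically before
#' sampling, so seeds are portable.
#'
#' @param model a `CoarseModel` containing both chains.
#' @param chainPair length-2 character vector of chain ids.
#' @param n number of restraints (default 50).
#' @param cutoff eligibility cutoff (angstrom).
#' @param seed integer seed.
#' @param k force constant.
#' @return a [RestraintSet-class] tagged `stage5_contact`.
#' @export
sampleContactRestraints <- function(model, chainPair, n = 50, cutoff = 10,
                                    seed = 1, k = 1) {
  ia <- which(chainIds(model) == chainPair[1])
  ib <- which(chainIds(model) == chainPair[2])
  if (!length(ia) || !length(ib))
    stop("chains not found in model: ", paste(chainPair, collapse = ", "))
  D <- crossDist(coords(model)[ia, , drop = FALSE],
                 coords(model)[ib, , drop = FALSE])
  elig <- which(D <= cutoff, arr.ind = TRUE)
  if (nrow(elig) < n)
    stop("only ", nrow(elig), " cross-chain pairs within ", cutoff,
         " angstrom; cannot sample ", n, " without replacement")
  keys <- beadKeys(model)
  pairKeys <- data.frame(a = keys[ia[elig[, 1]]], b = keys[ib[elig[, 2]]],
                         d = D[elig], stringsAsFactors = FALSE)
  pairKeys <- pairKeys[order(pairKeys$a, pairKeys$b), , drop = FALSE]
  pick <- withSeed(seed, sample.int(nrow(pairKeys), n))
  sets <- lapply(pick, function(i)
    distanceRestraint(pairKeys$a[i], pairKeys$b[i],
                      target = pairKeys$d[i], lowerPad = 0.5,
                      upperPad = 0.5, k = k, stage = "stage5_contact"))
  do.call(c, sets)
}
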