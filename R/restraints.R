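## Typed flat-bottom restraints and their evaluation.
##
## Every restraint contributes k * max(0, |deviation| - pad)^2 where the
## deviation and pad depend on the type:
##   distance   two-sided on the bead-bead distance
##   hbond      upper-bound only (a distance specialization)
##   air        upper-bound only on the r^-6-summed effective distance
##              between two bead groups (HADDOCK-style ambiguity)
##   torsion    two-sided on the 4-bead pseudo-dihedral, in radians
##   planarity  upper-bound on the RMS plane deviation of a bead group
##
## Energies are in reduced units (force constants default to 1 per square
## angstrom); they are invariant under rigid-body motion of the whole
## system by construction.

AIR_BEAD_OFFSET <- 3.0   # maps the 2.0-A atom-surface AIR target to beads

emptyRestraints <- function() {
  new("RestraintSet", table = data.frame(
    type = character(), selA = character(), selB = character(),
    target = numeric(), lowerPad = numeric(), upperPad = numeric(),
    k = numeric(), stage = character(), stringsAsFactors = FALSE))
}

beadKey <- function(chain, resno, role = "CA")
  paste(chain, resno, role, sep = ":")

joinSel <- function(keys) paste(keys, collapse = "+")

splitSel <- function(sel) if (nzchar(sel)) strsplit(sel, "+", fixed = TRUE)[[1]] else character()

restraintRow <- function(type, selA, selB, target, lowerPad, upperPad, k,
                         stage) {
  data.frame(type = type, selA = selA, selB = selB, target = target,
             lowerPad = lowerPad, upperPad = upperPad, k = k,
             stage = stage, stringsAsFactors = FALSE)
}

#' Build restraints of each type
#'
#' Constructors returning single-restraint [RestraintSet-class] objects;
#' sets concatenate with `c()`. Bead identifiers are `chain:resno:role`
#' keys as produced by [beadKeys()].
#'
#' @param beadA,beadB single bead keys.
#' @param groupA,groupB character vectors of bead keys (AIR groups; the
#'   active residue on side A, active + passive residues on side B).
#' @param beads character vector of >= 4 bead keys (planarity) or exactly
#'   4 consecutive-chain bead keys (torsion).
#' @param target restraint target (angstrom, or degrees for torsions).
#' @param lowerPad,upperPad flat-bottom half-widths (angstrom).
#' @param halfWidth torsion flat-bottom half-width (degrees).
#' @param maxRmsDeviation planarity RMS threshold (angstrom).
#' @param k force constant.
#' @param stage provenance tag.
#' @name restraint-constructors
NULL

#' @rdname restraint-constructors
#' @export
distanceRestraint <- function(beadA, beadB, target, lowerPad = 0.5,
                              upperPad = 0.5, k = 1, stage = "") {
  if (target <= 0) stop("distance target must be positive")
  new("RestraintSet", table = restraintRow("distance", beadA, beadB,
      target, lowerPad, upperPad, k, stage))
}

#' @rdname restraint-constructors
#' @export
hbondRestraint <- function(beadA, beadB, target, upperPad = 0.5, k = 1,
                           stage = "") {
  new("RestraintSet", table = restraintRow("hbond", beadA, beadB, target,
      0, upperPad, k, stage))
}

#' @rdname restraint-constructors
#' @export
ambiguousRestraint <- function(groupA, groupB,
                               target = 2.0 + AIR_BEAD_OFFSET,
                               upperPad = 0, k = 1, stage = "") {
  if (!length(groupA) || !length(groupB))
    stop("AIR groups must be non-empty")
  if (length(intersect(groupA, groupB)))
    stop("AIR groups must be disjoint")
  new("RestraintSet", table = restraintRow("air", joinSel(groupA),
      joinSel(groupB), target, 0, upperPad, k, stage))
}

#' @rdname restraint-constructors
#' @export
torsionRestraint <- function(beads, target, halfWidth = 10, k = 1,
                             stage = "") {
  if (length(beads) != 4L) stop("torsion needs exactly 4 beads")
  ch <- vapply(strsplit(beads, ":"), `[`, character(1), 1L)
  rn <- as.integer(vapply(strsplit(beads, ":"), `[`, character(1), 2L))
  if (length(unique(ch)) != 1L || any(diff(rn) != 1L))
    stop("torsion beads must be consecutive along one chain")
  new("RestraintSet", table = restraintRow("torsion", joinSel(beads), "",
      target, halfWidth, halfWidth, k, stage))
}

#' @rdname restraint-constructors
#' @export
planarityRestraint <- function(beads, maxRmsDeviation, k = 1,
                               stage = "") {
  if (length(beads) < 4L) stop("planarity needs >= 4 beads")
  new("RestraintSet", table = restraintRow("planarity", joinSel(beads),
      "", maxRmsDeviation, 0, 0, k, stage))
}

#' @rdname restraintTable
#' @export
setMethod("restraintTable", "RestraintSet", function(x) x@table)

#' Number of restraints in a set
#'
#' @param x a `RestraintSet`.
#' @export
setMethod("length", "RestraintSet", function(x) nrow(x@table))

#' Concatenate restraint sets (amalgamation across stages)
#'
#' @param x a `RestraintSet`.
#' @param ... further `RestraintSet`s.
#' @export
setMethod("c", "RestraintSet", function(x, ...) {
  tbs <- lapply(c(list(x), list(...)), restraintTable)
  new("RestraintSet", table = do.call(rbind, tbs))
})

setMethod("show", "RestraintSet", function(object) {
  tb <- object@table
  cat(sprintf("RestraintSet: %d restraints\n", nrow(tb)))
  if (nrow(tb)) print(table(type = tb$type, stage = tb$stage))
})

#' Effective distance of an ambiguous restraint
#'
#' HADDOCK-style r^-6 summation over all cross-pairs of the two groups:
#' `d_eff = (sum_ij d_ij^-6)^(-1/6)`. Always at most the minimum pairwise
#' distance, and monotone non-increasing as any pair approaches.
#' Coincident beads (d = 0) give 0 by convention.
#'
#' @param coordsA,coordsB coordinate matrices of the two groups.
#' @return effective distance (angstrom).
#' @examples
#' effectiveDistance(rbind(c(0, 0, 0)), rbind(c(5, 0, 0), c(0, 5, 0)))
#' @export
effectiveDistance <- function(coordsA, coordsB) {
  D <- crossDist(as.matrix(coordsA), as.matrix(coordsB))
  if (any(D == 0)) return(0)
  sum(D^-6)^(-1 / 6)
}

flatBottom <- function(dev, lowerPad, upperPad) {
  ifelse(dev > 0, pmax(0, dev - upperPad), pmax(0, -dev - lowerPad))
}

## Resolve restraint selections against a model: returns a compiled list
## (one element per restraint) of index vectors into the bead table.
compileRestraints <- function(set, model) {
  keys <- beadKeys(model)
  lookup <- function(sel, rowIdx) {
    ks <- splitSel(sel)
    idx <- match(ks, keys)
    if (anyNA(idx))
      stop("unresolvable bead(s) in restraint ", rowIdx, ": ",
           paste(ks[is.na(idx)], collapse = ", "))
    idx
  }
  tb <- restraintTable(set)
  lapply(seq_len(nrow(tb)), function(i) {
    list(type = tb$type[i], ia = lookup(tb$selA[i], i),
         ib = if (nzchar(tb$selB[i])) lookup(tb$selB[i], i) else integer(),
         target = tb$target[i], lowerPad = tb$lowerPad[i],
         upperPad = tb$upperPad[i], k = tb$k[i])
  })
}

## Energy and signed deviation of one compiled restraint term.
evalTerm <- function(term, xyz) {
  if (term$type %in% c("distance", "hbond")) {
    d <- vecNorm(xyz[term$ia, ] - xyz[term$ib, ])
    dev <- d - term$target
    if (term$type == "hbond" && dev < 0) dev <- 0
    v <- flatBottom(dev, term$lowerPad, term$upperPad)
  } else if (term$type == "air") {
    d <- effectiveDistance(xyz[term$ia, , drop = FALSE],
                           xyz[term$ib, , drop = FALSE])
    dev <- max(0, d - term$target)
    v <- flatBottom(dev, 0, term$upperPad)
  } else if (term$type == "torsion") {
    ang <- dihedralDeg(xyz[term$ia[1], ], xyz[term$ia[2], ],
                       xyz[term$ia[3], ], xyz[term$ia[4], ])
    dev <- ((ang - term$target + 180) %% 360) - 180
    v <- deg2rad(flatBottom(dev, term$lowerPad, term$upperPad))
  } else if (term$type == "planarity") {
    rms <- planeRms(xyz[term$ia, , drop = FALSE])
    dev <- max(0, rms - term$target)
    v <- dev
  } else stop("unknown restraint type: ", term$type)
  c(energy = term$k * v^2, deviation = dev)
}

#' Evaluate a restraint set on a model
#'
#' @param set a [RestraintSet-class].
#' @param model a [CoarseModel-class] (or `ComplexModel`; all beads are
#'   used) whose bead keys resolve every restraint selection.
#' @return list with `total` energy, `energies` per restraint, and
#'   `violations`: the restraint table augmented with `energy` and
#'   `deviation`, sorted by energy descending.
#' @examples
#' m <- coarseModel("A", 1:2, rbind(c(0, 0, 0), c(7, 0, 0)))
#' r <- distanceRestraint("A:1:CA", "A:2:CA", target = 5, lowerPad = 0.5,
#'                        upperPad = 0.5)
#' evaluateRestraints(r, m)$total   # 1 * (2 - 0.5)^2
#' @export
evaluateRestraints <- function(set, model) {
  if (is(model, "ComplexModel")) model <- complexBeads(model)
  terms <- compileRestraints(set, model)
  xyz <- coords(model)
  ev <- vapply(terms, evalTerm, numeric(2), xyz = xyz)
  tb <- restraintTable(set)
  tb$energy <- if (length(terms)) ev["energy", ] else numeric()
  tb$deviation <- if (length(terms)) ev["deviation", ] else numeric()
  list(total = sum(tb$energy), energies = tb$energy,
       violations = tb[order(-tb$energy), , drop = FALSE])
}

#' Fraction of restraints satisfied (zero flat-bottom energy)
#'
#' @inheritParams evaluateRestraints
#' @param tol energy below which a restraint counts as satisfied.
#' @export
restraintSatisfaction <- function(set, model, tol = 1e-9) {
  ev <- evaluateRestraints(set, model)
  if (!length(ev$energies)) return(1)
  mean(ev$energies <= tol)
}

#' Serialize restraints to a TSV file
#'
#' One row per restraint (`type`, `selA`, `selB`, `target`, `lowerPad`,
#' `upperPad`, `k`, `stage`); round-trips losslessly through
#' [readRestraints()].
#'
#' @param set a `RestraintSet`.
#' @param path output path.
#' @export
writeRestraints <- function(set, path) {
  utils::write.table(restraintTable(set), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRestraints
#' @export
readRestraints <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(selA = "character",
                                         selB = "character",
                                         stage = "character"))
  tb$selB[is.na(tb$selB)] <- ""
  tb$stage[is.na(tb$stage)] <- ""
  new("RestraintSet", table = tb)
}
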