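#' @import methods
NULL

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Double-stranded DNA probe
#'
#' Holds the top strand of a duplex oligonucleotide probe; the bottom strand
#' is always the reverse complement and is never stored independently.
#' Binding-site footprints found by [scanMotif()] can be attached to the
#' `siteHits` slot.
#'
#' @slot name probe name.
#' @slot topStrand upper-case A/C/G/T top-strand sequence.
#' @slot siteHits `data.frame` of site hits (columns `start`, `end`,
#'   `strand`, `matched`; `start`/`end` are 0-based half-open top-strand
#'   coordinates).
#' @export
setClass("DuplexProbe",
  representation(name = "character", topStrand = "character",
                 siteHits = "data.frame"),
  prototype(siteHits = data.frame(start = integer(), end = integer(),
                                  strand = character(),
                                  matched = character())))

setValidity("DuplexProbe", function(object) {
  s <- object@topStrand
  if (length(s) != 1L || nchar(s) < 1L)
    return("topStrand must be a single non-empty string")
  if (grepl("[^ACGT]", s))
    return("topStrand must be uppercase A/C/G/T only")
  TRUE
})

#' Coarse bead model of one or more chains
#'
#' One bead per protein residue (role `"CA"`) or per nucleotide
#' (role `"P"`). Beads are identified by the triple chain/residue/role,
#' which must be unique within a model.
#'
#' @slot chain character vector, one chain id per bead.
#' @slot resno integer residue (or base-pair) number per bead.
#' @slot role bead role per bead (`"CA"` for protein, `"P"` for DNA).
#' @slot coords numeric n x 3 coordinate matrix (angstroms).
#' @slot meta list of free-form annotations (sequence, region spans, ...).
#' @export
setClass("CoarseModel",
  representation(chain = "character", resno = "integer", role = "character",
                 coords = "matrix", meta = "list"),
  prototype(meta = list()))

setValidity("CoarseModel", function(object) {
  n <- nrow(object@coords)
  if (ncol(object@coords) != 3L) return("coords must be n x 3")
  if (length(object@chain) != n || length(object@resno) != n ||
      length(object@role) != n)
    return("chain/resno/role lengths must match coords rows")
  if (n > 0 && !all(is.finite(object@coords)))
    return("coords must be finite")
  keys <- paste(object@chain, object@resno, object@role, sep = ":")
  if (anyDuplicated(keys)) return("bead identifiers must be unique")
  TRUE
})

#' Coarse-grained B-DNA model
#'
#' One orthonormal frame per base pair: `origins` holds the frame origins
#' and `triads` the 3x3 orientation matrices (columns are the x, y, z axes;
#' x points into the major groove, z along the local helix axis). Two beads
#' per base pair -- one per strand, at fixed offsets in the frame -- are
#' derived from the frames with [dnaBeads()] and are never stored.
#'
#' @slot sequence top-strand A/C/G/T sequence.
#' @slot origins numeric n x 3 matrix of frame origins.
#' @slot triads 3 x 3 x n array of frame orientations.
#' @slot bendSpec list describing any bend applied (footprints, degrees,
#'   phasing), for provenance.
#' @export
setClass("DNAModel",
  representation(sequence = "character", origins = "matrix",
                 triads = "array", bendSpec = "list"),
  prototype(bendSpec = list()))

setValidity("DNAModel", function(object) {
  n <- nchar(object@sequence)
  if (grepl("[^ACGT]", object@sequence)) return("sequence must be A/C/G/T")
  if (nrow(object@origins) != n) return("one origin per base pair required")
  if (!identical(dim(object@triads), c(3L, 3L, as.integer(n))))
    return("triads must be 3 x 3 x n")
  for (i in seq_len(n)) {
    T <- object@triads[, , i]
    if (max(abs(t(T) %*% T - diag(3))) > 1e-9)
      return(sprintf("triad %d not orthonormal", i))
  }
  TRUE
})

#' Typed restraint set
#'
#' A table of flat-bottom restraints: two-sided distances, upper-bound
#' ambiguous interaction restraints (AIRs) and hydrogen-bond distances,
#' pseudo-torsions, and base-pair planarity restraints. Bead selections are
#' strings of `chain:resno:role` keys joined by `+`. Sets from different
#' modelling stages concatenate with `c()`.
#'
#' @slot table `data.frame` with columns `type` (one of `distance`, `air`,
#'   `hbond`, `torsion`, `planarity`), `selA`, `selB`, `target`,
#'   `lowerPad`, `upperPad`, `k`, `stage`.
#' @export
setClass("RestraintSet", representation(table = "data.frame"))

restraintTypes <- c("distance", "air", "hbond", "torsion", "planarity")

setValidity("RestraintSet", function(object) {
  tb <- object@table
  need <- c("type", "selA", "selB", "target", "lowerPad", "upperPad",
            "k", "stage")
  if (!all(need %in% names(tb))) return("missing restraint table columns")
  if (nrow(tb) > 0) {
    if (!all(tb$type %in% restraintTypes)) return("unknown restraint type")
    if (any(!is.finite(tb$target))) return("targets must be finite")
    if (any(tb$lowerPad < 0 | tb$upperPad < 0)) return("pads must be >= 0")
    if (any(tb$k < 0)) return("force constants must be >= 0")
  }
  TRUE
})

#' Four-parameter logistic fit of an EMSA titration
#'
#' @slot estimates named numeric: `a` (lower asymptote), `d` (upper
#'   asymptote), `kd` (midpoint, nM), `b` (steepness / Hill coefficient).
#' @slot se standard errors for the four parameters (Gauss-Newton
#'   curvature).
#' @slot converged logical convergence flag.
#' @slot residuals fit residuals.
#' @slot data the fitted `data.frame` (`conc`, `bound`).
#' @slot message optimizer diagnostic message.
#' @export
setClass("FourPLFit",
  representation(estimates = "numeric", se = "numeric",
                 converged = "logical", residuals = "numeric",
                 data = "data.frame", message = "character"))

#' Rigid-body docking ensemble
#'
#' @slot poses list of poses; each pose is a `list(R = 3x3 rotation,
#'   t = translation)` applied to the mobile chain's reference coordinates.
#' @slot energies numeric energy per trial (reduced units, AIR + clash).
#' @slot trial integer trial index per pose.
#' @slot seed the seed that generated the ensemble.
#' @slot mobileRef the mobile chain reference `CoarseModel`.
#' @slot receptor the receptor `CoarseModel`.
#' @export
setClass("DockEnsemble",
  representation(poses = "list", energies = "numeric", trial = "integer",
                 seed = "numeric", mobileRef = "CoarseModel",
                 receptor = "CoarseModel"))

setValidity("DockEnsemble", function(object) {
  if (length(object@poses) != length(object@energies) ||
      length(object@poses) != length(object@trial))
    return("poses, energies and trial must have equal length")
  if (any(!is.finite(object@energies))) return("energies must be finite")
  TRUE
})

#' Assembled dimeric protein-DNA complex
#'
#' @slot proteins list of two protein `CoarseModel`s (chains A and B; each
#'   spans the dimerization helix, linker and HMG domain).
#' @slot dna the `DNAModel`.
#' @slot restraints the amalgamated `RestraintSet` used in refinement.
#' @slot provenance list of stages applied, seeds and energies.
#' @export
setClass("ComplexModel",
  representation(proteins = "list", dna = "DNAModel",
                 restraints = "RestraintSet", provenance = "list"))

setValidity("ComplexModel", function(object) {
  if (length(object@proteins) != 2L) return("exactly two protein chains")
  if (!all(vapply(object@proteins, is, logical(1), "CoarseModel")))
    return("proteins must be CoarseModel objects")
  TRUE
})
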