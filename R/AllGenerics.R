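#' Bead coordinates of a model
#'
#' @param x a `CoarseModel` (or an object coercible to one).
#' @return numeric n x 3 matrix.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @param value replacement n x 3 coordinate matrix.
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' Bead identifier keys (`chain:resno:role`)
#'
#' @param x a `CoarseModel`.
#' @return character vector of unique bead keys.
#' @export
setGeneric("beadKeys", function(x) standardGeneric("beadKeys"))

#' Number of base pairs of a DNA model or probe
#'
#' @param x a `DNAModel` or `DuplexProbe`.
#' @export
setGeneric("nbp", function(x) standardGeneric("nbp"))

#' Top strand of a duplex probe
#'
#' @param x a `DuplexProbe`.
#' @export
setGeneric("topStrand", function(x) standardGeneric("topStrand"))

#' Site hits annotated on a probe
#'
#' @param x a `DuplexProbe`.
#' @return `data.frame` with columns `start`, `end`, `strand`, `matched`.
#' @export
setGeneric("siteHits", function(x) standardGeneric("siteHits"))

#' Restraint table of a RestraintSet
#'
#' @param x a `RestraintSet`.
#' @return the underlying `data.frame`.
#' @export
setGeneric("restraintTable", function(x) standardGeneric("restraintTable"))

#' Fitted 4PL parameter estimates
#'
#' @param object a `FourPLFit`.
#' @return named numeric vector `(a, d, kd, b)`.
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))

#' Standard errors of fitted 4PL parameters
#'
#' @param object a `FourPLFit`.
#' @export
setGeneric("stdErrors", function(object) standardGeneric("stdErrors"))

#' Docking trial energies
#'
#' @param object a `DockEnsemble`.
#' @export
setGeneric("energies", function(object) standardGeneric("energies"))

#' Protein chains of a complex
#'
#' @param x a `ComplexModel`.
#' @return list of two `CoarseModel`s.
#' @export
setGeneric("proteinChains", function(x) standardGeneric("proteinChains"))

#' DNA component of a complex
#'
#' @param x a `ComplexModel`.
#' @return the `DNAModel`.
#' @export
setGeneric("dnaModel", function(x) standardGeneric("dnaModel"))

#' Overall DNA bend angle
#'
#' Angle between the mean local helix axis over the first and last
#' `endWindow` base-pair frames, in degrees within `[0, 180]`.
#'
#' @param x a `DNAModel` or `ComplexModel`.
#' @param endWindow number of terminal frames averaged on each end.
#' @export
setGeneric("measureBend",
           function(x, endWindow = 5L) standardGeneric("measureBend"))
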