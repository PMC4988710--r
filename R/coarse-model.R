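#' Construct a coarse bead model
#'
#' @param chain chain id(s), recycled to the number of beads.
#' @param resno integer residue numbers.
#' @param coords numeric n x 3 coordinate matrix.
#' @param role bead role, recycled (`"CA"` for protein residues,
#'   `"P"` for DNA nucleotides).
#' @param meta optional list of annotations (e.g. `sequence`).
#' @return a [CoarseModel-class] object.
#' @examples
#' m <- coarseModel("A", 1:3, cbind(0:2 * 3.8, 0, 0))
#' beadKeys(m)
#' @export
coarseModel <- function(chain, resno, coords, role = "CA", meta = list()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  new("CoarseModel", chain = rep_len(as.character(chain), n),
      resno = rep_len(as.integer(resno), n),
      role = rep_len(as.character(role), n),
      coords = coords, meta = meta)
}

#' @rdname coords
#' @export
setMethod("coords", "CoarseModel", function(x) x@coords)

#' @rdname coords
#' @export
setReplaceMethod("coords", "CoarseModel", function(x, value) {
  value <- as.matrix(value)
  stopifnot(identical(dim(value), dim(x@coords)))
  x@coords <- value
  validObject(x)
  x
})

#' @rdname beadKeys
#' @export
setMethod("beadKeys", "CoarseModel", function(x)
  paste(x@chain, x@resno, x@role, sep = ":"))

#' Chain ids, residue numbers and roles of a model
#'
#' @param x a `CoarseModel`.
#' @name bead-info
NULL

#' @rdname bead-info
#' @export
chainIds <- function(x) x@chain

#' @rdname bead-info
#' @export
residueNumbers <- function(x) x@resno

#' @rdname bead-info
#' @export
beadRoles <- function(x) x@role

#' Concatenate coarse models into one coordinate system
#'
#' Bead identifiers must remain unique across the inputs.
#'
#' @param ... `CoarseModel` objects.
#' @return a single `CoarseModel`.
#' @export
combineModels <- function(...) {
  ms <- list(...)
  new("CoarseModel",
      chain = unlist(lapply(ms, function(m) m@chain)),
      resno = unlist(lapply(ms, function(m) m@resno)),
      role = unlist(lapply(ms, function(m) m@role)),
      coords = do.call(rbind, lapply(ms, coords)),
      meta = list())
}

#' Subset a coarse model by bead
#'
#' @param x a `CoarseModel`.
#' @param i logical or integer bead index.
#' @return the subset `CoarseModel`.
#' @export
subsetBeads <- function(x, i) {
  new("CoarseModel", chain = x@chain[i], resno = x@resno[i],
      role = x@role[i], coords = x@coords[i, , drop = FALSE],
      meta = x@meta)
}

#' Apply a rigid-body transform to a model
#'
#' @param x a `CoarseModel`.
#' @param R 3 x 3 rotation matrix.
#' @param t length-3 translation.
#' @return the transformed model.
#' @export
transformModel <- function(x, R = diag(3), t = c(0, 0, 0)) {
  coords(x) <- transformCoords(coords(x), R, t)
  x
}

setMethod("show", "CoarseModel", function(object) {
  ch <- table(object@chain)
  cat(sprintf("CoarseModel: %d beads in %d chain(s) [%s]\n",
              nrow(object@coords), length(ch),
              paste(sprintf("%s:%d", names(ch), ch), collapse = ", ")))
})

setMethod("show", "ComplexModel", function(object) {
  cat("ComplexModel: 2 protein chains + ",
      nchar(object@dna@sequence), "-bp DNA; ",
      nrow(object@restraints@table), " restraints\n", sep = "")
  if (length(object@provenance))
    cat("  stages:", paste(names(object@provenance), collapse = ", "), "\n")
})

#' @rdname proteinChains
#' @export
setMethod("proteinChains", "ComplexModel", function(x) x@proteins)

#' @rdname dnaModel
#' @export
setMethod("dnaModel", "ComplexModel", function(x) x@dna)

#' All beads of a complex (proteins + DNA) as one model
#'
#' @param x a `ComplexModel`.
#' @return a `CoarseModel`.
#' @export
complexBeads <- function(x) {
  do.call(combineModels, c(x@proteins, list(dnaBeads(x@dna))))
}
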