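## Sequence-level analysis of SOX binding probes and of the dimerization
## region: degenerate motif scanning on both strands, palindrome and
## site-spacing checks, helical-wheel projection with hydrophobic-face
## detection, and a rule-based dimerization phenotype predictor for
## substitution mutants.

#' Construct a duplex DNA probe
#'
#' @param name probe name.
#' @param topStrand uppercase A/C/G/T top-strand sequence. The bottom
#'   strand is always the reverse complement.
#' @return a [DuplexProbe-class].
#' @examples
#' duplexProbe("CC36", "GGGATCCTACACAAAGCCGGCTTTGTGTAGGATCCC")
#' @export
duplexProbe <- function(name, topStrand) {
  new("DuplexProbe", name = name, topStrand = toupper(topStrand))
}

#' @rdname topStrand
#' @export
setMethod("topStrand", "DuplexProbe", function(x) x@topStrand)

#' @rdname siteHits
#' @export
setMethod("siteHits", "DuplexProbe", function(x) x@siteHits)

#' @rdname nbp
#' @export
setMethod("nbp", "DuplexProbe", function(x) nchar(x@topStrand))

setMethod("show", "DuplexProbe", function(object) {
  cat(sprintf("DuplexProbe %s (%d bp)%s\n  %s\n", object@name,
              nchar(object@topStrand),
              if (checkPalindrome(object)) ", palindromic" else "",
              object@topStrand))
  if (nrow(object@siteHits) > 0) {
    cat(sprintf("  %d site hit(s):\n", nrow(object@siteHits)))
    print(object@siteHits)
  }
})

validIupac <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N")

#' Scan a duplex probe for a degenerate motif on both strands
#'
#' Matches an IUPAC degenerate pattern (e.g. `W` = A/T) against the top
#' strand and, via the reverse complement, the bottom strand. Mismatches
#' are counted per position against the degenerate pattern; no indels.
#' Hits are reported in 0-based half-open top-strand coordinates
#' (`[start, end)` is the footprint of the matched duplex region); a `-`
#' strand hit means the motif matches the bottom strand read 5'->3'.
#'
#' @param probe a [DuplexProbe-class].
#' @param pattern IUPAC nucleotide pattern string.
#' @param maxMismatch maximum number of mismatching positions (default 0).
#' @return the probe with its `siteHits` slot filled: a `data.frame` with
#'   columns `start`, `end`, `strand`, `matched` (the literal top-strand
#'   footprint), sorted by `start` then strand (`+` before `-`).
#' @examples
#' p <- scanMotif(bundledProbes()$CC36, "CACAAAG")
#' siteHits(p)
#' @export
scanMotif <- function(probe, pattern, maxMismatch = 0L) {
  stopifnot(is(probe, "DuplexProbe"))
  pattern <- toupper(pattern)
  if (nchar(pattern) < 1L)
    stop("motif pattern must have length >= 1")
  bad <- setdiff(strsplit(pattern, "")[[1]], validIupac)
  if (length(bad))
    stop("invalid IUPAC code(s) in pattern: ", paste(bad, collapse = ", "))
  top <- topStrand(probe)
  L <- nchar(top)
  len <- nchar(pattern)
  hits <- emptyHits()
  if (len <= L) {
    subj <- Biostrings::DNAString(top)
    pat <- Biostrings::DNAString(pattern)
    fixedSpec <- c(pattern = FALSE, subject = TRUE)
    fwd <- Biostrings::matchPattern(pat, subj, max.mismatch = maxMismatch,
                                    fixed = fixedSpec)
    rev <- Biostrings::matchPattern(pat, Biostrings::reverseComplement(subj),
                                    max.mismatch = maxMismatch,
                                    fixed = fixedSpec)
    ## with a mismatch budget Biostrings also reports partial matches
    ## hanging over the subject ends; footprints must lie fully inside
    plus <- Biostrings::start(fwd) - 1L
    plus <- plus[plus >= 0L & plus + len <= L]
    minus <- L - (Biostrings::start(rev) - 1L) - len
    minus <- minus[minus >= 0L & minus + len <= L]
    hits <- rbind(
      data.frame(start = plus, end = plus + len,
                 strand = rep("+", length(plus)),
                 stringsAsFactors = FALSE),
      data.frame(start = minus, end = minus + len,
                 strand = rep("-", length(minus)),
                 stringsAsFactors = FALSE))
    if (nrow(hits)) {
      hits$matched <- substring(top, hits$start + 1L, hits$end)
      hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
      rownames(hits) <- NULL
    } else hits <- emptyHits()
  }
  probe@siteHits <- hits
  probe
}

emptyHits <- function() {
  data.frame(start = integer(), end = integer(), strand = character(),
             matched = character(), stringsAsFactors = FALSE)
}

#' Is a duplex probe palindromic?
#'
#' TRUE iff the top strand equals its own reverse complement (so the two
#' strands read identically 5'->3').
#'
#' @param probe a [DuplexProbe-class].
#' @return logical.
#' @export
checkPalindrome <- function(probe) {
  s <- Biostrings::DNAString(topStrand(probe))
  as.character(Biostrings::reverseComplement(s)) == as.character(s)
}

#' Base pairs between two inverted site footprints
#'
#' The number of base pairs strictly between two site footprints in
#' top-strand coordinates; symmetric in argument order. The two hits must
#' lie on opposite strands (an inverted tandem arrangement).
#'
#' @param hits a 2-row site-hit `data.frame` as produced by [scanMotif()],
#'   or a scanned `DuplexProbe` carrying exactly two hits.
#' @return integer spacing in bp.
#' @export
siteSpacing <- function(hits) {
  if (is(hits, "DuplexProbe")) hits <- siteHits(hits)
  if (nrow(hits) != 2L)
    stop("siteSpacing requires exactly two site hits, got ", nrow(hits))
  if (hits$strand[1] == hits$strand[2])
    stop("siteSpacing requires hits on opposite strands")
  hits <- hits[order(hits$start), ]
  gap <- hits$start[2] - hits$end[1]
  if (gap < 0L) stop("site footprints overlap")
  as.integer(gap)
}

#' Helical-wheel projection of a protein region
#'
#' Projects residues onto an end-on wheel at `degreesPerResidue` (100 for a
#' canonical alpha-helix). Angles depend only on position within the
#' region, so relabelling `start` shifts residue numbers, not geometry.
#'
#' @param region list with `sequence` (one-letter string), `start`
#'   (residue number of the first character) and optional `label`; see
#'   [proteinRegion()].
#' @param degreesPerResidue rotation per residue (degrees).
#' @param hydrophobicSet one-letter codes treated as hydrophobic.
#' @return `data.frame` with columns `resno`, `aa`, `angle`, `hydrophobic`.
#' @export
wheelProjection <- function(region, degreesPerResidue = 100,
                            hydrophobicSet = c("A", "V", "I", "L", "M",
                                               "F", "W", "Y")) {
  aa <- strsplit(region$sequence, "")[[1]]
  n <- length(aa)
  resno <- region$start + seq_len(n) - 1L
  data.frame(resno = resno, aa = aa,
             angle = ((seq_len(n) - 1) * degreesPerResidue) %% 360,
             hydrophobic = aa %in% hydrophobicSet,
             stringsAsFactors = FALSE)
}

#' Define a protein region with construct residue numbering
#'
#' @param sequence one-letter amino-acid string (20-letter alphabet).
#' @param start residue number of the first character (1-based).
#' @param label free-text label.
#' @return a list of class `ProteinRegion`.
#' @examples
#' proteinRegion("SIREAVSQVLSGY", 72, "alpha0")
#' @export
proteinRegion <- function(sequence, start, label = "") {
  sequence <- toupper(sequence)
  bad <- setdiff(strsplit(sequence, "")[[1]], AA1)
  if (length(bad))
    stop("invalid amino-acid code(s): ", paste(bad, collapse = ", "))
  if (start < 1) stop("start residue number must be >= 1")
  structure(list(sequence = sequence, start = as.integer(start),
                 label = label), class = "ProteinRegion")
}

#' Hydrophobic face of a helical-wheel projection
#'
#' Finds the hydrophobic residues of a region, the smallest wheel arc
#' covering all of them, and whether that arc excludes every
#' non-hydrophobic residue ("clean separation", the signature of an
#' amphipathic helix). The smallest enclosing arc is the complement of the
#' largest angular gap between consecutive hydrophobic positions; ties are
#' broken by the smallest arc start angle.
#'
#' @inheritParams wheelProjection
#' @return list with `residues` (data.frame of hydrophobic residues),
#'   `arcStart`, `arcEnd`, `arcSpan` (degrees; `NA` and `arcDefined =
#'   FALSE` when no hydrophobic residue exists), and `cleanSeparation`
#'   (FALSE when there is no polar residue to separate from, or no arc
#'   excludes them all).
#' @examples
#' hydrophobicFace(proteinRegion("SIREAVSQVLSGY", 72))
#' @export
hydrophobicFace <- function(region, degreesPerResidue = 100,
                            hydrophobicSet = c("A", "V", "I", "L", "M",
                                               "F", "W", "Y")) {
  wheel <- wheelProjection(region, degreesPerResidue, hydrophobicSet)
  if (nrow(wheel) < 4L) stop("region must have length >= 4")
  hyd <- wheel[wheel$hydrophobic, , drop = FALSE]
  pol <- wheel[!wheel$hydrophobic, , drop = FALSE]
  if (nrow(hyd) == 0L)
    return(list(residues = hyd, arcStart = NA_real_, arcEnd = NA_real_,
                arcSpan = NA_real_, arcDefined = FALSE,
                cleanSeparation = FALSE))
  arc <- smallestEnclosingArc(unique(hyd$angle))
  clean <- nrow(pol) > 0 &&
    !any(angleInArc(pol$angle, arc$start, arc$span))
  list(residues = hyd, arcStart = arc$start,
       arcEnd = (arc$start + arc$span) %% 360, arcSpan = arc$span,
       arcDefined = TRUE, cleanSeparation = clean)
}

## Smallest arc [start, start+span] covering all angles; complement of the
## largest gap between consecutive sorted angles. Ties -> smallest start.
smallestEnclosingArc <- function(angles) {
  a <- sort(unique(angles %% 360))
  if (length(a) == 1L) return(list(start = a, span = 0))
  gaps <- c(diff(a), a[1] + 360 - a[length(a)])
  big <- max(gaps)
  idx <- which(gaps == big)
  starts <- a[(idx %% length(a)) + 1L]  # arc starts after the gap
  start <- min(starts)
  list(start = start, span = 360 - big)
}

angleInArc <- function(angle, start, span) {
  d <- (angle - start) %% 360
  d <= span + 1e-9
}

#' Predict the dimerization phenotype of a point substitution
#'
#' Rule-based call from the mutagenesis map: substitutions at hydrophobic-
#' face residues of the dimerization helix or at the HMG-domain platform
#' residues abolish dimerization; assayed neutral positions retain it;
#' anything else is unknown.
#'
#' @param substitution string like `"V77E"` or `"A119E"` (wild-type
#'   letter optional), or an integer residue number.
#' @param faceResidues hydrophobic-face residue numbers (default the six
#'   dimerization-helix face positions).
#' @param platformResidues HMG platform residue numbers (default A119 and
#'   L142).
#' @param neutralResidues assayed positions with no effect (default S78,
#'   Q79, A118, L145).
#' @return one of `"loss"`, `"retained"`, `"unknown"`.
#' @examples
#' predictPhenotype("V77E")
#' predictPhenotype("A118E")
#' @export
predictPhenotype <- function(substitution,
                             faceResidues = c(73, 76, 77, 80, 81, 84),
                             platformResidues = c(119, 142),
                             neutralResidues = c(78, 79, 118, 145)) {
  pos <- if (is.numeric(substitution)) as.integer(substitution)
  else {
    m <- regmatches(substitution, regexpr("[0-9]+", substitution))
    if (!length(m)) stop("cannot parse residue number from: ", substitution)
    as.integer(m)
  }
  if (pos %in% c(faceResidues, platformResidues)) "loss"
  else if (pos %in% neutralResidues) "retained"
  else "unknown"
}

#' Reverse complement of a DNA string
#'
#' @param x A/C/G/T string.
#' @return the reverse-complement string.
#' @export
reverseComplementStr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
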