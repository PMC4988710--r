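# Independent oracles used across the suite.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

revcompStr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Brute-force degenerate scan: every offset on both strands, counting
# per-position mismatches against the IUPAC pattern.
bruteScan <- function(top, pattern, maxMismatch = 0L) {
  L <- nchar(top)
  len <- nchar(pattern)
  pat <- strsplit(pattern, "")[[1]]
  hitsOn <- function(strandSeq) {
    out <- integer()
    if (len > nchar(strandSeq)) return(out)
    sv <- strsplit(strandSeq, "")[[1]]
    for (s in 0:(nchar(strandSeq) - len)) {
      mm <- sum(vapply(seq_len(len), function(k)
        !(sv[s + k] %in% IUPAC_SETS[[pat[k]]]), logical(1)))
      if (mm <= maxMismatch) out <- c(out, s)
    }
    out
  }
  plus <- hitsOn(top)
  minusRc <- hitsOn(revcompStr(top))
  minus <- L - minusRc - len
  df <- rbind(
    data.frame(start = plus, strand = rep("+", length(plus))),
    data.frame(start = minus, strand = rep("-", length(minus))))
  df[order(df$start, df$strand), , drop = FALSE]
}

# Brute-force smallest enclosing arc over candidate start angles.
bruteArc <- function(angles) {
  a <- sort(unique(angles %% 360))
  best <- NULL
  for (s in a) {
    span <- max((a - s) %% 360)
    if (is.null(best) || span < best$span ||
        (span == best$span && s < best$start))
      best <- list(start = s, span = span)
  }
  best
}

randomDnaString <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                            replace = TRUE),
                                     collapse = "")

TABLE1 <- data.frame(
  protein = c("D-HMG", "D-HMG", "HMG", "HMG"),
  probe = c("CC36", "S9WT", "CC36", "S9WT"),
  kd = c(98, 82, 109, 101),
  kdErr = c(5, 19, 10, 33),
  hill = c(4.4, 1.5, 2.2, 1.6),
  hillErr = c(0.6, 0.2, 0.4, 0.5))

# A small docked helix/receptor fixture shared by restraint and docking
# tests (deterministic).
dockedFixture <- function(seed = 21) {
  prob <- plantedDockingProblem(seed = seed)
  posed <- prob$mobile
  coords(posed) <- prob$trueCoords
  list(prob = prob, pair = combineModels(posed, prob$receptor))
}

# An ensemble with hand-constructed poses around a planted base
# orientation (17 jittered, 3 rotated ~90 degrees of interhelical angle),
# mirroring the two-orientation outcome of the docking stage.
makeOrientationFixture <- function(seed = 17) {
  prob <- plantedDockingProblem(seed = seed)
  base <- prob$truePose
  rec <- coords(prob$receptor)
  spans <- prob$receptor@meta$spans
  rres <- residueNumbers(prob$receptor)
  a1ax <- soxdimer:::principalAxis(
    rec[rres >= spans$a1[1] & rres <= spans$a1[2], ])
  axis <- as.numeric(base$R %*% c(0, 0, 1))
  theta0 <- soxdimer:::vecAngleDeg(axis, a1ax)
  ## rotate in the plane spanned by the two axes, in the direction that
  ## changes the interhelical angle by a full 90 degrees
  perp <- soxdimer:::unitVec(soxdimer:::crossProd3(axis, a1ax))
  rot90 <- function(sign) soxdimer:::rotAxis(perp,
                                             sign * soxdimer:::deg2rad(90))
  cand <- vapply(c(1, -1), function(s)
    soxdimer:::vecAngleDeg(as.numeric(rot90(s) %*% axis), a1ax),
    numeric(1))
  sgn <- c(1, -1)[which.max(abs(cand - theta0))]
  poses <- vector("list", 20)
  set.seed(seed)
  for (i in 1:17) {
    jitterAx <- soxdimer:::unitVec(rnorm(3))
    poses[[i]] <- list(
      R = soxdimer:::rotAxis(jitterAx,
                             soxdimer:::deg2rad(runif(1, 0, 5))) %*% base$R,
      t = base$t + rnorm(3, 0, 0.3))
  }
  for (i in 18:20)
    poses[[i]] <- list(R = rot90(sgn) %*% base$R,
                       t = base$t + rnorm(3, 0, 0.3))
  new("DockEnsemble", poses = poses, energies = as.numeric(1:20),
      trial = 1:20, seed = as.numeric(seed),
      mobileRef = prob$mobile, receptor = prob$receptor)
}
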