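## EMSA quantitation: the four-parameter logistic (4PL) binding model
##
##   AB = d + (a - d) / (1 + (B / Kd)^b)
##
## with B the protein concentration, AB the normalized shifted-band
## intensity, a/d the lower/upper asymptotes, Kd the midpoint and b the
## steepness (Hill coefficient). Plus kinetic back-calculation
## (k_off = ln2 / t_half, k_on = k_off / Kd) and the band-pattern
## classification of dimerizing vs non-dimerizing variants.

#' Build a titration series
#'
#' @param proteinConc protein concentrations (nM), strictly positive and
#'   strictly increasing.
#' @param boundFraction normalized shifted-band intensities (unitless).
#' @param dnaConc constant DNA concentration (nM). Carried for the
#'   sub-saturation check only; the 4PL does not use it.
#' @param label free text.
#' @return list of class `TitrationSeries`.
#' @export
titrationSeries <- function(proteinConc, boundFraction, dnaConc = 9,
                            label = "") {
  if (length(proteinConc) != length(boundFraction))
    stop("proteinConc and boundFraction must have equal length")
  if (any(proteinConc <= 0)) stop("concentrations must be positive")
  if (any(diff(proteinConc) <= 0))
    stop("concentrations must be strictly increasing")
  if (any(!is.finite(boundFraction)))
    stop("bound fractions must be finite")
  structure(list(proteinConc = as.numeric(proteinConc),
                 boundFraction = as.numeric(boundFraction),
                 dnaConc = dnaConc, label = label),
            class = "TitrationSeries")
}

#' 4PL forward model
#'
#' @param conc protein concentration(s) (nM).
#' @param a lower asymptote.
#' @param d upper asymptote.
#' @param kd midpoint concentration (nM).
#' @param b steepness (Hill coefficient).
#' @return predicted bound fraction(s).
#' @export
fourPL <- function(conc, a, d, kd, b) {
  d + (a - d) / (1 + (conc / kd)^b)
}

#' Simulate an EMSA titration from the 4PL model
#'
#' Evaluates the forward model on a concentration grid and adds
#' independent Gaussian noise; reproducible under `seed`.
#'
#' @inheritParams fourPL
#' @param concGrid positive, increasing concentration grid (nM).
#' @param noiseSd Gaussian noise standard deviation (>= 0).
#' @param seed optional integer seed.
#' @param dnaConc constant DNA concentration (nM), carried through.
#' @return a `TitrationSeries`.
#' @examples
#' simulateTitration(0, 1, 98, 4.4, logConcGrid(), noiseSd = 0.03, seed = 1)
#' @export
simulateTitration <- function(a, d, kd, b, concGrid, noiseSd = 0,
                              seed = NULL, dnaConc = 9) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (kd <= 0) stop("kd must be positive")
  mu <- fourPL(concGrid, a, d, kd, b)
  y <- if (noiseSd > 0)
    withSeed(seed, mu + stats::rnorm(length(mu), 0, noiseSd)) else mu
  titrationSeries(concGrid, y, dnaConc = dnaConc,
                  label = sprintf("sim a=%g d=%g kd=%g b=%g", a, d, kd, b))
}

#' Log-spaced concentration grid
#'
#' Default grid mirrors the assayed protein range: 12 points, 10-450 nM.
#'
#' @param from,to range endpoints (nM).
#' @param n number of points.
#' @export
logConcGrid <- function(from = 10, to = 450, n = 12) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Fit a titration to the four-parameter logistic curve
#'
#' Least-squares estimation of (a, d, Kd, b) by Levenberg-Marquardt, with
#' Kd and b fitted on the log scale for conditioning and reported on the
#' linear scale. Standard errors come from the Gauss-Newton curvature at
#' the optimum (delta method for the log-scale parameters). Initial values
#' default to a = min response, d = max response, Kd = geometric mid of
#' the grid, b = 1.
#'
#' @param series a `TitrationSeries`.
#' @param init optional named list overriding starting values
#'   (`a`, `d`, `kd`, `b`).
#' @param maxIter maximum iterations.
#' @param tol relative convergence tolerance.
#' @return a [FourPLFit-class]. A warning is emitted when the carried DNA
#'   concentration exceeds Kd / 5 (the binding regime assumed by the 4PL).
#' @examples
#' s <- simulateTitration(0, 1, 98, 4.4, logConcGrid())
#' fit4PL(s)
#' @export
fit4PL <- function(series, init = NULL, maxIter = 500, tol = 1e-10) {
  stopifnot(inherits(series, "TitrationSeries"))
  conc <- series$proteinConc
  y <- series$boundFraction
  if (length(conc) < 5L)
    stop("at least 5 titration points are required")
  if (diff(range(y)) < 1e-8)
    stop("degenerate flat titration: no dynamic range to fit")
  start <- list(a = min(y), d = max(y),
                lkd = mean(log(range(conc))), lb = 0)
  if (!is.null(init)) {
    if (!is.null(init$a)) start$a <- init$a
    if (!is.null(init$d)) start$d <- init$d
    if (!is.null(init$kd)) start$lkd <- log(init$kd)
    if (!is.null(init$b)) start$lb <- log(init$b)
  }
  dat <- data.frame(conc = conc, y = y)
  par0 <- unlist(start)
  residFn <- function(p)
    y - (p["d"] + (p["a"] - p["d"]) /
           (1 + (conc / exp(p["lkd"]))^exp(p["lb"])))
  out <- try(minpack.lm::nls.lm(
    par0, fn = residFn,
    control = minpack.lm::nls.lm.control(maxiter = maxIter, ftol = tol,
                                         ptol = tol)), silent = TRUE)
  if (inherits(out, "try-error")) {
    nas <- c(a = NA_real_, d = NA_real_, kd = NA_real_, b = NA_real_)
    return(new("FourPLFit", estimates = nas, se = nas,
               converged = FALSE, residuals = numeric(),
               data = dat, message = as.character(out)))
  }
  cf <- out$par
  est <- c(a = unname(cf["a"]), d = unname(cf["d"]),
           kd = unname(exp(cf["lkd"])), b = unname(exp(cf["lb"])))
  ## Gauss-Newton curvature standard errors; delta method for the
  ## log-scale parameters. A singular curvature (e.g. a perfect,
  ## zero-residual fit) yields NA.
  se <- tryCatch({
    n <- length(y); p <- 4L
    s2 <- out$deviance / max(1L, n - p)
    sp <- sqrt(diag(solve(out$hessian)) * s2)
    c(a = unname(sp["a"]), d = unname(sp["d"]),
      kd = unname(sp["lkd"] * exp(cf["lkd"])),
      b = unname(sp["lb"] * exp(cf["lb"])))
  }, error = function(e) c(a = NA_real_, d = NA_real_, kd = NA_real_,
                           b = NA_real_))
  conv <- out$info %in% 1:3
  if (is.finite(est["kd"]) && series$dnaConc > est["kd"] / 5)
    warning("DNA concentration exceeds Kd/5; the 4PL midpoint may be ",
            "depletion-biased")
  new("FourPLFit", estimates = est, se = se, converged = conv,
      residuals = as.numeric(residFn(cf)), data = dat,
      message = out$message %||% "")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @rdname estimates
#' @export
setMethod("estimates", "FourPLFit", function(object) object@estimates)

#' @rdname stdErrors
#' @export
setMethod("stdErrors", "FourPLFit", function(object) object@se)

setMethod("show", "FourPLFit", function(object) {
  e <- object@estimates; s <- object@se
  cat("FourPLFit", if (object@converged) "(converged)" else
    "(NOT converged)", "\n")
  cat(sprintf("  a  = %.4g +/- %.2g\n  d  = %.4g +/- %.2g\n", e["a"],
              s["a"], e["d"], s["d"]))
  cat(sprintf("  Kd = %.4g +/- %.2g nM\n  b  = %.4g +/- %.2g\n",
              e["kd"], s["kd"], e["b"], s["b"]))
})

#' Dissociation rate from a half-life
#'
#' `k_off = ln 2 / t_half`.
#'
#' @param halfLifeSec complex half-life in seconds (> 0).
#' @return k_off in 1/s.
#' @examples
#' koffFromHalfLife(600)   # a ~10 min residency
#' @export
koffFromHalfLife <- function(halfLifeSec) {
  if (any(halfLifeSec <= 0)) stop("half-life must be positive")
  log(2) / halfLifeSec
}

#' Association rate from Kd and k_off
#'
#' `k_on = k_off / Kd` at equilibrium.
#'
#' @param kdMolar dissociation constant in molar (> 0).
#' @param kOff dissociation rate in 1/s (> 0).
#' @return k_on in 1/(M s).
#' @export
konFromKdKoff <- function(kdMolar, kOff) {
  if (any(kdMolar <= 0) || any(kOff <= 0))
    stop("kdMolar and kOff must be positive")
  kOff / kdMolar
}

#' Kinetic back-calculation from a half-life and a Kd
#'
#' @param halfLifeSec complex half-life (s).
#' @param kdMolar equilibrium dissociation constant (M).
#' @return list with `halfLife`, `kOff` (1/s), `kOn` (1/(M s)), `kdUsed`.
#' @export
kineticEstimate <- function(halfLifeSec, kdMolar) {
  kOff <- koffFromHalfLife(halfLifeSec)
  list(halfLife = halfLifeSec, kOff = kOff,
       kOn = konFromKdKoff(kdMolar, kOff), kdUsed = kdMolar)
}

#' Classify a band pattern as dimerizing or not
#'
#' At sub-stoichiometric protein:DNA ratios a dimerizing variant fills
#' both half-sites cooperatively (a single, doubly occupied band), while a
#' non-dimerizing variant populates singly occupied intermediates (two
#' bands). Classification is invariant to overall intensity scaling:
#' fractions are renormalized before thresholding.
#'
#' @param bandFractions named numeric with entries `free`,
#'   `single_occupied`, `double_occupied` (non-negative; renormalized to
#'   sum to 1).
#' @param threshold single-occupancy fraction above which the pattern is
#'   called non-dimerizing (default 0.05).
#' @return one of `"dimerizing"`, `"non_dimerizing"`, `"indeterminate"`.
#' @examples
#' classifyDimerization(c(free = 0.5, single_occupied = 0,
#'                        double_occupied = 0.5))
#' @export
classifyDimerization <- function(bandFractions, threshold = 0.05) {
  need <- c("free", "single_occupied", "double_occupied")
  if (!all(need %in% names(bandFractions)))
    stop("bandFractions must name free, single_occupied, double_occupied")
  f <- bandFractions[need]
  if (any(f < 0)) stop("band fractions must be >= 0")
  tot <- sum(f)
  if (tot <= 0) stop("band fractions must not all be zero")
  f <- f / tot
  if (f["double_occupied"] <= 0 && f["single_occupied"] <= 0)
    return("indeterminate")
  if (f["single_occupied"] < threshold && f["double_occupied"] > 0)
    "dimerizing"
  else "non_dimerizing"
}

#' Read a titration table from delimited text
#'
#' Expects columns `conc_nM` and `bound_fraction` (CSV or TSV, sniffed
#' from the header line).
#'
#' @param path file path.
#' @param dnaConc constant DNA concentration (nM).
#' @return a `TitrationSeries`.
#' @export
readTitration <- function(path, dnaConc = 9) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tb <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("conc_nM", "bound_fraction") %in% names(tb)))
    stop("titration table needs columns conc_nM and bound_fraction")
  titrationSeries(tb$conc_nM, tb$bound_fraction, dnaConc = dnaConc,
                  label = basename(path))
}
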