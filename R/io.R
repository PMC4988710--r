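## Interchange with standard structure tooling: coarse models as PDB
## (Calpha for protein beads, P for DNA beads), FASTA sequences, flat
## key-value run configuration, and the end-to-end pipeline runner.

#' Write coarse models to a PDB file
#'
#' Protein beads are written as CA ATOM records, DNA beads as P records,
#' with 1-based residue numbering and the model's chain ids. A list of
#' models is written as a multi-model ensemble (MODEL/ENDMDL).
#'
#' @param model a `CoarseModel`, `ComplexModel`, or list of
#'   `CoarseModel`s (ensemble).
#' @param path output path.
#' @param bFactor optional per-bead B-factor column (e.g. restraint
#'   violation per bead).
#' @return the path, invisibly.
#' @export
writePDB <- function(model, path, bFactor = NULL) {
  if (is(model, "ComplexModel")) model <- complexBeads(model)
  models <- if (is(model, "CoarseModel")) list(model) else model
  multi <- length(models) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    writeOnePDB(models[[m]], con, bFactor)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

writeOnePDB <- function(model, con, bFactor = NULL) {
  xyz <- coords(model)
  n <- nrow(xyz)
  if (is.null(bFactor)) bFactor <- rep(0, n)
  elety <- ifelse(beadRoles(model) == "P", "P", "CA")
  resid <- ifelse(beadRoles(model) == "P", "DN", "ALA")
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_len(n), elety, resid, chainIds(model),
    residueNumbers(model), xyz[, 1], xyz[, 2], xyz[, 3], 1, bFactor)
  writeLines(lines, con)
  writeLines("TER", con)
}

#' Read coarse models from a PDB file
#'
#' Extracts Calpha and P atoms from a (possibly multi-model, possibly
#' all-atom) PDB file via `bio3d` and returns one `CoarseModel` per
#' model. Coordinates round-trip through [writePDB()] to within the PDB
#' fixed-width precision (1e-3 angstrom); numbering exactly.
#'
#' @param path PDB file path.
#' @return a `CoarseModel`, or a list of them for a multi-model file.
#' @export
readPDB <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("PDB parse error in ", path, ": ",
                         conditionMessage(e)))
  sel <- which(pdb$atom$elety %in% c("CA", "P"))
  if (!length(sel))
    stop("no CA or P atoms found in ", path, ": empty model")
  nModels <- nrow(pdb$xyz)
  mk <- function(xyzRow) {
    m3 <- matrix(xyzRow, ncol = 3, byrow = TRUE)[sel, , drop = FALSE]
    new("CoarseModel",
        chain = as.character(pdb$atom$chain[sel]),
        resno = as.integer(pdb$atom$resno[sel]),
        role = ifelse(pdb$atom$elety[sel] == "P", "P", "CA"),
        coords = m3, meta = list(source = path))
  }
  models <- lapply(seq_len(nModels), function(i) mk(pdb$xyz[i, ]))
  if (length(models) == 1L) models[[1]] else models
}

#' Read protein or DNA sequences from FASTA
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
readFastaSeqs <- function(path) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no FASTA records in ", path)
  names <- sub("^>\\s*(\\S+).*", "\\1", lines[heads])
  bounds <- c(heads, length(lines) + 1L)
  seqs <- vapply(seq_along(heads), function(i)
    paste(lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)], collapse = ""),
    character(1))
  stats::setNames(toupper(gsub("\\s", "", seqs)), names)
}

#' Read a flat key-value run configuration
#'
#' One `key = value` pair per line; `#` comments and blank lines are
#' ignored. Unknown keys are rejected up front, and all problems are
#' reported at once. Recognized keys: `probe_top_strand`, `probe_name`,
#' `motif`, `per_site_bend`, `bend_phasing`, `trans`, `n_trials`, `top`,
#' `n_contacts`, `seed`, `steps_per_stage`, `n_stages`, `start_t`,
#' `end_t`.
#'
#' @param path config file path.
#' @return an [assemblyConfig()].
#' @export
readAssemblyConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  problems <- character()
  known <- c("probe_top_strand", "probe_name", "motif", "per_site_bend",
             "bend_phasing", "trans", "n_trials", "top", "n_contacts",
             "seed", "steps_per_stage", "n_stages", "start_t", "end_t")
  vals <- list()
  for (p in kv) {
    if (length(p) != 2L) {
      problems <- c(problems, paste("malformed line:", paste(p,
        collapse = " ")))
      next
    }
    if (!(p[1] %in% known)) {
      problems <- c(problems, paste("unknown key:", p[1]))
      next
    }
    vals[[p[1]]] <- p[2]
  }
  if (length(problems))
    stop("config errors:\n  ", paste(problems, collapse = "\n  "))
  args <- list()
  if (!is.null(vals$probe_top_strand))
    args$probe <- duplexProbe(vals$probe_name %||% "probe",
                              vals$probe_top_strand)
  if (!is.null(vals$motif)) args$motif <- vals$motif
  if (!is.null(vals$per_site_bend))
    args$perSiteBend <- as.numeric(vals$per_site_bend)
  if (!is.null(vals$bend_phasing)) args$bendPhasing <- vals$bend_phasing
  if (!is.null(vals$trans)) args$trans <- toupper(vals$trans) %in%
    c("TRUE", "T", "1", "YES")
  if (!is.null(vals$n_trials)) args$nTrials <- as.integer(vals$n_trials)
  if (!is.null(vals$top)) args$top <- as.integer(vals$top)
  if (!is.null(vals$n_contacts))
    args$nContacts <- as.integer(vals$n_contacts)
  if (!is.null(vals$seed)) args$seed <- as.integer(vals$seed)
  sched <- list()
  if (!is.null(vals$steps_per_stage))
    sched$stepsPerStage <- as.integer(vals$steps_per_stage)
  if (!is.null(vals$n_stages)) sched$nStages <- as.integer(vals$n_stages)
  if (!is.null(vals$start_t)) sched$startT <- as.numeric(vals$start_t)
  if (!is.null(vals$end_t)) sched$endT <- as.numeric(vals$end_t)
  if (length(sched)) {
    if (!is.null(args$seed)) sched$seed <- args$seed
    args$schedule <- do.call(annealSchedule, sched)
  } else if (!is.null(args$seed)) {
    args$schedule <- annealSchedule(seed = args$seed)
  }
  do.call(assemblyConfig, args)
}

#' Run the assembly pipeline and write its artifacts
#'
#' Executes [assembleDimer()] and writes the final model as PDB (protein
#' chains A/B, DNA chains C/D) and the validation report as JSON
#' (including seeds, per-stage energies and the DNA bend).
#'
#' @param config an [assemblyConfig()] (or a path read with
#'   [readAssemblyConfig()]).
#' @param outPdb output PDB path.
#' @param outReport output JSON report path.
#' @return the report list, invisibly.
#' @export
runPipeline <- function(config = assemblyConfig(),
                        outPdb = "model.pdb",
                        outReport = "report.json") {
  if (is.character(config)) config <- readAssemblyConfig(config)
  res <- assembleDimer(config)
  writePDB(res$complex, outPdb)
  rep <- res$report
  rep$seed <- config$seed
  rep$stageEnergies <- res$trace$energy
  jsonlite::write_json(rep, outReport, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(rep)
}

#' Write all bundled fixtures to a directory
#'
#' Probe FASTA files, the dimerization-region FASTA, the toy HMG fold as
#' PDB, and the default AIR set as TSV -- the inputs used throughout the
#' documentation and tests.
#'
#' @param dir output directory (created if needed).
#' @return invisible vector of written paths.
#' @export
writeFixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  probes <- bundledProbes()
  for (nm in names(probes)) {
    p <- file.path(dir, paste0(nm, ".fa"))
    writeLines(c(paste0(">", nm), topStrand(probes[[nm]])), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "dimreg.fa")
  writeLines(c(">alpha0 residues 71-85", ALPHA0_SEQ), p)
  paths <- c(paths, p)
  p <- file.path(dir, "toy_hmg_synthetic.pdb")
  writePDB(toyHMG(), p)
  paths <- c(paths, p)
  p <- file.path(dir, "airs.tsv")
  writeRestraints(makeAIRs(), p)
  paths <- c(paths, p)
  invisible(paths)
}
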