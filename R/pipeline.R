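#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, fills the published defaults for every
#' unset algorithm parameter (W = 3, D = 67, alpha = 0.01, minReads = 10,
#' minPeakDistance = 10, peakThreshold = 0.1, relaxRbar = 0.5,
#' tolerance = 5, maxDist = 10, flank = 10), and validates the result,
#' reporting all problems at once. Recognised top-level keys:
#' `genome` (`name`, `length`, `circular`, optional `fasta`),
#' `libraries` (list of track `prefix` entries with optional `condition`),
#' `params` (any [trsParams()] field plus `tolerance`, `maxDist`, `flank`),
#' `annotation` (`gff`, optional `tu_table`), `outputDir`, `seed`,
#' `stages` (subset of `call`, `classify`).
#'
#' @param path YAML file path; an empty file yields an all-defaults
#'   configuration (without genome/libraries, only usable for parameter
#'   inspection).
#' @return A validated named list of class `RunConfig`.
#' @export
loadRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("genome", "libraries", "params", "annotation", "outputDir",
             "seed", "stages")
  problems <- character()
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    problems <- c(problems, paste("unknown key(s):", paste(extra, collapse = ", ")))
  defaults <- list(W = 3, D = 67, alpha = 0.01, minReads = 10,
                   minPeakDistance = 10, peakThreshold = 0.1,
                   minSigLibraries = NA, relaxRbar = 0.5,
                   tolerance = 5, maxDist = 10, flank = 10)
  p <- utils::modifyList(defaults, if (is.null(cfg$params)) list() else cfg$params)
  badp <- setdiff(names(cfg$params), names(defaults))
  if (length(badp))
    problems <- c(problems, paste("unknown params key(s):",
                                  paste(badp, collapse = ", ")))
  trsp <- tryCatch(
    trsParams(W = p$W, D = p$D, alpha = p$alpha, minReads = p$minReads,
              minPeakDistance = p$minPeakDistance,
              peakThreshold = p$peakThreshold,
              minSigLibraries = p$minSigLibraries, relaxRbar = p$relaxRbar),
    error = function(e) { problems <<- c(problems, conditionMessage(e)); NULL })
  if (!is.null(cfg$genome)) {
    g <- cfg$genome
    if (is.null(g$name) || is.null(g$length))
      problems <- c(problems, "genome requires 'name' and 'length'")
  }
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  structure(list(genome = cfg$genome, libraries = cfg$libraries,
                 params = trsp, tolerance = p$tolerance, maxDist = p$maxDist,
                 flank = p$flank, annotation = cfg$annotation,
                 outputDir = if (is.null(cfg$outputDir)) "." else cfg$outputDir,
                 seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
                 stages = if (is.null(cfg$stages)) c("call", "classify")
                          else cfg$stages),
            class = "RunConfig")
}

#' Export terminus calls as a tab-separated table
#'
#' Writes position (1-based), strand, the averaged statistic, per-library
#' local sums and raw/corrected p-values, the number of significant
#' libraries, the selection flag and (when classified) the class label and
#' assigned gene.
#'
#' @param calls a `GRanges` from [runTRS()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTerminiTSV <- function(calls, path) {
  df <- data.frame(position = GenomicRanges::start(calls),
                   strand = as.character(GenomicRanges::strand(calls)),
                   RBar = calls$RBar, stringsAsFactors = FALSE)
  addMat <- function(df, m, prefix) {
    m <- as.matrix(m)
    cols <- colnames(m)
    if (is.null(cols)) cols <- paste0("lib", seq_len(ncol(m)))
    for (j in seq_len(ncol(m))) df[[paste0(prefix, ".", cols[j])]] <- m[, j]
    df
  }
  df <- addMat(df, calls$L, "L")
  df <- addMat(df, calls$pRaw, "pRaw")
  df <- addMat(df, calls$pCorrected, "pCorrected")
  df$nSignificant <- calls$nSignificant
  df$selected <- calls$selected
  df$classLabel <- calls$classLabel
  df$assignedGene <- calls$assignedGene
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a terminus table written by [writeTerminiTSV()] (or any TSV with
#' `position` and `strand` columns) as a data.frame.
#'
#' @param path input file.
#' @return data.frame.
#' @export
readTerminiTSV <- function(path)
  read.delim(path, stringsAsFactors = FALSE)

#' Run the configured pipeline end to end
#'
#' Executes the staged analysis described by a [loadRunConfig()]
#' configuration: load the bedGraph tracks, run the terminus-detection
#' algorithm, classify the calls against annotation when requested, and
#' write `termini.tsv` plus a machine-readable `manifest.json` (parameters,
#' seed, library identifiers, per-stage record counts) into the output
#' directory. Reruns with identical configuration and inputs are
#' byte-identical.
#'
#' @param config a `RunConfig` from [loadRunConfig()].
#' @param verbose emit per-stage messages.
#' @return Invisibly, a list with `calls`, `manifest` and the output paths.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  if (is.null(config$genome) || is.null(config$libraries))
    stop("configuration must provide 'genome' and 'libraries'")
  g <- genomeRef(config$genome$name, config$genome$length,
                 isTRUE(config$genome$circular))
  tracks <- lapply(config$libraries, function(lib) {
    prefix <- if (is.list(lib)) lib$prefix else lib
    loadTrack(prefix, g)
  })
  collection <- libraryCollection(tracks)
  if (verbose) message("stage call: ", length(tracks), " libraries")
  calls <- runTRS(collection, config$params, verbose = verbose)
  manifest <- list(
    package = "terminR",
    version = as.character(utils::packageVersion("terminR")),
    seed = config$seed,
    genome = list(name = g@name, length = g@length, circular = g@circular),
    libraries = libraryIds(collection),
    params = list(W = config$params@W, D = config$params@D,
                  alpha = config$params@alpha,
                  minReads = config$params@minReads,
                  minPeakDistance = config$params@minPeakDistance,
                  peakThreshold = .peakThreshold(config$params),
                  relaxRbar = config$params@relaxRbar,
                  tolerance = config$tolerance, maxDist = config$maxDist,
                  flank = config$flank),
    stages = list(call = list(candidates = length(calls),
                              selected = sum(calls$selected))))
  if ("classify" %in% config$stages) {
    if (is.null(config$annotation))
      stop("stage 'classify' requires an 'annotation' entry")
    db <- loadAnnotation(config$annotation$gff, config$annotation$tu_table, g)
    calls <- classifyTermini(calls, db, config$tolerance)
    manifest$stages$classify <- list(
      classes = as.list(table(calls$classLabel[calls$selected])))
    if (verbose) message("stage classify: ", nrow(db@genes), " features")
  }
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  terminiPath <- file.path(config$outputDir, "termini.tsv")
  manifestPath <- file.path(config$outputDir, "manifest.json")
  writeTerminiTSV(calls, terminiPath)
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(calls = calls, manifest = manifest,
                 termini = terminiPath, manifestPath = manifestPath))
}
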