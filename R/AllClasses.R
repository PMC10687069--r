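#' @import methods
#' @importFrom stats var pnbinom ppois dnbinom dpois phyper rnbinom rbinom
#'   lm cooks.distance residuals median setNames complete.cases
#' @importFrom utils read.delim write.table head tail
NULL

#' Reference genome descriptor
#'
#' A minimal description of the genome that read-start tracks, annotation and
#' terminus calls refer to: a name, a length in nucleotides, and whether the
#' chromosome is circular (most bacterial chromosomes are). Circularity
#' controls whether the local and downstream windows of the readthrough
#' statistic wrap around the origin.
#'
#' @slot name single string, genome/chromosome identifier.
#' @slot length genome length in nucleotides (>= 1).
#' @slot circular logical, whether coordinates wrap.
#' @export
setClass("GenomeRef",
  representation(name = "character", length = "integer", circular = "logical"),
  validity = function(object) {
    msg <- NULL
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "'name' must be a single nonempty string")
    if (length(object@length) != 1L || is.na(object@length) || object@length < 1L)
      msg <- c(msg, "'length' must be a single integer >= 1")
    if (length(object@circular) != 1L || is.na(object@circular))
      msg <- c(msg, "'circular' must be TRUE or FALSE")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a GenomeRef
#'
#' @param name genome identifier.
#' @param length genome length in nucleotides.
#' @param circular whether the chromosome is circular (default `TRUE`,
#'   the typical bacterial case).
#' @return A [GenomeRef-class] object.
#' @examples
#' genomeRef("chr", 4641652, circular = TRUE)
#' @export
genomeRef <- function(name, length, circular = TRUE) {
  new("GenomeRef", name = as.character(name), length = as.integer(length),
      circular = as.logical(circular))
}

#' Strand-specific per-position read-start counts for one library
#'
#' Holds, for a single sequencing library, the number of reads whose first
#' sequenced base maps to each genomic position, separately for the plus and
#' minus strand. In RNAtag-seq the start of read 1 marks the 3' end of an RNA
#' fragment, so pileups of read starts mark transcript 3' termini.
#' Coordinates are 1-based.
#'
#' @slot genome a [GenomeRef-class].
#' @slot libraryId library identifier.
#' @slot countsPlus,countsMinus integer vectors of length `genomeLength(genome)`.
#' @export
setClass("ReadStartTrack",
  representation(genome = "GenomeRef", libraryId = "character",
                 countsPlus = "integer", countsMinus = "integer"),
  validity = function(object) {
    msg <- NULL
    n <- object@genome@length
    if (length(object@countsPlus) != n || length(object@countsMinus) != n)
      msg <- c(msg, "count vectors must have length equal to the genome length")
    if (anyNA(object@countsPlus) || anyNA(object@countsMinus) ||
        any(object@countsPlus < 0L) || any(object@countsMinus < 0L))
      msg <- c(msg, "counts must be non-negative integers")
    if (length(object@libraryId) != 1L)
      msg <- c(msg, "'libraryId' must be a single string")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a ReadStartTrack
#'
#' @param genome a [GenomeRef-class].
#' @param libraryId library identifier.
#' @param countsPlus,countsMinus integer count vectors (default all zero).
#' @return A [ReadStartTrack-class].
#' @examples
#' g <- genomeRef("toy", 100)
#' readStartTrack(g, "lib1")
#' @export
readStartTrack <- function(genome, libraryId = "lib",
                           countsPlus = integer(genomeLength(genome)),
                           countsMinus = integer(genomeLength(genome))) {
  new("ReadStartTrack", genome = genome, libraryId = as.character(libraryId),
      countsPlus = as.integer(countsPlus), countsMinus = as.integer(countsMinus))
}

#' Replicate libraries measured under one condition
#'
#' An ordered set of [ReadStartTrack-class] objects sharing one genome;
#' the replicate count M is the number of tracks. The readthrough statistic
#' is averaged across the members when narrowing down putative termini.
#'
#' @slot tracks list of [ReadStartTrack-class].
#' @slot conditionLabel free-text growth-condition label.
#' @export
setClass("LibraryCollection",
  representation(tracks = "list", conditionLabel = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@tracks) < 1L)
      msg <- c(msg, "at least one track is required")
    if (!all(vapply(object@tracks, is, logical(1), "ReadStartTrack")))
      msg <- c(msg, "all tracks must be ReadStartTrack objects")
    else {
      g <- lapply(object@tracks, slot, "genome")
      same <- vapply(g, function(x)
        identical(x@name, g[[1L]]@name) && identical(x@length, g[[1L]]@length),
        logical(1))
      if (!all(same)) msg <- c(msg, "all tracks must share one genome")
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a LibraryCollection
#'
#' @param tracks list of [ReadStartTrack-class] replicates on one genome.
#' @param conditionLabel condition label (default `"condition"`).
#' @return A [LibraryCollection-class].
#' @export
libraryCollection <- function(tracks, conditionLabel = "condition") {
  new("LibraryCollection", tracks = tracks,
      conditionLabel = as.character(conditionLabel))
}

#' Tuning parameters of the terminus-detection algorithm
#'
#' @slot W local half-window (nt); the local window spans `2W+1` positions.
#' @slot D downstream window length (nt).
#' @slot alpha significance level for the corrected per-library tests.
#' @slot minReads minimal read-start support for the local window sum L;
#'   below it the statistic R is set to 0.
#' @slot minPeakDistance minimal distance (nt) between two called peaks.
#' @slot peakThreshold minimal averaged statistic for a peak (`NA` = derive
#'   from the analytic null, rounded up to two decimals).
#' @slot minSigLibraries minimal number of significant libraries for the
#'   relaxed selection rule (`NA` = M - 1).
#' @slot relaxRbar averaged-statistic cutoff used by the relaxed rule.
#' @export
setClass("TRSParams",
  representation(W = "integer", D = "integer", alpha = "numeric",
                 minReads = "integer", minPeakDistance = "integer",
                 peakThreshold = "numeric", minSigLibraries = "integer",
                 relaxRbar = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@W < 0L) msg <- c(msg, "'W' must be >= 0")
    if (object@D < 1L) msg <- c(msg, "'D' must be >= 1")
    if (object@alpha <= 0 || object@alpha >= 1)
      msg <- c(msg, "'alpha' must be in (0, 1)")
    if (object@minReads < 0L) msg <- c(msg, "'minReads' must be >= 0")
    if (object@minPeakDistance < 1L)
      msg <- c(msg, "'minPeakDistance' must be >= 1")
    if (!is.na(object@peakThreshold) &&
        (object@peakThreshold < 0 || object@peakThreshold > 1))
      msg <- c(msg, "'peakThreshold' must be in [0, 1]")
    if (object@relaxRbar < 0 || object@relaxRbar > 1)
      msg <- c(msg, "'relaxRbar' must be in [0, 1]")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct the algorithm parameter set
#'
#' Defaults are the published parameter set for bacterial RNAtag-seq: a local
#' window of half-width 3 nt (7 positions), a 67-nt downstream region, a 0.01
#' significance level, a minimum of 10 read starts in the local window, a
#' 10-nt minimal peak distance, a peak threshold of 0.1 on the averaged
#' statistic, and the relaxed selection rule (significant in M-1 libraries
#' with averaged statistic >= 0.5).
#'
#' @param W local half-window (nt).
#' @param D downstream window (nt).
#' @param alpha significance level.
#' @param minReads minimal local read-start support.
#' @param minPeakDistance minimal peak spacing (nt).
#' @param peakThreshold peak threshold on the averaged statistic; `NA` derives
#'   it from [nullThreshold()] rounded up to two decimals.
#' @param minSigLibraries minimal significant libraries for the relaxed rule
#'   (`NA` = M - 1).
#' @param relaxRbar averaged-statistic cutoff of the relaxed rule.
#' @return A [TRSParams-class].
#' @examples
#' trsParams()                    # published defaults
#' trsParams(W = 2, D = 50)
#' @export
trsParams <- function(W = 3, D = 67, alpha = 0.01, minReads = 10,
                      minPeakDistance = 10, peakThreshold = 0.1,
                      minSigLibraries = NA, relaxRbar = 0.5) {
  new("TRSParams", W = as.integer(W), D = as.integer(D),
      alpha = as.numeric(alpha), minReads = as.integer(minReads),
      minPeakDistance = as.integer(minPeakDistance),
      peakThreshold = as.numeric(peakThreshold),
      minSigLibraries = as.integer(minSigLibraries),
      relaxRbar = as.numeric(relaxRbar))
}

#' Per-position readthrough statistic across libraries
#'
#' Stores, for each strand, the per-library scaled readthrough statistic R
#' (positions x libraries), its cross-library average, and the per-library
#' local-window sums L used for the statistical tests and for peak
#' tie-breaking.
#'
#' @slot genome a [GenomeRef-class].
#' @slot libraryIds library identifiers (column order of the matrices).
#' @slot params the [TRSParams-class] used.
#' @slot RPlus,RMinus numeric matrices (positions x libraries) of R values.
#' @slot RBarPlus,RBarMinus numeric vectors of cross-library averages.
#' @slot LPlus,LMinus numeric matrices of local-window read-start sums.
#' @export
setClass("ReadthroughProfile",
  representation(genome = "GenomeRef", libraryIds = "character",
                 params = "TRSParams",
                 RPlus = "matrix", RMinus = "matrix",
                 RBarPlus = "numeric", RBarMinus = "numeric",
                 LPlus = "matrix", LMinus = "matrix"),
  validity = function(object) {
    msg <- NULL
    n <- object@genome@length
    for (s in c("RPlus", "RMinus"))
      if (nrow(slot(object, s)) != n)
        msg <- c(msg, sprintf("'%s' must have one row per genome position", s))
    rng <- range(c(object@RPlus, object@RMinus), na.rm = TRUE)
    if (length(object@RPlus) && (rng[1] < 0 || rng[2] > 1))
      msg <- c(msg, "R values must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  }
)

#' Null distribution of the local-window read-start sum
#'
#' Method-of-moments fit of the per-position read-start law in the downstream
#' window: negative binomial when the variance exceeds the mean, Poisson
#' otherwise, degenerate when the window is all-zero. The law of the
#' local-window sum L is the (2W+1)-fold convolution.
#'
#' @slot mean,var per-position moment estimates.
#' @slot size,prob negative-binomial parameters of the per-position law
#'   (`NA` for the Poisson/degenerate cases).
#' @slot nLocal number of positions summed into L (2W+1).
#' @slot poisson logical, Poisson fallback used (variance <= mean).
#' @slot degenerate logical, all-zero downstream window.
#' @export
setClass("NBFit",
  representation(mean = "numeric", var = "numeric", size = "numeric",
                 prob = "numeric", nLocal = "integer", poisson = "logical",
                 degenerate = "logical"))

#' Gene and transcription-unit annotation database
#'
#' Feature table (CDS/ncRNA/rRNA/tRNA with stop-codon coordinates and optional
#' documented terminator / 5' UTR columns) plus transcription units, with the
#' derived gene-level flags needed by the terminus classifier.
#'
#' @slot genome a [GenomeRef-class].
#' @slot genes data.frame with columns `geneId`, `name`, `type`, `start`,
#'   `end`, `strand`, `stopCodonEnd`, `utr5Start`, `documentedTerminus`,
#'   plus derived `lastInAll` and `nonLastInAny`.
#' @slot tus data.frame with columns `tuId`, `strand`, `members` (list of
#'   ordered gene ids, 5' to 3'), `tuEnd`.
#' @export
setClass("AnnotationDB",
  representation(genome = "GenomeRef", genes = "data.frame", tus = "data.frame"))

setMethod("show", "GenomeRef", function(object) {
  cat("GenomeRef:", object@name, "-", object@length, "nt,",
      if (object@circular) "circular" else "linear", "\n")
})

setMethod("show", "ReadStartTrack", function(object) {
  cat("ReadStartTrack '", object@libraryId, "' on ", object@genome@name,
      " (", object@genome@length, " nt)\n",
      "  read starts: +", sum(object@countsPlus), " / -",
      sum(object@countsMinus), "\n", sep = "")
})

setMethod("show", "LibraryCollection", function(object) {
  cat("LibraryCollection (", object@conditionLabel, "): ",
      length(object@tracks), " replicate libraries on ",
      object@tracks[[1L]]@genome@name, "\n", sep = "")
})

setMethod("show", "TRSParams", function(object) {
  cat("TRSParams: W=", object@W, " D=", object@D, " alpha=", object@alpha,
      " minReads=", object@minReads, " minPeakDistance=",
      object@minPeakDistance, " peakThreshold=", object@peakThreshold,
      " minSigLibraries=", object@minSigLibraries, " relaxRbar=",
      object@relaxRbar, "\n", sep = "")
})

setMethod("show", "ReadthroughProfile", function(object) {
  cat("ReadthroughProfile on ", object@genome@name, ": ",
      length(object@libraryIds), " libraries, ", object@genome@length,
      " positions/strand\n", sep = "")
})

setMethod("show", "AnnotationDB", function(object) {
  cat("AnnotationDB on ", object@genome@name, ": ", nrow(object@genes),
      " features, ", nrow(object@tus), " transcription units\n", sep = "")
})
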