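#' Fragmentation and sequencing model of the tagged-library protocol
#'
#' Models the library-preparation steps that create the read-start pattern:
#' random hydrolysis of each transcript copy, ligation of the read-1 adapter
#' to fragment 3' ends, trimming of fragments to the sequencing read length,
#' and removal of fragments too short to map. Hydrolysis is modelled as an
#' independent break at each internucleotide bond with probability
#' `1/meanFragmentLength` (geometric fragment lengths), the standard
#' single-parameter model of alkaline/heat fragmentation.
#'
#' @param meanFragmentLength mean fragment length (nt); default 200.
#' @param readLength maximal sequencing read length (nt); default 70.
#' @param minFragmentLength minimal mappable fragment length (nt); default 25.
#' @return A list of class `FragmentationModel`.
#' @examples
#' fragmentationModel()
#' @export
fragmentationModel <- function(meanFragmentLength = 200, readLength = 70,
                               minFragmentLength = 25) {
  stopifnot(meanFragmentLength >= 1, minFragmentLength <= readLength)
  structure(list(meanFragmentLength = meanFragmentLength,
                 readLength = readLength,
                 minFragmentLength = minFragmentLength),
            class = "FragmentationModel")
}

#' Fragment one transcript copy and report read-start offsets
#'
#' Breakpoints are drawn independently at each of the `length - 1`
#' internucleotide bonds with probability `1/meanFragmentLength`; the
#' fragments are the intervals between consecutive breakpoints, and the
#' transcript's own 3' end is always a fragment 3' end. Every fragment at
#' least `minFragmentLength` long yields one read whose start is the
#' fragment's 3'-most base (1-based transcript offset). Trimming fragments
#' from the 3' end to the read length never moves the read start, so it does
#' not appear in the offsets.
#'
#' @param length transcript length (nt, >= 1).
#' @param model a [fragmentationModel()].
#' @return Integer vector of read-start offsets in transcript coordinates.
#' @examples
#' set.seed(1)
#' fragmentTranscript(300, fragmentationModel())
#' @export
fragmentTranscript <- function(length, model = fragmentationModel()) {
  stopifnot(length >= 1)
  nBonds <- length - 1L
  nBreaks <- if (nBonds > 0L)
    rbinom(1L, nBonds, 1 / model$meanFragmentLength) else 0L
  breaks <- if (nBreaks > 0L) sort(sample.int(nBonds, nBreaks)) else integer()
  fragmentReadStarts(breaks, length, model)
}

#' @describeIn fragmentTranscript read-start offsets for a fixed set of
#'   breakpoints (bond `b` separates bases `b` and `b+1`); the stochastic
#'   step factored out, useful for enumerating the fragmentation rule.
#' @param breaks sorted breakpoint bond indices in `1 .. length-1`.
#' @export
fragmentReadStarts <- function(breaks, length, model = fragmentationModel()) {
  ends <- c(breaks, length)
  lens <- diff(c(0L, ends))
  ends[lens >= model$minFragmentLength]
}

#' Simulate the read-start track of many copies of one transcript
#'
#' Applies [fragmentTranscript()] to `nCopies` independent copies of a
#' transcript and maps the resulting read-start offsets to genomic
#' coordinates on the transcript's strand. With many copies the genomic
#' position with the maximal read-start count is the genuine 3' terminus,
#' because the terminus is the one fragment end shared by every copy while
#' hydrolysis breakpoints scatter uniformly.
#'
#' @param start,end genomic span of the transcript (1-based inclusive).
#' @param strand `"+"` or `"-"` (the 3' end is at `end` on `+`, `start`
#'   on `-`).
#' @param genome a [GenomeRef-class].
#' @param nCopies number of transcript copies.
#' @param model a [fragmentationModel()].
#' @param libraryId identifier for the resulting track.
#' @return A [ReadStartTrack-class].
#' @export
simulateLibrary <- function(start, end, strand, genome, nCopies = 10000,
                            model = fragmentationModel(),
                            libraryId = "simulated") {
  strand <- .checkStrand(strand)
  if (start < 1L || end > genome@length || start > end)
    stop("transcript span [", start, ", ", end, "] outside the genome")
  len <- end - start + 1L
  offsets <- unlist(lapply(seq_len(nCopies), function(i)
    fragmentTranscript(len, model)), use.names = FALSE)
  pos <- if (strand == "+") start + offsets - 1L else end - offsets + 1L
  counts <- tabulate(pos, nbins = genome@length)
  if (strand == "+")
    readStartTrack(genome, libraryId, countsPlus = counts)
  else
    readStartTrack(genome, libraryId, countsMinus = counts)
}

#' Synthetic benchmark scenario
#'
#' Describes a complete synthetic dataset: genome, gene/transcription-unit
#' layout, expressed transcripts, planted 3' termini with termination
#' strengths, negative-binomial background noise, and the replicate count.
#' [generateFixture()] turns a scenario into sequence, annotation, replicate
#' tracks and a truth table.
#'
#' @param genomeLength genome length (nt).
#' @param circular circular genome.
#' @param genes data.frame: `geneId`, `type` (CDS/ncRNA/rRNA/tRNA), `start`,
#'   `end`, `strand`.
#' @param tus data.frame with `tuId`, `strand` and a `members` list column of
#'   ordered gene ids (may be empty; genes absent from any TU are implicit
#'   single-gene units).
#' @param transcripts data.frame: `txStart`, `txEnd`, `strand`, `nCopies`.
#'   The transcript 3' end (its primary terminus) is `txEnd` on `+`,
#'   `txStart` on `-`.
#' @param prematureTermini data.frame: `txIndex` (row of `transcripts`),
#'   `position` (genomic), `strength` in (0, 1] (fraction of copies ending
#'   there; the remainder read through towards the primary terminus).
#' @param truthClasses character vector: expected annotation class of each
#'   planted terminus, primary termini first (one per transcript) then the
#'   premature ones, in row order.
#' @param backgroundMean,backgroundSize negative-binomial background noise
#'   per position, strand and replicate.
#' @param M replicate count.
#' @param seed integer seed; replicate r uses `seed + r`.
#' @param model a [fragmentationModel()].
#' @return A list of class `SyntheticScenario`.
#' @export
syntheticScenario <- function(genomeLength, circular = TRUE, genes, tus,
                              transcripts, prematureTermini = NULL,
                              truthClasses = NULL,
                              backgroundMean = 0.2, backgroundSize = 0.5,
                              M = 3, seed = 1,
                              model = fragmentationModel()) {
  if (!is.null(prematureTermini) && nrow(prematureTermini)) {
    bad <- with(prematureTermini, strength <= 0 | strength > 1)
    if (any(bad)) stop("terminus strength must be in (0, 1]: rows ",
                       paste(which(bad), collapse = ", "))
    for (r in seq_len(nrow(prematureTermini))) {
      tx <- transcripts[prematureTermini$txIndex[r], ]
      p <- prematureTermini$position[r]
      if (p < tx$txStart || p > tx$txEnd)
        stop("prematureTermini row ", r, ": position outside its transcript")
    }
  }
  structure(list(genomeLength = as.integer(genomeLength),
                 circular = circular, genes = genes, tus = tus,
                 transcripts = transcripts,
                 prematureTermini = prematureTermini,
                 truthClasses = truthClasses,
                 backgroundMean = backgroundMean,
                 backgroundSize = backgroundSize,
                 M = as.integer(M), seed = as.integer(seed), model = model),
            class = "SyntheticScenario")
}

# One replicate's read-start counts for a single transcript, honouring the
# planted premature termini: each copy ends at the first premature terminus
# (in 5'->3' order) that fires (probability = strength), else at the
# transcript 3' end.
.simulateTranscriptCopies <- function(tx, premature, model, genomeLength) {
  full <- tx$txEnd - tx$txStart + 1L
  premLen <- integer(0)
  strengths <- numeric(0)
  if (!is.null(premature) && nrow(premature)) {
    # offset of a premature terminus from the transcript 5' end
    off <- if (tx$strand == "+") premature$position - tx$txStart + 1L
           else tx$txEnd - premature$position + 1L
    ord <- order(off)
    premLen <- off[ord]
    strengths <- premature$strength[ord]
  }
  lengths <- rep.int(full, tx$nCopies)
  if (length(premLen)) {
    undecided <- rep(TRUE, tx$nCopies)
    for (t in seq_along(premLen)) {
      fire <- undecided & (stats::runif(tx$nCopies) < strengths[t])
      lengths[fire] <- premLen[t]
      undecided <- undecided & !fire
    }
  }
  offsets <- unlist(lapply(lengths, fragmentTranscript, model = model),
                    use.names = FALSE)
  pos <- if (tx$strand == "+") tx$txStart + offsets - 1L
         else tx$txEnd - offsets + 1L
  tabulate(pos, nbins = genomeLength)
}

#' Generate a complete synthetic fixture from a scenario
#'
#' Produces a random genome sequence, the annotation database, M replicate
#' read-start tracks (fragmentation-simulated transcript reads plus
#' independent negative-binomial background noise per position, strand and
#' replicate), and a truth table listing every planted terminus for recovery
#' scoring. Fully reproducible from the scenario seed.
#'
#' @param scenario a [syntheticScenario()].
#' @return List with elements `genome` ([GenomeRef-class]), `sequence`
#'   ([Biostrings::DNAString]), `db` ([AnnotationDB-class]), `collection`
#'   ([LibraryCollection-class]) and `truth` (data.frame: `position`,
#'   `strand`, `kind` = primary/premature, `strength`, `classLabel`).
#' @export
generateFixture <- function(scenario) {
  sc <- scenario
  genome <- genomeRef("synthetic", sc$genomeLength, sc$circular)
  .withSeed(sc$seed, {
    sequence <- Biostrings::DNAString(paste(
      sample(c("A", "C", "G", "T"), sc$genomeLength, replace = TRUE),
      collapse = ""))
    tracks <- vector("list", sc$M)
    for (r in seq_len(sc$M)) {
      set.seed(sc$seed + r)
      plus <- integer(sc$genomeLength)
      minus <- integer(sc$genomeLength)
      for (t in seq_len(nrow(sc$transcripts))) {
        tx <- sc$transcripts[t, ]
        prem <- if (!is.null(sc$prematureTermini))
          sc$prematureTermini[sc$prematureTermini$txIndex == t, , drop = FALSE]
        else NULL
        cts <- .simulateTranscriptCopies(tx, prem, sc$model, sc$genomeLength)
        if (tx$strand == "+") plus <- plus + cts else minus <- minus + cts
      }
      plus <- plus + rnbinom(sc$genomeLength, size = sc$backgroundSize,
                             mu = sc$backgroundMean)
      minus <- minus + rnbinom(sc$genomeLength, size = sc$backgroundSize,
                               mu = sc$backgroundMean)
      tracks[[r]] <- readStartTrack(genome, paste0("rep", r), plus, minus)
    }
  })
  db <- annotationDB(genome, sc$genes, sc$tus)
  primary <- data.frame(
    position = ifelse(sc$transcripts$strand == "+",
                      sc$transcripts$txEnd, sc$transcripts$txStart),
    strand = sc$transcripts$strand, kind = "primary", strength = 1)
  truth <- primary
  if (!is.null(sc$prematureTermini) && nrow(sc$prematureTermini)) {
    prem <- data.frame(position = sc$prematureTermini$position,
                       strand = sc$transcripts$strand[sc$prematureTermini$txIndex],
                       kind = "premature",
                       strength = sc$prematureTermini$strength)
    truth <- rbind(truth, prem)
  }
  if (!is.null(sc$truthClasses)) truth$classLabel <- sc$truthClasses
  list(genome = genome, sequence = sequence, db = db,
       collection = libraryCollection(tracks, "synthetic"), truth = truth)
}

#' The default planted-termini benchmark scenario
#'
#' A 20-kb circular genome with seven expressed transcripts covering the
#' annotation classes: a single-gene unit with a terminus 50 nt past its stop
#' codon (Primary), one terminating 150 nt past the stop codon (Distant
#' Primary), a gene with a premature terminus inside its CDS (Internal) plus
#' its own primary terminus, a two-gene operon with an intercistronic
#' terminus past the first gene (AP in TU) and an operon-end terminus
#' (Primary), an antisense transcript ending inside a gene on the opposite
#' strand (Orphan AS), an isolated intergenic transcript (Orphan IGR), and a
#' minus-strand gene with a premature terminus in its 5' UTR
#' (Premature 5' UTR). Three replicates, 2000 copies per transcript, and
#' weak over-dispersed background noise (negative binomial, mean 0.2,
#' size 0.5 per position).
#'
#' @param seed scenario seed.
#' @param nCopies transcript copy number per replicate.
#' @return A [syntheticScenario()].
#' @export
defaultScenario <- function(seed = 1, nCopies = 2000) {
  genes <- data.frame(
    geneId = c("geneA", "geneB", "geneC", "geneD", "geneE", "geneF", "geneG"),
    type = "CDS",
    start = c(1001L, 4001L, 7001L, 10001L, 11001L, 14000L, 18500L),
    end   = c(2000L, 5000L, 8200L, 10900L, 11900L, 15000L, 19200L),
    strand = c("+", "+", "+", "+", "+", "+", "-"),
    stringsAsFactors = FALSE)
  tus <- data.frame(tuId = "tuDE", strand = "+", stringsAsFactors = FALSE)
  tus$members <- list(c("geneD", "geneE"))
  transcripts <- data.frame(
    txStart = c(950L, 3950L, 6950L, 9950L, 14500L, 17000L, 18400L),
    txEnd   = c(2050L, 5150L, 8300L, 12000L, 15500L, 17800L, 19500L),
    strand  = c("+", "+", "+", "+", "-", "-", "-"),
    nCopies = nCopies)
  premature <- data.frame(
    txIndex = c(3L, 4L, 7L),
    position = c(7600L, 10950L, 19250L),
    strength = c(0.5, 0.3, 0.4))
  truthClasses <- c(
    # primary termini of the seven transcripts, in transcript order
    "Primary", "DP", "Primary", "Primary", "Orphan_AS", "Orphan_IGR",
    "Primary",
    # premature termini
    "Internal", "AP_in_TU", "Premature_5UTR")
  syntheticScenario(genomeLength = 20000L, circular = TRUE, genes = genes,
                    tus = tus, transcripts = transcripts,
                    prematureTermini = premature,
                    truthClasses = truthClasses, M = 3, seed = seed)
}

#' Write a generated fixture to disk
#'
#' Emits the full file set of a synthetic dataset: `genome.fasta`,
#' `annotation.gff3` (with `utr5_start` / `documented_terminus` attributes
#' when present), `tus.tsv` (tu_id, strand, comma-separated ordered gene
#' list), one bedGraph strand pair per replicate (`rep<k>.plus.bedgraph` /
#' `.minus.bedgraph`), and `truth.tsv` listing the planted termini.
#'
#' @param fixture result of [generateFixture()].
#' @param dir output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- fixture$genome
  fa <- file.path(dir, "genome.fasta")
  seqs <- Biostrings::DNAStringSet(fixture$sequence)
  names(seqs) <- g@name
  Biostrings::writeXStringSet(seqs, fa)
  gff <- file.path(dir, "annotation.gff3")
  genes <- fixture$db@genes
  attrs <- paste0("ID=", genes$geneId, ";Name=", genes$name)
  extra <- function(col, tag) ifelse(is.na(genes[[col]]), "",
                                     paste0(";", tag, "=", genes[[col]]))
  attrs <- paste0(attrs, extra("utr5Start", "utr5_start"),
                  extra("documentedTerminus", "documented_terminus"))
  lines <- c("##gff-version 3",
             paste(g@name, "terminR", genes$type, genes$start, genes$end,
                   ".", genes$strand, ".", attrs, sep = "\t"))
  writeLines(lines, gff)
  tuPath <- file.path(dir, "tus.tsv")
  tus <- fixture$db@tus
  explicit <- !startsWith(tus$tuId, "tu_")   # skip implicit singletons
  writeLines(paste(tus$tuId[explicit], tus$strand[explicit],
                   vapply(tus$members[explicit], paste, character(1),
                          collapse = ","), sep = "\t"), tuPath)
  prefixes <- character(0)
  for (r in seq_along(fixture$collection@tracks)) {
    prefix <- file.path(dir, libraryId(fixture$collection@tracks[[r]]))
    serializeTrack(fixture$collection@tracks[[r]], prefix)
    prefixes <- c(prefixes, prefix)
  }
  truthPath <- file.path(dir, "truth.tsv")
  write.table(fixture$truth, truthPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(fasta = fa, gff = gff, tus = tuPath, tracks = prefixes,
                 truth = truthPath))
}
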