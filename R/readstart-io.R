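#' Remove duplicate alignment records
#'
#' Keeps exactly one representative among records with identical sequence
#' content (single-end) or identical mate-pair coordinates and sequences
#' (paired-end); survivors keep their input order. This removes PCR
#' duplicates, which would otherwise inflate the read-start count at a single
#' position and could be falsely called as a terminus.
#'
#' @param records data.frame with a `seq` column; for `paired = TRUE` also
#'   `pos` and `mpos` (own and mate alignment coordinates).
#' @param paired whether records are paired-end.
#' @return The deduplicated data.frame.
#' @examples
#' dedupIdentical(data.frame(seq = c("ACGT", "ACGT", "ACGT", "TTTT")))
#' @export
dedupIdentical <- function(records, paired = FALSE) {
  if (nrow(records) == 0L) return(records)
  key <- if (paired)
    paste(records$pos, records$mpos, records$seq, sep = "\r")
  else records$seq
  records[!duplicated(key), , drop = FALSE]
}

#' Extract strand-specific read-start counts from a BAM file
#'
#' Converts mapped reads into a per-position read-start track: for each
#' primary alignment of the selected read, one count is added at the genomic
#' coordinate of its first sequenced base (the leftmost aligned base for
#' plus-strand alignments, the rightmost for minus-strand alignments;
#' soft-clipped leading bases are skipped because the first *aligned* base is
#' used). Under `orientation = "reverse"` (the RNAtag-seq default, where
#' read 1 is the cDNA antisense to the transcript) the count is assigned to
#' the strand opposite the alignment strand; under `"forward"` to the same
#' strand. With `read = 2` the mate's starts are extracted instead - under
#' reverse orientation these mark transcript 5' ends and are assigned to the
#' alignment strand.
#'
#' @param bamFile path to a coordinate-mapped BAM file.
#' @param genome a [GenomeRef-class]; its name must match the BAM reference.
#' @param orientation `"reverse"` (default) or `"forward"`.
#' @param paired paired-end data; only the selected read contributes.
#' @param dedup remove duplicate records first (see [dedupIdentical()]).
#' @param minMapq minimal mapping quality (default 1; records with missing
#'   MAPQ pass).
#' @param libraryId identifier stored in the track.
#' @param read which read of the pair to use (1 = 3'-end track, 2 = 5'-end
#'   track); ignored for single-end data.
#' @return A [ReadStartTrack-class].
#' @export
readStartsFromBam <- function(bamFile, genome,
                              orientation = c("reverse", "forward"),
                              paired = FALSE, dedup = FALSE, minMapq = 1,
                              libraryId = basename(bamFile), read = 1) {
  orientation <- match.arg(orientation)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(what = c("flag", "mapq", "seq", "mpos"),
                                   flag = flag)
  aln <- GenomicAlignments::readGAlignments(bamFile, param = param)
  seqn <- as.character(GenomicAlignments::seqnames(aln))
  if (length(aln) && !all(seqn == genome@name))
    stop("BAM reference name(s) ", paste(unique(setdiff(seqn, genome@name)),
         collapse = ", "), " do not match genome '", genome@name, "'")
  meta <- S4Vectors::mcols(aln)
  keep <- is.na(meta$mapq) | meta$mapq >= minMapq
  if (paired) {
    isRead1 <- bitwAnd(meta$flag, 64L) != 0L
    keep <- keep & (if (read == 1) isRead1 else !isRead1)
  }
  aln <- aln[keep]
  meta <- S4Vectors::mcols(aln)
  rec <- data.frame(pos = GenomicAlignments::start(aln),
                    end = GenomicAlignments::end(aln),
                    strand = as.character(GenomicAlignments::strand(aln)),
                    mpos = if (!is.null(meta$mpos)) meta$mpos else NA_integer_,
                    seq = as.character(meta$seq),
                    stringsAsFactors = FALSE)
  if (dedup) rec <- dedupIdentical(rec, paired = paired)
  startPos <- ifelse(rec$strand == "+", rec$pos, rec$end)
  inRange <- startPos >= 1L & startPos <= genome@length
  if (any(!inRange)) {
    warning(sum(!inRange), " alignment record(s) outside [1, ",
            genome@length, "] rejected")
    rec <- rec[inRange, , drop = FALSE]
    startPos <- startPos[inRange]
  }
  flip <- if (read == 1) orientation == "reverse" else orientation == "forward"
  outStrand <- if (flip) ifelse(rec$strand == "+", "-", "+") else rec$strand
  plus <- tabulate(startPos[outStrand == "+"], nbins = genome@length)
  minus <- tabulate(startPos[outStrand == "-"], nbins = genome@length)
  readStartTrack(genome, libraryId, plus, minus)
}

#' @describeIn readStartsFromBam convert a SAM text file to BAM first
#'   (via [Rsamtools::asBam()]) and extract read starts from it.
#' @param samFile path to a SAM text file.
#' @param ... passed on to `readStartsFromBam`.
#' @export
readStartsFromSam <- function(samFile, genome, ...) {
  bam <- Rsamtools::asBam(samFile,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  readStartsFromBam(bam, genome, ...)
}
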