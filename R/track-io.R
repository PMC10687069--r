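# bedGraph persistence of read-start tracks: one file per strand
# (<prefix>.plus.bedgraph / <prefix>.minus.bedgraph), 0-based half-open
# intervals, zero-count runs omitted. Internal coordinates are 1-based.

.writeStrandBedgraph <- function(counts, chrom, path) {
  r <- rle(as.integer(counts))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values > 0L
  df <- data.frame(chrom = rep(chrom, sum(keep)), start = starts[keep] - 1L,
                   end = ends[keep], value = r$values[keep])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.readStrandBedgraph <- function(path, genome) {
  counts <- integer(genome@length)
  lines <- readLines(path)
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(line) || startsWith(line, "track") || startsWith(line, "#"))
      next
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 4L)
      stop("malformed bedGraph line ", ln, " in '", path,
           "': expected 4 tab-separated fields")
    start0 <- suppressWarnings(as.integer(f[2L]))
    end0 <- suppressWarnings(as.integer(f[3L]))
    val <- suppressWarnings(as.numeric(f[4L]))
    if (is.na(start0) || is.na(end0) || is.na(val) || start0 < 0L ||
        end0 <= start0)
      stop("malformed bedGraph line ", ln, " in '", path, "'")
    if (end0 > genome@length)
      stop("bedGraph line ", ln, " in '", path, "': interval end ", end0,
           " exceeds genome length ", genome@length)
    counts[(start0 + 1L):end0] <- counts[(start0 + 1L):end0] + as.integer(val)
  }
  counts
}

#' Write a read-start track as a strand pair of bedGraph files
#'
#' Writes `<prefix>.plus.bedgraph` and `<prefix>.minus.bedgraph` with
#' 0-based half-open intervals and zero-count runs omitted. The round trip
#' through [loadTrack()] reproduces the track exactly.
#'
#' @param track a [ReadStartTrack-class].
#' @param prefix output path prefix.
#' @return The two file paths, invisibly.
#' @export
serializeTrack <- function(track, prefix) {
  paths <- c(paste0(prefix, ".plus.bedgraph"), paste0(prefix, ".minus.bedgraph"))
  .writeStrandBedgraph(track@countsPlus, track@genome@name, paths[1L])
  .writeStrandBedgraph(track@countsMinus, track@genome@name, paths[2L])
  invisible(paths)
}

#' Load a read-start track from a strand pair of bedGraph files
#'
#' @param prefix path prefix (as used by [serializeTrack()]).
#' @param genome a [GenomeRef-class].
#' @param libraryId identifier for the loaded track (default: the prefix
#'   basename).
#' @return A [ReadStartTrack-class].
#' @export
loadTrack <- function(prefix, genome, libraryId = basename(prefix)) {
  paths <- c(paste0(prefix, ".plus.bedgraph"), paste0(prefix, ".minus.bedgraph"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("track file(s) not found: ", paste(missing, collapse = ", "))
  readStartTrack(genome, libraryId,
                 .readStrandBedgraph(paths[1L], genome),
                 .readStrandBedgraph(paths[2L], genome))
}
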