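#' Mean read-start count over a genomic interval
#'
#' Arithmetic mean of the per-position read-start counts over a closed
#' interval on one strand; used to measure CDS and 3' UTR expression.
#'
#' @param track a [ReadStartTrack-class].
#' @param start,end 1-based inclusive interval bounds.
#' @param strand `"+"` or `"-"`.
#' @return The mean count per position.
#' @export
regionMeanReadStarts <- function(track, start, end, strand) {
  strand <- .checkStrand(strand)
  if (start > end) stop("empty interval: start > end")
  .checkPosition(c(start, end), track@genome)
  mean(trackCounts(track, strand)[start:end])
}

# 3' UTR interval of a gene given its called primary/DP terminus: the region
# from the base after the stop codon to the terminus, strand-aware.
.utr3Interval <- function(gene, terminusPos) {
  if (gene$strand == "+") c(gene$stopCodonEnd + 1L, terminusPos)
  else c(terminusPos, gene$stopCodonEnd - 1L)
}

#' Detect genes whose 3' UTR expression departs from the CDS trend
#'
#' For genes transcribed alone or last in their operon that received a
#' Primary or Distant Primary terminus, the mean read-start count in the CDS
#' and in the 3' UTR (stop codon to the called terminus) are computed per
#' library, log10-transformed with a pseudo-count, and an ordinary
#' least-squares line of UTR on CDS expression is fitted per library.
#' Genes whose Cook's distance exceeds 3 times the library average in at
#' least `minLibraries` libraries are flagged; their direction (`UTR_high` /
#' `CDS_high`) follows the sign of the mean residual. High-UTR outliers are
#' candidate 3' UTR-derived small RNAs.
#'
#' @param calls classified terminus calls (a `GRanges` from [runTRS()] +
#'   [classifyTermini()], or equivalent data.frame with `position`, `strand`,
#'   `classLabel`, `assignedGene`).
#' @param db an [AnnotationDB-class].
#' @param collection the [LibraryCollection-class] the calls came from.
#' @param eps pseudo-count added before log10 (default 0.01 read
#'   starts/position, keeping very low-expression genes representable).
#' @param ratioCutoff Cook's-distance-to-average ratio (default 3).
#' @param minLibraries libraries that must exceed the cutoff (default 2).
#' @return data.frame: `geneId`, `cdsMean.*`/`utrMean.*` per library,
#'   `cooks.*` per library, `nExceeding`, `flagged`, `direction`.
#' @export
utrCdsOutliers <- function(calls, db, collection, eps = 0.01,
                           ratioCutoff = 3, minLibraries = 2) {
  isGR <- is(calls, "GRanges")
  pos <- if (isGR) GenomicRanges::start(calls) else calls$position
  lab <- if (isGR) calls$classLabel else calls$classLabel
  gid <- if (isGR) calls$assignedGene else calls$assignedGene
  sel <- !is.na(lab) & lab %in% c("Primary", "DP") & !is.na(gid)
  genes <- db@genes
  use <- data.frame(geneId = gid[sel], terminus = pos[sel],
                    stringsAsFactors = FALSE)
  use <- use[!duplicated(use$geneId), , drop = FALSE]
  gi <- match(use$geneId, genes$geneId)
  ok <- !is.na(gi) & genes$type[gi] == "CDS" & genes$lastInAll[gi]
  use <- use[ok, , drop = FALSE]
  gi <- gi[ok]
  if (nrow(use) < 3L)
    stop("need at least 3 genes with a Primary/DP terminus for the regression")
  M <- nLibraries(collection)
  cdsMean <- utrMean <- cooks <- resid <- matrix(NA_real_, nrow(use), M)
  for (j in seq_len(M)) {
    track <- collection@tracks[[j]]
    for (g in seq_len(nrow(use))) {
      gene <- genes[gi[g], ]
      cdsMean[g, j] <- regionMeanReadStarts(track, gene$start, gene$end,
                                            gene$strand)
      u <- .utr3Interval(gene, use$terminus[g])
      if (u[1L] > u[2L]) u <- c(min(u), max(u))
      utrMean[g, j] <- regionMeanReadStarts(track, u[1L], u[2L], gene$strand)
    }
    x <- log10(cdsMean[, j] + eps)
    y <- log10(utrMean[, j] + eps)
    fit <- lm(y ~ x)
    e <- residuals(fit)
    # an (numerically) exact fit has no outliers; Cook's ratios on
    # machine-epsilon residuals would be noise
    cooks[, j] <- if (sqrt(mean(e^2)) < 1e-8) 0 else cooks.distance(fit)
    resid[, j] <- e
  }
  avg <- colMeans(cooks)
  avg[avg <= 0 | !is.finite(avg)] <- Inf   # all-collinear library: nothing to flag
  ratio <- sweep(cooks, 2L, avg, "/")
  nEx <- rowSums(ratio > ratioCutoff)
  flagged <- nEx >= minLibraries
  direction <- ifelse(rowMeans(resid) > 0, "UTR_high", "CDS_high")
  direction[!flagged] <- NA_character_
  out <- data.frame(geneId = use$geneId, stringsAsFactors = FALSE)
  colnames(cdsMean) <- paste0("cdsMean.", libraryIds(collection))
  colnames(utrMean) <- paste0("utrMean.", libraryIds(collection))
  colnames(cooks) <- paste0("cooks.", libraryIds(collection))
  cbind(out, cdsMean, utrMean, cooks,
        data.frame(nExceeding = as.integer(nEx), flagged = flagged,
                   direction = direction, stringsAsFactors = FALSE))
}

#' Rank premature termini by between-condition readthrough change
#'
#' For premature-class termini (Internal, Premature 5' UTR) outside rRNA
#' genes, with local read-start support of at least `minCov` in at least
#' `minReps` replicates of each condition, computes the difference in the
#' condition-wise averaged readthrough statistic, `delta = RbarA - RbarB`,
#' ranks candidates by `|delta|` (descending) and marks those strictly above
#' the median as selected. A large positive delta means the premature
#' terminus is much stronger under condition A - a candidate
#' condition-specific termination or processing event.
#'
#' @param profileA,profileB [ReadthroughProfile-class] objects of the two
#'   conditions (same genome).
#' @param calls classified calls (with `classLabel`, `assignedGene`).
#' @param db an [AnnotationDB-class].
#' @param minCov minimal local-window read-start sum per replicate
#'   (default 20).
#' @param minReps minimal replicates meeting `minCov` per condition
#'   (default 2).
#' @return data.frame: `position`, `strand`, `classLabel`, `RbarA`, `RbarB`,
#'   `delta`, `rank`, `selected`, ordered by rank.
#' @export
conditionDeltaReadthrough <- function(profileA, profileB, calls, db,
                                      minCov = 20, minReps = 2) {
  if (profileA@genome@name != profileB@genome@name)
    stop("profiles must share one genome")
  isGR <- is(calls, "GRanges")
  pos <- if (isGR) GenomicRanges::start(calls) else calls$position
  strand <- if (isGR) as.character(GenomicRanges::strand(calls)) else calls$strand
  lab <- calls$classLabel
  gid <- calls$assignedGene
  genes <- db@genes
  rRNA <- !is.na(gid) & genes$type[match(gid, genes$geneId)] == "rRNA"
  prem <- !is.na(lab) & lab %in% c("Internal", "Premature_5UTR") & !rRNA
  out <- data.frame(position = pos[prem], strand = strand[prem],
                    classLabel = lab[prem], stringsAsFactors = FALSE)
  if (!nrow(out))
    return(cbind(out, RbarA = numeric(), RbarB = numeric(),
                 delta = numeric(), rank = integer(), selected = logical()))
  getL <- function(profile, p, s)
    if (s == "+") profile@LPlus[p, ] else profile@LMinus[p, ]
  getR <- function(profile, p, s)
    if (s == "+") profile@RPlus[p, ] else profile@RMinus[p, ]
  keep <- logical(nrow(out))
  RbarA <- RbarB <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    la <- getL(profileA, out$position[i], out$strand[i])
    lb <- getL(profileB, out$position[i], out$strand[i])
    keep[i] <- sum(la >= minCov) >= minReps && sum(lb >= minCov) >= minReps
    RbarA[i] <- mean(getR(profileA, out$position[i], out$strand[i]))
    RbarB[i] <- mean(getR(profileB, out$position[i], out$strand[i]))
  }
  out <- out[keep, , drop = FALSE]
  out$RbarA <- RbarA[keep]
  out$RbarB <- RbarB[keep]
  out$delta <- out$RbarA - out$RbarB
  ord <- order(-abs(out$delta))
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$selected <- abs(out$delta) > median(abs(out$delta))
  rownames(out) <- NULL
  out
}

#' Signed distance from a gene's stop codon to a terminus
#'
#' Positive when the terminus lies downstream of the 3'-most base of the
#' stop codon (the usual 3' UTR case), negative when upstream of it (inside
#' the CDS, suggesting premature termination or processing), zero at the
#' stop codon's last base. A species-comparable coordinate for conservation
#' analyses of termination sites.
#'
#' @param terminusPosition terminus coordinate.
#' @param terminusStrand terminus strand.
#' @param gene one row of an [AnnotationDB-class] gene table (a CDS).
#' @return Signed distance in nt.
#' @examples
#' g <- data.frame(geneId = "g", type = "CDS", start = 100, end = 400,
#'                 strand = "+", stopCodonEnd = 400)
#' stopCodonDistance(450, "+", g)   #  50
#' stopCodonDistance(370, "+", g)   # -30
#' @export
stopCodonDistance <- function(terminusPosition, terminusStrand, gene) {
  if (gene$type != "CDS") stop("stop-codon distance requires a CDS gene")
  if (gene$strand != terminusStrand)
    stop("terminus and gene are on different strands")
  .downstreamDist(terminusPosition, gene$stopCodonEnd, gene$strand)
}

#' Positional nucleotide frequencies around terminus positions
#'
#' Extracts the flanking sequence of each terminus (`upstream` nt before to
#' `downstream` nt after, in transcript orientation; minus-strand flanks are
#' reverse-complemented so all read 5' to 3'), aligns them at the terminus,
#' and returns per-position A/C/G/U frequencies. Intrinsic terminators show
#' a GC-rich hairpin upstream and a poly-U tract at and after the terminus.
#'
#' @param genomeSeq a [Biostrings::DNAString] (or character) genome sequence.
#' @param termini data.frame with `position` and `strand`.
#' @param upstream,downstream flank sizes in nt (defaults 40 and 10).
#' @param circular wrap flanks around the origin (default FALSE; termini
#'   whose flank would run off a linear genome end are excluded with a
#'   warning).
#' @return 4 x (upstream + 1 + downstream) matrix of frequencies, rows
#'   A/C/G/U, columns named by offset from the terminus (0 = terminus);
#'   each contributing column sums to 1.
#' @export
flankProfile <- function(genomeSeq, termini, upstream = 40, downstream = 10,
                         circular = FALSE) {
  if (is.character(genomeSeq)) genomeSeq <- Biostrings::DNAString(genomeSeq)
  n <- length(genomeSeq)
  width <- upstream + downstream + 1L
  seqs <- character(0)
  dropped <- 0L
  for (i in seq_len(nrow(termini))) {
    p <- termini$position[i]
    s <- termini$strand[i]
    if (s == "+") { lo <- p - upstream; hi <- p + downstream }
    else { lo <- p - downstream; hi <- p + upstream }
    if (lo < 1L || hi > n) {
      if (!circular) { dropped <- dropped + 1L; next }
      idx <- ((seq.int(lo, hi) - 1L) %% n) + 1L
      sq <- paste(strsplit(as.character(genomeSeq), "")[[1L]][idx],
                  collapse = "")
    } else {
      sq <- as.character(Biostrings::subseq(genomeSeq, lo, hi))
    }
    if (s == "-")
      sq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
    seqs <- c(seqs, sq)
  }
  if (dropped)
    warning(dropped, " terminus flank(s) truncated by the genome end excluded")
  mat <- matrix(0, 4L, width,
                dimnames = list(c("A", "C", "G", "U"),
                                as.character(seq.int(-upstream, downstream))))
  if (!length(seqs)) return(mat)
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs),
                                    as.prob = TRUE)
  for (b in c("A", "C", "G")) if (b %in% rownames(cm)) mat[b, ] <- cm[b, ]
  if ("T" %in% rownames(cm)) mat["U", ] <- cm["T", ]
  mat
}
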