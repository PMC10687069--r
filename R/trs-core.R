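#' Local and downstream read-start window counts
#'
#' For position `i` on the given strand, returns `L`, the read-start count in
#' the local window of `2W+1` positions centred on `i`, and `Dcount`, the
#' read-start count in the `D` positions immediately downstream of the local
#' window (positions `i+W+1 .. i+W+D` in transcript orientation; on the minus
#' strand downstream means decreasing coordinates). Windows wrap on circular
#' genomes and are zero-padded on linear ones.
#'
#' @param track a [ReadStartTrack-class].
#' @param i 1-based genomic position.
#' @param strand `"+"` or `"-"`.
#' @param params a [TRSParams-class] supplying `W` and `D`.
#' @return Named list with elements `L` and `Dcount`.
#' @examples
#' g <- genomeRef("toy", 200, circular = FALSE)
#' tr <- readStartTrack(g, countsPlus = rep(1L, 200))
#' windowCounts(tr, 100, "+", trsParams())   # L = 7, Dcount = 67
#' @export
windowCounts <- function(track, i, strand, params = trsParams()) {
  strand <- .checkStrand(strand)
  .checkPosition(i, track@genome)
  counts <- trackCounts(track, strand)
  circ <- track@genome@circular
  W <- params@W; D <- params@D
  list(L = .windowSumAt(counts, i, -W, W, strand, circ),
       Dcount = .windowSumAt(counts, i, W + 1L, W + D, strand, circ))
}

#' The scaled local-readthrough statistic R
#'
#' `R = L / (L + Dcount)` measures one minus the local transcription
#' readthrough at a position: it is 1 when no read starts downstream (no
#' readthrough, as expected at a strong terminator) and approaches 0 when
#' read starts downstream dominate. When `L` is below `minReads` the
#' position is considered unsupported and R is set to 0, as it is when the
#' combined count is zero.
#'
#' @param L local-window read-start count.
#' @param Dcount downstream-window read-start count.
#' @param minReads minimal local support.
#' @return R in `[0, 1]` (vectorised over `L`/`Dcount`).
#' @examples
#' readthroughStatistic(12, 0)            # 1: no readthrough
#' readthroughStatistic(7, 67)            # 0: below the 10-read support
#' readthroughStatistic(35, 35)           # 0.5
#' @export
readthroughStatistic <- function(L, Dcount, minReads = 10) {
  if (any(L < 0) || any(Dcount < 0)) stop("counts must be non-negative")
  tot <- L + Dcount
  r <- ifelse(L < minReads | tot == 0, 0, L / tot)
  pmin(pmax(r, 0), 1)
}

#' Analytic null value of the readthrough statistic
#'
#' Under identically distributed read-start counts (no terminus), the
#' expected value of R depends only on the window sizes:
#' `(2W+1) / ((2W+1) + D)`. It serves as the minimal peak-calling threshold;
#' with the default windows (W = 3, D = 67) it is 7/74, 0.095 at three
#' decimals, rounded up to the working threshold 0.1.
#'
#' @param W local half-window (nt).
#' @param D downstream window (nt).
#' @return The expected null value of R.
#' @examples
#' round(nullThreshold(3, 67), 3)   # 0.095
#' nullThreshold(0, 1)              # 0.5
#' @export
nullThreshold <- function(W = 3, D = 67) {
  if (W < 0) stop("'W' must be >= 0")
  if (D < 1) stop("'D' must be >= 1 (the statistic has no null without a downstream window)")
  (2 * W + 1) / ((2 * W + 1) + D)
}

# Effective peak threshold: explicit value, or the analytic null rounded up
# to two decimals when unset.
.peakThreshold <- function(params) {
  if (!is.na(params@peakThreshold)) return(params@peakThreshold)
  ceiling(nullThreshold(params@W, params@D) * 100) / 100
}

# Per-strand L and R matrices for every library, vectorised via cumulative
# sums.
.profileStrand <- function(collection, params, strand) {
  g <- refGenome(collection)
  n <- g@length
  M <- nLibraries(collection)
  L <- matrix(0, n, M)
  R <- matrix(0, n, M)
  for (j in seq_len(M)) {
    counts <- trackCounts(collection@tracks[[j]], strand)
    Lj <- .windowSumAll(counts, -params@W, params@W, strand, g@circular)
    Dj <- .windowSumAll(counts, params@W + 1L, params@W + params@D, strand,
                        g@circular)
    L[, j] <- Lj
    R[, j] <- readthroughStatistic(Lj, Dj, params@minReads)
  }
  list(L = L, R = R)
}

#' Compute the readthrough profile of a replicate collection
#'
#' Computes, per strand and library, the local-window sums L and the scaled
#' statistic R at every genomic position, and averages R across the M
#' replicate libraries. The average is what peak calling operates on:
#' scaling to `[0, 1]` makes libraries of different depth comparable, and
#' positions that are not genuine termini fluctuate around the analytic null
#' value while genuine termini stand out.
#'
#' @param collection a [LibraryCollection-class].
#' @param params a [TRSParams-class].
#' @return A [ReadthroughProfile-class].
#' @export
readthroughProfile <- function(collection, params = trsParams()) {
  g <- refGenome(collection)
  p <- .profileStrand(collection, params, "+")
  m <- .profileStrand(collection, params, "-")
  new("ReadthroughProfile", genome = g, libraryIds = libraryIds(collection),
      params = params,
      RPlus = p$R, RMinus = m$R,
      RBarPlus = rowMeans(p$R), RBarMinus = rowMeans(m$R),
      LPlus = p$L, LMinus = m$L)
}

# Peak calling on one strand: candidate = local maximum of RBar above the
# threshold; conflicts within minPeakDistance resolved greedily in favour of
# the larger cross-library L sum, ties to the 3'-most position on the strand.
.callPeaksStrand <- function(rbar, Lsum, strand, params, circular) {
  n <- length(rbar)
  Tthr <- .peakThreshold(params)
  if (n == 0L) return(integer())
  left <- if (circular) c(rbar[n], rbar[-n]) else c(-Inf, rbar[-n])
  right <- if (circular) c(rbar[-1L], rbar[1L]) else c(rbar[-1L], -Inf)
  cand <- which(rbar >= Tthr & rbar >= left & rbar >= right)
  if (!length(cand)) return(integer())
  threePrime <- if (strand == "+") cand else -cand    # larger = more 3'
  ord <- order(-Lsum[cand], -threePrime)
  cand <- cand[ord]
  keep <- integer()
  for (i in cand) {
    d <- abs(keep - i)
    if (circular && length(d)) d <- pmin(d, n - d)
    if (!length(keep) || all(d >= params@minPeakDistance)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Call candidate terminus peaks on the averaged statistic
#'
#' Returns positions where the cross-library average of R is a local maximum
#' at or above the peak threshold, with closely spaced peaks (closer than
#' `minPeakDistance`) suppressed: within a conflicting pair the position with
#' the larger summed local read-start count wins, remaining ties going to the
#' 3'-most position on the strand.
#'
#' @param profile a [ReadthroughProfile-class].
#' @param params a [TRSParams-class]; defaults to the profile's own.
#' @return data.frame with columns `position` and `strand`.
#' @export
callPeaks <- function(profile, params = profile@params) {
  circ <- profile@genome@circular
  plus <- .callPeaksStrand(profile@RBarPlus, rowSums(profile@LPlus), "+",
                           params, circ)
  minus <- .callPeaksStrand(profile@RBarMinus, rowSums(profile@LMinus), "-",
                            params, circ)
  data.frame(position = c(plus, minus),
             strand = rep(c("+", "-"), c(length(plus), length(minus))),
             stringsAsFactors = FALSE)
}

#' Estimate the null law of the local-window sum from the downstream region
#'
#' Under the null hypothesis that a candidate peak is not a terminus, the
#' read-start counts around it are distributed like those downstream of it,
#' so the null parameters are estimated from the `D` downstream per-position
#' counts by the method of moments: per-position mean `m` and variance `v`
#' give a negative binomial with `prob = m/v`, `size = m^2/(v-m)` when
#' over-dispersed (`v > m`), and a Poisson with mean `m` otherwise. The law
#' of L is the `(2W+1)`-fold sum. An all-zero downstream window is flagged
#' degenerate (a perfect terminator).
#'
#' @param track a [ReadStartTrack-class].
#' @param peakPosition candidate position.
#' @param strand `"+"` or `"-"`.
#' @param params a [TRSParams-class].
#' @return An [NBFit-class].
#' @export
estimateNullNB <- function(track, peakPosition, strand, params = trsParams()) {
  strand <- .checkStrand(strand)
  .checkPosition(peakPosition, track@genome)
  counts <- trackCounts(track, strand)
  d <- .downstreamCounts(counts, peakPosition, params@W, params@D, strand,
                         track@genome@circular)
  m <- mean(d)
  v <- var(d)
  if (is.na(v)) v <- 0   # D = 1: no dispersion estimate, Poisson fallback
  nLocal <- 2L * params@W + 1L
  if (all(d == 0))
    return(new("NBFit", mean = 0, var = 0, size = NA_real_, prob = NA_real_,
               nLocal = nLocal, poisson = FALSE, degenerate = TRUE))
  if (v > m)
    new("NBFit", mean = m, var = v, size = m^2 / (v - m), prob = m / v,
        nLocal = nLocal, poisson = FALSE, degenerate = FALSE)
  else
    new("NBFit", mean = m, var = v, size = NA_real_, prob = NA_real_,
        nLocal = nLocal, poisson = TRUE, degenerate = FALSE)
}

#' Upper-tail p-value of an observed local-window sum
#'
#' `P(L >= Lobs)` under the summed null law from [estimateNullNB()]: a
#' negative binomial with `size * (2W+1)` and the fitted `prob`, or a Poisson
#' with mean `(2W+1) * m`. For the degenerate all-zero-downstream null the
#' p-value is 0 when the observed sum reaches the minimal support and 1
#' otherwise: a pileup with literally nothing downstream is a perfect
#' terminator and needs no distributional test.
#'
#' @param LObs observed local-window read-start sum.
#' @param null an [NBFit-class].
#' @param minReads minimal support used for the degenerate case.
#' @return p-value in `[0, 1]`.
#' @export
peakPvalue <- function(LObs, null, minReads = 10) {
  if (null@degenerate) return(if (LObs >= minReads) 0 else 1)
  if (LObs <= 0) return(1)
  if (null@poisson)
    ppois(LObs - 1, lambda = null@mean * null@nLocal, lower.tail = FALSE)
  else
    pnbinom(LObs - 1, size = null@size * null@nLocal, prob = null@prob,
            lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' Multiplies each raw p-value by the number of tests in the family (the
#' candidate peaks tested in that library), capping at 1.
#'
#' @param pRaw numeric vector of raw p-values.
#' @param nTests family size (>= 1).
#' @return Corrected p-values.
#' @examples
#' correctPvalues(c(1e-6, 0.02), 2)
#' @export
correctPvalues <- function(pRaw, nTests) {
  if (nTests < 1) stop("'nTests' must be >= 1")
  pmin(1, pRaw * nTests)
}

#' Select final termini from tested candidates
#'
#' A candidate becomes a terminus when its corrected p-value is at or below
#' `alpha` in all M libraries, or - by the relaxed rule - in at least
#' `minSigLibraries` (default M-1) libraries while the averaged statistic is
#' at least `relaxRbar`.
#'
#' @param candidates data.frame from [callPeaks()].
#' @param pCorrected matrix (candidates x libraries) of corrected p-values.
#' @param rbar averaged statistic at each candidate.
#' @param params a [TRSParams-class].
#' @param M number of libraries.
#' @return Logical vector of selections.
#' @export
selectTermini <- function(candidates, pCorrected, rbar, params, M) {
  if (M < 1) stop("at least one library required")
  minSig <- if (is.na(params@minSigLibraries)) M - 1L else params@minSigLibraries
  nSig <- rowSums(pCorrected <= params@alpha)
  nSig == M | (nSig >= minSig & rbar >= params@relaxRbar)
}

#' Run the full terminus-detection algorithm
#'
#' Orchestrates the pipeline per strand: compute the readthrough profile,
#' call candidate peaks on the cross-library average, test each candidate in
#' each library against its downstream-estimated negative-binomial null,
#' Bonferroni-correct within each library (family = candidates tested), and
#' select termini by the all-libraries or relaxed rule. Structural-RNA
#' filtering is a separate, subsequent step ([filterStructural()]).
#'
#' @param collection a [LibraryCollection-class] of M >= 2 replicates.
#' @param params a [TRSParams-class].
#' @param verbose emit per-step messages.
#' @return A [GRanges][GenomicRanges::GRanges-class] of candidate positions
#'   with metadata columns `RBar`, `L` (matrix, per library), `pRaw`,
#'   `pCorrected` (matrices), `nSignificant`, `selected` and an empty
#'   `classLabel` / `assignedGene` filled in by [classifyTermini()].
#' @export
runTRS <- function(collection, params = trsParams(), verbose = FALSE) {
  g <- refGenome(collection)
  M <- nLibraries(collection)
  profile <- readthroughProfile(collection, params)
  peaks <- callPeaks(profile, params)
  if (verbose)
    message("candidate peaks: ", nrow(peaks), " (threshold ",
            .peakThreshold(params), ")")
  nC <- nrow(peaks)
  pRaw <- matrix(1, nC, M, dimnames = list(NULL, libraryIds(collection)))
  Lmat <- matrix(0, nC, M, dimnames = list(NULL, libraryIds(collection)))
  if (nC > 0L) {
    for (j in seq_len(M)) {
      track <- collection@tracks[[j]]
      for (k in seq_len(nC)) {
        s <- peaks$strand[k]
        i <- peaks$position[k]
        Lmat[k, j] <- if (s == "+") profile@LPlus[i, j] else profile@LMinus[i, j]
        fit <- estimateNullNB(track, i, s, params)
        pRaw[k, j] <- peakPvalue(Lmat[k, j], fit, params@minReads)
      }
    }
  }
  pCorr <- if (nC == 0L) pRaw else apply(pRaw, 2L, correctPvalues, nTests = nC)
  if (nC == 1L) pCorr <- matrix(pCorr, 1L, M, dimnames = dimnames(pRaw))
  rbar <- ifelse(peaks$strand == "+",
                 profile@RBarPlus[peaks$position],
                 profile@RBarMinus[peaks$position])
  nSig <- if (nC) rowSums(pCorr <= params@alpha) else integer()
  sel <- if (nC) selectTermini(peaks, pCorr, rbar, params, M) else logical()
  if (verbose)
    message("tests per library: ", nC, "; selected termini: ", sum(sel))
  gr <- GenomicRanges::GRanges(
    seqnames = rep(g@name, nC),
    ranges = IRanges::IRanges(start = peaks$position, width = 1L),
    strand = peaks$strand,
    seqinfo = GenomeInfoDb::Seqinfo(seqnames = g@name, seqlengths = g@length,
                                    isCircular = g@circular))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    RBar = as.numeric(rbar), L = I(Lmat), pRaw = I(pRaw),
    pCorrected = I(pCorr), nSignificant = as.integer(nSig),
    selected = as.logical(sel),
    classLabel = rep(NA_character_, nC),
    assignedGene = rep(NA_character_, nC))
  sort(gr)
}
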