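#' Match two terminus sets within a distance cutoff
#'
#' Pairs query termini with reference termini at most `maxDist` nt apart on
#' the same strand. Matching is one-to-one and greedy by increasing distance;
#' among equidistant alternatives the 5'-most reference terminus on the
#' strand wins. `k` is the number of matched query termini.
#'
#' @param query,reference data.frames with `position` and `strand` columns
#'   (duplicate (position, strand) pairs are not allowed).
#' @param maxDist maximal pairing distance in nt (default 10).
#' @return List with `pairs` (data.frame: `queryIndex`, `referenceIndex`,
#'   `distance`) and `k`.
#' @examples
#' q <- data.frame(position = 100, strand = "+")
#' r <- data.frame(position = 110, strand = "+")
#' matchTermini(q, r)$k   # 1: exactly 10 nt apart
#' @export
matchTermini <- function(query, reference, maxDist = 10) {
  stopifnot(!anyDuplicated(query[c("position", "strand")]),
            !anyDuplicated(reference[c("position", "strand")]))
  pairs <- data.frame(queryIndex = integer(), referenceIndex = integer(),
                      distance = integer())
  if (nrow(query) && nrow(reference)) {
    qr <- IRanges::IRanges(start = query$position - maxDist,
                           end = query$position + maxDist)
    rr <- IRanges::IRanges(start = reference$position, width = 1L)
    hits <- IRanges::findOverlaps(qr, rr)
    qi <- S4Vectors::queryHits(hits)
    ri <- S4Vectors::subjectHits(hits)
    ok <- query$strand[qi] == reference$strand[ri]
    qi <- qi[ok]; ri <- ri[ok]
    if (length(qi)) {
      dist <- abs(query$position[qi] - reference$position[ri])
      fiveMost <- ifelse(reference$strand[ri] == "+",
                         reference$position[ri], -reference$position[ri])
      ord <- order(dist, fiveMost)
      usedQ <- logical(nrow(query)); usedR <- logical(nrow(reference))
      keep <- logical(length(ord))
      for (x in ord) {
        if (!usedQ[qi[x]] && !usedR[ri[x]]) {
          usedQ[qi[x]] <- TRUE; usedR[ri[x]] <- TRUE; keep[x] <- TRUE
        }
      }
      chosen <- which(keep)
      pairs <- data.frame(queryIndex = qi[chosen],
                          referenceIndex = ri[chosen],
                          distance = dist[chosen])
    }
  }
  list(pairs = pairs, k = nrow(pairs))
}

#' Size of the flanked reference footprint
#'
#' The number of genomic positions covered by the union of +-`flank` nt
#' windows around the reference termini (overlaps counted once), per strand,
#' summed over strands, clamped to the genome when one is supplied. This is
#' the `K` of the hypergeometric overlap test.
#'
#' @param reference data.frame with `position` and `strand`.
#' @param flank window half-width in nt (default 10).
#' @param genome optional [GenomeRef-class] for boundary clamping.
#' @return Integer number of covered positions.
#' @examples
#' referenceFootprint(data.frame(position = c(100, 105), strand = "+"))  # 26
#' @export
referenceFootprint <- function(reference, flank = 10, genome = NULL) {
  if (nrow(reference) == 0L) return(0L)
  total <- 0L
  for (s in unique(reference$strand)) {
    p <- reference$position[reference$strand == s]
    lo <- p - flank
    hi <- p + flank
    if (!is.null(genome)) {
      lo <- pmax(lo, 1L)
      hi <- pmin(hi, genome@length)
    }
    total <- total + sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = lo, end = hi))))
  }
  as.integer(total)
}

#' Hypergeometric overlap significance
#'
#' Upper-tail probability `P(X >= k)` of drawing at least `k` reference-
#' footprint positions when `n` termini are placed among `N` genomic
#' positions of which `K` belong to the flanked reference footprint.
#' Computed in log space, so overlaps whose probability underflows double
#' precision are still reported through `log10p`.
#'
#' @param N population size (genomic positions; both strands by default in
#'   [compareTerminusSets()]).
#' @param K reference footprint size.
#' @param n query set size.
#' @param k overlap count.
#' @return List with `p` and `log10p`.
#' @examples
#' overlapPvalue(20, 5, 4, 4)   # 5 / choose(20, 4)
#' @export
overlapPvalue <- function(N, K, n, k) {
  if (K > N || n > N || k > min(n, K) || any(c(N, K, n, k) < 0))
    stop("require 0 <= k <= min(n, K) and K, n <= N")
  log10p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE) / log(10)
  list(p = 10^log10p, log10p = log10p)
}

#' Compare a query terminus set against a reference set
#'
#' Convenience wrapper assembling the full overlap report: matches termini
#' within `maxDist` nt ([matchTermini()]), computes the flanked reference
#' footprint `K` ([referenceFootprint()]), and the hypergeometric
#' significance with population `N` equal to both strands of the genome
#' (termini are stranded).
#'
#' @param query,reference data.frames with `position`, `strand`.
#' @param genome a [GenomeRef-class].
#' @param maxDist match distance (default 10).
#' @param flank footprint flank (default 10).
#' @param bothStrands count the population over both strands (default TRUE).
#' @return List with `k`, `n`, `K`, `N`, `p`, `log10p`, `pairs`.
#' @export
compareTerminusSets <- function(query, reference, genome, maxDist = 10,
                                flank = 10, bothStrands = TRUE) {
  m <- matchTermini(query, reference, maxDist)
  K <- referenceFootprint(reference, flank, genome)
  N <- (if (bothStrands) 2L else 1L) * genome@length
  pv <- overlapPvalue(N, K, nrow(query), m$k)
  c(list(k = m$k, n = nrow(query), K = K, N = N, pairs = m$pairs), pv)
}

#' Precision and sensitivity of a terminus set against references
#'
#' Precision is the fraction of query termini matched (within `maxDist` nt,
#' same strand) by at least one of the reference sets; sensitivity is the
#' fraction of a designated reference set matched by the query. When the
#' query carries class labels, the same metrics are also reported for the
#' primary-group classes (Primary, AP, DP, AP in TU).
#'
#' @param query data.frame with `position`, `strand`, optional `classLabel`.
#' @param references a single data.frame or list of data.frames.
#' @param maxDist match distance (default 10).
#' @param sensitivityReference index of the reference used for sensitivity
#'   (default 1).
#' @return List with `precision`, `sensitivity`, counts, and - when class
#'   labels are present - `primary` (the same fields for the primary group).
#' @export
precisionSensitivity <- function(query, references, maxDist = 10,
                                 sensitivityReference = 1) {
  if (is.data.frame(references)) references <- list(references)
  supported <- rep(FALSE, nrow(query))
  for (ref in references) {
    m <- matchTermini(query, ref, maxDist)
    supported[m$pairs$queryIndex] <- TRUE
  }
  sref <- references[[sensitivityReference]]
  ms <- matchTermini(sref, query, maxDist)
  out <- list(
    nQuery = nrow(query), nSupported = sum(supported),
    precision = if (nrow(query)) sum(supported) / nrow(query) else NA_real_,
    nReference = nrow(sref), nRecovered = ms$k,
    sensitivity = if (nrow(sref)) ms$k / nrow(sref) else NA_real_)
  if ("classLabel" %in% names(query)) {
    primaryClasses <- c("Primary", "AP", "DP", "AP_in_TU")
    sel <- query$classLabel %in% primaryClasses
    out$primary <- list(
      nQuery = sum(sel), nSupported = sum(supported[sel]),
      precision = if (any(sel)) sum(supported[sel]) / sum(sel) else NA_real_)
  }
  out
}

#' Worked precision ratio
#'
#' Turns a supported/total count pair into the percentage reported in
#' performance tables, rounded to a whole percent.
#'
#' @param nSupported,nTotal counts.
#' @return Percentage (0-100, integer-rounded).
#' @examples
#' precisionPercent(1613, 1814)   # 89
#' precisionPercent(841, 876)     # 96
#' @export
precisionPercent <- function(nSupported, nTotal)
  round(100 * nSupported / nTotal)
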