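#' Build an annotation database from feature and transcription-unit tables
#'
#' Normalises a gene table (CDS/ncRNA/rRNA/tRNA features) and a
#' transcription-unit table into the database the terminus classifier
#' consumes. Genes absent from every listed TU are treated as implicit
#' single-gene units. Missing `stopCodonEnd` values for CDS features default
#' to the 3'-most coordinate of the feature (its end on `+`, start on `-`);
#' `utr5Start` and `documentedTerminus` are optional and `NA` when unknown.
#'
#' @param genome a [GenomeRef-class].
#' @param genes data.frame with at least `geneId`, `type`, `start`, `end`,
#'   `strand`; optional `name`, `stopCodonEnd`, `utr5Start`,
#'   `documentedTerminus`.
#' @param tus data.frame with `tuId`, `strand` and a `members` list column of
#'   ordered (5' to 3') gene ids; may be `NULL` or empty.
#' @return An [AnnotationDB-class].
#' @export
annotationDB <- function(genome, genes, tus = NULL) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  req <- c("geneId", "type", "start", "end", "strand")
  if (!all(req %in% names(genes)))
    stop("gene table must have columns: ", paste(req, collapse = ", "))
  if (any(genes$start > genes$end)) stop("gene start must be <= end")
  if (any(genes$start < 1L | genes$end > genome@length))
    stop("gene coordinates outside the genome")
  if (!"name" %in% names(genes)) genes$name <- genes$geneId
  if (!"stopCodonEnd" %in% names(genes)) genes$stopCodonEnd <- NA_integer_
  if (!"utr5Start" %in% names(genes)) genes$utr5Start <- NA_integer_
  if (!"documentedTerminus" %in% names(genes))
    genes$documentedTerminus <- NA_integer_
  isCDS <- genes$type == "CDS"
  fill <- isCDS & is.na(genes$stopCodonEnd)
  genes$stopCodonEnd[fill] <- ifelse(genes$strand[fill] == "+",
                                     genes$end[fill], genes$start[fill])
  if (is.null(tus) || nrow(tus) == 0L)
    tus <- data.frame(tuId = character(), strand = character(),
                      members = I(list()), stringsAsFactors = FALSE)
  tus <- as.data.frame(tus, stringsAsFactors = FALSE)
  known <- unlist(tus$members, use.names = FALSE)
  if (length(known) && !all(known %in% genes$geneId))
    stop("TU member gene(s) not in the gene table: ",
         paste(setdiff(known, genes$geneId), collapse = ", "))
  orphanGenes <- setdiff(genes$geneId, known)
  if (length(orphanGenes)) {
    implicit <- data.frame(tuId = paste0("tu_", orphanGenes),
                           strand = genes$strand[match(orphanGenes, genes$geneId)],
                           stringsAsFactors = FALSE)
    implicit$members <- as.list(orphanGenes)
    tus <- rbind(tus[, c("tuId", "strand", "members")], implicit)
  }
  # 3'-most genomic coordinate of each TU: the 3' end of its last gene
  lastGene <- vapply(tus$members, function(m) m[[length(m)]], character(1))
  li <- match(lastGene, genes$geneId)
  tus$tuEnd <- ifelse(tus$strand == "+", genes$end[li], genes$start[li])
  # gene-level flags used by the classifier
  genes$lastInAll <- TRUE
  genes$nonLastInAny <- FALSE
  for (g in seq_len(nrow(genes))) {
    id <- genes$geneId[g]
    inTU <- vapply(tus$members, function(m) id %in% m, logical(1))
    isLast <- vapply(tus$members[inTU],
                     function(m) m[[length(m)]] == id, logical(1))
    genes$lastInAll[g] <- all(isLast)
    genes$nonLastInAny[g] <- any(!isLast)
  }
  new("AnnotationDB", genome = genome, genes = genes, tus = tus)
}

#' Load annotation from a GFF3 file and a transcription-unit table
#'
#' Reads CDS, ncRNA, rRNA and tRNA features from a GFF3 file (gene ids taken
#' from the `ID`, `locus_tag` or `gene_id` attribute, in that order of
#' preference; optional `utr5_start` / `documented_terminus` attributes are
#' honoured) and an optional TU table, a tab-separated file with columns
#' `tu_id`, `strand`, and a comma-separated ordered gene list. Additional
#' columns (e.g. promoters) are accepted and ignored.
#'
#' @param gffPath path to a GFF3 file.
#' @param tuPath path to the TU table, or `NULL`.
#' @param genome a [GenomeRef-class].
#' @return An [AnnotationDB-class].
#' @export
loadAnnotation <- function(gffPath, tuPath = NULL, genome) {
  gr <- rtracklayer::import(gffPath, format = "gff3")
  gr <- gr[as.character(gr$type) %in% c("CDS", "ncRNA", "rRNA", "tRNA")]
  meta <- S4Vectors::mcols(gr)
  pick <- function(...) {
    out <- rep(NA_character_, length(gr))
    for (col in c(...))
      if (col %in% names(meta)) {
        v <- as.character(meta[[col]])
        out[is.na(out) & !is.na(v)] <- v[is.na(out) & !is.na(v)]
      }
    out
  }
  ids <- pick("ID", "locus_tag", "gene_id")
  if (anyNA(ids))
    ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
  numAttr <- function(col)
    if (col %in% names(meta)) suppressWarnings(as.integer(as.character(meta[[col]])))
    else rep(NA_integer_, length(gr))
  genes <- data.frame(
    geneId = ids,
    name = if ("Name" %in% names(meta)) as.character(meta$Name) else ids,
    type = as.character(meta$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    utr5Start = numAttr("utr5_start"),
    documentedTerminus = numAttr("documented_terminus"),
    stringsAsFactors = FALSE)
  tus <- NULL
  if (!is.null(tuPath)) {
    tt <- read.delim(tuPath, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tt) < 3L) stop("TU table must have >= 3 tab-separated columns")
    tus <- data.frame(tuId = as.character(tt[[1L]]),
                      strand = as.character(tt[[2L]]),
                      stringsAsFactors = FALSE)
    tus$members <- strsplit(as.character(tt[[3L]]), ",", fixed = TRUE)
  }
  annotationDB(genome, genes, tus)
}

# Strand-aware signed distance from a reference 3' coordinate to a position:
# positive downstream of it, negative upstream.
.downstreamDist <- function(position, ref3, strand)
  (position - ref3) * ifelse(strand == "+", 1, -1)

# Classify one terminus; `others` are the remaining call positions on the
# same strand (used by the AP-vs-DP distinction).
.classifyOne <- function(position, strand, db, tol, others) {
  genes <- db@genes
  same <- genes$strand == strand
  isCDS <- genes$type == "CDS"
  isNC <- genes$type %in% c("ncRNA", "rRNA", "tRNA")
  ref3 <- ifelse(isCDS, genes$stopCodonEnd,
                 ifelse(genes$strand == "+", genes$end, genes$start))
  dd <- .downstreamDist(position, ref3, genes$strand)

  # (iv) AP in TU: <= 250 nt downstream of a non-last gene, not beyond the
  # 3' end of its longest containing TU
  cand <- which(same & genes$nonLastInAny & dd >= -tol & dd <= 250 + tol)
  for (g in cand) {
    id <- genes$geneId[g]
    inTU <- vapply(db@tus$members, function(m) id %in% m, logical(1)) &
      vapply(db@tus$members, function(m) m[[length(m)]] != id, logical(1))
    tuEnds <- db@tus$tuEnd[inTU]
    if (!length(tuEnds)) next
    cap <- if (strand == "+") max(tuEnds) else min(tuEnds)
    beyond <- .downstreamDist(position, cap, strand)
    if (beyond <= tol)
      return(list(label = "AP_in_TU", gene = id))
  }

  # (i) Primary: within the 3' UTR up to a documented terminator; or <= 100
  # nt downstream of the stop codon of a gene last in all its TUs; for
  # non-coding RNAs, at the documented 3' end
  prim <- which(same & isCDS & genes$lastInAll &
                  !is.na(genes$documentedTerminus) &
                  dd >= -tol &
                  .downstreamDist(position, genes$documentedTerminus,
                                  genes$strand) <= tol)
  if (length(prim)) return(list(label = "Primary", gene = genes$geneId[prim[1L]]))
  prim <- which(same & isCDS & genes$lastInAll & dd >= -tol & dd <= 100 + tol)
  if (length(prim)) return(list(label = "Primary", gene = genes$geneId[prim[1L]]))
  prim <- which(same & isNC & abs(dd) <= tol)
  if (length(prim)) return(list(label = "Primary", gene = genes$geneId[prim[1L]]))

  # (v) Internal: within a CDS, or premature within a non-coding RNA
  int <- which(same & (isCDS | isNC) &
                 position >= genes$start - tol & position <= genes$end + tol)
  if (length(int)) return(list(label = "Internal", gene = genes$geneId[int[1L]]))

  # (vi) Premature in 5' UTR (estimated as <= 100 nt upstream of the start
  # codon when undocumented)
  for (g in which(same & isCDS)) {
    if (genes$strand[g] == "+") {
      lo <- if (!is.na(genes$utr5Start[g])) genes$utr5Start[g]
            else genes$start[g] - 100L
      hi <- genes$start[g] - 1L
    } else {
      lo <- genes$end[g] + 1L
      hi <- if (!is.na(genes$utr5Start[g])) genes$utr5Start[g]
            else genes$end[g] + 100L
    }
    if (position >= lo - tol && position <= hi + tol)
      return(list(label = "Premature_5UTR", gene = genes$geneId[g]))
  }

  # (ii) AP / (iii) DP: 101-200 nt downstream of the stop codon of a
  # last-in-all-TUs gene; AP when another call sits in the first 100 nt
  far <- which(same & isCDS & genes$lastInAll & dd >= 101 - tol & dd <= 200 + tol)
  if (length(far)) {
    g <- far[1L]
    dOthers <- .downstreamDist(others, ref3[g], strand)
    hasNear <- any(dOthers >= -tol & dOthers <= 100 + tol)
    return(list(label = if (hasNear) "AP" else "DP", gene = genes$geneId[g]))
  }

  # (vii) Orphan antisense / (viii) orphan intergenic
  anti <- which(!same & position >= genes$start - tol & position <= genes$end + tol)
  if (length(anti)) return(list(label = "Orphan_AS", gene = genes$geneId[anti[1L]]))
  list(label = "Orphan_IGR", gene = NA_character_)
}

#' Classify termini against gene and transcription-unit annotation
#'
#' Assigns each terminus one of eight classes by its genomic position
#' relative to genes and transcription units, with a +-`tolerance` slack on
#' every class-boundary test, evaluated in the fixed priority order:
#' AP in TU, Primary, Internal, Premature 5' UTR, AP, DP, Orphan antisense,
#' Orphan intergenic. The AP-vs-DP distinction (a terminus 101-200 nt past a
#' stop codon with vs without a companion call in the first 100 nt) looks at
#' the other calls in the same input set.
#'
#' @param calls a `GRanges` of terminus calls (as from [runTRS()]), or a
#'   data.frame with `position` and `strand` columns.
#' @param db an [AnnotationDB-class].
#' @param tolerance boundary slack in nt (default 5).
#' @return The input with `classLabel` and `assignedGene` filled in.
#' @export
classifyTermini <- function(calls, db, tolerance = 5) {
  isGR <- is(calls, "GRanges")
  pos <- if (isGR) GenomicRanges::start(calls) else calls$position
  strand <- if (isGR) as.character(GenomicRanges::strand(calls)) else calls$strand
  # companion termini for the AP-vs-DP rule: only members of the final set
  # when a selection flag is present (unselected candidates are not termini)
  inSet <- if (!is.null(calls$selected)) calls$selected else rep(TRUE, length(pos))
  labels <- character(length(pos))
  genesOut <- character(length(pos))
  for (k in seq_along(pos)) {
    others <- pos[strand == strand[k] & inSet]
    others <- others[others != pos[k]]
    cl <- .classifyOne(pos[k], strand[k], db, tolerance, others)
    labels[k] <- cl$label
    genesOut[k] <- cl$gene
  }
  if (isGR) {
    calls$classLabel <- labels
    calls$assignedGene <- genesOut
  } else {
    calls$classLabel <- labels
    calls$assignedGene <- genesOut
  }
  calls
}

#' Remove termini associated with structural RNAs
#'
#' In `dataset_final` mode (trimming the final terminus set), calls inside
#' rRNA or tRNA genes on the same strand are removed - ribosomal-RNA
#' depletion distorts the read distribution there and structural-RNA termini
#' are excluded from the reported set. In `comparison` mode (preparing sets
#' for cross-dataset overlap), the filter is positional and stricter: any
#' call within an rRNA-operon span extended by +-`flank` nt, or within a
#' tRNA gene, is removed regardless of strand. rRNA operons are the
#' transcription units containing at least one rRNA gene (an rRNA gene in no
#' TU counts as its own operon).
#'
#' @param calls a `GRanges` or data.frame of calls (see [classifyTermini()]).
#' @param db an [AnnotationDB-class].
#' @param flank comparison-mode flank in nt (default 100).
#' @param mode `"dataset_final"` or `"comparison"`.
#' @return The filtered calls.
#' @export
filterStructural <- function(calls, db, flank = 100,
                             mode = c("dataset_final", "comparison")) {
  mode <- match.arg(mode)
  isGR <- is(calls, "GRanges")
  pos <- if (isGR) GenomicRanges::start(calls) else calls$position
  strand <- if (isGR) as.character(GenomicRanges::strand(calls)) else calls$strand
  genes <- db@genes
  drop <- rep(FALSE, length(pos))
  if (mode == "dataset_final") {
    for (g in which(genes$type %in% c("rRNA", "tRNA")))
      drop <- drop | (strand == genes$strand[g] &
                        pos >= genes$start[g] & pos <= genes$end[g])
  } else {
    rgenes <- which(genes$type == "rRNA")
    operon <- rep(FALSE, nrow(db@tus))
    if (length(rgenes)) {
      rIds <- genes$geneId[rgenes]
      operon <- vapply(db@tus$members, function(m) any(rIds %in% m), logical(1))
    }
    for (t in which(operon)) {
      m <- db@tus$members[[t]]
      gi <- match(m, genes$geneId)
      lo <- min(genes$start[gi]) - flank
      hi <- max(genes$end[gi]) + flank
      drop <- drop | (pos >= lo & pos <= hi)
    }
    for (g in which(genes$type == "tRNA"))
      drop <- drop | (pos >= genes$start[g] & pos <= genes$end[g])
  }
  if (isGR) calls[!drop] else calls[!drop, , drop = FALSE]
}
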