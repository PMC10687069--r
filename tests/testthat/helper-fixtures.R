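# Shared helpers: toy tracks, annotation tables, SAM record builders.

toyGenome <- function(len = 1000, circular = FALSE, name = "toy")
  genomeRef(name, len, circular)

# track with named counts, e.g. toyTrack(g, plus = c(`100` = 5))
toyTrack <- function(genome, plus = NULL, minus = NULL, id = "lib") {
  cp <- integer(genomeLength(genome))
  cm <- integer(genomeLength(genome))
  if (!is.null(plus)) cp[as.integer(names(plus))] <- as.integer(plus)
  if (!is.null(minus)) cm[as.integer(names(minus))] <- as.integer(minus)
  readStartTrack(genome, id, cp, cm)
}

randomTrack <- function(genome, lambda = 2, id = "lib") {
  n <- genomeLength(genome)
  readStartTrack(genome, id, rpois(n, lambda), rpois(n, lambda))
}

# Annotation: one last-in-TU CDS gene plus companions used across tests.
toyAnnotation <- function(genome = toyGenome(6000)) {
  genes <- data.frame(
    geneId = c("lastA", "opB1", "opB2", "ncr", "trn", "rrl"),
    type = c("CDS", "CDS", "CDS", "ncRNA", "tRNA", "rRNA"),
    start = c(1001L, 2501L, 3101L, 4001L, 4501L, 5001L),
    end = c(2000L, 3000L, 3700L, 4100L, 4580L, 5500L),
    strand = c("+", "+", "+", "+", "+", "+"),
    stringsAsFactors = FALSE)
  tus <- data.frame(tuId = c("opB", "rrnOp"), strand = "+",
                    stringsAsFactors = FALSE)
  tus$members <- list(c("opB1", "opB2"), "rrl")
  annotationDB(genome, genes, tus)
}

# Minimal single-reference SAM text; records are c(qname, flag, pos, cigar, seq)
samText <- function(records, genomeName = "toy", genomeLen = 2000) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", genomeName, "\tLN:", genomeLen))
  body <- vapply(records, function(r) {
    paste(r$qname, r$flag, genomeName, r$pos, r$mapq %||% 60, r$cigar,
          r$rnext %||% "*", r$pnext %||% 0, r$tlen %||% 0, r$seq,
          strrep("I", nchar(r$seq)), sep = "\t")
  }, character(1))
  c(header, body)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeSam <- function(records, ...) {
  path <- tempfile(fileext = ".sam")
  writeLines(samText(records, ...), path)
  path
}

# Profile built directly from crafted per-strand RBar / L-sum vectors
# (libraries all identical), for exercising the peak caller in isolation.
craftProfile <- function(genome, rbarPlus, lPlus = rbarPlus * 100,
                         rbarMinus = rep(0, genomeLength(genome)),
                         lMinus = rbarMinus * 100,
                         params = trsParams()) {
  n <- genomeLength(genome)
  new("ReadthroughProfile", genome = genome, libraryIds = "lib1",
      params = params,
      RPlus = matrix(rbarPlus, n, 1), RMinus = matrix(rbarMinus, n, 1),
      RBarPlus = rbarPlus, RBarMinus = rbarMinus,
      LPlus = matrix(lPlus, n, 1), LMinus = matrix(lMinus, n, 1))
}

# A small expression panel: nGenes single-gene units on a common layout,
# CDS 200 nt + 50 nt 3' UTR, terminus at the UTR end; per-gene CDS level
# cdsLevel[i] and UTR level utrLevel[i] written as flat counts.
expressionPanel <- function(cdsLevel, utrLevel, nLibs = 3,
                            perturb = NULL) {
  nGenes <- length(cdsLevel)
  g <- genomeRef("panel", nGenes * 300L, circular = FALSE)
  genes <- data.frame(geneId = paste0("g", seq_len(nGenes)), type = "CDS",
                      start = (seq_len(nGenes) - 1L) * 300L + 1L,
                      end = (seq_len(nGenes) - 1L) * 300L + 200L,
                      strand = "+", stringsAsFactors = FALSE)
  db <- annotationDB(g, genes)
  tracks <- lapply(seq_len(nLibs), function(j) {
    counts <- integer(genomeLength(g))
    for (i in seq_len(nGenes)) {
      u <- utrLevel[i]
      if (!is.null(perturb) && perturb$lib == j && perturb$gene == i)
        u <- perturb$utr
      counts[genes$start[i]:genes$end[i]] <- cdsLevel[i]
      counts[(genes$end[i] + 1L):(genes$end[i] + 50L)] <- u
    }
    readStartTrack(g, paste0("lib", j), counts, integer(genomeLength(g)))
  })
  calls <- data.frame(position = genes$end + 50L, strand = "+",
                      classLabel = "Primary", assignedGene = genes$geneId,
                      stringsAsFactors = FALSE)
  list(db = db, collection = libraryCollection(tracks), calls = calls,
       genes = genes)
}
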