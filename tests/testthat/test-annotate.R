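test_that("annotation loading builds TUs and implicit single-gene units", {
  g <- toyGenome(6000)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "toy\tsrc\tCDS\t1001\t2000\t.\t+\t.\tID=gA;Name=gA",
               "toy\tsrc\tCDS\t2501\t3000\t.\t+\t.\tID=gB1",
               "toy\tsrc\tCDS\t3101\t3700\t.\t+\t.\tID=gB2",
               "toy\tsrc\tCDS\t4001\t4600\t.\t+\t.\tID=gB3",
               "toy\tsrc\ttRNA\t5001\t5080\t.\t-\t.\tID=tr1"), gff)
  tu <- tempfile(fileext = ".tsv")
  writeLines("opB\t+\tgB1,gB2,gB3", tu)
  db <- loadAnnotation(gff, tu, g)
  expect_equal(nrow(db@genes), 5)
  # explicit 3-gene operon kept in order; others become singleton units
  opB <- db@tus[db@tus$tuId == "opB", ]
  expect_equal(opB$members[[1]], c("gB1", "gB2", "gB3"))
  expect_equal(nrow(db@tus), 3)          # opB + 2 implicit singletons
  expect_true(db@genes$lastInAll[db@genes$geneId == "gA"])
  expect_true(db@genes$nonLastInAny[db@genes$geneId == "gB1"])
  expect_false(db@genes$lastInAll[db@genes$geneId == "gB2"])
  expect_true(db@genes$lastInAll[db@genes$geneId == "gB3"])
  # stop codon end defaults to the 3'-most CDS base
  expect_equal(db@genes$stopCodonEnd[db@genes$geneId == "gA"], 2000)
  # a TU naming an unknown gene is rejected
  tuBad <- tempfile(fileext = ".tsv")
  writeLines("opX\t+\tgB1,missing", tuBad)
  expect_error(loadAnnotation(gff, tuBad, g), "missing")
  # malformed GFF is rejected
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "toy\tonly\tthree"), bad)
  expect_error(loadAnnotation(bad, NULL, g))
})

test_that("class assignment follows the eight-class priority scheme", {
  db <- toyAnnotation()
  cls <- function(pos, strand = "+", others = data.frame()) {
    calls <- rbind(data.frame(position = pos, strand = strand),
                   others)
    classifyTermini(calls, db)[1, ]
  }
  # 50 nt past the stop codon of a last-in-TU gene: Primary
  expect_equal(cls(2050)$classLabel, "Primary")
  expect_equal(cls(2050)$assignedGene, "lastA")
  # 150 nt past, no companion call in the first 100 nt: Distant Primary
  expect_equal(cls(2150)$classLabel, "DP")
  # same with a companion Primary call in the first 100 nt: Alternative Primary
  expect_equal(cls(2150, others = data.frame(position = 2050, strand = "+"))$classLabel,
               "AP")
  # inside a CDS on the same strand: Internal
  expect_equal(cls(1500)$classLabel, "Internal")
  # inside a CDS on the opposite strand: Orphan antisense
  expect_equal(cls(1500, "-")$classLabel, "Orphan_AS")
  # within 100 nt upstream of a start codon: premature in the 5' UTR
  expect_equal(cls(950)$classLabel, "Premature_5UTR")
  # downstream of a non-last operon gene, within the TU: AP in TU
  expect_equal(cls(3050)$classLabel, "AP_in_TU")
  expect_equal(cls(3050)$assignedGene, "opB1")
  # past the TU end it is no longer AP in TU
  expect_equal(cls(3760)$classLabel, "Primary")   # 60 nt past opB2's stop
  # at the documented 3' end of an ncRNA: Primary
  expect_equal(cls(4100)$classLabel, "Primary")
  expect_equal(cls(4050)$classLabel, "Internal")  # premature within the ncRNA
  # far from everything: Orphan intergenic
  expect_equal(cls(5900)$classLabel, "Orphan_IGR")
})

test_that("every position receives exactly one class (total function)", {
  db <- toyAnnotation()
  set.seed(3)
  pos <- sample.int(6000, 200)
  strand <- sample(c("+", "-"), 200, replace = TRUE)
  out <- classifyTermini(data.frame(position = pos, strand = strand), db)
  valid <- c("Primary", "AP", "DP", "AP_in_TU", "Internal",
             "Premature_5UTR", "Orphan_AS", "Orphan_IGR")
  expect_true(all(out$classLabel %in% valid))
  expect_equal(length(out$classLabel), 200)
})

test_that("growing the tolerance never demotes a call to a lower-priority class", {
  db <- toyAnnotation()
  priority <- c(AP_in_TU = 1, Primary = 2, Internal = 3, Premature_5UTR = 4,
                AP = 5, DP = 6, Orphan_AS = 7, Orphan_IGR = 8)
  set.seed(9)
  pos <- sample.int(6000, 150)
  strand <- sample(c("+", "-"), 150, replace = TRUE)
  calls <- data.frame(position = pos, strand = strand)
  ranks <- sapply(c(0, 2, 5, 10, 20), function(tol)
    priority[classifyTermini(calls, db, tolerance = tol)$classLabel])
  expect_true(all(apply(ranks, 1, function(r) all(diff(r) <= 0))))
})

test_that("distant annotation on either strand does not change a call's class", {
  db <- toyAnnotation()
  before <- classifyTermini(data.frame(position = 2050, strand = "+"), db)
  genes2 <- rbind(db@genes[, c("geneId", "type", "start", "end", "strand")],
                  data.frame(geneId = "far", type = "CDS", start = 5800,
                             end = 5950, strand = "-"))
  db2 <- annotationDB(db@genome, genes2, db@tus[db@tus$tuId %in% c("opB", "rrnOp"),
                                                c("tuId", "strand", "members")])
  after <- classifyTermini(data.frame(position = 2050, strand = "+"), db2)
  expect_equal(after$classLabel, before$classLabel)
})

test_that("structural-RNA filtering distinguishes final-set and comparison modes", {
  db <- toyAnnotation()
  calls <- data.frame(
    position = c(4540,   # inside the tRNA
                 5550,   # 50 nt downstream of the rRNA operon end
                 5650,   # 150 nt downstream of the rRNA operon
                 2050),  # ordinary terminus
    strand = "+")
  final <- filterStructural(calls, db, mode = "dataset_final")
  expect_equal(final$position, c(5550, 5650, 2050))
  comp <- filterStructural(calls, db, mode = "comparison")
  expect_equal(comp$position, c(5650, 2050))
  # comparison mode is positional: an antisense call near the rRNA also goes
  anti <- data.frame(position = 5550, strand = "-")
  expect_equal(nrow(filterStructural(anti, db, mode = "comparison")), 0)
  expect_equal(nrow(filterStructural(anti, db, mode = "dataset_final")), 1)
})
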