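test_that("interval means of read starts match a direct loop", {
  g <- toyGenome(500)
  tr <- toyTrack(g, plus = setNames(c(0, 0, 6), 101:103))
  expect_equal(regionMeanReadStarts(tr, 101, 103, "+"), 2)
  flat <- readStartTrack(g, "f", rep(4L, 500), integer(500))
  expect_equal(regionMeanReadStarts(flat, 17, 401, "+"), 4)
  set.seed(12)
  rnd <- randomTrack(g)
  for (iv in list(c(1, 1), c(10, 50), c(450, 500))) {
    expect_equal(regionMeanReadStarts(rnd, iv[1], iv[2], "-"),
                 mean(vapply(iv[1]:iv[2], function(i)
                   rnd@countsMinus[i], integer(1))))
  }
  expect_error(regionMeanReadStarts(rnd, 50, 10, "+"), "empty interval")
})

test_that("UTR/CDS regression flags the planted outlier and only it", {
  lv <- as.integer(round(2^(seq(1, 7, length.out = 18))))
  # collinear in log space: UTR = CDS / 2 for all genes but one
  utr <- pmax(1L, lv %/% 2L)
  utrOut <- utr
  utrOut[7] <- lv[7] * 100L                 # 3' UTR-derived sRNA candidate
  panel <- expressionPanel(lv, utrOut)
  rep <- utrCdsOutliers(panel$calls, panel$db, panel$collection)
  expect_equal(rep$geneId[rep$flagged], "g7")
  expect_equal(rep$direction[rep$flagged], "UTR_high")
  # perfectly collinear (UTR level = CDS level exactly): nothing flagged
  clean <- expressionPanel(lv, lv)
  repClean <- utrCdsOutliers(clean$calls, clean$db, clean$collection)
  expect_false(any(repClean$flagged))
  # deviation in a single library is not enough
  oneLib <- expressionPanel(lv, lv,
                            perturb = list(lib = 1, gene = 7, utr = lv[7] * 100L))
  repOne <- utrCdsOutliers(oneLib$calls, oneLib$db, oneLib$collection)
  expect_false(any(repOne$flagged))
  # CDS-high direction
  cdsHigh <- utr
  cdsHigh[3] <- 1L
  lv2 <- lv; lv2[3] <- 120L
  panel2 <- expressionPanel(lv2, cdsHigh)
  rep2 <- utrCdsOutliers(panel2$calls, panel2$db, panel2$collection)
  if (any(rep2$flagged))
    expect_true(all(rep2$direction[rep2$flagged] == "CDS_high"))
  expect_error(utrCdsOutliers(panel$calls[1:2, ], panel$db, panel$collection),
               "at least 3 genes")
})

test_that("outlier flags are invariant to library relabelling", {
  lv <- as.integer(round(2^(seq(1, 7, length.out = 15))))
  utr <- pmax(1L, lv %/% 2L)
  utr[4] <- lv[4] * 80L
  panel <- expressionPanel(lv, utr)
  rep1 <- utrCdsOutliers(panel$calls, panel$db, panel$collection)
  shuffled <- libraryCollection(panel$collection@tracks[c(3, 1, 2)])
  rep2 <- utrCdsOutliers(panel$calls, panel$db, shuffled)
  expect_equal(rep1$flagged, rep2$flagged)
  expect_equal(rep1$geneId, rep2$geneId)
})

test_that("Cook's distances equal the leave-one-out refit oracle", {
  lv <- as.integer(round(2^(seq(1, 6, length.out = 12))))
  utr <- pmax(1L, lv %/% 3L)
  utr[5] <- lv[5] * 40L
  panel <- expressionPanel(lv, utr, nLibs = 1)
  rep <- utrCdsOutliers(panel$calls, panel$db, panel$collection,
                        minLibraries = 1)
  x <- log10(rep$cdsMean.lib1 + 0.01)
  y <- log10(rep$utrMean.lib1 + 0.01)
  fit <- lm(y ~ x)
  s2 <- sum(residuals(fit)^2) / (length(y) - 2)
  oracle <- vapply(seq_along(y), function(i) {
    fitI <- lm(y[-i] ~ x[-i])
    yhatI <- cbind(1, x) %*% coef(fitI)
    sum((fitted(fit) - yhatI)^2) / (2 * s2)
  }, numeric(1))
  expect_equal(unname(rep$cooks.lib1), oracle, tolerance = 1e-8)
})

test_that("condition deltas rank premature termini and are antisymmetric", {
  g <- toyGenome(100)
  mkProf <- function(r) {
    v <- rep(0, 100); v[c(10, 20, 30)] <- r
    craftProfile(g, v, lPlus = rep(100, 100))
  }
  pA <- mkProf(c(0.9, 0.5, 0.30))
  pB <- mkProf(c(0.1, 0.4, 0.25))
  genes <- data.frame(geneId = c("gc", "gr"), type = c("CDS", "rRNA"),
                      start = c(5L, 60L), end = c(35L, 90L), strand = "+",
                      stringsAsFactors = FALSE)
  db <- annotationDB(g, genes)
  calls <- data.frame(position = c(10, 20, 30, 70), strand = "+",
                      classLabel = c("Internal", "Internal", "Premature_5UTR",
                                     "Internal"),
                      assignedGene = c("gc", "gc", "gc", "gr"),
                      stringsAsFactors = FALSE)
  out <- conditionDeltaReadthrough(pA, pB, calls, db, minCov = 20, minReps = 1)
  expect_equal(nrow(out), 3)            # the rRNA-assigned terminus excluded
  expect_equal(out$position[1], 10)     # largest |delta| first
  expect_equal(out$delta[1], 0.8)
  expect_identical(out$selected, c(TRUE, FALSE, FALSE))  # above median only
  # antisymmetry under condition swap
  swapped <- conditionDeltaReadthrough(pB, pA, calls, db, minCov = 20,
                                       minReps = 1)
  expect_equal(swapped$delta[order(swapped$position)],
               -out$delta[order(out$position)])
  # coverage rule: support below the threshold in one condition excludes
  pLow <- mkProf(c(0.9, 0.5, 0.3))
  pLow@LPlus[10, ] <- 10
  outLow <- conditionDeltaReadthrough(pLow, pB, calls, db, minCov = 20,
                                      minReps = 1)
  expect_false(10 %in% outLow$position)
  # degenerate: a single candidate is never above the median
  one <- calls[1, , drop = FALSE]
  outOne <- conditionDeltaReadthrough(pA, pB, one, db, minCov = 20, minReps = 1)
  expect_false(any(outOne$selected))
})

test_that("stop-codon distances carry the sign convention", {
  gene <- data.frame(geneId = "g", type = "CDS", start = 100, end = 400,
                     strand = "+", stopCodonEnd = 400)
  expect_equal(stopCodonDistance(450, "+", gene), 50)
  expect_equal(stopCodonDistance(400, "+", gene), 0)
  expect_equal(stopCodonDistance(370, "+", gene), -30)
  expect_error(stopCodonDistance(450, "-", gene), "different strands")
  geneM <- data.frame(geneId = "m", type = "CDS", start = 100, end = 400,
                      strand = "-", stopCodonEnd = 100)
  expect_equal(stopCodonDistance(50, "-", geneM), 50)   # downstream on minus
  expect_error(stopCodonDistance(50, "-",
                                 transform(geneM, type = "ncRNA")), "CDS")
})

test_that("flank profiles align sequences 5' to 3' on the transcript strand", {
  allA <- strrep("A", 200)
  prof <- flankProfile(allA, data.frame(position = 100, strand = "+"))
  expect_true(all(prof["A", ] == 1))
  expect_true(all(colSums(prof) == 1))
  # single terminus: 0/1 indicator of its flank
  sq <- paste(rep(c("A", "C", "G", "T"), 50), collapse = "")
  p1 <- flankProfile(sq, data.frame(position = 100, strand = "+"),
                     upstream = 3, downstream = 2)
  expect_true(all(p1 %in% c(0, 1)))
  expect_equal(substr(sq, 97, 102),
               paste(c("A", "C", "G", "U")[apply(p1, 2, which.max)],
                     collapse = "") |> chartr(old = "U", new = "T"))
  # poly-U tract downstream of minus-strand termini (genomic A upstream)
  sq2 <- strrep("G", 300)
  substr(sq2, 140, 149) <- strrep("A", 10)
  p2 <- flankProfile(sq2, data.frame(position = 150, strand = "-"),
                     upstream = 20, downstream = 10)
  expect_true(all(p2["U", as.character(1:10)] == 1))
  expect_true(all(p2["C", as.character(-20:0)] == 1))   # revcomp of G
  # flanks truncated by a linear genome end are excluded with a warning
  expect_warning(
    p3 <- flankProfile(allA, data.frame(position = c(5, 100), strand = "+")),
    "truncated")
  expect_true(all(colSums(p3) == 1))
})
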