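test_that("window counts honour window sizes, strand and wrap-around", {
  g <- toyGenome(200)
  tr <- toyTrack(g, plus = c(`100` = 12))
  wc <- windowCounts(tr, 100, "+")
  expect_equal(wc$L, 12)
  expect_equal(wc$Dcount, 0)

  uni <- readStartTrack(g, "u", rep(1L, 200), rep(1L, 200))
  wc <- windowCounts(uni, 100, "+")
  expect_equal(wc$L, 7)       # 2W+1 positions
  expect_equal(wc$Dcount, 67) # D positions
  # minus strand: downstream = decreasing coordinates
  wcm <- windowCounts(uni, 100, "-")
  expect_equal(wcm$L, 7)
  expect_equal(wcm$Dcount, 67)

  # circular wrap: count at position 1 enters the local window of i = 99
  gc <- toyGenome(100, circular = TRUE)
  tc <- toyTrack(gc, plus = c(`1` = 5))
  expect_equal(windowCounts(tc, 99, "+")$L, 5)
  # linear genome: same query sees nothing (zero padding)
  gl <- toyGenome(100, circular = FALSE)
  tl <- toyTrack(gl, plus = c(`1` = 5))
  expect_equal(windowCounts(tl, 99, "+")$L, 0)
  expect_error(windowCounts(tl, 101, "+"), "out of range")
})

test_that("readthrough statistic is bounded, supported and symmetric", {
  expect_equal(readthroughStatistic(12, 0), 1)      # no readthrough
  expect_equal(readthroughStatistic(7, 67), 0)      # below 10-read support
  expect_equal(readthroughStatistic(35, 35), 0.5)
  expect_equal(readthroughStatistic(0, 0, minReads = 0), 0)
  expect_error(readthroughStatistic(-1, 5), "non-negative")
  # property: bounded in [0,1]; 1 iff no downstream reads and supported
  set.seed(42)
  L <- rpois(500, 20); D <- rpois(500, 30)
  r <- readthroughStatistic(L, D)
  expect_true(all(r >= 0 & r <= 1))
  expect_identical(r == 1, D == 0 & L >= 10)
})

test_that("analytic null threshold matches the window-size ratio", {
  expect_equal(nullThreshold(3, 67), 7 / 74)
  expect_equal(round(nullThreshold(3, 67), 3), 0.095)
  expect_equal(nullThreshold(0, 1), 0.5)
  expect_equal(nullThreshold(1, 27), 0.1)
  expect_error(nullThreshold(3, 0), "downstream")
})

test_that("cross-library averaging matches a direct per-position recomputation", {
  g <- toyGenome(300)
  set.seed(7)
  tracks <- lapply(1:3, function(j) randomTrack(g, lambda = 3, id = paste0("l", j)))
  coll <- libraryCollection(tracks)
  prm <- trsParams()
  prof <- readthroughProfile(coll, prm)
  # independent oracle: single-position window counts + scalar statistic
  for (i in c(1, 2, 50, 150, 299, 300)) {
    for (s in c("+", "-")) {
      rs <- vapply(tracks, function(tr) {
        wc <- windowCounts(tr, i, s, prm)
        readthroughStatistic(wc$L, wc$Dcount, prm@minReads)
      }, numeric(1))
      expect_equal(rBar(prof, s)[i], mean(rs), tolerance = 1e-12)
    }
  }
  # idempotence: M identical libraries average to each library's R
  coll1 <- libraryCollection(tracks[c(1, 1, 1)])
  prof1 <- readthroughProfile(coll1, prm)
  expect_equal(prof1@RBarPlus, prof1@RPlus[, 1])
  # two libraries with R = 1 and 0 at a position average to 0.5
  t1 <- toyTrack(g, plus = c(`100` = 50))
  t0 <- toyTrack(g, plus = setNames(rep(3, 100), 101:200))
  prof2 <- readthroughProfile(libraryCollection(list(t1, t0)), prm)
  expect_equal(prof2@RPlus[100, 1], 1)   # spike, nothing downstream
  expect_equal(prof2@RPlus[100, 2], 0)   # local sum 9 < 10-read support
  expect_equal(prof2@RBarPlus[100], 0.5)
})

test_that("peak calling keeps thresholded local maxima with distance suppression", {
  g <- toyGenome(50)
  rbar <- rep(0, 50)
  rbar[20] <- 0.8
  pk <- callPeaks(craftProfile(g, rbar))
  expect_equal(pk$position, 20)
  expect_equal(pk$strand, "+")
  # all below threshold: empty
  expect_equal(nrow(callPeaks(craftProfile(g, rep(0.05, 50)))), 0)
  # two peaks 5 nt apart: the stronger (larger L) suppresses the weaker
  rbar2 <- rep(0, 50)
  rbar2[c(20, 25)] <- c(0.8, 0.6)
  pk2 <- callPeaks(craftProfile(g, rbar2))
  expect_equal(pk2$position, 20)
  # 10 nt apart: both survive (distance >= minPeakDistance)
  rbar3 <- rep(0, 50)
  rbar3[c(20, 30)] <- c(0.8, 0.6)
  expect_equal(callPeaks(craftProfile(g, rbar3))$position, c(20, 30))
  # exhaustive check of the suppression rule on a 20-nt toy vector
  rbar4 <- rep(0, 50)
  rbar4[11:30] <- c(0.2, 0.3, 0.25, 0, 0, 0.5, 0.45, 0, 0.44, 0,
                    0, 0, 0, 0, 0.41, 0, 0, 0, 0, 0.6)
  pk4 <- callPeaks(craftProfile(g, rbar4))
  # local maxima above T: 12, 16, 19, 25, 30; greedy by L (prop. to RBar):
  # 30 (0.6), 16 (0.5) kill 12/19/25 within 10 nt except 12 (|16-12|<10 kill),
  # 19 (<10 of 16, kill), 25 (<10 of 16 and 30, kill)
  expect_equal(pk4$position, c(16, 30))
})

test_that("null estimation fits moments and the summed law", {
  g <- toyGenome(300)
  prm <- trsParams(W = 3, D = 67)
  # constant downstream (variance 0): Poisson with L-mean 7 * 2
  tr <- toyTrack(g, plus = setNames(rep(2, 67), 104:170))
  fit <- estimateNullNB(tr, 100, "+", prm)
  expect_true(fit@poisson)
  expect_equal(fit@mean * fit@nLocal, 14)
  # m = 2, v = 4 -> p = 0.5, r = 2 per position; L ~ NB(14, 0.5)
  prm5 <- trsParams(W = 3, D = 5)
  tr2 <- toyTrack(g, plus = setNames(c(0, 0, 2, 4, 4), 104:108))
  fit2 <- estimateNullNB(tr2, 100, "+", prm5)
  expect_false(fit2@poisson)
  expect_equal(fit2@prob, 0.5)
  expect_equal(fit2@size, 2)
  # mean/variance of the summed law by convolution oracle
  sumSize <- fit2@size * fit2@nLocal
  xs <- 0:400
  mass <- dnbinom(xs, size = sumSize, prob = fit2@prob)
  expect_equal(sum(mass * xs), 7 * 2, tolerance = 1e-6)
  expect_equal(sum(mass * xs^2) - sum(mass * xs)^2, 7 * 4, tolerance = 1e-4)
  # all-zero downstream flagged degenerate
  fit0 <- estimateNullNB(toyTrack(g), 100, "+", prm)
  expect_true(fit0@degenerate)
})

test_that("tail p-values match brute-force mass summation and are monotone", {
  g <- toyGenome(300)
  prm <- trsParams()
  tr <- toyTrack(g, plus = setNames(rep(2, 67), 104:170))
  fit <- estimateNullNB(tr, 100, "+", prm)        # Poisson, L-mean 14
  expect_equal(peakPvalue(0, fit), 1)
  expect_equal(peakPvalue(30, fit), sum(dpois(30:5000, 14)), tolerance = 1e-12)
  # degenerate null: decisive at the support threshold
  fit0 <- estimateNullNB(toyTrack(g), 100, "+", prm)
  expect_equal(peakPvalue(15, fit0, minReads = 10), 0)
  expect_equal(peakPvalue(5, fit0, minReads = 10), 1)
  # monotone non-increasing in the observed count
  ps <- vapply(0:60, peakPvalue, numeric(1), null = fit)
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(correctPvalues(0.001, 100), 0.1)
  expect_equal(correctPvalues(0.5, 10), 1)
  expect_equal(correctPvalues(c(1e-6, 0.02), 2), c(2e-6, 0.04))
  expect_error(correctPvalues(0.5, 0), ">= 1")
})

test_that("terminus selection applies the strict and relaxed library rules", {
  prm <- trsParams()   # minSigLibraries = M - 1, relaxRbar = 0.5
  cand <- data.frame(position = 1:3, strand = "+")
  pc <- rbind(c(0.001, 0.002, 0.005),   # significant in 3/3
              c(0.001, 0.002, 0.500),   # 2/3
              c(0.001, 0.002, 0.500))   # 2/3
  sel <- selectTermini(cand, pc, rbar = c(0.3, 0.6, 0.4), prm, M = 3)
  expect_identical(sel, c(TRUE, TRUE, FALSE))
})

test_that("the full algorithm recovers a planted coverage drop and nothing else", {
  g <- toyGenome(1000)
  drop <- 500
  mk <- function(seed) {
    set.seed(seed)
    counts <- integer(1000)
    counts[1:drop] <- rpois(drop, 20)
    counts[drop] <- counts[drop] + 200      # terminal pileup
    readStartTrack(g, paste0("l", seed), counts, integer(1000))
  }
  coll <- libraryCollection(lapply(1:3, mk))
  calls <- runTRS(coll)
  sel <- calls[calls$selected]
  expect_equal(length(sel), 1L)
  expect_lte(abs(GenomicRanges::start(sel) - drop), 3)  # within W of the drop
  expect_equal(as.character(GenomicRanges::strand(sel)), "+")
  expect_true(all(sel$pCorrected <= 0.01))
  # all-zero input yields no calls
  empty <- libraryCollection(lapply(1:3, function(i) toyTrack(g, id = paste0("z", i))))
  expect_equal(length(runTRS(empty)), 0L)
  # planted terminus below the minimal support: never called
  weak <- libraryCollection(lapply(1:3, function(i)
    toyTrack(g, plus = c(`500` = 5), id = paste0("w", i))))
  expect_equal(sum(runTRS(weak)$selected), 0L)
})
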