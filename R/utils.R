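# Internal helpers shared across modules.

# Sum counts over the offset window [a, b] relative to every position,
# where offsets are in 5'->3' transcript orientation on the given strand
# (offset +1 is one nt downstream). Circular genomes wrap; linear genomes
# treat out-of-range positions as zero.
.windowSumAll <- function(counts, a, b, strand, circular) {
  n <- length(counts)
  if (strand == "-") { tmp <- -a; a <- -b; b <- tmp }   # mirror offsets
  pad <- max(abs(a), abs(b), 1L)
  if (circular) {
    reps <- ceiling(pad / n)
    left <- tail(rep(counts, reps), pad)
    right <- head(rep(counts, reps), pad)
  } else {
    left <- numeric(pad)
    right <- numeric(pad)
  }
  y <- c(left, counts, right)
  cs <- cumsum(c(0, y))
  idx <- seq_len(n) + pad
  cs[idx + b + 1L] - cs[idx + a]
}

# Single-position window sum by explicit index arithmetic (reference path,
# also used by windowCounts()).
.windowSumAt <- function(counts, i, a, b, strand, circular) {
  n <- length(counts)
  if (strand == "-") { tmp <- -a; a <- -b; b <- tmp }
  k <- i + (a:b)
  if (circular) {
    k <- ((k - 1L) %% n) + 1L
    sum(counts[k])
  } else {
    k <- k[k >= 1L & k <= n]
    if (length(k)) sum(counts[k]) else 0
  }
}

# Per-position counts in the downstream window (i+W+1 .. i+W+D in transcript
# orientation), as a vector ordered 5'->3'.
.downstreamCounts <- function(counts, i, W, D, strand, circular) {
  n <- length(counts)
  off <- (W + 1L):(W + D)
  k <- if (strand == "+") i + off else i - off
  if (circular) {
    k <- ((k - 1L) %% n) + 1L
    counts[k]
  } else {
    out <- numeric(D)
    ok <- k >= 1L & k <= n
    out[ok] <- counts[k[ok]]
    out
  }
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.checkStrand <- function(strand) match.arg(strand, c("+", "-"))

.checkPosition <- function(i, genome) {
  if (any(i < 1L | i > genome@length))
    stop("position out of range [1, ", genome@length, "]")
  invisible(i)
}
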