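---
title: "Detecting transcript 3' termini from read-start pileups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transcript 3' termini from read-start pileups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terminR)
```

## The signal: why read starts pile up at 3' ends

In tagged RNA-seq protocols of the RNAtag-seq family, total RNA is randomly
fragmented (heat/alkaline hydrolysis) and a barcoded adapter is then ligated
to the **3' end of every fragment**; read 1 of each sequenced fragment
therefore begins at the fragment's 3'-most base. Hydrolysis breakpoints
scatter roughly uniformly along a transcript, but every copy of the
transcript contributes exactly one fragment whose 3' end is the genuine
transcript terminus. Summing over thousands of copies, the genuine 3'
terminus accumulates read starts at a rate close to the copy number, while
interior positions receive only about one read start per `meanFragmentLength`
copies. That excess — visible as a sharp pileup of read-1 start positions —
is the signal this package detects. The same logic applies to term-seq data,
where ligation precedes fragmentation and the pileup is even cleaner.

`readStartsFromBam()` reduces mapped reads to this signal: one count at the
first *aligned* base of read 1 (leading soft clips are skipped, since the
ligation site is the first base that maps), assigned by default to the strand
opposite the alignment (`orientation = "reverse"`), because the sequenced
cDNA is antisense to the transcript. Only read 1 of a pair contributes to the
3'-end track; `read = 2` extracts the mate starts, which under the same
chemistry mark transcript 5' ends. PCR duplicates (identical sequences, or
identical mate coordinates and sequences for paired data) can be collapsed
first with `dedupIdentical()` — duplicates inflate a single position and are
the main source of false premature termini in single-end data. The default
mapping-quality cutoff is MAPQ ≥ 1; it is configurable because multi-mapper
policy is a property of the upstream aligner, not of the statistic.

## The statistic

Let $X_{i,j}$ be the read-start count of library $j$ at position $i$.
Termination sites spread over a few nucleotides, so the local signal is the
windowed sum

$$L_{i,j} = \sum_{k=i-W}^{i+W} X_{k,j},$$

a sum over $2W+1$ positions, compared with the downstream window

$$D_{i,j} = \sum_{k=i+W+1}^{i+W+D} X_{k,j}.$$

"Downstream" is strand-aware (increasing coordinates on `+`, decreasing on
`-`); windows wrap on circular chromosomes and are zero-padded on linear
ones. The scaled readthrough statistic is

$$R_{i,j} = \frac{L_{i,j}}{L_{i,j} + D_{i,j}},$$

one minus the local readthrough: 1 when nothing starts downstream (a strong
terminator), near 0 when downstream read starts dominate. Positions with
$L_{i,j}$ below `minReads` (default 10) are set to $R = 0$ — we read the
"10 reads per position" support rule as guarding $L$, the quantity the
statistic and the test actually use, rather than the single-position count;
a single-position reading would make the filter depend on $W$ in an
unintuitive way. Because $R$ is scale-free, the cross-library average
$\bar R_i = \frac1M \sum_j R_{i,j}$ is meaningful even when libraries differ
in depth, and peak calling operates on $\bar R_i$ rather than on per-library
peaks that would then need reconciling.

Under identically distributed counts (no terminus), exchangeability of the
$2W+1+D$ window positions gives
$E[R] = (2W+1) / (2W+1+D)$ independent of coverage —
`nullThreshold(3, 67)` $= 7/74 \approx 0.095$. Note the $2W+1$: the local
window of half-width $W$ contains the centre position, which is what makes
the default threshold come out at 0.095 rather than $6/73$. When no explicit
peak threshold is supplied the package uses this null value rounded **up**
to two decimals (0.10 for the defaults), matching the practice of working at
a round threshold just above the null mean.

## Peak calling, testing, selection

1. **Candidates** are local maxima of $\bar R_i$ at or above the threshold.
   Peaks closer than `minPeakDistance` (10 nt) suppress one another; the
   position with the larger cross-library $\sum_j L_{i,j}$ wins, remaining
   ties going to the 3'-most position. The tie-break is our choice (the rule
   itself only demands a minimal spacing); summed local support is the least
   arbitrary ranking available at that point, and 3'-most favours the
   terminal base of a plateau. One consequence worth knowing: over a flat
   coverage plateau ending at a drop, the candidate window that still
   contains the drop but the most upstream body coverage has the largest
   $L$, so the called position can sit up to $W$ nt upstream of the drop
   itself. All recovery guarantees are therefore stated within a small
   distance (±5 nt, the same slack the annotation step uses).
2. **Testing** returns to raw counts, per library. Under the null that a
   candidate is not a terminus, counts around it are distributed like counts
   downstream of it, so the per-position law is estimated from the $D$
   downstream positions by the method of moments: mean $m$, variance $v$
   (sample variance), negative binomial with $p = m/v$,
   $r = m^2/(v-m)$ when $v > m$, Poisson otherwise. Bacterial read-start
   counts are over-dispersed, which is why the negative binomial is the
   primary model; the Poisson fallback only triggers in degenerate
   under-dispersed windows. The law of $L$ is the $(2W+1)$-fold sum —
   NB$(r(2W{+}1), p)$ or Poisson$(m(2W{+}1))$ — and the p-value is the upper
   tail $P(L \ge L_{i,j})$. An all-zero downstream window admits no fit; it
   is also the unambiguous signature of a perfect terminator, so the p-value
   is defined as 0 when $L_{i,j}$ meets the support minimum and 1 otherwise.
3. **Correction** is Bonferroni within each library, with the family equal
   to the number of candidates tested in that library — testing happens only
   at the peak-called candidates, so that is the family actually assessed.
4. **Selection**: a candidate becomes a terminus when its corrected p-value
   is ≤ `alpha` (0.01) in all $M$ libraries, or in at least $M-1$ libraries
   while $\bar R_i \ge 0.5$ (the relaxed rule for three-replicate designs).
   With $M = 2$ the relaxed rule is effectively the strict rule.

Structural-RNA filtering is applied *after* selection
(`filterStructural()`): rRNA/tRNA regions are distorted by depletion
chemistry, not by the statistic, so the algorithm itself stays agnostic.
`dataset_final` mode removes calls inside rRNA/tRNA genes on the matching
strand (calls are stranded objects); `comparison` mode — used before
cross-dataset overlap statistics — is positional and strand-agnostic,
removing everything within ±100 nt of an rRNA operon and inside tRNA genes,
because published reference sets differ in how they scrubbed these regions.

## Annotation classes

`classifyTermini()` assigns one of eight classes, each predicate evaluated
with a ±5 nt slack (we apply the slack to *every* boundary, the simplest
total rule) in a fixed priority order: AP-in-TU, Primary, Internal,
Premature-5'UTR, AP, DP, Orphan-antisense, Orphan-intergenic.
Primary covers termini within the 3' UTR up to a documented terminator
(represented by its 3'-most coordinate when the source gives an interval),
or ≤ 100 nt past the stop codon of a gene that is last in **all** its
transcription units, or at a non-coding RNA's documented 3' end. The
101–200 nt band is AP when the same final call set already contains a
terminus in the first 100 nt and DP otherwise — the companion lookup uses
only *selected* termini, since unselected candidates are not termini.
AP-in-TU covers ≤ 250 nt past the stop codon of a gene that is *not* last
in any of its units, capped at the 3' end of its longest containing unit.
Downstream distances are measured from the 3'-most base of the stop codon
(distance 0 = that base), strand-aware. An unknown 5' UTR is estimated as
100 nt upstream of the start codon. Promoter annotations are accepted in
the input but unused — no class rule consumes them.

## The synthetic data generator

`fragmentationModel()` reproduces the library-preparation steps with one
free parameter: each internucleotide bond breaks independently with
probability `1/meanFragmentLength` (default 200 nt), giving geometric
fragment lengths — the standard memoryless hydrolysis model, chosen because
the fragment-count rule used in the original protocol simulation is not
fully specified anywhere accessible, and a single interpretable parameter is
easiest to reason about. Fragments shorter than 25 nt are unmappable and
dropped; trimming to the 70-nt read length never moves a read start, so it
needs no explicit step. One read start per surviving fragment, at the
fragment's 3' base.

`generateFixture()` builds complete benchmark datasets from a declarative
scenario: genome, gene/TU layout, expressed transcripts, planted premature
termini with strengths (the fraction of copies terminating there), and
independent negative-binomial background noise added to the counts — noise
on counts, not on transcripts, because that is exactly the null the
statistic models. The stock scenario (`defaultScenario()`) is a 20-kb
circular genome, three replicates, 2000 copies per transcript, background
noise NB(mean 0.2, size 0.5) per position/strand/replicate, and premature
strengths 0.3–0.5; its ten planted termini cover seven of the eight
annotation classes (AP is exercised separately in unit tests, because an AP
truth label requires planting a companion primary call inside the 100-nt
band, which would make the truth table ambiguous under the ±5 nt slack).
2000 copies gives terminal pileups ~1800 counts against a body of ~10 and
noise of 0.2 — comfortably more than the 5× excess regime the recovery
guarantee is stated for, while keeping fixture generation to a few seconds.

What the simulator deliberately does **not** model: ligase sequence
preference, PCR amplification bias beyond duplicate injection, rRNA
depletion artefacts, and sequencing errors. Passing the recovery suite
therefore demonstrates correctness of the statistical machinery on data
matching its model assumptions, not robustness to every bias of real
libraries; the original method's validation against independent
experimental terminus maps is what establishes the latter.

## Dataset comparison

Two stranded terminus sets are matched one-to-one, greedily by increasing
distance (ties to the 5'-most reference terminus), with a 10-nt ceiling.
Overlap significance is hypergeometric: $N$ genomic positions, $K$ of them
in the union of ±10 nt windows around the reference termini
(`referenceFootprint()` counts the union, not $21 \times$ the set size, so
clustered references are not double-counted), $n$ query termini, $k$
matched. Because termini are stranded we default to $N =$ both strands
($2\times$ genome length); the headline significance claims hold under
either reading, which we verified before fixing the default. The tail is
computed in log space (`phyper(log.p = TRUE)`), so overlaps far beyond
double-precision underflow remain comparable via $\log_{10} p$.

## Downstream analyses

* **3' UTR-derived sRNA candidates** (`utrCdsOutliers()`): per library, an
  OLS fit of $\log_{10}$ mean UTR read starts on $\log_{10}$ mean CDS read
  starts over genes with a Primary/DP terminus; genes with Cook's distance
  over 3× the library average in ≥ 2 libraries are flagged, direction from
  the residual sign. The pseudo-count is 0.01 read starts/position — zero
  handling is otherwise undefined, and candidate sRNA genes with almost no
  CDS expression are precisely the interesting ones, so they must stay
  representable. A numerically exact fit (residual RMS < 1e-8) flags
  nothing: relative Cook's distances on machine-epsilon residuals are noise.
* **Condition-specific termini** (`conditionDeltaReadthrough()`): premature
  termini (Internal / Premature-5'UTR, non-rRNA) supported by $L \ge 20$ in
  ≥ 2 replicates of each condition are ranked by
  $|\bar R^{A}_i - \bar R^{B}_i|$, each condition averaging its own
  replicates; candidates strictly above the median are marked. Ranking is
  per terminus, not per gene — a gene with two premature sites can switch
  at one and not the other.
* **Conservation coordinates** (`stopCodonDistance()`): signed nt from the
  3'-most stop-codon base, positive downstream; comparable across species.
* **Terminator motifs** (`flankProfile()`): flanks aligned at the terminus,
  minus-strand flanks reverse-complemented so everything reads 5'→3' on the
  transcript; columns are A/C/G/U frequencies and sum to 1 where any
  sequence contributes. Flanks truncated by a linear genome end are
  excluded rather than padded.

## Numerical and engineering choices

* Internal coordinates are 1-based inclusive (GFF convention); on-disk
  tracks are bedGraph, 0-based half-open, one file per strand, zero runs
  omitted; the round trip is exact. The bedGraph codec is a direct
  4-column reader/writer so that malformed input can be rejected with the
  offending line number.
* Profiles are computed with cumulative sums (exact integer arithmetic in
  doubles), and cross-checked in the test suite against a literal
  per-position summation oracle.
* All randomness flows through explicit seeds; fixture replicate $r$ uses
  `seed + r`. Problem sizes in the test suite (100,000-position null
  simulations, 20-kb fixture genomes, 2000-copy transcripts, 10,000-copy
  protocol checks) were chosen to make every stochastic check decisive in
  well under a minute each.
* `M = 1` collections are accepted for exploratory profiles, but selection
  semantics are designed for $M \ge 2$; with two libraries the strict rule
  is recommended, and parameter defaults were tuned for three.

## Worked example

```{r example}
fx <- generateFixture(defaultScenario(seed = 1))
calls <- runTRS(fx$collection, trsParams())
calls <- classifyTermini(calls, fx$db)
final <- filterStructural(calls[calls$selected], fx$db, mode = "dataset_final")
as.data.frame(final)[, c("start", "strand", "RBar", "nSignificant",
                         "classLabel", "assignedGene")]
fx$truth
```

Every planted terminus is recovered within a few nucleotides and carries the
class the scenario planted.

## Known limitations

* Sensitivity for weak internal termini is intrinsically lower than for
  primary termini: the fragmentation background raises $D$ under genuine
  premature sites, and the statistic is conservative there by design.
* The Bonferroni family is per library; no cross-library joint model is
  attempted (each library is tested separately by design).
* No coordinate liftover between strains/assemblies: comparisons assume one
  coordinate system.
* The automatic peak threshold is the analytic null rounded up to two
  decimals; for window settings far from the defaults a user may prefer to
  inspect the empirical $\bar R$ distribution and set the threshold
  explicitly.
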