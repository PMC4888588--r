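---
title: "Copy-number calling and karyotype heterogeneity with karyoHMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number calling and karyotype heterogeneity with karyoHMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoHMM)
```

# The problem

Low-coverage single-cell whole-genome sequencing measures each cell's DNA
content along the genome with, typically, 50,000–300,000 usable reads per
cell. At that depth the only robustly estimable signal is the integer
copy number of megabase-scale windows. Two population summaries matter
for studying chromosomal instability: how far the cells diverge from the
euploid baseline (aneuploidy), and how much the cells differ from each
other (heterogeneity) — the latter being the readout for *ongoing*
mis-segregation, which a clonal aberration does not produce.

This vignette explains the models and the numerical choices; every
quantitative claim here is recomputed by the test suite or by
`scripts/acceptance.R`, not asserted from memory.

# Binning and GC correction

Coverage at fixed genomic width is confounded by mappability, so bins are
built with *variable width and constant mappable mass*: per chromosome the
number of bins is `round(length / target_width)` (at least one; default
target 1 Mb) and boundaries are placed by greedy left-to-right
accumulation of the mappability track — a boundary falls at the first
base where the cumulative mass reaches the per-bin quota, the last bin
absorbing the remainder, ties resolved toward the smaller bin. The
greedy rule is deterministic and independent of how the input track is
chunked. Two mass sources are accepted, because either is defensible and
neither is canonical: an aligned euploid-reference read file (per-read
unit mass) or a per-base mappability track (bedGraph/BigWig). On a
constant track the result coincides boundary-for-boundary with
fixed-width binning.

Reads are counted at their leftmost mapped base with single-end
semantics (paired data count first mates only), default MAPQ ≥ 10,
duplicates discarded. Bins overlapping a blacklist by ≥ 50% of their
width are removed.

GC bias is corrected multiplicatively: mean count is regressed on GC by
ordinary least squares with a quadratic polynomial — the canonical
unimodal shape of amplification bias — fitted to 0.01-wide GC strata
holding at least 5 bins, so single outlier bins cannot dominate the fit.
Each count is rescaled by `mean(x) / f(g)`; bins where the fitted trend
is non-positive (outside the supported GC range) keep their raw counts.
No global rescale is applied afterwards; on the simulated fixtures the
correction is mean-preserving within 1% and idempotent within 2%, which
the test suite asserts.

# The copy-number HMM

Hidden states are copy numbers 0–10 (`c_max = 10`). State 0 is a delta
distribution at zero (floored at log-probability −10^10 rather than −∞ so
arithmetic stays finite); states `c ≥ 1` are negative binomials with the
tying rule

$$x \mid c \sim \mathrm{NB}(c\,r_1,\ p), \qquad
  \mathbb{E}[x \mid c] = c\,\mu_1,\quad \mu_1 = r_1\frac{1-p}{p},$$

so mean *and* variance grow linearly with copy number. The tying keeps
eleven states identifiable from a few dozen reads per bin; untied
per-state NB parameters would be unconstrained on states visited by a
handful of bins. Corrected counts are rounded to the nearest integer for
emission evaluation, since the NB pmf is defined on integers and a
continuous surrogate would be harder to test exactly.

Fitting is standard Baum–Welch with per-position scaling constants (not
log-domain recursions — the contract is the posteriors, which the tests
pin against exhaustive path enumeration at 1e-10 on small instances).
Chromosomes are independent observation sequences sharing one parameter
set. The M-step is closed-form for the initial distribution and
transition matrix; for `(r₁, p)` no closed form exists under tying, so
`r₁` is maximised one-dimensionally (tolerance 1e-8, on the log scale)
with `p` profiled from the expected-mean constraint
`μ₁ = Σγ_{ic} x_i / Σγ_{ic} c`; this is a proper profile-ascent step, and
an explicit guard never accepts an update that lowers the EM objective,
so the loglikelihood is monotone (asserted on every fit, slack 1e-6).
EM stops when the relative improvement drops below `tol` (default 1e-4)
or after `max_iter = 200` iterations; the convergence flag is reported
honestly. Decoding assigns each bin its max-posterior state, ties broken
toward the *lower* state (conservative calls).

## Initialisation and the scale ambiguity

`μ₁` starts from the modal level of the nonzero counts divided by
`most_frequent_state` (default 2): the kernel-density mode anchors a
window `[0.7, 1.4]×mode` whose mean estimates the modal component's mean
(the raw density mode of a skewed NB is biased low). `r₁` follows by
method-of-moments within the window, falling back to `r₁ = μ₁` (a
moderate index of dispersion of 2) when the window variance is
uninformative. Transitions start sticky (self-transition 0.99).

Count-only copy-number inference has an intrinsic scale ambiguity: a
genome read as disomic at baseline mean μ is nearly as likely as the same
genome read as trisomic at 2μ/3, and the finer state grid of the
rescaled reading can even win by a few log units. The package treats
`most_frequent_state` as the declaration of the library's modal ploidy
and enforces it softly: among seeded multiplicative restarts (default 3,
factors within ±18%) the highest-likelihood fit *whose modal decoded
state equals `most_frequent_state`* is kept; if no restart achieves it,
one steering refit reinterprets the fitted modal level at the requested
ploidy and is kept when it decodes to that modal state. Forcing an
implausible ploidy (e.g. modal disomy on a near-tetraploid cell with
odd-copy chromosomes) therefore still converges — to a strictly worse
loglikelihood, which is exactly the comparison used to discriminate
genome-doubled populations.

# Library quality control

Four scale-heterogeneous measures — spikiness (sum of absolute
successive count differences over the total, never crossing chromosome
boundaries), per-bin loglikelihood (normalised so genome size does not
dominate), number of copy-number segments, and the Bhattacharyya
distance between the fitted copy-1 and copy-2 emissions (the closest
biologically meaningful pair) — are z-standardised and clustered
hierarchically (Ward linkage, Euclidean distance). The tree is cut at
1–3 clusters, the count chosen by mean silhouette width with a 0.3 floor
for declaring any structure at all: silhouette is deterministic,
scale-free and honours the 1–3 bound. The selected cluster minimises the
mean rank over (low spikiness, high Bhattacharyya, few segments, high
loglikelihood); ranks rather than a weighted score keep the rule
unit-free. Libraries with non-finite metrics are rejected before
clustering. The exact composite rule is a design choice of this package;
other rank aggregations would be defensible.

# Karyotype scores

With bins weighted by width (variable-width bins cover unequal
territory) and baseline ploidy P per chromosome:

$$D = \frac{\sum_i w_i \, \overline{|\hat c_i - P|}}{\sum_i w_i},
\qquad
H = \frac{\sum_i w_i h_i}{\sum_i w_i},\quad
h_i = \frac{1}{n} \sum_j (j-1)\, n_{(j)},$$

where `n_(1) ≥ n_(2) ≥ …` are the sorted state frequencies across the n
cells at bin i. `h` is zero iff the bin is clonal and increases with both
the number of distinct states and the size of the minority fractions; a
two-way 50/50 split gives 0.5, a four-way (2,1,1) split 0.75. D is
measured in absolute copies — deliberately *not* divided by P, so a
cross-implementation comparison against a ploidy-normalised variant must
rescale. Genome-wide scores are exactly the width-weighted means of the
per-chromosome scores (an identity the tests assert), and cells failing
QC are excluded before scoring. Pseudo-bulk aggregation, profile
clustering (width-weighted mean absolute state difference, average
linkage) and the odd-modal-state flag (width-weighted majority state per
chromosome, ties toward even — conservative for separating G2 cells from
genuine near-tetraploids) complete the population view.

# The simulator and what it does (not) show

The simulator is the package's study-condition generator, not a tuning
dial. Defaults, chosen once: a mouse-scale genome (20 chromosomes,
~2.6 Gb, hence ~2,600 bins at 1 Mb), 40 cells, 130,000 reads per cell
(~50 reads per disomic bin — the paper-typical low-coverage regime), NB
size 15 (index of dispersion ≈ 4 at 50 reads, a realistic single-cell
library), per-bin GC from a truncated normal (mean 0.42, sd 0.04) and an
optional unimodal multiplicative GC-bias curve. Karyotypes start from a
clonal base, optionally doubled (whole-genome duplication) with given
probability, then receive Poisson(q · n_chrom) whole-chromosome ±1
events (uniform chromosome, gain/loss equiprobable, floored at 0, capped
at 10); segmental events (uniform breakpoint, ±1 over the suffix) exist
behind a flag and are off by default since heterogeneity is quantified
on states. Every cell draws from a stream seeded by the cohort seed and
the cell counter, so cohorts are bit-exactly reproducible and
order-independent.

Two deliberate infidelities bound what passing tests prove. First,
simulated variance is `μ + μ²/size` — quadratic in the state — whereas
the fitted model's tied variance is linear; decoding therefore slightly
under-covers high states' tails, a mismatch kept on purpose so recovery
is tested under misspecification rather than in-model only (in-model
recovery is tested separately and is near-perfect). Second, the
simulator draws counts per bin directly: artefacts of real libraries —
mappability residuals, replication-timing waves, chimeric reads — are
absent, so QC separation results on simulated cohorts demonstrate the
mechanics of the selection rule, not its sensitivity on real data.

# Problem sizes and numerical conventions

Tests and the acceptance script run the recovery study at 10–20 cohorts
of 40 cells on the 2,600-bin genome and smaller genomes elsewhere; these
sizes were chosen as the smallest that make the medians stable.
Coordinates are 0-based half-open everywhere internally (BED native; SAM
converted on input). Degenerate inputs have defined behaviour: all-zero
libraries are errors at initialisation ("degenerate library"), all-zero
chromosomes in the binning emit zero bins with a warning, fewer than two
usable QC libraries select everything with a warning, and a single-cell
population has H = 0 by definition.

# Known limitations

No sub-bin breakpoint refinement; no allele-specific or LOH calling
(coverage at this depth cannot sample alternative alleles); no claim to
distinguish G2 from near-tetraploid G1 cells beyond the odd-modal-state
rule; heterogeneity is descriptive — no significance test comparing two
populations is provided. The aneuploidy/heterogeneity formulas follow
the package's stated definitions; published scores computed with other
formula variants are not numerically comparable without rescaling.
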