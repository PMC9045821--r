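---
title: "Single-molecule RNA modification profiling: models and methods"
author: "modprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule RNA modification profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(modprofiler)
```

## The problem

Eukaryotic ribosomal RNA carries over a hundred chemically modified
nucleotides — pseudouridine (Ψ), 2′-O-methylations (Am/Cm/Gm/Um), ac4C and
others — concentrated at the ribosome's functional centers. Ensemble assays
estimate the modified fraction one site at a time and therefore cannot see
whether modifications on the *same molecule* rise and fall together.
Nanopore direct RNA sequencing reads a full-length transcript as a sequence
of ionic-current events, one event per pore-occupying kmer, so a single
read in principle carries the modification state of every site it covers.

`modprofiler` turns per-read event sequences into **modification
profiles**: a probability of modification at every annotated site, per
molecule. Downstream it provides the statistics that make such profiles
useful — frequency-change tests against replicated wild type, pairwise
Spearman correlations between sites on the same molecule with Fisher-z
comparisons across conditions, Empirical Brown's combination of dependent
tests, Ward clustering of profiles and of raw event means, and a
comparative Kolmogorov–Smirnov site detector. A synthetic event-level
generator with planted ground truth stands in for real sequencing data, so
every component is testable offline.

## The signal model

### Branchable kmer space

The reference contig is expanded into *slots*: windows of k consecutive
positions (default k = 5). Every annotated, callable site contributes a
single dedicated **modification character** to the alphabet, drawn
deterministically from a fixed pool (lowercase letters, then digits, then a
declared ASCII list) in (contig, position) order; this guarantees that the
kmers covering different sites never collide, so each modification is
modeled independently of all others, including others of the same chemical
class. A slot covering *b* annotated positions lists all 2^b variant kmers
(capped at 4 ambiguous positions per slot; the densest cluster we model,
three adjacent sites, needs 3). Each variant kmer has a Gaussian current
model (level mean and sd in pA); modified kmers are initialized as copies
of their canonical counterparts and acquire their own parameters in
training.

Positions within the first 15 nt of the 5′ end are flagged *not callable*:
nanopore RNA sequencing proceeds 3′→5′ and never captures signal for the
final stretch. The dead-zone length is a configurable constant.

Because a mod-character pool of single characters is smaller than the
total number of annotated yeast sites, characters are unique *per contig*
and reused across contigs; kmer tables that mix contigs should therefore
be kept per contig.

### The variable-order HMM

A read is an ordered sequence of event means (reversed to reference 5′→3′
order at load time). The alignment HMM has, per slot and variant, a Match
state emitting one event from the variant's Gaussian, and an Insert state
emitting from a broad background Gaussian (mean of the canonical levels,
3× their spread). Transitions from Match are fixed: stay 0.3, step 0.55,
skip 0.1 (a silent jump over one slot), insert-open 0.05; an insert
extends with probability 0.1. Only emission Gaussians are trained,
mirroring the practice of initializing transitions from a prior model and
re-estimating emissions only.

The *variable-order* property: consecutive slots overlap in k−1 reference
positions, so a variant of slot j may only transition to a variant of slot
j+1 that agrees with it on the shared positions. Transition mass is split
uniformly over the characters newly revealed by the destination slot,
which makes the per-site prior over {canonical, modified} uniform.
Marginalizing the posterior over any slot covering a site therefore
reflects a single per-site character choice, not independent choices per
slot.

All recursions (forward, backward, maximum-expected-accuracy decoding) run
in log space in compiled code. A diagonal band (default ±40 slots around
the linear event↔slot interpolation) bounds the dynamic program; a banded
alignment that finds no admissible path is retried unbanded, and a read
with no admissible path at all is reported as a failed alignment rather
than an error. Banding at this width changed no likelihood in our checks
(stay/skip drift over a full-length read is an order of magnitude smaller
than the margin).

Per-site probability of modification for a read is the posterior mass on
variants carrying the site's modification character over all slots
covering the site, divided by the total mass on those slots; a site with
no aligned mass is *missing*, never 0. The MEA path is the monotone path
maximizing summed match posteriors, with deterministic tie-breaking toward
the smaller slot and variant index.

### Normalization

Each read is corrected for an affine current distortion (shift in pA,
dimensionless scale). The default estimator matches the read's sorted
event means against quantiles of the model's predicted event distribution
for the mapped slots (the equal-weight Gaussian-mixture over slot levels)
by a trimmed least-squares line fit. We also expose the simpler
median/MAD-matching estimator; it is biased upward in scale by the event
noise (the read's spread is the level spread convolved with noise, the
model levels' spread is not), which at a ±25 pA level range puts ~1 pA of
systematic error at the extremes — the quantile estimator absorbs this by
construction, which is why it is the default.

## Training

Supervised, per-dataset labels: one read set is treated as fully modified
at every callable site, the other (an in vitro transcript, IVT) as fully
unmodified. Each round aligns every read against its label-fixed
single-variant model, takes the MEA event-to-kmer assignments, pools event
means per kmer, and re-estimates mean = median, sd = MAD (raw MAD by
default, exactly as specified; the ×1.4826 consistent scaling is an
opt-in, because raw MAD deliberately narrows the Gaussians). Defaults: 30
rounds, 500 reads per class, minimum pool 10 events per kmer per round
(below which previous parameters are carried forward with a warning —
median/MAD are unstable on smaller pools).

Two implementation details matter for accuracy and are part of the
package's design:

* before pooling, the per-read affine transform is re-fitted by trimmed
  least squares against the model levels of the MEA-assigned kmers,
  removing the residual per-read scale error of the pre-alignment
  normalization;
* only events whose slot assignment carries at least 0.5 posterior mass
  enter the pools — an event the model itself considers ambiguous between
  neighbouring kmers is likelier to be contamination than signal. The
  same 0.5 threshold is used when collecting per-kmer event samples for
  density plots.

Hard (best-path) assignment rather than soft expected counts is a
recorded design choice: the pooled quantity is an empirical kmer
distribution built from generated alignments.

## Downstream statistics

**Frequencies and calls.** A molecule is called modified at a site when
its probability exceeds 0.5 (strictly; the tie goes to unmodified).
Per-site frequency is the fraction of non-missing calls. Reads that do
not cover every site are removed before clustering and correlation work.

**Frequency change.** Per site, 2×2 chi-square tests compare every
wild-type replicate against every experiment repeat; the *largest* p and
the *smallest* |Δf| over pairs are kept (the most conservative choice),
p-values are BH-corrected per contig, and a site is reported as changed
only when q < 0.05, |Δf| ≥ 10% (the global conservative cutoff), and |Δf|
exceeds the wild-type replicate range at that site (batch control). The
Yates continuity correction is applied automatically when an expected cell
is below 5.

**Correlations.** Spearman rank correlation between the probability
columns of all site pairs (probabilities, not binarized calls, and
midrank ties), two-sided t-test p-values with n−2 df, BH over pairs.
Comparisons between samples use the Fisher z-transform two-sample test;
with replicates, the minimum-magnitude Δρ and the maximum corrected p
over all repeat×repeat comparisons are reported, and a pair is starred
only when it is both significantly different between samples and
significantly nonzero in the focal sample.

**Empirical Brown's method** combines dependent p-values: each underlying
per-read data column is transformed to −2·ln(empirical right-tail
probability) through its empirical CDF, the covariance of the transformed
columns rescales the χ² null (f = 2E²/Var, c = Var/2E with E = 2m,
Var = 4m + 2Σ cov), and the Fisher statistic is referred to χ²_f after
division by c. With zero covariance it reduces exactly to Fisher's
method; with duplicated columns it approaches the halved-df limit. Which
per-read quantity feeds the covariance is not prescribed anywhere;
probabilities are used (a flag could switch to binarized calls).

**Clustering.** Ward's method on Euclidean distances (`ward.D2`),
identical for probability profiles and for the raw event-mean validation
matrices (whole-read z-standardized signal, MEA slot assignment,
multi-event slots averaged, reads with missing slots in the region
dropped, columns standardized). Cutting at N clusters reports per-sample
fractions; cluster ids are numbered by first appearance in leaf order so
repeated runs agree.

**Comparative site detection.** Two samples' per-position signal
distributions (from canonical-only MEA alignments — the detector must not
presume a trained modified model; events are attributed to the slot's
central position) are compared by the exact two-sample KS D-statistic,
masked below 10 events per side, then smoothed to the 3-position windowed
mean w_i = (d_{i−1}+d_i+d_{i+1})/3. Evaluation offers the strict
per-position protocol and the relaxed window-peak protocol (each modified
position scored by the maximum w in its ±2 window, with the 2 flanking
positions on each side of every modification excluded from the negatives;
overlapping exclusion zones are unioned).

## The synthetic data generator

`simulate_dataset()` emulates the parts of a nanopore run the model
consumes, with planted truth for every quantity: a seeded random
reference; annotated sites; a canonical 5-mer level table (levels uniform
in 75–125 pA) with modified kmers shifted +3 pA; per-read, per-site binary
modification states drawn from subpopulation templates (optionally with a
Gaussian-copula dependence calibrated so the *binary* Spearman correlation
hits its target); event emission walking slots 5′→3′ with geometric stays
(p_stay = 0.3), rare skips (0.05) and background inserts (0.01); and a
per-read affine distortion (scale 0.95–1.05, shift ±5 pA). Reads are
emitted 3′→5′ like real RNA reads. The default geometry — 300-nt contig,
12 well-spaced sites, +3 pA shift at 1 pA event noise, 500 reads per
sample — was chosen once as the regime where calling is reliable but not
trivial, and is used unchanged by the test suite and the acceptance
script.

What it does *not* emulate: raw pre-event squiggles, dwell-time physics,
homopolymer pathologies, basecalling or mapping errors, and the
sequence-dependent confusability of real pore chemistry. Passing tests on
this generator demonstrate internal correctness of the algorithms — the
likelihood equals enumeration, training recovers planted parameters,
statistics hold their nominal levels — not accuracy on any real organism's
data.

`simulate_profile_matrix()` bypasses the HMM entirely (probabilities drawn
from state-conditional Beta distributions, or exactly 0/1) to test the
statistics and clustering in isolation.

## Numerical choices and degenerate inputs

* All HMM math in log space with log-sum-exp; no probability-space path.
* Normalization requires ≥8 events and non-constant means; constant reads
  are an error, failed alignments are data (dropped with a logged reason
  at the matrix level).
* Exact ties: probability = cutoff counts as unmodified; MEA ties resolve
  to the smallest slot then variant; cluster ids follow leaf order.
* χ² with expected cells < 5 switches to the continuity-corrected form.
* p-values of exactly 0 entering Brown's method are clipped to the
  machine minimum with a warning; |ρ| = 1 pairs are flagged
  not-comparable rather than transformed to ±∞.
* Trained level sds are floored at 0.05 pA.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run the full study design:
training at 500 reads/class × 30 rounds on the default 300-nt/12-site
geometry; calling on 170 half-modified reads (~2000 cells); the null
frequency-change calibration on 500 sites × 300 reads × 4 samples;
clustering on 200 and 320 planted reads; site detection on 120-nt tracks
with 60 reads per sample. Enumeration oracles cover ≥100 random miniature
instances (≤4 events, ≤3 slots, ≤2 variants per slot) plus a brute-force
Ward agglomeration on ≤12 rows.

## Known limitations

* Modification calls are binary (modified vs canonical), not typed; a
  site's probability says nothing about *which* chemical modification is
  present beyond the annotation.
* Dense clusters beyond 4 ambiguous positions per kmer slot are rejected;
  raise the cap knowingly — the state space grows as 2^b.
* Characters are unique per contig, not globally; per-contig model tables
  are the intended usage.
* The UMAP embedding and heatmap figures of typical workflows are left to
  external tools; this package computes the matrices, linkages and
  statistics behind them.
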