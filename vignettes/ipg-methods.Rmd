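---
title: "Calling interaction profile groups from trans Hi-C: models and methods"
author: "ipgtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling interaction profile groups from trans Hi-C: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipgtools)
```

## The problem

Genome-wide chromosome conformation capture (Hi-C) measures contact
frequencies between all pairs of genomic loci. Loci that share a chromatin
state tend to co-segregate in the nucleus and therefore share long-range
contact *profiles*. Classifying 50-kb bins by the similarity of their
**trans** (interchromosomal) contact profiles partitions the genome into
*interaction profile groups* (IPGs) — a generalization of the classical
A/B compartments and of subcompartments. `ipgtools` implements this
classification and the downstream analytics used to characterize the
groups: saddle plots, per-group contact decay P(s), diamond insulation
with prominence-ranked boundaries, pileups at oriented CTCF motifs,
two-state HMM domain calling on chromatin and replication-timing tracks,
and a one-dimensional loop-extrusion simulator.

## The spectral IPG procedure

Starting from a raw binned contact matrix:

1. **Bin filtering.** Bins whose total coverage falls more than 5 median
   absolute deviations below the median, or with fewer than 2 nonzero
   pixels, are marked invalid and excluded everywhere downstream. The MAD
   multiplier and pixel floor are package defaults; any stricter or more
   lenient policy can be set per call.
2. **Iterative correction (ICE).** Multiplicative per-bin biases are
   removed by symmetric Sinkhorn iteration until the relative variance of
   the valid-bin marginals drops below 1e-5 (at most 300 iterations).
   Weights are missing on invalid bins.
3. **Cis masking.** Contact profiles within a chromosome are dominated by
   genomic distance, not chromatin state, so every cis pixel (i, j) is
   replaced by a pixel drawn uniformly at random from the trans entries of
   row i or column j (one fair coin flip per pixel, seeded). The upper
   triangle is mirrored so symmetry is preserved. This keeps the matrix
   full (every bin keeps a complete profile) while erasing the distance
   signal.
4. **Doubly stochastic scaling.** The masked matrix is rescaled by
   iterative proportional fitting so every valid row and column sums to 1,
   making profiles comparable across bins of different coverage.
5. **Eigendecomposition.** The valid-bin submatrix is symmetric, so its
   eigenpairs are real; they are ordered by *descending eigenvalue
   modulus* — negative eigenvalues carry anti-correlated structure and
   must not be discarded by algebraic sorting. The leading eigenvector of
   a doubly stochastic matrix is constant and carries no information; it
   is detected by its vanishing coefficient of variation (below 1e-3,
   which comfortably covers the residual non-uniformity left by the
   finite scaling tolerance) and dropped before the components are
   numbered E1..Em. Nine components are kept by default. Eigenvector
   signs are arbitrary; each is oriented so that its correlation with a
   user-named reference track (GC content in real data, the planted
   active-state track in tests) is non-negative, falling back to making
   the first nonzero entry positive.
6. **k-means.** Each unit-norm eigenvector is multiplied by its
   eigenvalue modulus — components are thereby weighted by how much
   structure they capture — and the rescaled vectors are concatenated as
   columns. k-means (default k = 8, 30 restarts, best inertia kept,
   seeded) clusters the rows. The mean silhouette width on the same
   representation scores the partition; `silhouette_scan()` reports it
   over a k grid (default 4–12) when the choice of k is open. Alternative
   rescalings (`unit-variance`, `none`) are available because the
   eigenvalue weighting, while standard practice, is a choice rather than
   a theorem.
7. **Consolidation.** Chromosomal position (distance from the centromere)
   contributes a state-independent gradient to trans profiles — the E2
   component — so k-means typically splits one chromatin state into a
   centromere-proximal and a centromere-distal cluster. Clusters are
   therefore consolidated by their *functional* profiles: the per-cluster
   means of the supplied chromatin tracks are standardized track-wise and
   clusters whose profile vectors correlate above 0.98 are merged
   (connected components of the correlation graph). Within-state cluster
   pairs correlate near 1 in practice, hence the high default; an
   explicit cluster-to-group map always overrides the automatic merge.

Determinism: every stochastic stage (masking, k-means initialization)
takes an explicit seed, and identical seeds give identical labels.
Clustering is empirically insensitive to the masking seed (adjusted Rand
index above 0.95 across masking seeds on synthetic data; asserted in the
test suite).

## The synthetic genome

Every stage of the pipeline is verified against a generator that plants
known structure at desk scale. The default genome has three chromosomes
of 550/500/450 bins of 50 kb with centromeres at 40% of their length —
large enough for trans decomposition, small enough that the full pipeline
runs in seconds.

**Labels.** States are painted per chromosome as a Markov chain with
geometric run lengths (mean 10 bins); consecutive domains never repeat a
state. Five states are planted by default, named after the groups they
emulate: two active-like states (A1, A2), a neutral silent state (B0),
facultative (B1) and constitutive (B4) heterochromatin.

**Contacts.** The expected intensity of pixel (i, j) is the product of

* a state-pair **affinity** `A[s_i, s_j]`,
* a **positional** similarity `exp(-w |Δc| / L)` in the distance of the
  two bins from their centromeres (`w = 0.4`, `L = 150` bins), which
  reproduces the E2-like gradient, and
* a **distance decay**: `s^-1` in cis, multiplied inside domains by an
  extrusion shoulder `1 + a exp(-s / s0)` (per-state scale `s0`,
  default 8 bins), and a constant (0.02 relative to the one-bin cis
  decay) in trans.

Counts are Poisson draws scaled to a total depth (default 1e7 pairs).
Poisson rather than negative-binomial noise is deliberate: recovery tests
need a realistic sampling floor, not a dispersion model.

The default affinity matrix preserves the qualitative structure of the
real system — the B4-like state has the largest homotypic affinity in the
matrix, the B0-like row is flat apart from a modest homotypic preference,
and the A2-like state interacts with A1 at least as strongly as with
itself — but its contrasts are deliberately **stronger than real trans
observed/expected values**. Two facts force this. First, after the matrix
is made doubly stochastic, a purely diagonal contrast between two states
is scaled away; states remain separable only through their contacts with
*third* states, so the informative structure must be placed in the
off-diagonal pattern. Second, cis masking injects resampling noise whose
eigenvalue bulk does not shrink with sequencing depth and is far larger
on a 1,500-bin toy genome (cis fraction ~1/3) than on a real genome
(~60,000 bins, cis fraction ~1/23). The default contrasts are chosen so
that all four informative eigenvalues clear that bulk, which is what
makes end-to-end recovery (ARI > 0.9) a meaningful test of the *pipeline*
rather than a lottery over noise realizations. Consequently, passing
recovery tests demonstrates correctness of the machinery on separable
data; it does not certify performance on real matrices, where separation
is weaker, depth matters, and translocations must be excluded by hand (a
user-supplied list of bins to invalidate — the package performs no
structural-variant detection).

**Tracks.** Four Gaussian tracks (H3K9me3-, H3K27me3-, H2A.Z- and
replication-timing-like) are emitted per bin from state-specific means
(sd 0.3). The B4-like state has a high H3K9me3-like mean; the RT-like
track is bimodal, positive for the two active-like (early) states and
negative otherwise. The A1/A2 means are separated in three of the four
tracks so that consolidation at the 0.98 threshold cannot confuse them.
CTCF sites are planted at domain boundaries not flanked by the B4-like
state (probability 0.7 per boundary, fold-change 1 + Exp(2), random
orientation), mirroring the depletion of extrusion barriers in
constitutive heterochromatin.

## Compartment metrics

**Expected and P(s).** Cis decay curves pool valid pixels into geometric
separation strata of ratio 2^(1/8); the stratum mean of balanced contact
frequency is the expected value at that distance. Per-group P(s) admits a
pixel only when both bins fall in the *same* labeled domain, then
normalizes the curve to 1 at the stratum containing the reference
separation (default 10 kb). The log-log derivative uses centered finite
differences with an optional moving average; strata with nonpositive P
are dropped. On synthetic data the derivative dip lands within a factor
of 2 of the planted shoulder scale.

**Saddles and pairwise O/E.** Observed/expected uses the per-chromosome
stratum expected in cis and the per-chromosome-pair mean in trans. Valid
bins are ranked by the chosen track (ties broken by bin index for
reproducibility) and split into equal-count quantile groups (default 50);
mean O/E per group pair is reported after dividing out the global mean
over included pixels, which is 1 within 1% by construction. The group
version (`ipg_pairwise_oe()`) replaces quantiles with labels. The main
diagonal is excluded throughout.

## Insulation and pileups

The diamond insulation score of bin b is the mean balanced contact
frequency over pixels spanning b (window 100 kb on each side at 25-kb
resolution), log2-scaled relative to its chromosome mean; bins within a
window of a chromosome edge are missing. Insulating loci are local minima
ranked by **topographic prominence** computed on the negated score: from
each minimum, walk outward until a deeper minimum (higher peak of the
negated signal) or the chromosome edge — edges act as maxima — and take
the drop to the lower of the two flanking maxima. The two stringency
tiers used in practice are prominence 0.01 and 0.1; calls at the stricter
threshold are always a subset of the looser one.

Pileups cut square snippets centered on the diagonal at oriented CTCF
motif midpoints, mirror minus-strand snippets, divide by a
**group-specific** distance expected (computed only from pixels inside
the group's own territory, so that a group's different P(s) shape does
not masquerade as boundary strength), and average per group. Sites too
close to a chromosome edge or centered on invalid bins are skipped and
counted.

## Two-state HMMs

Broad-mark domains (H3K9me3-like) are segmented with a Bernoulli HMM on
tracks binarized at z ≥ 1 of log(signal + 1); replication-timing domains
with a Gaussian HMM on z-scored log2(Early/Late). Baum–Welch runs per
observation sequence — **missing bins break sequences** rather than being
imputed — with seeded restarts (quantile-split initialization for
Bernoulli, k-means for Gaussian, 5 restarts, best likelihood kept),
scaled forward–backward recursions in C++, and a monotone log-likelihood
guaranteed by EM. States are ordered post hoc so state 1 is the
high-emission state; Viterbi runs of state 1 become domains, and runs
separated by at most `min_gap` low-state bins (default 1) merge. Viterbi
agrees with exhaustive path enumeration on all sequences short enough to
enumerate.

Replication timing: early/late counts are library-normalized to equal
totals (per-library total is the package's normalization choice), the
per-bin log2 ratio is z-scored, and differential regions between two
conditions are bins with |Δz| ≥ 0.75, merged within 250 kb, labeled
hastened or delayed by the sign of the change. Bins with a zero count in
either fraction are missing rather than infinite.

## The loop-extrusion simulator

A lattice of 1-kb monomers carries N = n/600 loop-extruding factors
(LEFs). Per time step, each free leg steps outward with probability 1/2
unless the target monomer is occupied by another leg or lies in a blocked
region; a leg arriving on a CTCF site whose blocking orientation faces it
is captured with probability min((fc − 1)/fc_med, 1) and stays until
released (probability 0.006 per step); each LEF unloads with probability
1/100 per step and immediately reloads at a uniformly random unoccupied
adjacent pair, keeping density constant. A "+" site blocks right-moving
(downstream) legs and a "−" site left-moving (upstream) legs — the
convergent rule; an orientation-agnostic mode is available because the
blocking convention is a modeling choice. Legs are processed in fixed
order within a step; a leg denied its move simply waits. The RNG is R's,
so trajectories are bit-reproducible under a seed.

Steady-state consequences used as checks: with no barriers the mean loop
size is growth rate (1 monomer/step) times the mean memoryless age
(≈ 1/unload − 1), i.e. ≈ 100 monomers; captured dwell times are
geometric with mean 1/0.006 ≈ 167 steps. Dwell statistics use the
exposure estimator — total captured time (censored episodes included)
divided by the number of release events — which is unbiased under
unload censoring. The loop-size assay runs at low density (separation
4,000) because at the default separation of 600 leg collisions shave a
few percent off the collision-free value; the collision effect is real
dynamics, not an artifact, but the analytic check is only exact without
it.

The 3D molecular-dynamics layer is *not* simulated. For insulation
readout, `contact_map_from_trajectory()` stacks loop-base contacts from
sampled states on a smooth power-law background of equal mass — enough to
recover corner dots and boundary insulation at convergent sites, not a
substitute for polymer conformations. The traversal assay compares an
open versus a blocked heterochromatin-like interval flanked by convergent
CTCF clusters: the fraction of legs loaded outside that fully cross the
interval is exactly 0 when blocked, and the peripheral-edge contact
fraction collapses with it.

## Numerical choices and degenerate inputs

* ICE/IPF convergence: relative marginal variance below 1e-5 (ICE) or
  1e-10 (row-stochastic scaling); non-convergence is an error carrying
  the iteration count, never a silent partial result.
* Missing data are explicit `NA` everywhere; no operation imputes zero.
  All-missing tracks, zero-variance tracks (binarization), zero-total
  count fractions (RT) and single-class labels (ROC) are errors.
* ROC thresholds are the unique observed values, ties resolved by the
  rank convention AUC = P(score+ > score−) + ½ P(tie); AUC is exactly
  complementary under score negation.
* Quantile and percentile groups use stable ranks (ties by bin index),
  so group sizes differ by at most one and runs are reproducible.
* k = 1 clustering reports a missing silhouette rather than an error.
* Coordinates are 0-based half-open in every file and structure;
  chromosome order is fixed by the bin table and never silently re-sorted.

## Problem sizes

The test suite and the acceptance script run, by design, at desk scale:
the 1,500-bin three-chromosome genome for pipeline recovery (seconds per
run), 200–300 bins for brute-force insulation comparisons, n = 10,000
observations and 20 replicates for HMM calibration, and ≥ 1e6 LEF-steps
for extrusion steady-state checks. These sizes were chosen as the
smallest at which the checked statistics are stable, so that the whole
verification cycle stays fast enough to run routinely.

## Known limitations

* Matrix IO is the package's plain-text COO dialect with a TSV sidecar
  bin table plus bedGraph/BED for tracks and intervals; binary cooler
  files are out of scope here and should be exported to the text dialect
  upstream.
* The insulation minima calling uses a single window; multi-window
  sweeps and directionality indices are not provided.
* The pipeline assumes the karyotype is clean after the user excludes
  translocated segments; no SV detection is attempted.
* The LEF contact-map synthesis is a 1D proxy; spatial observables
  (radius of gyration, 3D distances) are outside the model.
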