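---
title: "Refitting reference mutational signatures and extracting de novo signatures from the residual"
author: "signovo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refitting reference mutational signatures and extracting de novo signatures from the residual}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signovo)
```

# The model and its assumptions

A cohort of tumour genomes is summarised as a count matrix $A$
($n_g$ samples $\times$ $n_t$ mutation-type channels). For single-base
substitutions we use the SBS-96 channel set: six substitution classes
(C>A, C>G, C>T, T>A, T>C, T>G, after collapsing purine-reference
substitutions onto the reverse-complement strand) times sixteen 5′/3′
flanking-base contexts. Strand symmetry is assumed throughout — the
package never distinguishes transcribed from untranscribed strand.

Mutational processes are modelled as signatures: rows of a matrix $H$
($n_k \times n_t$), each a probability distribution over channels. The
cohort is approximated as $A \approx W \cdot H$ with non-negative
exposures $W$ ($n_g \times n_k$), interpreted as mutations attributed to
each signature in each sample.

The analysis has two stages.

**Stage 1 — refitting.** $H$ is fixed to a reference panel and each
sample's exposure row is the solution of a non-negative least-squares
problem; rows are independent, so the fit decomposes into $n_g$ small
Lawson–Hanson active-set problems sharing the basis $H^\top$. The model
cost is the sample-size-normalised Frobenius norm
$C = n_g^{-1}\,\lVert A - W H \rVert_F$. Because reference panels are
large and collinear, fitting the full panel overfits; stepwise selection
(forward: grow from the empty model; backward: shrink from the full
model, each step refitting every candidate exactly) produces a cost
curve over model sizes. The package deliberately returns the *full*
curve and leaves truncation to the user: `suggestElbow()` implements the
maximum-distance-to-chord heuristic but is advisory only, because where
to stop is a judgement about how much unexplained structure one is
willing to ignore.

**Stage 2 — de novo extraction.** The residual
$A' = A - W H$ holds whatever the reference panel cannot explain. It is
factorised as $A' \approx W' H'$, where $H'$ stacks the $n_{k_{ref}}$
fixed reference rows above $n_{k_{new}}$ free rows; Frobenius-objective
multiplicative updates modify only $W'$ and the free rows. The number of
free signatures is chosen by leave-$k$-out cross-validation: for every
candidate $n_{k_{new}}$ and fold, a model is trained on the retained
samples, the held-out samples' exposures are inferred by non-negative
projection onto the trained $H'$, and the held-out reconstruction cost is
averaged over folds. Test cost falling sharply up to some rank and
flattening after it indicates that rank; past it the extra signatures fit
noise (test cost meets or exceeds training cost).

Signature similarity is scored with the Hellinger distance
$H(p, q) = \tfrac{1}{\sqrt 2}\sqrt{\sum_i (\sqrt{p_i} - \sqrt{q_i})^2}$,
the natural bounded metric between probability distributions: 0 iff
identical, 1 for disjoint supports. We use the $1/\sqrt 2$ normaliser —
the unique scaling under which the bound 1 is attained exactly on
disjoint supports.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `direction` | backward | stepwise order; backward is markedly more reliable (see below) |
| `nKeep` | user choice | signatures kept after selection; `suggestElbow()` advises |
| `nNew` / `maxNew` | user choice | candidate de novo ranks for cross-validation |
| `k` | 1 | samples held out per CV fold (leave-one-out); folds assigned in sample order, remainder in the last fold |
| `nRestarts` | 10 | random NMF initialisations; best final objective kept |
| `maxIter` | 10000 | multiplicative-update cap per restart |
| `tol` | 1e-8 | relative objective decrease over 10 iterations that stops a run |
| `concentration` | 25 | Dirichlet spread of per-sample fractions in `scenarioPreset` |

Counts are unitless non-negative integers; exposures are in mutations;
costs are in mutation counts per sample (Frobenius norm over the cohort
divided by $n_g$).

# Numerical choices

* **NNLS.** Lawson–Hanson active set, compiled, solved independently per
  sample row; deterministic. Ties in stepwise candidate costs (within
  1e-12 relative) are broken by panel order so runs are reproducible.
* **Negative residuals.** $A - WH$ can be negative where the fit
  overshoots; NMF requires non-negative input, so negatives are clamped
  to zero and the clamped mass is reported. Clamping is not free — see
  *Limitations*.
* **NMF initialisation.** Free rows of $H'$ start Uniform(0,1)
  row-normalised, $W'$ Uniform(0, max $A'$); every restart's seed is
  derived from the user seed and recorded. Free rows are renormalised to
  sum to one only at the end, with the scale folded into the matching
  $W'$ columns (the objective is invariant to this), so the per-iteration
  objective trace is non-increasing as the update rules guarantee.
* **Division guards.** 1e-12 is added to update denominators.
* **Degenerate free rows.** A free row driven to all-zero is reset to
  uniform with zero exposure rather than propagating NaN.
* **Channel alignment.** Catalogs and panels align by channel *label*
  with explicit reordering; mismatched label sets are an error, never an
  implicit intersection.
* **Elbow.** Maximum perpendicular distance to the chord joining the
  curve endpoints; for backward curves the x-axis is the number of
  signatures remaining, so both directions read left-to-right as
  decreasing cost. The CV elbow is computed over candidates
  $n_{k_{new}} \ge 1$; the optional rank-0 baseline is reported but
  excluded, since its trivially large drop would otherwise dominate the
  chord.

# The synthetic benchmark panel and generator

Published reference panels are not redistributed with the package.
`syntheticSignaturePanel()` deterministically constructs a synthetic
SBS-96 panel whose six core signatures reuse the names the scenario
presets expect and emulate the qualitative character of the
corresponding processes: spiky CpG C>T (Signature.1), two broad "flat"
profiles with different class tilts (Signature.3, Signature.5), broad
non-CpG C>T (Signature.11), peaked C>A (Signature.18) and peaked T>A
(Signature.22), plus decoys alternating spiky and broad shapes. The
broad decoys matter: a single flat signature can fit a *mixture* well,
which is precisely what makes greedy forward selection fallible and
backward selection the safer default.

`simulateCatalog()` draws each sample's counts from one multinomial of
size `nMutations` with channel probabilities given by the
exposure-weighted signature mixture (equivalently, per-signature
multinomials behind `perSignature = TRUE`, which keeps integer
per-signature ground truth). `scenarioPreset()` builds three cohort
designs over the six core signatures — A: one dominant process (0.75
vs 0.05 each); B: two dominant (0.375 each vs 0.0625); C: all equal —
and draws per-sample fractions from a Dirichlet centred on those values
(concentration 25). The per-sample variation is essential, not
cosmetic: with identical fractions in every sample the expected residual
matrix has rank one, and no factorisation method could separate two
hidden signatures from it. Real cohorts vary; the generator does too.

What the generator does *not* emulate: sequencing-depth and trinucleotide
composition biases, subclonal structure, correlated errors between
samples, inter-cohort batch effects, and real panels' exact probability
tables. Passing tests on this generator therefore demonstrate the
algorithms' correctness and behaviour under the stated sampling model,
not end-to-end performance on any particular real dataset.

# Design decisions where the design was open

* **Stepwise trial scoring** refits all samples exactly for every
  candidate model rather than using a cheaper score; panels are small
  enough (tens of signatures) that exactness wins.
* **Stage-2 reference exposures** are *added* to the stage-1 fit in
  `combineExposures()`; both addends are kept as attributes so the
  alternative reading (replacement) stays recoverable.
* **De novo naming**: `Denovo_1..n` in decreasing order of attributed
  mutations.
* **Multi-allelic VCF records** are split into one candidate SNV per
  ALT; records whose REF disagrees with the genome base are skipped and
  counted, not reinterpreted — the safest policy for mixed-build inputs.
* **Genome access** uses indexed FASTA (`.fai`) rather than a bespoke
  binary chromosome format; the index fills the same role as a
  conversion cache.

# Problem sizes used by the test-suite and acceptance script

The tests and `scripts/acceptance.R` run scaled-down versions of the
benchmark grids, chosen as the smallest sizes at which the qualitative
results are stable: 12-dataset selection grids (3 cohort sizes 15/25/50 ×
4 burdens 500–5000) per scenario; de novo runs at 25 samples ×
20000–35000 mutations with 5-fold (k = 5) cross-validation, 2 restarts
during CV and 10 for the final factorisation; property checks over 10–25
seeded replicates.

# Known limitations

* Clamping negative residuals biases the residual upward with a
  channel-dependent mean, so even a cohort fully explained by the
  reference panel leaves a residual with learnable low-rank structure;
  spurious CV candidates can cut held-out cost by a few percent. A
  genuine hidden signature cuts it several-fold more, which is what the
  elbow detects. Corollary: recovered de novo profiles are biased images
  of the truth (part of a hidden signature's mass is absorbed by the
  stage-1 fit), so Hellinger distances to truth plateau around 0.25–0.35
  rather than approaching zero with more data.
* Selection is cohort-level; no per-sample signature selection and no
  significance testing of exposures.
* DBS-78 / ID-83 catalogs are consumed (read, fitted, factorised) but
  not generated from VCF; only SBS-96 generation is built in.
* The elbow heuristics are advisory; silent automatic truncation is
  deliberately not offered.
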