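---
title: "Models and methods for amplicon denoising and chimera removal"
author: "pyroclean"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for amplicon denoising and chimera removal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyroclean)
```

# The problem

PCR-amplified marker genes (16S rRNA and the like) sequenced on 454-style
pyrosequencers carry three distinct kinds of noise: signal-intensity errors
from the sequencing chemistry itself (miscalled homopolymer lengths, seen as
insertions/deletions), single-base substitutions introduced by the
polymerase during amplification, and PCR chimeras spliced together from two
templates when an incompletely extended fragment primes the wrong molecule
in a later cycle. Left in the data, all three inflate the number of
operational taxonomic units (OTUs) and fabricate a long tail of rare,
spurious taxa. `pyroclean` removes the three noise sources in that order —
flowgram clustering, sequence clustering, chimera classification — and ships
the evaluation machinery (per base error rates, reference-based chimera
labels, OTU accuracy) and a synthetic-community generator so every stage can
be exercised and scored without any external data.

# Stage 1: pyrosequencing noise (flowgram EM)

A pyrosequencing read is a *flowgram*: one real-valued light intensity per
nucleotide flow, with the true homopolymer length `n` of each flow producing
an intensity `f` drawn from a distribution `P(f | n)` whose spread grows
with `n`. Given an intensity model (the binned table of
`d(f | n) = -log P(f | n)`), the distance between an observed flowgram
`f = (f_1, ..., f_M)` and a candidate true sequence — represented by its
*perfect flowgram* of integer run lengths `u_i` — is the length-normalised
sum

```
d'(f, U) = sum_i d(f_i | u_i) / M .
```

Reads are modelled as a mixture: each of `L` true sequences `S_j` with
relative frequency `tau_j` generates flowgrams with density proportional to
`exp(-d'(f, U_j) / sigma_p)`. The log-likelihood is maximised by
expectation-maximization:

* **E step** — responsibilities
  `z[i, j] = tau_j exp(-d'_ij / sigma_p) / sum_k tau_k exp(-d'_ik / sigma_p)`
  (computed in log space);
* **M step** — each component's sequence is the candidate perfect flowgram
  minimising the responsibility-weighted total distance to all reads, and
  `tau_j` is the mean responsibility.

Candidate centres are restricted to the perfect flowgrams obtained by
rounding the *observed* flowgrams, so every denoised sequence is traceable
to real reads and the full read-by-candidate distance matrix can be
computed once up front (which also makes the exact full-scan M step cheap —
no candidate pruning is needed at the scales this package targets). The EM
is initialised from a complete-linkage clustering of the pairwise flowgram
distances cut at `cut_p`; the defaults `sigma_p = 1/60` and `cut_p = 0.01`
are the standard published operating point.

## The distance scale, and a calibration convention

With a fine binning (0.01 intensity units), the raw `-log P(f | n)` of even
a perfectly matching flow is around 3 (the mode bin of a tight distribution
still holds only a few percent of the mass), which would put `d'` of a read
against its own true sequence far above `cut_p`. The package therefore
stores the raw table (so each column is a genuine probability distribution)
but clusters on the per-flow likelihood-ratio form

```
d*(f | n) = d(f | n) - min_n' d(f | n'),
```

which is zero whenever the hypothesised run length is the most likely one
for the observed intensity, and positive exactly where the read disagrees
with the hypothesis. Because the subtracted term depends only on the
observed intensity, it is constant across mixture components for a given
read: responsibilities, M-step argmins and the monotonicity of the
likelihood are unchanged, and the resulting distances live on the mismatch
scale that `sigma_p` and `cut_p` refer to. `flowgram_distance()` exposes
both forms via its `normalize` argument (default `FALSE`, the literal
definition).

## The default intensity model

Calibrating `P(f | n)` needs reads of known templates
(`calibrate_intensity_model()` does this from flowgram/truth pairs). As a
default the package generates the table deterministically from a parametric
recipe: run length `n` gets a discretised normal centred on `n` with
`sd = 0.05 + 0.035 n`, truncated to non-negative intensities — unimodal at
the run length with variance growing linearly, the qualitative shape of
454 signal distributions. A parametric recipe regenerates exactly and
documents itself; empirical tables can be dropped in through the same
plain-text serialisation (`write_intensity_model()` /
`read_intensity_model()`).

## Read filtering

Before clustering, reads are filtered with the strict standard rules: exact
tag and IUPAC-exact primer match at the read start; truncation at the first
intensity in `[0.5, 0.7)` (the half-open reading of the noisy-signal
window; the boundary assignment is a documented choice) or at the first
frame of four flows with no intensity at or above 0.5; rejection if that
happens before flow 360; and end truncation at flow 360 (GS FLX, 400 raw
flows) or 720 (Titanium, 800 raw flows) to drop the noisy last 10% of the
run. Truncation is rounded down to whole frames of four flows, which keeps
the one-signal-per-frame invariant testable, and the whole filter is
idempotent. Whether the noisy-window check should apply before or after
primer trimming is not specified by the protocol; the package applies it to
the full flowgram.

# Stage 2: PCR point errors (sequence EM)

PCR substitutions survive stage 1 (they are real sequence differences, not
intensity noise), so the denoised sequences — now carrying abundances — are
clustered again with a model matched to that error process. The distance
between a read `r` and a candidate true sequence `S` is the negative log
probability of the necessary base transitions, normalised by the alignment
length `A` (all columns, terminal gaps included — a documented choice):

```
e(r, S) = sum_l -log P(r_l = m | s_l = n) / A .
```

The 4x4 transition matrix defaults to the empirical per-base PCR error
frequencies of a standard Taq polymerase, in which transitions (A↔G, C↔T)
are an order of magnitude more likely than transversions; rows are
renormalised to exact unit sums at load time to remove printing drift, and
the diagonal cost is kept (not zeroed) so `e` is the literal
per-column negative log likelihood. Alignment uses a Needleman–Wunsch
variant with a reduced gap penalty for homopolymer gaps: a gap column costs
4.0 when the inserted/deleted base equals either adjacent base of the other
sequence at that point (a run extension or contraction, the signature of
residual pyrosequencing noise) and 15.0 otherwise; the test is cell-local,
so the dynamic-programming optimum is well defined, and the traceback
breaks ties deterministically. One standard gap per 100 columns therefore
contributes 15/100 = 0.15 to `e`.

The EM machinery is shared with stage 1 (one tested implementation,
parameterised by the distance); sequence weights enter both the component
weights and the effective read multiplicities, so output frequencies sum
exactly to the input weight. Sequences are truncated to 220 bp (GS FLX) or
400 bp (Titanium) by default before clustering, because error rates climb
towards read ends. Defaults `sigma_s = 0.033` and `cut_s = 0.08` are the
GS FLX operating point; 0.04 and 0.1 are the documented Titanium presets.

# Chimera classification

Because a chimera is born in a later cycle than either parent, both parents
are present at equal or greater abundance. For each query (processed in
decreasing abundance) the candidate parents are all other sequences at
least as abundant, ties included, in deterministic id order. Aligning the
query to every candidate gives per-parent prefix- and suffix-mismatch
arrays in query coordinates; minimising best-prefix plus best-suffix over
all breakpoints finds the optimal parent pair and breakpoint without
enumerating pairs. The query is a chimera *candidate* only if its distance
to the spliced reconstruction is below 0.15 and no greater than its
distance to the closest of the two parents. (When the same parent wins both
sides, the "splice" is that single parent, the change counts below vanish
and the index is zero — the degenerate case costs nothing.)

A candidate still needs to look *unlikely to have evolved*. From a three-row
alignment of closest parent A, distant parent B and query C — built by
projecting the two pairwise alignments onto query coordinates, with
per-column majority (parsimony) ancestors and no change attributed to
columns with three distinct states — the branch change counts `x` (to A),
`y` (to B), `z` (to C) are split at the breakpoint into the part matching A
and the part matching B. Under the null, changes scatter binomially with
probability proportional to part size (measured in ungapped query columns),
so the chimera index is the joint tail surprise

```
I = -ln( Pr[Bin(y, len_A / (len_A + len_B)) >= y_A]
       * Pr[Bin(x, len_B / (len_A + len_B)) >= x_B] ) .
```

The final call is a logistic regression on `I`:
`P(chimeric) = 1 / (1 + exp(-(alpha + beta I)))`, chimeric when above 0.5.
`logistic_train()` fits data-set-specific parameters (reporting separation
when the classes divide perfectly, in which case the decision point is
still meaningful but its uncertainty is not); the shipped default
`alpha = -7.5`, `beta = 0.5` — a decision point of `I = 15` — is the
recommended cross-data-set operating point. Sequences with no adequate
chimeric match are assigned probability zero.

# Evaluation machinery

* `per_base_error_rate()` aligns each read to its closest reference
  (unit-cost global alignment: mismatches and gap columns each count one
  difference) and reports summed differences over summed alignment lengths.
  For denoised data it counts differences between the denoised sequence a
  read maps to and the closest reference of the *original* read, so
  misassignment during denoising is charged as error.
* `classify_vs_reference()` labels a sequence Good / Bimera / Trimera /
  Quadramera by whether the best 1-, 2-, 3-breakpoint reconstruction from
  the references improves the match by at least three nucleotides per
  additional breakpoint (dynamic programming over prefix-mismatch arrays,
  exhaustive over breakpoints), requiring `e < 0.15` for any label;
  otherwise Unclassified.
* `cluster_otus()` builds OTUs by hierarchical clustering (complete or
  average linkage) of exact pairwise percent differences; the unit-cost
  scoring (mismatch 1, gap 1, over all alignment columns) is this package's
  choice of percent-difference definition. `otu_accuracy()` clusters
  references and denoised sequences jointly and labels each OTU Good
  (both), Missed (references only) or Noise (denoised only).

# The synthetic generator

`mock_community()` emulates a mixture of known clones: references descend
from a common root at ~12% divergence (pairwise at least 7%, so every read
maps unambiguously), with even or geometrically spread abundances.
`simulate_amplicon_pool()` applies per-cycle substitutions — a random final
molecule's lineage contains Binomial(cycles, 1/2) synthesis events under
ideal doubling, which is why a total observed frequency `f` corresponds to
a per-cycle rate `2 f / cycles` — and injects chimeras by splicing two
references at a breakpoint drawn uniformly from the 20–50% span of the
molecule, with type counts never exceeding either parent's count (the
abundance ordering the classifier exploits). `simulate_flowgrams()` draws
each flow's intensity from the intensity model's distribution for the true
run length. Everything is seeded and reproducible.

What the generator does *not* emulate: optical crosstalk and
carry-forward/incomplete-extension phasing (the 454 analogue of
cross-talk), primer or GC amplification bias, abundance-dependent PCR
bias, quality-score structure, and contaminants. Passing tests on this
generator therefore show that the algorithms remove the noise *they
model* under realistic magnitudes — not that real 454 runs contain only
that noise.

## Study scale

The standard benchmark (`synthetic_benchmark()`) uses 20 references of
300 nt, 2000 reads, 30 PCR cycles at the default per-cycle rates, 5%
chimeras, and GS FLX geometry (400 raw flows, 360 kept). A random sequence
consumes about 1.5 flows per base, so 300 nt references comfortably fill
the 400-flow window and the 360 kept flows call about 240 nt; analyses
truncate at 200 bp, safely inside every filtered read. Chimera breakpoints
are drawn mid-molecule (20–50%) because incomplete extension is a
mid-molecule event and both fragments must lie inside the sequenced window
to be observable at all. These sizes were chosen once as a desk-scale
analogue of a mock-community run.

# Numerical choices and degenerate inputs

* Intensity bins of 0.01 flow units (the native precision of 454 flow
  values), run lengths modelled to 9 (longer runs reuse the last column),
  empty bins at distance cap 100 (−log of a vanishing probability; keeps
  arithmetic finite).
* EM convergence: largest responsibility change below 1e-6, cap of 1000
  iterations (a warning flags the cap); the observed-data log-likelihood is
  asserted non-decreasing to 1e-8 in the tests. The `1/sigma` normaliser of
  the exponential kernel is constant and omitted from likelihood
  comparisons.
* Tie-breaking: candidates are ordered by abundance (descending) then
  sequence (lexicographic); argmin/argmax take the first index. Runs are
  therefore bit-reproducible.
* Complete-linkage cuts above the dendrogram height, or below the smallest
  merge, degrade to one cluster / all singletons; empty inputs error.
* Binomial tails with zero changes are 1 (index contribution 0); parts with
  no ungapped columns leave the candidate unscored (probability 0).

# Limitations

The flowgram stage assumes all filtered reads share a common truncated
flow count and does not align flowgrams, so it corrects intensity noise
only — indels that survive into the called sequence are handled by the
homopolymer-aware aligner of stage 2. The chimera index is defined for
two-parent chimeras; higher-order chimeras are usually caught anyway
(their best two-parent reconstruction is already convincing), and the
reference-based labeller handles up to four parents for evaluation. Runtime
is dominated by the pairwise distance matrices; both are exact, so very
large runs should be pre-split (e.g. by sample) as is standard practice.
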