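---
title: "Models and methods for duplicated-gene evolution and expression divergence"
author: "paralogEvol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for duplicated-gene evolution and expression divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogEvol)
```

# Scope

`paralogEvol` implements the analysis pipeline used to characterise small
duplicated gene subfamilies — the motivating case being the tomato
phytochrome-interacting factor (*PIF*) clades, each represented by three
Solanaceae orthologs. Five questions drive the design: how far have the
paralogs diverged at synonymous and non-synonymous sites; when did the
duplications happen; has codon usage drifted; is any paralog under
positive selection, and at which residues; and has the *regulatory*
rather than the coding sequence diverged (promoter motifs, expression
profiles). Every stage has a matching simulator with known ground truth,
so the whole pipeline is testable without external sequence downloads.

# Coding-sequence divergence

## Alignment handling

All codon-level statistics operate on a `CodonAlignment`: equal-length
in-frame sequences from which every codon column containing a gap, an
ambiguous base, or a stop codon in *any* sequence has been deleted whole.
Complete deletion at codon granularity is the only gap treatment that
preserves the reading frame, and Nei–Gojobori site counting is undefined
for ambiguous codons, so `N` is treated like a gap. Deletion is
idempotent and never splits a codon.

## NG86 distances with Jukes–Cantor correction

`countSites()` scores each codon position by the fraction of its three
single-base changes that are synonymous, excluding changes to stop
codons from the denominator — the classic NG86 convention, which keeps
S + N = 3 per codon exactly. `countPathwayDifferences()` averages
synonymous/non-synonymous step counts over all orderings of the differing
positions, excluding pathways that pass through stop codons; in the
degenerate case where every pathway is blocked, the average is taken over
all pathways with stop steps scored non-synonymous and the result is
flagged. Observed proportions pS and pN are corrected for multiple hits
with Jukes–Cantor, d = −(3/4) ln(1 − 4p/3); p ≥ 3/4 is reported as a
saturation error naming the pair.

The per-pair "± SD" summary is the sample standard deviation across the
n(n−1)/2 pairwise comparisons. With three sequences this is a coarse
dispersion measure, not a bootstrap standard error; the two are not
interchangeable, and no bootstrap SE is implemented.

## Molecular clock

`divergenceTime()` applies T = dS / (2K). The default K = 4.38 × 10⁻⁹
substitutions/site/year is a mean synonymous rate estimated across
multiple *Solanum* loci and is only appropriate for tomato and close
relatives; it is an explicit argument everywhere it is used.

## Effective number of codons

`effectiveNumberOfCodons()` implements Wright's Nc from per-amino-acid
codon homozygosity F. The default estimator is the raw Σp² (deterministic
on fixed input); the bias-corrected (nΣp² − 1)/(n − 1) variant used by
CodonW is available. Families observed fewer than twice take the mean F
of the observed families in their degeneracy class; a wholly unobserved
class falls back to its uniform expectation F = 1/k, which keeps Nc
defined on short sequences. Under uniform synonymous usage Nc is exactly
61; with one codon per amino acid the formula gives exactly 20 (the
often-quoted lower bound of 21 does not follow from the formula, and this
package reports 20). Estimates above 61 are clamped with a warning.

# Site models of selection

## The codon model

Likelihoods use the Goldman–Yang codon substitution model: instantaneous
rates proportional to π_j, multiplied by κ for transitions and ω for
non-synonymous changes, zero for multi-nucleotide changes. Equilibrium
frequencies default to F3x4 (position-specific nucleotide frequencies,
renormalised over sense codons, floored at 10⁻¹⁰ so the reversible
machinery stays defined). Transition matrices exp(Qt) come from
eigendecomposition of the generator in the π-symmetrised basis, which is
numerically stable for the 61-state reversible chain. In mixtures the
class generators share a single scale factor (the mixture mean rate), so
a branch length is the expected number of substitutions per codon
averaged over classes — the same convention the simulator uses.

## M0, M1a, M2a and the LRT

Three standard site models are fitted by bounded L-BFGS-B over κ, the
branch lengths and the model parameters: M0 (one ω), M1a (purifying
class 0 ≤ ω₀ < 1 plus a neutral class fixed at ω₁ = 1) and M2a (M1a plus
a positive class ω₂ ≥ 1). Bounds are ω ∈ [10⁻⁴, 99], κ ∈ [0.1, 30],
branch lengths ∈ [10⁻⁶, 10]; the default run uses 5 optimizer starts
(the first from a default or warm start, the rest jittered under a fixed
seed), relative log-likelihood tolerance ≈ 10⁻⁸ and parameter scaling
matched to the start. Starting branch lengths come from the mean pairwise
Jukes–Cantor nucleotide distance. Fitting a nested chain with warm starts
(`init = previous fit`) is both faster and guarantees in practice the
nesting order lnl(M0) ≤ lnl(M1a) ≤ lnl(M2a); the pipeline always does
this. κ and branch lengths are re-estimated per model rather than fixed
from M0 — the cheaper alternative was rejected because the LRT compares
maximised likelihoods.

`likelihoodRatioTest()` computes 2Δl with χ² upper-tail p-values (df 1
for M1a vs M0, df 2 for M2a vs M1a). Small negative statistics are
optimizer noise on boundary fits and are clamped to zero; magnitudes
beyond 0.01 additionally warn. Because the null values of the extra
parameters lie on the boundary of the parameter space, the χ² reference
distribution is conservative — the empirical type-I error of the
M2a-vs-M1a test in the test suite's 200 null simulations is well below
the nominal 5%.

## Bayes empirical Bayes site identification

`bebSitePosteriors()` computes, for an M2a fit, the posterior probability
that each codon site belongs to the positive-selection class, integrating
over parameter uncertainty on a discrete prior grid: (p0, p1) uniform
over the probability triangle and ω₀ ∈ (0, 1), ω₂ ∈ (1, 11) each
discretised into 10 bin midpoints (the conventional grid size). Branch
lengths, κ, the codon frequencies and the generator scale are fixed at
their maximum-likelihood values. The flagging threshold defaults to a
posterior of 0.95. Sites are reported with their 1-based position in the
gap-deleted alignment and the residue of a named reference sequence —
positions therefore shift relative to the raw CDS by the number of
deleted codon columns before them.

# Trees

Distance matrices use p-distance or Jukes–Cantor with *pairwise* deletion
of gap/ambiguous positions — promoter alignments are gappy, and pairwise
deletion keeps more signal; the codon module deliberately keeps complete
deletion, and the difference is intentional. Neighbor-joining and newick
I/O delegate to `ape` (Saitou–Nei NJ with the standard Q-criterion);
negative branch-length estimates are clamped to zero and counted.
`bootstrapSupport()` resamples alignment columns, rebuilds the NJ tree
per replicate, and reports the percentage of replicates containing each
internal bipartition of the full-data tree, reproducible under a fixed
seed.

# Promoter motifs

Promoters are modelled as 2-kb fragments upstream of the translation
start. Motifs are IUPAC consensus strings with fixed-length repeat
notation (`CCW{6}GG`); matching uses `Biostrings` degenerate pattern
matching on both strands, with minus-strand hits reported in forward
0-based half-open coordinates. All overlapping matches are reported (no
masking); a palindromic consensus matching the same span on both strands
yields a single hit. The shipped motif set (CArG, PBE-box, G-box, E-box,
ACE, CA-hybrid, CG-hybrid) lives in a configuration file rather than in
code because the hybrid/ACE consensus strings come from the
light-signalling literature, not from a single canonical source, and
should be revalidated before biological use.
`comparePromoterMotifs()` partitions observed motif names of a paralog
pair into shared and exclusive sets with per-motif counts.

# qPCR expression analysis

`windowOfLinearity()` re-implements the window-of-linearity idea for
absolute fluorescence data: baseline = mean of cycles 1–5 subtracted;
best 4–6-cycle window by r² of the log-linear fit; efficiency
E = 10^slope; threshold = geometric midpoint of the window's
fluorescence span; Ct = fractional crossing cycle; quantity = threshold /
E^Ct. The original tool's iterative baseline estimation is deliberately
simplified to a fixed baseline window — a documented deviation that is
exact for curves with a flat early phase. Efficiencies outside (1, 2.5]
are flagged rather than rejected.

Normalisation divides each target quantity by the mean of two
constitutively expressed reference genes (arithmetic by default; the
geometric option exists because the literature is split on this point).
Technical replicates are collapsed by geometric mean of quantities before
biological-replicate statistics. Fold changes divide per-sample means by
the baseline-sample mean, making the baseline column identically 1.

The permutation test uses the absolute difference of group means,
enumerating all label reassignments exhaustively when their count is at
most 20,000 (deterministic, seed-independent) and Monte Carlo sampling
otherwise, with the add-one correction p = (count + 1)/(m + 1) for
validity. One discreteness consequence deserves emphasis: with exactly
3 + 3 replicates the exhaustive two-sided test has a minimum attainable
p of 3/21 ≈ 0.14, so no 3-vs-3 comparison can reach P < 0.05 — a real
limitation of distribution-free testing at minimal replication, not a
bug. Power examples in the test suite therefore use 4 replicates, where
the minimum p is 3/71 ≈ 0.04. Raw per-comparison p-values are reported
(mirroring per-comparison testing at P < 0.05); Benjamini–Hochberg
adjusted values are emitted alongside for users who prefer them.

# Simulators and what passing tests show

The three generators produce data with the statistical structure the
analysis assumes, each deterministic under a fixed seed and each emitting
its ground truth: codon alignments evolved site-by-site from exact
transition matrices under an ω-class mixture (no Gillespie simulation —
sampling from exp(Qt) is exact at 61 states) with hidden class labels;
qPCR experiments with constant reference genes and planted fold changes
(Ct tables or full sigmoidal curves); promoter sequences with planted
IUPAC motif instances and BED-style truth. Default conditions mirror the
motivating study: 3-taxon alignments of a few hundred codons with
synonymous divergence in the few-percent range, two reference genes with
at least three biological replicates and 2–5-fold expression changes, and
2-kb promoters.

The simulators deliberately omit features of real data: no indels (the
alignment stage consumes aligned input), no within-codon rate
heterogeneity beyond the ω classes, no amplification inhibitors or
multi-plate batch effects, and i.i.d. promoter background. Passing
recovery tests therefore demonstrates correctness of the estimators under
the model's own assumptions, not robustness to alignment error,
saturation, or non-exponential amplification.

# Problem sizes and numerical choices

Test and example problem sizes are chosen so each check is decisive at
desk scale: M0 recovery uses 500-codon 3-taxon alignments; the BEB
recovery case uses 800 codons with ω₂ = 8 at 10% of sites; the
M2a-vs-M1a type-I error study uses 200 null replicates of 200 codons
with warm-started single-start fits; permutation-test calibration uses
2000 null datasets of 5 + 5 replicates; stationarity of the codon
simulator is checked at 50,000 sites. Degenerate inputs are handled
explicitly: saturated distances, flat amplification curves, all-gap
columns and stop-only sequences are errors with informative messages;
boundary likelihood fits (proportions at 0/1) are valid results, and the
LRT clamps the resulting noise at zero.

# Known limitations

Only the standard genetic code ships (the code table is injectable, and
tests exercise toy codes); pairwise dN/dS is NG86-with-JC only (no
transition/transversion-weighted counting, no ML pairwise estimates);
site models cover M0/M1a/M2a (no branch or branch-site models, no
M7/M8); trees are distance-based NJ only; motif scanning is consensus
matching, not PWM scoring; and the qPCR module does not model melt
curves or multi-plate calibration.
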