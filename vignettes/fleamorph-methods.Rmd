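---
title: "Dual-evidence flea species discrimination: methods and design notes"
author: "fleamorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-evidence flea species discrimination: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fleamorph)
```

## The problem

The dog flea *Ctenocephalides canis* and the oriental cat flea
*C. orientis* co-occur on dogs across Asia and are hard to tell apart with
traditional morphological keys: the discriminating characters (setae-bearing
notches on the hind tibia, the angle of the cephalic profile) overlap
between the species, and in surveys where both occur a third to a half of
*C. orientis* can be mislabelled as *C. canis*. fleamorph implements a
two-track identification workflow for this problem:

1. **Geometric morphometrics of the head.** Thirteen two-dimensional
   landmarks per flea head — five fixed anatomical points plus a head-outline
   curve resampled into ten equally spaced semilandmarks, two of which
   coincide with fixed landmarks — are superimposed by generalized
   Procrustes analysis (GPA) and analysed in the tangent space of shape
   space (Procrustes ANOVA, canonical variate analysis, two-group
   discriminant function analysis with leave-one-out cross-validation).
2. **cox1 DNA barcoding** as the reference identification: amplicons are
   collapsed into haplotypes, matched against a reference haplotype panel,
   and summarized through Kimura-2-parameter (K2P) distances and a
   neighbor-joining / minimum-evolution tree with bootstrap support.

Survey-level statistics (prevalence with Wald confidence intervals, species
composition, sex ratios, and contingency tables comparing morphological
against molecular identification) tie the two tracks together. Because the
original specimens are not redistributable, the package carries seeded
generators that emulate the statistical structure of such a survey; every
stage of the pipeline is exercised and tested against them.

## Shape model and superimposition

A configuration is an ordered set of p = 13 points in the plane. Centroid
size — the root summed squared distance of the landmarks from their
centroid — is the size variable removed by superimposition. GPA here fixes
every configuration at unit centroid size, and iterations only **rotate**
each specimen onto the running consensus (the per-iteration mean shape,
renormalized to unit size); there is no per-iteration rescaling by the
cosine of the Procrustes distance. This is the convention of the standard
"Procrustes fit" in morphometric software, and it differs slightly from
"full Procrustes mean" estimators that rescale. Reflections are never
allowed (rotation determinant +1), so a mirrored specimen is a different
shape; an optional per-specimen reflect step before analysis is the
caller's responsibility. Convergence is declared when the consensus moves
less than `tol = 1e-10` between sweeps (root sum of squares). The iteration
cap defaults to 500: realistic datasets converge in a handful of sweeps,
but widely dispersed shape sets — which arise in invariance testing — can
legitimately need over a hundred.

Aligned pre-shapes are projected orthogonally onto the tangent space at the
consensus (the component along the consensus vector is removed). The
resulting n x 2p coordinate matrix has rank at most 2p - 4 = 22: two
dimensions of translation, one of scale and one of rotation are gone.
Pairwise full Procrustes distances are computed from the planar
complex-coordinate closed form; numerically they use the residual-vector
form ||u_A - b u_B|| with b the complex least-squares coefficient, which
remains accurate when two shapes nearly coincide (the naive
sqrt(1 - |b|^2) bottoms out near sqrt(machine epsilon)).

## Procrustes ANOVA

The sex-by-species factorial ANOVA is Goodall-style isotropic: sequential
(Type I) sums of squares, in the order sex, species, sex x species, are
computed coordinate-wise from nested least-squares fits and summed over all
2p tangent coordinates. Degrees of freedom multiply the univariate effect
df by the shape dimension 22, so a 165-specimen dataset has df
(22, 22, 22, 3542). Published tables of this design test the two main
effects against the **interaction** mean square and the interaction against
the residual; that convention is the default (`error_stratum =
"interaction"`), with the plain everything-over-residual Goodall convention
available via `error_stratum = "residual"`. The sequential order is
configurable; with unbalanced cells the main-effect SS depend on it, their
sum does not.

## CVA, DFA and validation

Tangent coordinates are rank-deficient, so both CVA and DFA first project
onto the principal subspace of the pooled within-group covariance
(relative eigenvalue above 1e-9). Canonical axes solve the between/within
generalized eigenproblem there and are scaled to unit pooled within-group
variance; with four groups there are exactly min(g - 1, rank) = 3 canonical
variates and their variance percentages sum to 100. Mahalanobis distances
between group means use the pooled within-group covariance with divisor
n - g.

Permutation tests on pairwise group distances (Mahalanobis or between-mean
Euclidean/Procrustes) permute the labels of the two groups' specimens; the
p-value is (b + 1)/(n_perm + 1) with ties counted as extreme, so the
smallest attainable p is 1/(n_perm + 1). The default is 10,000 rounds;
1,000 is a supported alternative, because the source workflow reports both
figures in different places and the discrepancy is preserved as a
parameter rather than resolved. A single integer seed makes every
permutation stream reproducible and is recorded in the result object.

Two-group DFA uses the discriminant axis W^-1 (mu1 - mu2) in the reduced
space and classifies by score against the **midpoint of the two group mean
scores** — not by Mahalanobis distance to centroids, and with no prior
weighting, which keeps the null misclassification rate near 50% even for
unbalanced groups. Leave-one-out cross-validation refits the entire
pipeline (subspace, axis, cutoff) on each fold. Fold improvements over an
external observer are quoted the way field reports do: per-class
misclassification rates are rounded to whole percent first and the fold is
the ratio of the rounded rates to one decimal (31% over 6% is "5.2-fold").

## Molecular track

Sequences are assumed to be ungapped cox1 amplicons (550–650 bp) sharing a
5' anchor; comparison regions come from simple end-trimming, never from a
full alignment, and a length difference above 60 bases is an error. A
haplotype is an exact string match over the comparison region (the whole
sequence in `full_length` mode; the 5'-anchored common overlap of at least
400 positions in `common_overlap` mode, so terminal truncations do not
split haplotypes). Reference-panel matching uses the same rule; an overlap
under 400 positions is a no-call, and multiple panel hits are an ambiguity
error rather than a silent choice.

K2P distances delete sites pairwise wherever either sequence carries a gap,
N or ambiguity code, then apply d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)
to the transition proportion P and transversion proportion Q. Saturation
(either log argument non-positive) is an error in the scalar function and a
flagged NA in the matrix. Trees are built by Saitou–Nei neighbor joining
(negative branches clamped to zero; exact on additive matrices) and refined
under the minimum-evolution criterion: ordinary-least-squares non-negative
branch lengths, greedy nearest-neighbor-interchange moves accepted only
while total tree length strictly decreases. Bootstrap support resamples
alignment columns, rebuilds the full k2p → NJ → ME pipeline per replicate,
and reports the percentage of replicates containing each internal
bipartition of the point tree; saturated replicates are skipped and
counted.

## What the generators emulate — and what they do not

`simulateLandmarkDataset()` produces the study-scale structure: group sizes
(86, 26, 45, 8) for canis-F/canis-M/orientis-F/orientis-M, isotropic
Gaussian landmark noise (the classical assumption behind Goodall-style
ANOVA), and species/sex/interaction displacements along fixed orthogonal
unit tangent vectors. The defaults are set once from the scale of the
published shape ANOVA: per-coordinate noise sd 0.007 Procrustes units
(which reproduces a residual mean square near 5e-5 at n = 165), species
and sex displacements 0.024 and 0.027 (variance partitioning of the
printed sums of squares), interaction 0.004. The template head (five
anchors plus a circular arc) is a documented fixture, not an anatomical
reconstruction, so wireframe geometry and the published canonical-variate
percentages (79.3/18.8) are **not** reproduced — group sizes, df
bookkeeping, error scales and separability are. Digitization nuisance
(rotation, log-uniform scale in [0.5, 2], translation) is applied per
specimen and must be fully absorbed by GPA.

`simulateCox1Dataset()` realizes the published haplotype profile — 22
*C. canis* haplotypes with multiplicities 56, 20, 7, 2, 2, 1, 1, 7, 1, 1,
2, 1, 1, 1, 1, 1, 1, 2, 1, 2, 1, 1 and 3 *C. orientis* haplotypes (25, 18,
10); 25 haplotypes over 166 sequences — at amplicon length 614. Within-
species maximum K2P targets default to the published 0.012 (canis) and
0.064 (orientis); the between-species divergence is not printed in the
source and defaults to 0.12, a typical congeneric cox1 distance.
Substitution counts are solved exactly from the K2P inversion at
transition/transversion ratio 2 and placed at uniform random sites with no
rate heterogeneity, so the generator is a structural stand-in, not a
coalescent simulation. One reported discrepancy is worth noting: the
source's results text counts 25 haplotypes while a figure legend mentions
17; the generator follows the results text.

`simulateObserverIds()` draws morphological calls from a row-stochastic
confusion matrix whose defaults encode the published error pattern (31%
of female and 57% of male *C. orientis* called *canis*; ~8% errors on
*C. canis*; 10% indeterminate). `simulateSurvey()` produces 77 dogs with
infestation probability 43/77, zero-truncated-geometric flea burdens with
mean 199/43, and the published species composition and per-species sex
splits.

A green test on synthetic data therefore establishes that the machinery is
correct and calibrated to the study's scales — it does not establish the
published real-data F statistics, CV percentages or LOO error counts,
which depend on the deposited specimens.

## Numerical choices and edge cases

* Rounding: percentages to whole percent, half away from zero (base R's
  `round` is half-even, which would turn 31.5 into 32 but 16.5 into 16);
  sex ratios to two decimals half-to-even, so 45/8 = 5.625 prints 5.62.
  The Wald interval with z = 1.959964 is the default CI because it
  reproduces standard spreadsheet survey reporting; Wilson and
  Clopper–Pearson are available behind a flag.
* Indeterminate morphological calls are tabulated but excluded from
  misclassification denominators — only specimens identified by both
  methods count.
* TPS coordinates pass through untransformed (tpsDig's origin is the lower
  left of the image); `flip_y` negates y on request, and `SCALE=` is
  applied only when asked. GPA is invariant to both, raw exports are not.
* Haplotype ids are assigned in decreasing count order, ties by first
  appearance; all tree tie-breaks are deterministic, and every stochastic
  routine takes an explicit seed that is recorded in its output.
* Degenerate inputs fail loudly: all-identical landmark configurations,
  zero-length curves, empty factorial cells, saturated distances, mixed-
  species haplotypes and unknown dog ids are errors, not silent fixes.
  Zero shape variance turns the ANOVA F into NaN with a warning.

## Known limitations

* The landmark template is synthetic; anatomical wireframes and published
  canonical-variate geometry are out of reach by design.
* Sequence handling assumes ungapped, 5'-anchored amplicons; indels or
  5'-truncated reads would require a real aligner, which is out of scope.
* Minimum-evolution search is NNI-only (no subtree pruning), matching the
  default search depth of standard distance-tree software.
* DFA is strictly two-group; the four-group ordination is CVA's job.
* The acceptance property on LOO accuracy at a 3-sigma species effect is
  averaged over 25 replicates (observed mean ~0.998 against a 0.90 bound);
  the null-effect 50% +/- 5% check runs the full 200 replicates.
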