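---
title: "Methods: compositional encoding and hierarchical SVM prediction of heat shock proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional encoding and hierarchical SVM prediction of heat shock proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Heat shock proteins (HSPs) are molecular chaperones found across all
domains of life, conventionally grouped by molecular weight into HSP20,
HSP40 (DnaJ), HSP60, HSP70, HSP90 and HSP100; DnaJ proteins subdivide
further into Types I–IV by the presence of the J-domain, the G/F-rich
region and the zinc-finger domain. hspkit predicts, from amino-acid
sequence alone, (1) whether a protein is an HSP, (2) which family it
belongs to, and (3) for HSP40, its DnaJ sub-type — a three-stage cascade
of kernel support-vector machines over compositional sequence
descriptors.

## Descriptors

**GPC — g-spaced amino-acid pair composition.** For a gap $G \ge 0$, a
pair occupies positions $p$ and $p+G+1$ (i.e. $G$ residues are skipped
between its members), so $G=0$ is the ordinary dipeptide composition. A
sequence of length $N$ contains exactly $N-G-1$ such pairs, and the
descriptor for the ordered pair $(i,j)$ is

$$f_G(i,j) = \frac{D_G(i,j)}{N-G-1},$$

where $D_G(i,j)$ counts occurrences. Each gap contributes 400
descriptors summing to one; the concatenation over gaps 0–3 ("GPC-0123")
has 1,600. This gap semantics is the only reading under which the
denominator equals the number of pairs, which is why we adopted it.

**PAAC — pseudo amino-acid composition.** A residue property
$\Theta_o$ (default: Kyte–Doolittle hydropathy) is standardized over the
alphabet to zero mean and unit root-mean-square deviation
(denominator 20). The tier-$j$ sequence-order factor is
$\rho_j = \frac{1}{L-j}\sum_i [\Theta(\psi_i)-\Theta(\psi_{i+j})]^2$,
and the $(20+d)$-vector is
$\theta_x = f_x / (\sum f + w \sum \rho)$ for the 20 compositions and
$\theta_{20+j} = w\rho_j / (\sum f + w \sum \rho)$ for the order terms.
We take $f_x$ as the raw occurrence count (Chou's original convention),
which makes $\sum_x \theta_x = 1$ an exact identity — the package tests
assert it to $10^{-9}$. Defaults $d=1$, $w=0.05$ follow the classical
convention; both are configurable. The correlation function is the
squared difference of standardized property values: a homopolymer
therefore has $\rho_j = 0$ exactly, another asserted identity.

**CTD — composition/transition/distribution.** Each physicochemical
attribute partitions the alphabet into three groups; per attribute we
emit 3 composition fractions, 3 transition frequencies (adjacent pairs
across a group pair, either order, over $N-1$), and 15 distribution
values: the positions of the first, 25%, 50%, 75% and last residue of
each group, divided by $N$, using the `ceiling(q·count)`-th occurrence
for the interior quantiles and all-zero for an absent group. The default
scheme ships as a data file with seven classical attributes
(hydrophobicity, van der Waals volume, polarity, polarizability, charge,
secondary structure, solvent accessibility), hence 147 descriptors; any
other three-group scheme can be supplied as a TSV. A fixed 21-per-attribute
layout is the standard (Dubchak) encoding; we chose it because a
descriptor whose dimension grows with sequence length cannot feed a
fixed-width classifier.

**ACF — property autocorrelation.** For each property table $u$
(standardized exactly as in PAAC) and lag $j \le n$:
$\mathrm{acf}_u(j) = \frac{1}{N-j}\sum_{i=1}^{N-j} u(\psi_i)\,u(\psi_{i+j})$.
This mean-lagged-product form is the simplest autocorrelation consistent
with "dependencies between sequence features at each location"; we use
standardized rather than raw property values so tables on arbitrary
scales contribute comparably. The bundled collection has five classical
scales; a full AAindex-style collection (531 entries) can be supplied as
a TSV, giving $531\,n$ descriptors.

## Feature selection

Five rankers are provided, each pinned to its standard literature
formulation because the upstream criteria are not otherwise specified:
two-class F-score (Chen & Lin style), mutual information after
equal-frequency 10-bin discretization, absolute L1-logistic coefficients
at the penalty chosen by internal 5-fold cross-validation (glmnet),
impurity importance from a 500-tree random forest (ranger), and absolute
linear-SVM weights. Ties break by feature name for determinism, and
stochastic rankers take an explicit seed. The default subset size
$k=484$ mirrors the convention of selecting as many features as the L1
path retains with non-zero coefficients; since that count is
data-dependent, $k$ is a free parameter here.

## Classifiers and the cascade

SVMs use e1071 (libsvm) with the four basic kernels at their default
parameters: cost 1 and $\gamma = 1/\text{(number of features)}$ where
applicable. `kernel_screen()` picks the kernel with the highest
cross-validated mean accuracy (ties broken radial, linear, polynomial,
sigmoid). Columns are standardized inside the fit — e1071's own default.
This matters numerically: raw GPC entries are of order $1/400$, so
without rescaling the squared distance between two feature vectors is
$\sim 10^{-2}$ and the radial kernel at $\gamma = 1/d$ is nearly
constant across all pairs, which we measured to both slow convergence
severely and waste the signal. The standardization is recorded in the
model's provenance.

The cascade (stage 1: HSP vs non-HSP at probability threshold 0.5,
configurable; stage 2: six-family multi-class, maximum probability;
stage 3: DnaJ sub-type, consulted only for stage-2 HSP40 calls) shares
one encoder and one selected feature list across stages, enforced at
composition time. Stage 2 is a single multi-class classifier with
probability outputs (libsvm's pairwise coupling) rather than six
independent binary machines, because a predictor must emit exactly one
family per sequence; the evaluation module still reproduces the
per-family one-vs-rest binary protocol for reporting. Model bundles
serialize to a directory with a JSON manifest (kernels, classes, feature
list, seeds, training-data digests) for reproducibility.

## Evaluation protocol

Sensitivity, specificity, accuracy, precision and Matthews correlation
are computed from exact confusion counts; any ratio with a zero
denominator is reported as `NA` rather than 0, so undefined folds cannot
drag averages down silently. AUC-ROC is the trapezoidal area over the
full threshold sweep, which the tests verify equals the exhaustive
pairwise-ordering probability with ties counted one half. AUC-PR uses
the step-wise average-precision rule, not trapezoids, because linear
interpolation in PR space is biased; comparisons against other
implementations should note the convention.

Cross-validation is stratified five-fold by default (per-fold class
counts within one of proportionality) with leave-one-out available;
fold-mean metrics are averaged, not pooled. For imbalanced
positive/negative pools, `balanced_resample_eval()` draws repeated
equal-sized samples (100 by default), cross-validates each, and reports
means with standard errors across samples.

## The synthetic benchmark

The generator emulates the one property of real HSP data this method
exploits: family-specific enrichment of gapped residue pairs. Each
family profile plants four unique (residue, residue, gap) signatures,
one per gap 0–3, by rewriting positions of an i.i.d. background sequence
— rewriting guarantees the intended enrichment at any length in bounded
time, where rejection sampling would not. Defaults are the study
conditions: family counts 354/1257/159/278/52/81 (the heavy imbalance of
curated HSP collections), 2,181 signal-free non-HSP sequences (a
balanced stage-1 design mirroring the practice of drawing equal-sized
negative samples), uniform background frequencies, enrichment multiplier
8, and lengths uniform on 80–600 to straddle the length variability real
families show. The DnaJ benchmark uses counts 63/53/1107/22 with two
planted pairs per type.

What passing tests on this benchmark do show: the whole pipeline —
encoding, selection, training, gating, evaluation — recovers a planted
compositional signal at realistic class imbalance, and stays at chance
(accuracy within 0.45–0.55 over resampled draws) when no signal exists.
What they do not show: performance on real proteins, whose families
share homology, domain architecture and length structure far richer than
planted pairs; accuracy figures on this benchmark are not comparable to
published accuracies on curated HSP datasets.

## Problem sizes and numerical choices

The acceptance analyses run the full Table-shaped benchmark (4,362
sequences, 1,600 GPC features reduced to 484 by random-forest ranking)
for stage-1 five-fold cross-validation, one-vs-rest family evaluation,
and an 80/20 stratified hold-out for the end-to-end cascade; the DnaJ
evaluation uses five-fold cross-validation rather than leave-one-out,
whose 1,245 refits would cost hours without changing the conclusion at
this scale. The null calibration averages ten balanced draws of 200+200
from 300-sequence pools. Unit tests use smaller generated fixtures
(tens to hundreds of sequences) chosen to exercise every contract.

Degenerate inputs are errors, not warnings: sequences shorter than
$G+2$ (GPC), $d+1$ (PAAC) or the ACF order; constant property tables
(standardization undefined); all-constant feature matrices for the
L1/SVM rankers; draws exceeding a resampling pool. Encoding a dataset
reports every failing sequence, not just the first; batch prediction
records per-sequence failures inline and continues.

## Known limitations

- The generator plants independent pair signals; it does not simulate
  homology, motifs, domains or phylogenetic structure.
- Probability calibration uses libsvm's internal sigmoid fit on training
  data; probabilities near the 0.5 stage-1 threshold should be read as
  ordering scores, not calibrated frequencies.
- LOOCV is provided and tested but not used in the large acceptance
  analyses (see above).
- The bundled property collection is a five-scale stand-in for the full
  AAindex database; ACF feature counts quoted for 531 indices require a
  user-supplied table file.
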