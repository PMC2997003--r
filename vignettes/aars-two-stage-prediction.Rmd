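---
title: "Two-stage prediction of aminoacyl-tRNA synthetases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage prediction of aminoacyl-tRNA synthetases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Aminoacyl-tRNA synthetases (aaRSs) charge tRNAs with their cognate amino
acids and fall into two structural classes: class-1 enzymes carry the
Rossmann-fold catalytic domain with the HIGH and KMSKS signature
peptides, while class-2 enzymes are built around an antiparallel
beta-sheet with three conserved motifs. Because aaRSs have limited
sequence homology, plain similarity search annotates them poorly, which
motivates a feature-based classifier. `aaRSpred` implements a two-stage
cascade: stage 1 decides aaRS versus non-aaRS, and stage 2, applied only
to stage-1 positives, assigns class-1 (the positive label) versus
class-2.

## The model

Every sequence is mapped to a fixed-length vector combining:

* **Amino-acid composition** — 20 features, the percentage of each
  residue, `100 * count(r) / L`.
* **Dipeptide composition** — 400 features over overlapping length-2
  windows, `100 * count(d) / (L - 1)`, in grid order (first letter
  major). The denominator `L - 1` is the number of windows; composition
  blocks therefore each sum to 100.
* **Selected dipeptides** — fixed reference subsets shipped with the
  package: 18 dipeptides separating aaRS from non-aaRS and 14 separating
  class-1 from class-2 (`selectedDipeptides()`). These printed subsets
  are the default hybrid features; `rankFeatures()` reproduces the
  selection procedure (recursive elimination by squared linear-SVM
  weight) when users want to re-derive subsets on their own data.
* **Domain bits** — 1/0 presence of PROSITE domains: four for stage 1
  (PS50862, PS00178, PS50860, PS50861) plus PS50889 for stage 2
  (`prositeDomains()`). PS00178 and PS50889 are preferred in class-1,
  the other three in class-2 (`classPreferredDomains()`).

The hybrid vectors have 22 dimensions (18 + 4) for stage 1 and 19
(14 + 5) for stage 2; the amino-acid hybrids have 24/25 and the full
dipeptide hybrids 404/405.

Classification uses a soft-margin SVM with an RBF kernel,
$K(u,v) = \exp(-\gamma\|u-v\|^2)$. Features enter the kernel as raw
percentages and 0/1 bits, with no per-feature rescaling: the vector is
already bounded and commensurable, and skipping rescaling means a stored
model and freshly extracted features are always on the same scale. A
decision value $\ge$ threshold (default 0) calls the positive class.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| SVM cost C | 1 | the library default; the planted synthetic signal is strong enough that CV results are insensitive to C, and `tuneSVM()` (grid C in 0.1-100, gamma in $2^{-7}..2^3$, selected by mean 5-fold CV accuracy with MCC tie-break) is available when they are not |
| RBF gamma | 1/dimension | standard heuristic for percent-scale inputs |
| decision threshold | 0, swept over $-1..1$ in steps of 0.1 | the sweep grid matches the published per-threshold evaluation layout |
| RFE batch | 1 feature/round at $\le 50$ survivors, else 10% of survivors | per-attribute elimination is the reference behaviour; batching keeps 400-feature runs around a minute |
| RFE cost | C = 1, linear kernel | matches the reference attribute-evaluator settings |
| alignment scoring | BLOSUM62, gap open 11 / extend 1 | standard protein local-alignment defaults; a score threshold stands in for an E-value cut-off and is *not* equivalent to one |

## Evaluation

`makeFolds()` produces stratified k-fold splits (per-class fold sizes
differ by at most one). `classMetrics()` computes sensitivity,
specificity and accuracy in percent and the Matthews correlation
coefficient from TP/TN/FP/FN. Conventions: a metric with a zero
denominator is *undefined* (`NA`), except the MCC, which is 0 by
convention; rounding to 2 decimals happens only at presentation
(`presentMetrics()`). Cross-validation reports both the unweighted mean
over folds (the headline figure) and pooled-count metrics, labeled
separately, because the two differ when folds are uneven. ROC curves
are computed internally (points at every distinct decision value,
trapezoidal area); the area equals the normalized Mann-Whitney U
statistic, and the test suite cross-checks it against an independent
implementation.

The similarity baseline classifies each held-out sequence by the label
of its top Smith-Waterman hit against the training folds. The published
no-hit accounting is deliberately preserved: a no-hit positive counts
as a false negative *and a no-hit negative as a false positive*, which
depresses specificity. Because that rule is counterintuitive, a
`corrected` mode (no-hit negative counts as a true negative) is
available behind a flag; the default stays faithful.

## Feature selection placement

The reference subsets were fixed once on the original training data, so
the default pipelines treat them as constants — selection happens
outside the cross-validation loop. Re-deriving the subset inside each
training fold (run `rankFeatures()` on the fold's training partition)
avoids selection bias and is the right choice when reporting CV
estimates for a *newly selected* subset; both routes are exposed, and
the default mirrors the fixed published lists.

## What the synthetic generator emulates

`generateDataset()` draws residues i.i.d. from a background frequency
table (uniform by default; a Swiss-Prot-like table is bundled), then

1. enriches chosen dipeptides by inserting extra copies at random
   positions — direct, verifiable control of exactly the features the
   classifier consumes, rather than indirect Markov-chain tuning;
2. plants signature motifs at uniform random interior positions,
   rejecting positions inside previously planted motifs so every
   recorded motif survives intact (the truth record stores final
   coordinates);
3. emits a domain-hit table consistent with the plan: a coupled hit
   (e.g. PS00178) is emitted only when its motif (HIGH) actually occurs
   in the finished sequence.

Preset conditions, chosen once:

* **stage1** — 200 sequences per class, lengths 300–600 (typical aaRS
  lengths). Positives carry HIGH and KMSKS with probability 0.9,
  PS00178 coupled to HIGH, the class-2-type domains at moderate rates
  (0.25/0.12/0.12, since the aaRS positive set spans both classes), and
  a +0.8-percentage-point enrichment of each of the 18 reference
  dipeptides — a roughly 3-sigma per-feature shift at these lengths.
  Negatives emit each stage-1 domain at 2.5%, so roughly one in ten
  negatives carries some domain, mirroring the low domain contamination
  observed in real negative sets.
* **stage2** — 100 per class. Both classes carry the stage-1 aaRS
  signal (so the full cascade is exercisable end to end: class-2 aaRSs
  are still aaRSs); the contrast comes from splitting the 14 reference
  dipeptides between the classes, class-specific motifs, and hit tables
  drawn exclusively from the class-preferred domain sets. The
  profile-type domains get synthetic stand-in motifs
  (`syntheticDomainMotifs()`), clearly labeled as synthetic: real
  profile hits come from external scanners, which this package ingests
  but does not re-implement.
* **null** — no bias, no motifs, no domains; labels are arbitrary.
  Used for chance-level checks (cross-validated MCC near 0).

What the generator does **not** emulate: phylogenetic correlation
between sequences, real aaRS length and composition distributions,
PROSITE profile score distributions, or partial/degraded motifs.
Passing the synthetic benchmark therefore demonstrates that the
machinery — feature extraction, learning, selection, evaluation —
recovers planted signal at realistic sizes; it does not certify the
published accuracies on real Swiss-Prot data, which would require the
original (unpublished) dataset.

## Numerical choices and degenerate inputs

* Non-standard residues (B, Z, X, U, O, J) are dropped with a warning
  by default (`drop_nonstandard`), keeping the 20/400-dimensional
  feature spaces exact; `strict` mode turns them into errors. Cleaning
  is idempotent and composition denominators use the cleaned length.
* A sequence must be non-empty after cleaning; dipeptide composition
  additionally requires length $\ge 2$.
* RFE ties (identical squared weights, e.g. duplicated columns) break
  lexicographically: earlier names get better ranks.
* Smith-Waterman scores are floored at 0 (the local-alignment empty
  alignment); top-hit ties break by database order.
* Decision-value orientation is fixed empirically at training time so
  positive scores always mean the positive class, independent of the
  underlying library's internal label order.
* Fold assignment, generation and ranking all take explicit seeds and
  restore the caller's RNG state; rerunning with the same seed is
  bit-identical.

## Problem sizes used by the test suite

The suite exercises the exhaustive composition oracle over a 3-letter
alphabet up to length 7, the alignment oracle exhaustively at lengths
$\le 2$ and on several hundred sampled pairs at lengths 3–6 over a
4-letter alphabet, selection recovery over 10 generator seeds with 5
planted dipeptides at 100 sequences per class, and the cross-validation
benchmarks at the preset sizes above. These sizes were chosen so the
whole suite completes in a couple of minutes while keeping every
statistical check well-powered (the recovery and null bands are
multiple standard errors wide at these n).

## Known limitations

* Profile-type PROSITE domains are ingested, never scored: there is no
  generalized-profile (weight-matrix) scanner, and no score cut-off
  logic — presence is whatever the upstream scanner reported.
* The similarity baseline's score threshold is not an E-value; absolute
  baseline numbers are not comparable to BLAST-based ones.
* No probability calibration on SVM outputs; decision values are
  ranking scores, not probabilities.
* The published accuracies on the original Swiss-Prot-derived dataset
  are not reproducible without that dataset; the package reproduces the
  *method* and verifies the metric engine against the published
  independent-set threshold table instead.

## A minimal session

```{r example}
library(aaRSpred)

g <- generateDataset("stage1", seed = 1)
r <- crossValidate(g$dataset, pipelineConfig("hybrid2", "stage1"),
                   g$annotation, seed = 1)
presentMetrics(r$mean)

ts <- trainSyntheticTwoStage(seed = 1)
q <- generateDataset("stage2", seed = 99)
head(twoStagePredict(q$dataset, ts$model, q$annotation))
```
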