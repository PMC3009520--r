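---
title: "Predicting FAD-interacting residues from sequence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting FAD-interacting residues from sequence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fadpred)
```

## The problem

Flavoproteins carry the redox cofactor flavin adenine dinucleotide (FAD)
and mediate much of cellular electron transport and oxidative metabolism.
Their function depends on a small set of residues in atomic contact with
the bound cofactor — FAD-interacting residues (FIRs). Identifying FIRs
experimentally requires a solved co-crystal structure; `fadpred`
implements the classical sequence-only alternative: classify each residue
of a chain as interacting or not from the local sequence neighbourhood,
optionally augmented with evolutionary conservation.

## The model

**Windows.** Every residue is represented by the odd-length window of `w`
residues centred on it (defaults: `w` = 17; 15 and 19 are also standard).
Positions that would fall outside the chain are padded with the dummy
symbol X, so every residue — including terminal ones — receives exactly
one pattern. The window inherits its label from its centre residue. This
"one pattern per residue" scheme follows the established turn- and
binding-site-prediction practice of window classifiers; a
`skip_terminal` flag drops padded windows instead for users who prefer
the no-padding variant.

**Encodings.** Two feature maps are provided:

* *binary*: each window position becomes a 21-slot one-hot block
  (alphabetical amino-acid order A…Y, X last), giving a `21w`-dimensional
  0/1 vector with exactly one 1 per block;
* *pssm*: each position contributes the corresponding row of the chain's
  position-specific scoring matrix (PSSM) from an iterative profile
  search (by convention three PSI-BLAST iterations against `nr` at
  inclusion e-value 0.001), normalized to [0, 1], giving a
  `20w`-dimensional vector.

PSI-BLAST log-odds scores are mapped to [0, 1] with the logistic
transform `1/(1 + exp(-val))` — strictly increasing, symmetric, 0.5 at a
raw score of 0. This is the standard normalization in PSSM-based residue
predictors; a dataset min–max alternative is exposed
(`transform = "minmax"`), and every persisted model records which
transform produced its features. Terminal positions in profile windows
contribute all-zero rows rather than neutral 0.5 rows, so padding stays
inert under dot-product kernels and is distinguishable from a genuinely
neutral score.

**Datasets.** Window patterns are deduplicated per class (first
occurrence wins, deterministic order). A string occurring with both
labels is kept once as positive by default — missing a true interacting
residue is the costlier error — with the conflict counted and the rule
configurable. Negatives are then sampled uniformly without replacement,
once per dataset and before any fold assignment, to match the positive
count exactly; the draw is seeded and reproducible.

**Classifier.** A soft-margin kernel SVM (libsvm backend via `e1071`),
with the conventional parameterization: polynomial kernel
`(u·v + 1)^d` or RBF kernel `exp(-g|u-v|²)`, trade-off `c`, and a cost
factor `j` applied as the positive-class error weight. Decision values
are used raw (signed margins, swept over [-1, +1] by convention) rather
than probability-calibrated: the threshold is part of the reported
operating characteristic. Six named presets ship with the package
(`fadpred_presets()`), one per window × encoding combination, with the
AUC each reference model reported. Note that decision-value scales are
model-relative: thresholds are not transferable between SVM
implementations, so the sweep — not any single fixed cutoff — is the
primary evaluation object.

**Evaluation.** Five-fold cross-validation, stratified by class so each
fold holds a nearly equal number of interacting and non-interacting
patterns (per-class fold sizes within ±1). For each threshold `t` in
-1.0, -0.9, …, +1.0 the confusion counts give

* sensitivity `Sn = 100·TP/(TP+FN)`,
* specificity `Sp = 100·TN/(TN+FP)`,
* accuracy `Acc = 100·(TP+TN)/n`,
* Matthews correlation
  `MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.

Per-threshold metrics are averaged across folds with unweighted means;
fold sizes differ by at most one pattern, so the difference from pooled
computation is O(1/n). The highlighted operating point is the *balanced
threshold*: the sweep row minimizing |Sn − Sp|, ties broken by higher
MCC, then lower threshold. AUC is computed as the rank statistic (the
probability that a random positive outscores a random negative, ties
half) rather than a trapezoid over the 21 grid points — the grid
trapezoid systematically understates the threshold-independent ranking
quality the statistic is meant to capture. AUC is reported both fold-
averaged and pooled over all held-out scores, since the two conventions
differ and neither is canonical.

Splitting is at pattern level by default, mirroring the reference
protocol. Because overlapping windows from one chain are near-identical,
pattern-level splits can leak information across folds;
`assign_folds(..., by_chain = TRUE)` offers the stricter chain-grouped
split (at the price of exact per-fold class balance), and is recommended
when estimating generalization to unseen proteins.

## Numerical conventions and edge cases

* MCC with a zero denominator factor caused by degenerate *predictions*
  (all-positive or all-negative calls, routine at sweep endpoints) is
  reported as 0 with a warning, so sweeps never abort; an empty *truth*
  class is an error, because Sn or Sp is then undefined.
* On exactly balanced counts the metrics reduce to closed forms
  `Acc = (Sn+Sp)/2` and
  `MCC = (Sn+Sp−100)/√((Sn+100−Sp)(Sp+100−Sn))` (percent scale); the
  test suite asserts equivalence with the general formulas over 10,000
  randomized confusion tables, and uses the closed forms to reconstruct
  and verify the shipped reference tables from their printed Sn/Sp
  pairs. Five of the 126 reference rows are internally inconsistent with
  their own printed rates beyond print precision (typographic errors in
  the source tables); `published_performance()` flags them in its
  `consistent` column, and the tests pin their recomputed values instead.
* Nonstandard residue codes (B, Z, J, U, O, `*`) map to the dummy symbol
  X rather than being dropped, so residue indices stay aligned with PSSM
  rows; the mapping is warned about.
* Chain identifiers are free text; the `PDBID_chain` convention is
  recommended but not enforced.

## The synthetic benchmark

Real FIR annotation requires curated structure-derived contact data and
`nr`-scale profile searches, neither of which belongs in a test suite.
The package therefore ships a seeded generator
(`generate_chains()` / `generate_profiles()`) whose defaults define the
benchmark used throughout the tests and the acceptance script: 200
chains of length 120, marginal interacting rate 0.1, uniform background
composition (a Swiss-Prot-like table is available), and two independently
plantable signals:

* **Compositional** (`composition_shift`, default 3): interacting
  positions draw G, Y and S — the residue types characteristically
  over-represented at FAD contact sites — at `shift` times their
  background frequency, with the other 17 residues renormalized. The
  realized interacting/non-interacting frequency ratio therefore equals
  the configured value exactly, which is what the generator's
  enrichment-recovery test asserts.
* **Evolutionary** (`profile_signal`, default 5): in the synthetic
  PSSMs (integer noise around 0, sd 2), the column of the residue
  actually present is boosted at interacting positions *and their ±2
  neighbours*, emulating the elevated conservation of contact stretches
  and their flanks.

Interacting positions are drawn as short contiguous segments (length
3–7, marginal rate `positive_fraction`) rather than independently per
residue. This models how FAD contact residues actually occur — in a few
short sequence stretches per binding site — and it is what makes window
classifiers work at all: if labels were independent and enrichment
confined to the centre position, flanking positions would carry no
information and the Bayes-optimal AUC of *any* window classifier would
be capped near 0.6 at ratio-3 enrichment. With clustered labels the
window sees several enriched positions, and the planted signal is
genuinely recoverable; an analytic bound still applies (roughly
AUC ≈ 0.75–0.78 at the default enrichment), which is worth keeping in
mind when interpreting synthetic results — compositional signal alone,
at realistic enrichment, supports only moderate ranking quality, which
is precisely why profile features matter.

What the generator does **not** emulate: real amino-acid dependence
between neighbouring positions, homologous redundancy between chains
(the upstream curation step of real datasets), genuine PSI-BLAST
profiles (synthetic PSSMs have no phylogenetic structure), and
structural motifs such as Rossmann folds. Passing the synthetic suite
therefore demonstrates that the pipeline recovers signal of the planted
kind and magnitude — not that any particular accuracy will be attained
on real proteins.

Problem sizes in the test and acceptance runs (200×120 chains for the
cross-validation properties; 10,000 examples per class for metric
reconstruction; 10,000 random tables for oracle equivalence) were chosen
so each property is measured well inside binomial noise while a full run
completes comfortably on a single CPU.

## Known limitations

* Thresholds are decision-value scales of *this* SVM backend; a model's
  balanced threshold need not transfer to other implementations, and the
  [-1, +1] sweep convention assumes roughly margin-scaled scores.
* Pattern-level cross-validation (the default, matching the reference
  protocol) is optimistic for between-protein generalization; use
  chain-grouped folds for honest protein-level estimates.
* The PSSM path requires externally computed profiles (or a local
  PSI-BLAST and database); the package wraps but does not bundle the
  tool, and profile quality depends on the database snapshot used.
* Only sequence-derived features are implemented; no secondary
  structure, solvent accessibility, or structural descriptors.
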