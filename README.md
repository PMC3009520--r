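# fadpred

Sequence-based prediction of FAD-interacting residues in flavoproteins.

Flavoproteins bind the redox cofactor flavin adenine dinucleotide (FAD)
through a small set of contact residues (FIRs). Knowing which residues
those are is a prerequisite for understanding and engineering
flavoenzyme function, but it normally requires a co-crystal structure.
`fadpred` is for computational biologists and flavoprotein researchers
who want per-residue FIR predictions from primary sequence alone, and a
rigorous, reproducible protocol for training and evaluating such
predictors.

## The method

Each residue is represented by the odd-length window of *w* residues
centred on it (*w* = 15, 17 or 19; chain termini are padded with the
dummy symbol X). Windows are encoded either as

- a **binary pattern** — *w* one-hot blocks of 21 symbols (20 amino
  acids + X), dimension 21*w*; or
- a **PSSM profile** — the corresponding *w* rows of the chain's
  PSI-BLAST position-specific scoring matrix, logistic-normalized to
  [0, 1], dimension 20*w*

and classified by a soft-margin kernel SVM (polynomial `(u·v + 1)^d` or
RBF `exp(-g|u−v|²)`, trade-off `c`, positive-class cost factor `j`).
Training data are class-balanced, deduplicated pattern sets; evaluation
is five-fold cross-validation with a decision-threshold sweep over
[-1, +1] reporting, at each threshold,

    Sn  = 100·TP/(TP+FN)        Sp  = 100·TN/(TN+FP)
    Acc = 100·(TP+TN)/n         MCC = (TP·TN−FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))

plus rank-based ROC AUC. The highlighted operating point is the
*balanced threshold*, where sensitivity and specificity are closest.
The six published reference models (window × encoding) are shipped as
presets together with their full per-threshold reference tables
(`fadpred_presets()`, `published_performance()`).

Case-annotated FASTA (lowercase = interacting residue) and PSI-BLAST
ASCII PSSMs (both `psiblast` and legacy `blastpgp` layouts) are read and
written natively; a seeded synthetic-benchmark generator with plantable
compositional (G/Y/S enrichment) and conservation signal makes the whole
pipeline testable without any external data or tools.

## Worked example

```r
library(fadpred)

# a seeded synthetic benchmark: 40 chains of 100 residues, ~10% FIRs,
# G/Y/S enriched 3x at interacting positions
cfg    <- synthetic_config(n_chains = 40, length_range = c(100, 100), seed = 42)
chains <- generate_chains(cfg)

round(compositional_analysis(chains)[c("G", "S", "Y", "A", "L"), ], 2)
#>     FIR nonFIR
#> G 16.07   4.77
#> S 13.67   4.94
#> Y 16.55   4.88
#> A  2.16   4.66
#> L  2.88   5.41

ds <- make_pattern_dataset(chains, w = 17, seed = 42)
ds
#> <pattern_dataset> w=17: 417 positive + 417 negative patterns (seed 42)

folds <- assign_folds(ds, k = 5, seed = 42)
cv <- crossvalidate(ds, binary_encoder(17), fadpred_preset(17, "binary"), folds)
cv
#> <cv_result> balanced threshold 0.0: Sn 68.33, Sp 75.30, Acc 71.82,
#>             MCC 0.439; AUC 0.784 (fold mean), 0.783 (pooled)

round(cv$sweep[9:13, ], 2)
#>    threshold    Sn    Sp   Acc  MCC
#> 9       -0.2 90.40 40.75 65.58 0.36
#> 10      -0.1 80.33 58.98 69.65 0.40
#> 11       0.0 68.33 75.30 71.82 0.44
#> 12       0.1 54.19 85.62 69.90 0.42
#> 13       0.2 38.61 92.33 65.47 0.37
```

The composition table shows the planted hallmark of FAD contact sites —
glycine, serine and tyrosine about three times more frequent among
interacting residues. The cross-validated sweep behaves as it should:
lowering the threshold trades specificity for sensitivity, and the
balanced threshold (here 0.0) is where the two meet; at that operating
point the binary 17-window model recovers the planted compositional
signal with ~72% balanced accuracy and AUC ≈ 0.78.

A command-line interface wraps the same workflow
(`inst/cli/fadpred.R`; subcommands `synth`, `make-dataset`, `train`,
`crossvalidate`, `predict`), writing TSV outputs with 1-based residue
coordinates and a JSON run-manifest per command.

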