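# nadbinder

Sequence-based prediction of NAD-interacting residues (NIRs) in proteins.

Nicotinamide adenine dinucleotide (NAD) is one of the most widely used
organic cofactors in the cell; hundreds of structurally diverse proteins
bind it, and similarity-based annotation fails for the many NAD-binding
proteins that lack the classical Rossmann fingerprint. `nadbinder` is for
computational biologists who need to annotate probable NAD contact sites —
and call whole proteins as NAD binders — from amino-acid sequence alone,
with no structure or close homolog required.

## Method

Each residue is classified from the odd-length window of sequence centred
on it (terminal windows are completed with dummy `X` residues, `(W−1)/2`
per side). Two encodings are supported:

* **binary** — each window position is a 21-dimensional one-hot vector
  (20 amino acids + `X`), giving a `21·W` feature vector;
* **pssm** — each window position contributes its 20 log-odds scores from a
  position-specific scoring matrix (PSSM, e.g. from PSI-BLAST), logistic
  scaled to (0,1), giving `20·W` features; padding positions contribute
  zero rows.

A kernel support vector machine (default RBF, `t 2 g 0.1 j 1 c 10` in the
short-letter notation: gamma 0.1, cost 10, positive-class cost factor 1)
separates NIR from non-NIR windows. Because non-interacting residues vastly
outnumber interacting ones, training uses an *equal* dataset by default
(all positives plus an equally sized seeded sample of negatives); the
*real* mode keeps the natural imbalance.

Evaluation is chain-level five-fold cross-validation (no window of a chain
ever straddles folds), reporting

* sensitivity `Sn = TP/(TP+FN)·100`, specificity `Sp = TN/(TN+FP)·100`
  (percent coverage of non-interacting residues),
* accuracy `Acc = (TP+TN)/N·100`,
* Matthews correlation coefficient
  `MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
* a native threshold-sweep ROC curve with trapezoidal AUC,

with the final figures the unweighted mean over folds. At protein level, a
chain is called an NAD binder when the fraction of residues predicted
positive, `(TP+FP)/L`, reaches a cutoff (default 10% at residue-score
threshold 0.3 — a 100-residue protein with 10 or more predicted NIRs is a
binder).

Training labels can be derived from protein–NAD complex structures:
`label_contacts()` marks a residue as an NIR when any side-chain heavy atom
(CA for glycine) lies within a distance cutoff (default 4.5 Å) of any NAD
atom, and `reduce_redundancy()` removes chains above 40% pairwise identity
by greedy longest-first clustering. A synthetic-data module generates
motif-planted labeled chains (default motif `GxGxxG`, the phosphate-binding
fingerprint consensus), matching pseudo-PSSMs and toy PDB complexes, so the
entire pipeline is testable offline.

## Worked example

```r
library(nadbinder)

sim <- simulate_chains(n_chains = 50, seed = 42)   # motif-planted chains
fit <- fit_nadbinder(sim$chains, sim$labels, mode = "binary", W = 17,
                     spec = kernel_spec("rbf", gamma = 0.1, cost = 10),
                     seed = 42)
fit
```

```
NAD-interacting-residue predictor
  encoding: binary, window 17 (357 features)
  kernel:   t 2 g 0.1 j 1 c 10
  training: 50 chains, 400 NIR / 3497 non-NIR residues (equal dataset)
  default decision threshold: 0
```

The window-17 binary encoding is 21·17 = 357 features; the 50 chains
contain 400 planted NIRs, and the equal-mode trainer paired them with 400
sampled negatives. Cross-validated performance:

```r
cross_validate(sim$chains, sim$labels, mode = "binary",
               cfg = window_config(17),
               spec = kernel_spec("rbf", gamma = 0.1, cost = 10), seed = 42)
```

```
5-fold chain-level cross-validation (binary mode, W = 17, t 2 g 0.1 j 1 c 10, Thr = 0)
mean of fold metrics: Sn 100.00%  Sp 97.45%  Acc 97.71%  MCC 0.893  AUC 1.000
```

Every planted NIR in the held-out chains is recovered (Sn 100%) at 97.45%
specificity; the MCC of 0.89 summarises both under the ~10:1 class
imbalance. Per-residue predictions are rendered with the predicted NIRs
uppercase and starred:

```r
rep <- predict(fit, sim$chains[2], type = "report")
format_prediction_report(rep, width = 60)
```

```
>sim002  predicted NIRs: 11/98
kkrhfwhimmshvaqsvffvymwdtfdnlTSGGYGHSGGHptcrdpvmfckclgdcsiil
.............................***********....................
idwmttvygessvtdectddnnkdssykyicialeekf
......................................
```

The 11 starred residues sit on the planted `GxGxxG`-family site. Protein
level calls at the 0.3/10% operating point:

```r
predict(fit, sim$chains[1:3], type = "protein", threshold = 0.3)
```

```
 chain_id length n_predicted predicted_fraction is_binder threshold cutoff
   sim001     96           8         0.08333333     FALSE       0.3    0.1
   sim002     98           8         0.08163265     FALSE       0.3    0.1
   sim003     64           8         0.12500000      TRUE       0.3    0.1
```

`sim003` clears the 10% cutoff (8/64 = 12.5%) and is called a binder; the
longer chains fall just below it at this conservative threshold.

A command-line wrapper with `simulate`, `build-dataset`, `train`, `cv`,
`sweep` and `predict` subcommands is installed at
`inst/cli/nadbinder.R` (run `Rscript <path> <command> --help`).

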