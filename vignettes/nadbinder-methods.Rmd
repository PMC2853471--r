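---
title: "Predicting NAD-interacting residues: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting NAD-interacting residues: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

NAD-binding proteins are structurally heterogeneous: classical ones carry
the Rossmann βαβαβ fold with its `GXGXXG` phosphate-binding fingerprint,
but many non-classical binders share no detectable similarity with them.
`nadbinder` therefore treats NAD-site annotation as a *local sequence
classification* problem: whether residue *i* contacts NAD is predicted
from the window of `W` residues centred on it, with no alignment or
structure required.

The classifier is a kernel SVM over one of two window encodings:

* **Binary (one-hot).** Each window position is an indicator vector over a
  21-letter alphabet — the 20 amino acids in PSSM column order
  (A,R,N,D,C,Q,E,G,H,I,L,K,M,F,P,S,T,W,Y,V) plus the dummy `X` used for
  terminal padding and unknown residues — so a window is a `21·W` vector
  with exactly `W` ones. Sharing one alphabet ordering between the binary
  and profile encodings keeps the two feature spaces positionally
  comparable.
* **Evolutionary profile (PSSM).** Each window position contributes its
  20 log-odds scores from a position-specific scoring matrix, so a window
  is `20·W` values. Scores are squashed by the logistic function
  `s(x) = 1/(1+e^{-x})` into (0,1) — the common practice in this family of
  residue-level predictors, which keeps the RBF kernel's length scale
  comparable between encodings; `identity` and `divide-by-100` scalers are
  available as configuration for users whose profiles are already scaled.

The underlying assumptions are (i) the contact signal is local in
sequence, concentrated within ±10 residues; (ii) for the profile mode,
binding-site columns are more conserved than background, so the PSSM
carries signal the raw sequence does not.

## Window padding

Terminal residues must still yield a full window, so `(W−1)/2` dummy `X`
residues are appended at each terminus: for `W = 17`, 8 per side. In the
binary encoding `X` occupies the 21st indicator slot; in the profile
encoding padding positions contribute an all-zero row, which stays exactly
0 *after* scaling (padding is excluded from the scaler) so that padding is
distinguishable from a real score of 0, which scales to 0.5.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `W` | 17 (binary), 19 (pssm) | window length, residues; the lengths at which each encoding peaks in cross-validation |
| kernel | RBF, `g = 0.1`, `c = 10`, `j = 1` | `t 2 g 0.1 j 1 c 10` in the short-letter notation of SVM performance tables; linear, polynomial (`d`) and sigmoid kernels are available |
| `j` (cost factor) | 1 | multiplier on positive-class training errors; raise it to favour sensitivity when training on the imbalanced *real* dataset |
| decision threshold | 0 | residue-level operating point; lower it (e.g. −0.2) for sensitivity, raise it (e.g. 0.3) for specificity |
| balance | `equal` | all positives plus a seeded equal-size negative sample; `real` keeps the full imbalance |
| contact cutoff | 4.5 Å | side-chain heavy-atom distance defining an NIR from a complex structure |
| identity threshold | 0.40 | maximum pairwise identity retained by redundancy reduction |
| protein-level cutoff | 10% at threshold 0.3 | predicted-NIR fraction `(TP+FP)/L` at which a chain is called an NAD binder |

The negative sample for the `equal` dataset is drawn once per fit (or once
per fold in cross-validation) with a recorded seed, since nothing in the
method requires resampling within a fold.

## Contact labeling from structures

Ligand–protein contact annotation services define contacts by surface
complementarity, a criterion that cannot be recomputed from coordinates
alone; `label_contacts()` uses the standard distance proxy instead: a
residue is an NIR when any side-chain heavy atom lies within the cutoff of
any NAD atom. The proxy is monotone in the cutoff (labels only grow), which
the tests exploit. Two conventions matter:

* **Glycine.** Gly has no side-chain heavy atom; its CA is treated as the
  side chain. Without this, glycine — one of the residues most enriched at
  NAD sites — could never be labeled positive.
* **Edge cases.** Only the first alternate conformer and first model are
  read; multiple NAD copies contribute the union of their contacts;
  residues with non-standard 3-letter codes map to `X` and are never
  labeled positive.

Redundancy reduction is greedy longest-first clustering (ties broken by id)
with identity = alignment matches / length of the shorter chain, computed
by global alignment. This reproduces the *behaviour* of CD-HIT-style
clustering deterministically; an externally produced cluster membership
file can be imported instead when exact parity with an external tool is
needed.

## Evaluation design

Cross-validation folds are cut at **chain level** — sequences, not
windows, are shuffled into five folds — because windows of one chain
overlap by `W−1` residues and residue-level folds would leak information
between training and test. Fold assignment is a seeded shuffle followed by
round-robin, so fold sizes differ by at most one.

The final performance figures are the **unweighted mean of the per-fold
metrics** (not metrics of pooled counts), matching the convention of
averaging the performance of the five test sets. Two numerical rules:

* **MCC with a zero denominator** (any empty margin of the confusion
  table) is reported as 0 and flagged in the result rather than NaN.
* **Score ties at the threshold go to the positive class** (`score ≥ thr`
  predicts NIR), so sweeping the threshold downward is monotone in the
  number of positive calls.

ROC curves are built natively by sweeping the threshold over all distinct
scores with ties grouped, and AUC is the trapezoidal area; the tests verify
equality with the Mann–Whitney pair-counting statistic and with an
independent ROC implementation.

## The synthetic-data generator

`simulate_chains()` emulates the statistical structure the method assumes:
uniform background over the 20 amino acids, one planted `GxGxxG` motif per
chain (wildcards and one flanking position per side drawn from the
enrichment alphabet G, Y, T, H, S of residues favoured at NAD sites), with
the motif span ± flank labeled as NIRs. Chains are 60–100 residues, giving
roughly a 10:1 negative:positive residue imbalance — the same order as
real NAD-binding chains. `simulate_pssm()` emulates profile conservation:
labeled positions receive a high self-score (+9 by default) and negative
off-scores, unlabeled positions integer noise in [−2, 2].
`simulate_complex()` writes a toy PDB complex whose geometry encodes the
labels exactly: the backbone runs along a line at 3.8 Å spacing, labeled
side-chain anchors (for glycine, the whole displaced residue) sit ~20 Å
off the line with an NAD pseudo-atom 3.0 Å beyond, so planted contacts are
recovered for any cutoff between 3 and ~20 Å by construction. Deterministic
line geometry is used instead of realistic folds because the contact
operator consumes only distances.

What the generator does **not** emulate: real amino-acid background
composition, homology between chains, multiple binding sites per chain,
discontiguous 3-D sites brought together by folding, and real PSSM score
distributions. Passing the recovery experiments therefore demonstrates
that the pipeline is correct and that the learner recovers a planted local
signal under realistic imbalance — not that real-data accuracy will reach
the same values; published figures on PDB-derived datasets (e.g. ~74%
accuracy binary, ~87% PSSM) depend on external data and profile databases
and are out of scope here.

## Problem sizes and reproducibility

The recovery experiments use 150 chains (~12,000 residues) for
cross-validation, 100 chains for the permutation null, 200 chains for the
composition check, and 20 toy complexes for label recovery — sizes at which
every experiment completes in minutes on one core while leaving the
binomial noise on each metric well inside the asserted margins. All
randomness (simulation, folds, negative sampling, label flips) flows from
explicit integer seeds, and internal RNG use saves and restores the
caller's `.Random.seed`.

For the profile-vs-binary comparison, 10% label noise is applied to the
*training* labels only and both modes are scored against the clean planted
truth: this measures each encoding's robustness to annotation noise, which
is where the evolutionary profile's advantage over the raw sequence shows
as a trend (noisy-label MCC ≈ 0.92 for pssm vs ≈ 0.60 for binary at the
default settings) without asserting any real-data magnitude.

## Known limitations

* The distance-cutoff contact criterion is a proxy, not a reimplementation
  of surface-complementarity annotation; labels near the cutoff boundary
  will differ from annotation-service output.
* Greedy identity clustering approximates, but is not bit-compatible with,
  CD-HIT.
* PSSMs are consumed as files; generating them (e.g. three PSI-BLAST
  iterations at e-value 0.001 against a large database) is the user's
  responsibility and profile quality directly bounds pssm-mode accuracy.
* The SVM solver is a standard max-margin implementation honouring the
  kernel/C/j contract; decision-score magnitudes are not bit-compatible
  with other SVM packages, so thresholds tuned elsewhere should be
  re-swept here.
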