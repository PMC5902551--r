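---
title: "Classifying RNA editing sites from sequence context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying RNA editing sites from sequence context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editnet)
library(dplyr)
```

## The problem

RNA editing — in animals, dominantly A-to-I deamination by ADAR enzymes —
shows up in RNA-seq as mismatches between reads and the genomic reference.
After read mapping and variant calling, every candidate single-nucleotide
variant (SNV) is one of three things: a genuine editing site, a genomic SNP,
or an artifact of sequencing and alignment ("other"). Conventional pipelines
separate these with stacks of prior-knowledge filters (dbSNP lookups, repeat
annotations, cluster heuristics). editnet instead classifies each candidate
directly from the reference sequence surrounding it: the only inputs at
prediction time are a FASTA and a list of candidate SNVs.

Two sequence signals make this possible. First, composition: A>G is by far
the most common mismatch among true editing sites, much less so among
negatives. Second, local context: ADAR has a nearest-neighbour preference —
G is depleted immediately 5' of an edited adenosine and enriched immediately
3' — and weaker positional information extends tens of bases to either side.

## Model

The classifier is a four-level averaging hierarchy over small feed-forward
networks:

1. **Individual net.** The window of `2 * flank + 1` bases centred on the
   candidate is one-hot encoded with the fixed channel map A→(1,0,0,0),
   T→(0,1,0,0), C→(0,0,1,0), G→(0,0,0,1) (N and out-of-contig padding are
   all-zero rows), flattened row-major by position, and passed through fully
   connected hidden layers (default 1000 then 100 ReLU units) to a 3-unit
   softmax over EDITING / SNP / OTHER.
2. **Ensemble.** 20 such nets, each trained on its own class-balanced
   bootstrap draw (the same number of examples per class, drawn with
   replacement per class), combined by the arithmetic mean of their
   probability triples. The bootstrap balancing is what counters the heavy
   class imbalance of realistic candidate lists.
3. **Module.** Two ensembles at different input scales — 101 bp
   (`flank = 50`) and 41 bp (`flank = 20`), both centre-cropped from the
   same windows so the candidate stays at the midpoint — again averaged.
4. **Component and final model.** One module per gold-standard training set
   (the design uses 11 per component), averaged into a component; two
   components (trained on "separate-samples" and "pooled-samples" flavoured
   gold sets) averaged into the final classifier.

Simple averaging at every level makes the hierarchy transparent: the final
prediction is a weighted mean of leaf-net probabilities with weights induced
by the tree structure, and every level's output lies on the probability
simplex. Sites are called where `p_editing` is strictly greater than the
cutoff (default 0.5; applications tune it to match a target call count).

### Training choices left open by the architecture

The architecture fixes layer sizes, ensemble counts and scales, but not the
optimisation recipe. We use minibatch Adam (learning rate `1e-3`, batch 128,
a fixed epoch budget, no early stopping) with He-normal initialisation and
ReLU activations; all are `train_config()` / `net_spec()` fields. Every
source of randomness flows from one master seed through a documented
derivation (level tag, module index, member index), so training is exactly
reproducible. Cross-validation is stratified k-fold (default 5) with
bootstrap balancing applied inside training folds only, never to test folds
— balancing a test fold would leak the class prior into the estimate.

Numerical details: softmax is computed with the row-max subtracted;
probability rows sum to 1 within 1e-9 at every level; exact argmax ties
(never observed in float practice) would resolve EDITING < SNP < OTHER.
Windows overlapping a contig end are padded with N (all-zero rows), which
keeps the input dimension fixed and contributes no gradient signal.

## Evaluation suite

`confusion_metrics()` reproduces the comparison-table conventions of the
editing literature, two of which are non-textbook and deserve flagging:

* the tabled "F1 score" is the harmonic mean of **sensitivity and
  specificity** (the textbook precision/recall F1 is exposed separately as
  `f1_textbook`); this is the definition that reproduces published
  comparison rows, and we keep it under the explicit name `f1_published`;
* `validation_rate` and `misclassification_rate` divide verified (and
  verified-false) predictions by **all** predictions, verified or not.
  These definitions approximate but do not exactly match some published
  rate columns, whose denominators are not derivable from the stated
  counts; we document ours and do not tune them.

`roc_auc()` is the Mann–Whitney rank statistic (ties count one half) and is
tested against a brute-force all-pairs oracle; `pr_auc()` is the step-wise
precision–recall integral tested against an exhaustive threshold sweep.
`a_to_i_ratio()` is the A>G fraction of a call set, a precision proxy.
`fdr_equal_error()` estimates the false-discovery rate of A-to-I calls
assuming all non-A-to-I calls are false with errors spread equally over the
11 non-A-to-I mismatch types: `FDR = ((n_total - n_a2i)/11) / n_a2i`.
Undefined ratios are reported as `NA`, never silently as 0.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` produces a background genome of i.i.d. bases at a
configured GC content and plants labeled candidates into it:

* positives are adenosines whose −1/+1 neighbours follow the ADAR
  preference (defaults: G at +1 with probability 0.70, at −1 with 0.05, vs
  a 0.25 background) and whose flanks carry a linearly decaying G-bias out
  to ±25 bp; 86.3% of positives are A>G;
* negatives get no motif — only their centre base is written — and are A>G
  with probability 34.8%; SNP and OTHER negatives are distributionally
  identical unless the transition-bias knob is set.

The class-composition fractions are the one quantitatively published
property; the motif *strengths* are not published (only directions), so the
defaults above are package conventions chosen once so that a trained module
can provably recover the planted structure. Candidate windows never overlap
(rejection sampling with re-draws), coverage fields come from a negative
binomial purely to exercise the coverage filter, and the whole dataset is
byte-reproducible from `master_seed`.

Deliberate non-realism: real genomes are not i.i.d. (repeats, GC waves,
transcript structure), real editing clusters in Alu elements, real negatives
include alignment artifacts with their own sequence signatures, and there is
no read-level error model. Passing tests on this generator therefore
demonstrates that the architecture, training loop and statistics behave as
designed and can recover planted signal of realistic strength — not that the
trained toy models would transfer to real RNA-seq. Training on real
gold-standard sets is what the pipeline functions are for.

## Problem sizes used in the shipped tests

The package's own test suite runs a desk-scale profile chosen to exercise
every property on one CPU: hidden layers of 32/16 units, 8 training epochs,
ensembles of up to 20 members at `flank = 20`–25, datasets of 1000–1500
examples per class with 500 per class held out, and 5-seed repetitions for
the stochastic properties (ensemble-vs-member AUC, component-vs-module AUC,
importance recovery). The full-scale architecture (1000/100 hidden units,
2 × 11 modules × 2 scales × 20 nets) remains the documented default of the
spec constructors and is exercised structurally rather than at full training
cost.

## Importance scoring

`position_importance()` quantifies which window positions drive the
editing-vs-rest separation. The default is model-agnostic permutation
importance: shuffle one position's bases across examples, re-score, record
the AUC drop (averaged over repeats, clamped at zero). An impurity-based
alternative (`method = "gini"`, mean decrease in Gini from a random forest
on the one-hot features) needs no trained net and mirrors the classic
forest-based analysis of editing windows. On generator output the profile
reproduces the expected shape: a sharp peak within ±2 bp of the candidate,
a medium shoulder to ±25, and near-zero beyond.

## Known limitations

* Windows are taken from the reference strand as given; for unstranded
  callers the `collapse_revcomp_a2i` flag folds T>C into the A-to-I count,
  but sequence windows are not reverse-complemented.
* The generator's SNP and OTHER classes are identical by default, so
  three-class accuracy between them is at chance unless the transition-bias
  knob is used; all shipped performance properties score editing-vs-rest.
* Pure-R training is practical for desk-scale hierarchies (seconds per
  net at the test sizes); the full 880-net configuration is supported but
  slow — it exists for fidelity, not for routine use.
* The exact "modified" element of the published 5-fold cross-validation is
  not public; we implement stratified folds with training-fold-only
  balancing, which matches the stated purpose (imbalance handling during
  training) without leakage.
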