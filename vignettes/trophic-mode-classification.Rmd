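---
title: "Classifying in situ trophic modes of marine protists from Pfam expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying in situ trophic modes of marine protists from Pfam expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protroph)
```

## The problem

Many marine protists are mixotrophs: they can photosynthesize and ingest
prey, and they switch between strategies with conditions. Microscopy-based
prey-ingestion assays do not scale to ocean surveys, but metatranscriptomes
do. `protroph` implements a pipeline that predicts the *in situ* trophic
mode — phototrophy, mixotrophy, or heterotrophy — of protist species bins
from their transcriptional profiles summarized at the level of Pfam protein
families, and then aggregates those per-sample predictions into
trophic-capability calls (mixotrophic-capable vs. phototrophic or
heterotrophic specialist) and spike-in-calibrated transcript concentrations
per trophic group.

The central modeling assumption is that protists regulate trophic mode
through gene expression, so transcriptional shifts — not genomic potential —
carry the signal. Predictions are made per species bin and sample, which
also means the model can legitimately assign different modes to the same
species in different samples.

## Expression profiles

Contig-level inputs (the tabular outputs of upstream annotation and
pseudo-alignment tools) are reduced to species-bin × Pfam TPM profiles:

1. **Annotation filtering.** Pfam hits with e-value ≥ 1e-05 are discarded;
   each contig keeps its best-bitscore hit. Bitscore ties are broken by the
   lexicographically smallest accession, a deterministic choice where any
   rule would do.
2. **TPM.** Within each (species bin, sample): `RPK = est_count /
   (length_nt/1000)`, a conversion factor `sum(RPK)/1e6`, and `TPM =
   RPK/factor`. TPM sums to one million per bin and sample; the nt-vs-kb
   length convention cancels (asserted in the tests). A bin with zero
   mapped reads in a sample yields all-zero TPM rather than an error,
   because environmental samples legitimately lack bins.
3. **Aggregation.** TPM is summed per Pfam; feature Pfams with no mapped
   transcripts are zero-filled.

Training transcriptomes must pass quality control — at least 1,200
sequences, at least 500 assigned Pfam domains, and contamination strictly
below 50% — with contamination consumed as precomputed metadata.

Expression enters the classifier min-max scaled to [0, 1] per feature.
The scaler is fitted on the training corpus and applied, with clipping,
to environmental profiles; this keeps environmental inputs on the scale the
classifier saw in training even when a field profile exceeds the cultured
range. Whether one should instead re-fit the scaler per environmental
dataset is genuinely open — both behaviors are implemented
(`scaler_mode = "bundle"` or `"refit"`), with the training-fitted scaler as
the default because it makes prediction a pure function of the trained
bundle. A binarized (presence/absence) input variant is available via
`binarize_input = TRUE`.

## Training protocol

The reference training composition is 258 phototrophic, 85 mixotrophic,
and 44 heterotrophic transcriptomes. Because of this imbalance, feature
selection runs on four undersampled versions of the corpus keeping 50, 80,
100, and 120 randomly chosen phototrophic profiles alongside all
mixotrophic and heterotrophic ones.

**Permutation importance (mean decrease in F1).** Each undersampled dataset
is split 10 times into random 70/30 train/test partitions. Per split, a
gradient-boosted classifier (xgboost, `multi:softprob`) is fitted on the
training part; then, for each Pfam, the feature's held-out values are
shuffled across samples and predictions recomputed. The importance is
`(F1 − F1_shuffled)/F1` with weighted multiclass F1, defined as 0 when the
baseline F1 is 0, and averaged over the 10 splits. Under this sign
convention, positive means shuffling degraded performance. A Pfam is
retained as a feature if its mean importance is positive in at least one of
the four datasets — i.e. if its inclusion improved the model anywhere, by
any magnitude. Shuffling is applied to the held-out partition only, without
refitting (standard permutation importance). Two numerical notes: a feature
that is constant across the test samples has importance exactly 0 (the
shuffle is a no-op), and a feature that appears in no tree split of the
fitted booster also has importance exactly 0, which the implementation
exploits by only re-predicting features the booster uses.

**Hyperparameters.** The full grid is n_estimators (10, 100, 1000) ×
max_depth (3, 10, 20) × learning_rate (0.05, 0.1, 0.15, 0.2) × gamma
(0, 0.5, 1) × reg_lambda (0, 0.5, 1) — 324 combinations — scored by mean
weighted F1 over stratified 5-fold cross-validation, ties broken by grid
order. Because an exhaustive search is expensive and its winner is
data-dependent, the package's default hyperparameters are the mid-grid
values (100 rounds, depth 10, learning rate 0.1, gamma 0.5, reg_lambda
0.5), used everywhere a search is not explicitly run.

**Evaluation.** Cross-validation uses six random stratified 83/17 splits
(class proportions preserved; splits are independent draws, not a
partition). Per-mode F1 and support-weighted F1 are reported with standard
errors across splits. A split that loses a class from either side is
regenerated under a new sub-seed and logged. The learning curve repeats
this while training on 25–100% of each split's training part.

All randomness flows from one top-level seed through named substreams
(undersampling, splits, shuffles), so every run is bit-reproducible.

## Applying the model to environmental profiles

Predictions are only made for species bins with sufficient transcriptional
completeness: at least 70% of the 605 Core Transcribed Gene (CTG) Pfams —
a reference set expressed by nearly all eukaryotes — must have at least one
mapped read in that bin and sample (424/605 = 70.08% passes; 423/605 does
not). Ineligible pairs are emitted with an exclusion flag rather than
dropped, for auditability.

Because phototrophy and heterotrophy are not biologically expected for the
same species bin under the same conditions, a group of predictions (same
bin within a grouping unit such as cruise + latitude) in which *both*
phototrophy and heterotrophy each exceed 25% of predictions across
replicates and size fractions is flagged as model failure and excluded.
The grouping key is configuration-driven per dataset kind (surface:
cruise + latitude; depth profiles: latitude + depth; incubations:
latitude + treatment + timepoint; diel studies: date). The rule is applied
after the CTG gate and before capability aggregation — the gate defines
which predictions exist at all, so it must come first.

Prediction agreement across replicates and size fractions (the modal-mode
proportion per group) is reported as a per-group reliability summary.

## Trophic capabilities

Non-excluded predictions are pooled per species bin across all datasets
(aggregation is a sum of counts, so merging datasets in any order is
equivalent). A bin is **mixotrophic-capable** if at least 23% of its
predictions differ from its dominant mode — 23% matching the estimated
model error rate, so smaller divergence is indistinguishable from noise —
and the divergence is not attributable solely to replicate or size-fraction
disagreement; or if strictly more than 77% of its predictions are
mixotrophy. Otherwise it is a specialist named by its dominant mode.
Dominance ties use the fixed precedence heterotrophy > mixotrophy >
phototrophy, so ties never default to phototrophy.

The replicate-split caveat is the vaguest of these rules, and our
operationalization is deliberately explicit: divergence counts as
reproducible iff at least one grouping unit is *unanimous* for a
non-dominant mode. If every non-dominant prediction co-occurs in its unit
with dominant-mode predictions from sibling replicates or size fractions,
the divergence is treated as split-only and does not trigger the 23% rule
(the >77% mixotrophy rule still applies regardless).

## Transcript abundance

With `standard_copies_added` spike-in RNA copies added before sequencing
and `reads_mapped_to_standards` recovered from them, each read represents
`copies/standard_reads` transcripts, giving

    T/L = bin_reads / standard_reads × copies_added / volume_filtered.

This is the standard internal-standard estimator; the exact accounting of
the upstream read-merging/mapping is external, and only its resulting
counts are consumed. Abundances are summed across size fractions of the
same sample, dinoflagellate bins are scaled down by 6.4 (they carry ~6.4×
more transcripts per unit carbon biomass than other plankton; the factor
is a configurable per-lineage table), and trophic-group totals are formed
by summing within replicate across a group's bins, then averaging across
replicates, with per-location group proportions.

## The synthetic-data generator

Every stage is testable without sequence data via a generator that emulates
the statistical structure the pipeline assumes. Pfams fall into archetypes:
photosynthesis-like (40; elevated in phototrophs and mixotrophs, largely
silent in heterotrophs), motility-like (30) and phagocytosis-like (30;
both elevated in mixotrophs and heterotrophs), housekeeping/CTG-like (605,
doubling as the synthetic CTG list), and 1,295 mode-independent noise
Pfams — 2,000 in all, with training class counts 258/85/44. Expression is
zero-inflated log-normal with archetype-by-mode means and dropout, a
per-Pfam baseline offset, and renormalization to one million TPM.

Two design choices matter and were fixed as part of the generator's
realism, not tuned per-test:

* **Individual features are weak.** On/off mean contrast is modest (600 vs
  50–60 TPM) and the log-scale standard deviation wide (1.0), so no single
  Pfam separates the modes reliably; the signal is aggregate, as in real
  corpora.
* **Species use overlapping but different feature subsets.** On-mode
  dropout of roughly one third means each profile expresses about
  two-thirds of its mode's informative Pfams (medians stay non-zero). A
  first, cleaner draft of the generator made archetype Pfams effectively
  interchangeable; gradient boosting then needed only ~20 of the 100
  planted features and the rest scored exactly zero importance — an
  unrealistic degeneracy this structure removes.

The mock environmental scenario is a six-station latitudinal gradient with
two replicates and two size fractions per station and five species bins:
two phototrophic specialists, a heterotrophic specialist, and two bins
(one a dinoflagellate) that shift mode between southern and northern
stations. Spike-in records and per-bin read counts are generated
consistently with drawn true concentrations (kept real-valued), so the
internal-standard estimator inverts the generator exactly; a CTG-dropout
knob exercises the 70% gate.

What the generator does *not* emulate: phylogenetic correlation between
profiles, compositional coupling between bins of one sample, contig-level
noise (lengths and counts are simulated only in the profile-module tests),
label error, and cross-dataset batch effects. Passing the recovery tests
therefore shows the protocol is implemented correctly and can recover
planted structure under realistic sparsity and noise — not that the same
F1 would be achieved on ocean data.

## Problem sizes and numerical choices

The parameter-recovery suite runs the full default generator (≈390
profiles × 2,000 Pfams, four undersampled datasets × 10 importance splits)
in a few minutes on one core; unit tests use an 80-Pfam miniature of the
same spec. Degenerate cases are defined, not error-prone: all-zero count
groups give all-zero TPM, constant features scale to 0, F1 = 0 before
shuffling gives importance 0, probability vectors must sum to 1 within
1e-9. Thresholds compare exactly as printed: e-value strictly < 1e-05,
contamination strictly < 50, CTG coverage ≥ 0.70, exclusion strictly
> 0.25, divergence ≥ 0.23, mixotrophy override strictly > 0.77.

## Known limitations

* Feature lists and F1 scores obtained on real training corpora (hundreds
  of cultured transcriptomes) and on ocean metatranscriptomes are
  corpus-specific; nothing computed from synthetic data reproduces them,
  and no field-performance claim is made here.
* The replicate-split operationalization is one defensible reading of an
  underspecified rule; it is isolated behind `detect_replicate_split()`.
* Feature selection is seed-dependent by construction (random
  undersampling and splits); only the protocol, not a specific feature
  list, is the package's contract.
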