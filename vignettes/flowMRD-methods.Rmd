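---
title: "Automated MRD quantification with patient-specific RBF-SVM models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated MRD quantification with patient-specific RBF-SVM models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After induction therapy, an acute myeloid leukemia (AML) patient's marrow
may retain a small population of leukemic blasts — minimal residual disease
(MRD) — whose size predicts relapse. Multi-colour flow cytometry can see
these cells through a leukemia-associated immunophenotype (LAIP); the panel
assumed here is CD7-FITC, CD117-PE, HLA-DR-APC and CD45-PE-Cy7 plus forward
and side scatter, targeting CD7+/CD117+ co-expressing blasts. Conventional
readout draws 2-D gates by hand, which is subjective and uses only two of
the measured dimensions at a time.

flowMRD replaces the manual readout with a patient-specific supervised
classifier. At diagnosis the blast population is abundant and can be
selected once; those events, labeled 1, are pooled with events from healthy
donor marrows, labeled 0, and a soft-margin support vector machine with a
radial basis function (RBF) kernel

$$K(u, v) = \exp(-\gamma \lVert u - v \rVert^2)$$

is trained on the labeled mixture. At each follow-up visit, every acquired
event is classified by the stored model, and the MRD estimate is simply the
percentage of events predicted leukemic. The same specimen can also be read
with a conventional gate set ("P1 AND P2 AND P3"), and the two readouts are
compared with a paired t-test, Pearson correlation and Bland–Altman limits
of agreement.

## The pipeline and its parameters

`run_full_pipeline()` executes the canonical stage sequence:

1. **Training-file derivation** (`build_training_set()`): diagnosis blasts
   (flag 1) are concatenated with all donor events (flag 0). Each event
   keeps its source-file identifier.
2. **Stratified subsampling** (`stratified_sample()`, default
   `n = 10^4`): the full pool (2 × 10^5 events and up) makes grid search
   needlessly slow; a 10^4-event subsample tunes and trains just as well
   (the package's subsample-equivalence checks, and the bundled ten-pair
   reference comparison with its paired t-test p = 0.0792, both support
   this). Strata are the distinct source files — the only structure that
   exists before a model does — which preserves the leukemic:normal ratio
   and the donor balance to within one event via largest-remainder quotas.
3. **Saved-range scaling** (`fit_scaling()` / `apply_scaling()`): each
   feature channel is mapped affinely from its training min/max to
   [−1, 1] (the conventional target interval of LIBSVM's `svm-scale`).
   The range is persisted and re-applied verbatim at prediction time;
   follow-up values outside the training range extrapolate linearly — no
   clipping — so the transform stays affine and invertible. A constant
   training channel maps to the lower bound.
4. **Grid search** (`grid_search()`): every
   $(C, \gamma) = (2^a, 2^b)$ on a log2 lattice (defaults
   $a \in \{-5, -3, \dots, 15\}$, $b \in \{3, 1, \dots, -15\}$) is scored
   by 5-fold cross-validated accuracy. Folds are label-stratified and
   seeded: at MRD-like class imbalance an unstratified fold can lose all
   flag-1 events, making accuracy undefined in exactly the cases that
   matter. Ties — common on well-separated data, where a whole plateau of
   the grid reaches 100% — break towards larger C, then smaller γ: at
   equal cross-validated accuracy this selects the hard margin with the
   smoothest kernel, the simplest decision function consistent with the
   data, and in practice a far sparser support-vector set (a small-C
   winner on a 10^4-event separable pool keeps thousands of margin-bound
   support vectors; the large-C winner keeps a handful, making
   whole-specimen prediction proportionally faster). The overfitting risk
   usually associated with large C is confined to regimes where
   accuracies tie exactly — i.e. cleanly separable ones, where it is
   moot. The default bounds contain every optimum the method is expected
   to report (C up to 2^15 = 32768, γ down past 0.13 ≈ 2^−3).
5. **Model building** (`train_model()`): the SVM is fitted by LIBSVM (via
   e1071) at the chosen $(C, \gamma)$. The model object stores the dual
   representation — support vectors, coefficients, intercept — plus the
   scaling range and channel list, and all predictions are computed from
   that stored representation. This makes persistence exact: a model
   written with `write_patient_model()` and reloaded produces
   bit-identical predictions. LIBSVM orients its decision function towards
   whichever class appears first in the training data, so the coefficients
   are sign-normalised at training time so that positive decision values
   always mean "leukemic".
6. **Prediction** (`predict_mrd()`): events are restricted to the model's
   channels, rescaled with the embedded range, and classified; the
   reported fraction is `100 * #(flag 1) / n`. Decision values are
   evaluated in chunks sized so the event × support-vector kernel block
   stays near 2 × 10^7 elements, which keeps memory flat even when a
   small-C model retains thousands of support vectors.

## The synthetic-data generator

No clinical files ship with the package; every quantitative claim is
exercised on synthetic specimens from `simulate_specimen()` and
`spike_mrd()`. A specimen is a mixture of multivariate Gaussian
populations in intensity space (arbitrary linear units on a 0–1000-like
scale), truncated at zero. Two deliberate design choices:

* **Deterministic composition.** Per-population counts are the exact
  largest-remainder apportionment of `n_events` by the population
  fractions, and `spike_mrd()` places exactly `round(fraction * n)`
  leukemic events. Ground truth is therefore exact, and any recovery error
  is attributable to the classifier, not to multinomial sampling noise in
  the generator.
* **Gaussian populations.** Real LAIP clusters are compact but not
  Gaussian; Gaussians are the simplest shape that reproduces the scatter
  morphology the gates and the classifier have to handle. Truncation at
  zero (rather than resampling) keeps output a pure function of the seed.

The reference geometry (`normal_marrow_spec()`, `aml_blast_population()`)
places lymphocyte, granulocyte and monocyte populations at typical
scatter/marker positions and a CD7+/CD117+, CD45-dim blast cluster more
than 6 pooled standard deviations from every normal population on CD117.
Default sizes mirror the assumed acquisition floor of 10^5 events per
clinical file: 5 × 10^4 diagnosis blasts plus 15 donors × 10^4 events give
a 2 × 10^5-event training pool, and follow-ups carry 10^5 events.

What passing these tests does **not** show: robustness to spectral
spillover, autofluorescence, doublets, debris, acquisition drift, or an
LAIP that genuinely overlaps normal marrow. With partially overlapping
phenotypes the detection floor is known to degrade by an order of
magnitude, and the synthetic separable regime cannot speak to it.
Compensation is likewise out of scope — stored intensities are taken
as-is, as exported.

## File formats

The FCS 3.0 reader accepts `$DATATYPE` F, D and I (both byte orders);
integer channels with log amplification `$PnE = d,offset` are decoded to
scale units as `offset * 10^(d·x/$PnR)` (offset 0 read as 1). Other FCS
versions are rejected outright rather than coerced. The writer emits
single-data-segment little-endian files; it defaults to 32-bit float
storage, with 64-bit (`datatype = "D"`) available — and used by the
fixture generator — so that double-precision simulated values survive a
round trip bit-exactly. Models, training sets, scaling ranges and gate
sets all persist as versioned plain text, so artifacts diff cleanly and
reproduce across processes.

## Numerical conventions

* Gate membership is boundary-inclusive (a point on an edge or vertex is
  inside), so edge ties are deterministic; the point-in-polygon test is a
  crossing-number scan with an explicit on-segment check, validated
  against an independent winding-number implementation.
* Largest-remainder apportionment breaks remainder ties by index order.
* Bland–Altman limits use the large-sample 1.96 multiplier (classic 95%
  limits, no small-sample t correction); a difference exactly on a limit
  counts as inside. Differences are `a − b`, first method minus second.
* The paired t-test refuses zero-variance differences rather than
  fabricating a p-value.
* Grid-search CV accuracy is pooled over folds (total correct / total
  events), matching the conventional tuning-script readout.

## Problem sizes used by the test suite

The packaged checks run the full pipeline at the study conditions above:
recovery of spiked fractions {0.05%, 0.1%, 1%, 5%, 25%} on 10^5-event
follow-ups across two synthetic patients (twenty specimens, reduced log2
step 4 grid), and a subsample-vs-full comparison training one model on the
10^4-event subsample and one on the full 2 × 10^5-event pool across ten
follow-ups of 5 × 10^4 events. Small-instance oracle checks (≤ 200
events) compare grid-search CV accuracies against a from-scratch SMO dual
solver, point-in-polygon masks against a winding-number oracle, and
t-test p-values against direct quadrature of the Student-t density.

## Known limitations

* Blast selection at diagnosis is an input (a gate or truth labels), not
  an output: the package does not identify the diagnostic blast population
  automatically.
* One kernel (RBF), two classes, no probability outputs, no per-class
  weighting — class imbalance is managed by training-set composition.
* The choice of whether scatter channels join the feature space is left to
  configuration (default: all channels present), since reasonable
  laboratories differ here; the per-run log records the choice.
* Agreement statistics assume paired percentages on a common scale;
  regression-based Bland–Altman variants and confidence intervals on the
  limits are not provided.
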