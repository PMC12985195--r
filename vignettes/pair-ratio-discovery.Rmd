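---
title: "Pairwise Ct-ratio biomarker discovery: model, design choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise Ct-ratio biomarker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpair)
```

## The measurement model

RT-qPCR reports, per sample $s$ and assay $m$, a cycle threshold
$Ct_{s,m}$; each missing amplification within the cycling ceiling
(40 cycles by default) is exported as "Undetermined". `mirpair` treats the
observed Ct as

$$ Ct_{s,m} = \mu_m + \delta_m \,[s \in \text{case}] + u_s + \varepsilon_{s,m}, $$

where $\mu_m$ is the assay baseline, $\delta_m$ a case-vs-control shift,
$u_s$ a per-sample *technical offset* (RNA input, extraction and RT
efficiency — it hits every assay of a sample equally), and
$\varepsilon_{s,m} \sim N(0, \sigma_m^2)$ assay noise. Plasma has no
trusted reference gene, so normalization uses within-sample pair ratios:

$$ \text{Ratio}(a,b) = 2^{\,Ct_a - Ct_b}, \qquad
   \log_2 \text{Ratio}(a,b) = Ct_a - Ct_b . $$

The offset $u_s$ cancels *exactly* in the difference — not approximately.
The package asserts this to $10^{-12}$ in its tests; under the additive
model it is an algebraic identity. (Multiplicative efficiency differences
between assays, which do not cancel, are absorbed into $\mu_m$; see
Limitations.) A note on sign conventions: the package stores the ratio
exactly as printed above, so the *expression* of $a$ relative to $b$ is
its reciprocal; since every downstream statistic is either invariant to
monotone transforms (AUC) or learns the sign (logistic slope,
orientation flag), the convention has no effect on results.

Censored wells are imputed at the ceiling and flagged, never dropped:
dropping samples would silently change cohort sizes, and the QC stage is
the right place to remove unreliable assays. Replicate wells for one
(sample, assay) cell collapse by the median of their amplifying wells —
robust to single-well dropouts; whether source studies average replicates
or run single wells is typically unstated, and the median is a safe
superset of both.

## QC elimination

Panels are commonly curated from a longer candidate list (e.g. 61
candidates reduced to 48) by removing assays with poor detectability,
excessive variability or failed controls. Published reports rarely state
numeric cutoffs, so `mirpair` makes them explicit configuration with
stated conventions, echoed in every report:

| parameter | default | unit | meaning |
|---|---|---|---|
| `min_detect_rate` | 0.8 | fraction | uncensored share required per cohort |
| `max_assay_sd` | 3.0 | Ct | within-cohort SD ceiling (uncensored wells) |
| `ntc_max_ct_margin` | 5.0 | Ct | NTC must sit this far above the plate sample median |
| `spikein_sd_max` | 2.0 | Ct | across-plate spike-in SD ceiling |

Detection and variability are evaluated *per cohort* so an assay cannot
pass by being reliable in one group only. Spike-ins (UniSp3/UniSp6) are
used strictly as flags, never for normalization — the ratio features make
scale normalization unnecessary by construction. Filtering is idempotent
and never alters retained Ct values; lowering the detection floor can only
shrink the eliminated set (a monotonicity the tests enforce).

## Single-pair screening

Each pair's log2 feature is evaluated as a binary classifier the way an
exploratory screen does it:

- logistic regression of cohort on the feature (maximum likelihood);
  sensitivity, specificity and accuracy read off **in-sample** at the
  $p \ge 0.5$ rule ($p = 0.5$ classifies as case). In-sample evaluation is
  the screening design being mirrored, and is optimistically biased —
  outputs are ranked candidates, not validated performance. A
  cross-validated mode is deliberately absent from the default path.
- AUC by midranks, which equals the Mann–Whitney statistic
  $U/(n_1 n_2)$; the package computes it that way and tests the identity
  against an exhaustive pair-counting oracle. AUC is reported oriented
  ($\ge 0.5$) with the flip recorded.
- 95% CI by DeLong's method (default) or a seeded stratified bootstrap.
  No single CI convention dominates published panel studies; DeLong is the
  standard asymptotic choice and is recorded in output metadata.
- two-sided Mann–Whitney p, exact when $n_1 n_2 \le 400$ and tie-free,
  otherwise the tie-corrected normal approximation.
- gate: pairs with AUC $\ge 0.8$ (inclusive) advance. **No
  multiple-testing correction** is applied to the gate — a deliberate
  property of hypothesis-generating screens; BH q-values are carried in
  the output for readers who want them but never used for gating.

Perfectly separable features (an exhaustive screen will hit some) make the
logistic MLE diverge; the fit falls back to a deterministic ROC-optimal
step rule and is flagged. Constant features yield a flagged AUC-0.5
degenerate row rather than an error, so a screen never aborts mid-panel.

## Equal-weight combinations

Gated pairs are combined $k$ at a time (default $k = 3$, configurable
1–4) with *equal weights* and a sigmoid:

$$ P(\text{case}) = \frac{1}{1 + e^{-\text{score}}}, \qquad
   \text{score} = \frac{1}{k} \sum_{j=1}^{k} z_j . $$

Taken literally with $z_j$ the raw $2^{\Delta Ct}$ ratios, this formula is
internally inconsistent: ratios are strictly positive, so the score is
positive, $P > 0.5$ always, and every sample is classified as a case
(specificity 0). The package ships that literal form as `raw_ratio` mode,
carrying a caveat flag, and asserts the all-case behavior as a regression
test. The default `standardized_log` mode is the minimal repair that
preserves "equal-weight linear combination of pair features" and the
$p = 0.5$ rule: each member's oriented log2 feature is centered at the
midpoint between its class means and scaled to unit pooled within-class
SD, so score 0 is a meaningful boundary. Whether the original analyses
rescaled before the sigmoid is unknowable from the outside; the choice is
exposed, not hidden.

The search over combinations is **exhaustive** — all $\binom{g}{k}$
subsets of a $g$-pair gate (70,300 for $g=76, k=3$) — with no greedy
shortcut, no randomness, ranking by AUC then accuracy then lexicographic
member ids (the tie-break is this package's convention; none is standard).
Selection floors (`min_sens`, `min_spec`, `min_auc`) default to 0: any
"predefined criteria" are a reporting choice the caller must own.

Equal weighting is deliberately naive: the tests include a constructed
case where a forcibly mis-oriented member drags the combination below its
best member — equal weights cannot down-weight a bad input. They also show
the flip side: three independent planted pairs at true AUC 0.9 combine to
beat every member.

## Concordance

Plasma-vs-tissue similarity is quantified as Spearman + Pearson
correlation of per-assay mean Ct profiles (uncensored wells), plus the
mean Ct shift and a detectability cross-table. Published figures of this
kind usually report no statistic at all; the correlation pair is this
package's explicit quantification and is labeled as such. Adding a
constant to one matrix moves the shift by exactly that constant and leaves
both correlations unchanged.

## The synthetic generator and what passing tests mean

`simulate_cohort()` draws from exactly the measurement model above —
that is the point: under it, ratio normalization is *exactly* correct, and
every pair has the closed-form AUC

$$ \text{AUC}(a,b) = \Phi\!\left( \frac{|\delta_a - \delta_b|}
   {\sqrt{2(\sigma_a^2 + \sigma_b^2)}} \right), $$

recorded in the returned truth table. Defaults emulate the pilot design
the package targets: 30 + 30 samples, 48 assays, baselines $U[22, 34]$ Ct,
$\sigma_m = 1$, $\tau = 1.5$ Ct sample offsets, 40-cycle censoring, four
samples per plate with UniSp3/UniSp6/BlankSpot/NTC/positive-control wells
(pass-by-default, with switches for NTC contamination and spike-in drift),
and a 61-assay / 13-killed variant whose poorly detectable assays sit at a
0.3 detection rate. Matched tissue is generated as the plasma mean profile
shifted −6 Ct with 1.7-Ct pattern noise.

Two structural notes. First, planting *exactly* five differential pairs is
impossible with per-assay shifts: one shifted assay perturbs all 47 of its
pairs. Recovery scenarios therefore plant opposite shifts
($\pm\Phi^{-1}(0.95)$ Ct) on a few assays so the designated pairs sit at
theoretical AUC 0.95 while side pairs sit lower (≈0.79); tests assert the
planted pairs are gated and that the winning combination consists of truly
differential pairs — with many combinations reaching AUC 1.0 at $n = 60$,
the specific winner among them is tie-broken, not meaningful. Second, the
1128 pair features share 48 assays and are strongly *dependent*; a
Kolmogorov–Smirnov uniformity check on their null p-values would be
mis-specified (it rejects even under a perfect null). Calibration is
therefore tested on independent draws — the 24 assay-disjoint pairs from
each of 47 independent null cohorts — while the mean-AUC-near-0.5 check
runs over the full dependent set, where averaging is unaffected.

What passing does **not** show about real data: plasma Ct noise is not
Gaussian (degradation, hemolysis and platelet contamination are
structured), offsets are not perfectly additive across assays of very
different abundance, censoring is informative at low abundance, and
cohorts carry confounders (age, sex, race, collection tube) that the
generator deliberately omits. Simulation results validate the *machinery*,
not clinical performance.

## Numerical choices and degenerate inputs

- AUC uses midranks; ties contribute 1/2 — so all-tied scores give exactly
  0.5, and AUC is invariant under strictly increasing transforms (log2 vs
  ratio scale is tested `identical`).
- Problem sizes in the test suite and acceptance script (200 recovery
  replicates, 500 coverage simulations, one full 1128-pair screen, one
  70,300-combination search) were chosen as the smallest sizes at which the
  Monte-Carlo tolerances quoted are comfortably non-binding.
- The exact Mann–Whitney p switches to the normal approximation above
  $n_1 n_2 = 400$ or in the presence of ties.
- DeLong intervals are truncated to $[0, 1]$; at AUC 1.0 the variance is
  zero and the degenerate width-0 interval is flagged rather than hidden.
- Bootstrap intervals are stratified by class and seeded; the same seed
  reproduces the interval bit-for-bit.
- Youden thresholds (separable fallback) use midpoints between adjacent
  distinct scores, making the step rule deterministic.
- `run_discovery()` is deterministic end to end; reruns with an identical
  config reproduce every table byte-for-byte, and the log records seed,
  package version and a config hash.

## Known limitations

- In-sample metrics only, by design; no validation-cohort machinery.
- No covariate adjustment (age/sex/race) and no survival endpoints.
- No inter-plate Ct calibration — ratios make it unnecessary under the
  additive model, but plate-by-assay interactions would violate that.
- Triplet or higher-order ratio features, learned (non-equal) weights and
  regularized multivariate models are out of scope: the procedure
  implemented is the equal-weight exhaustive one, and its naivety is
  documented rather than patched.
- Parsing proprietary instrument binaries and melt-curve analysis are out
  of scope; input is exported delimited text.
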