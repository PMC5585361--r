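---
title: "Models and methods behind pdcscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pdcscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcscreen)
```

pdcscreen analyses the data produced by a personalized-oncology screening
platform: short-term patient-derived cultures (PDC) screened against
compound libraries in 384-well plates, paired fluorescence co-culture
screens that compare a patient's primary and metastatic tumour populations
in the same well, dose-response confirmation of hits, expression profiling
that checks how faithful the models are to the source tumour, and xenograft
(PDX) treatment studies that validate candidate compounds in vivo. This
vignette records the statistical models, the tunable parameters, and the
design choices made where more than one defensible option existed.

## Plate scoring

The primitive observation is a well's fluorescence (or luminescence) signal
in arbitrary units. A compound well is scored by the inhibition score

$$I(c) = \frac{\text{signal}(c)}{\mathrm{median}\{\text{signal(DMSO)}\}},$$

and reported as percent inhibition $(1 - I)\times 100$. The DMSO median is
taken **per plate per channel** by default: the ratio then cancels any
plate-level gain, which is the dominant nuisance in multi-plate screens (a
screen-wide median is available via `dmso_scope = "screen"` for designs
where plates are known to be balanced). Replicate wells of a compound are
pooled by median after per-plate normalization (mean via `aggregate`),
so a single bad well cannot drag a triplicate. Negative inhibition
(stimulation, $I > 1$) is retained rather than floored — it is information,
and the display threshold below handles presentation.

Each plate must carry at least 8 DMSO wells per channel before its control
median is trusted. The number is a validation default, configurable in
`screen_layout()`: medians over fewer wells have too much sampling noise to
anchor a whole plate.

For cross-line comparison, percent-inhibition profiles are arranged as a
compound × line matrix; rows with no entry at or above the display
threshold (50% by default) are dropped, and entries below it are flagged as
a grey-out mask. Profiles are clustered by complete-linkage agglomeration
on Euclidean distances. Merge heights under complete linkage equal the
maximum pairwise distance between the merged clusters, which the test suite
verifies against a brute-force agglomerator. Ties are broken
deterministically by sorting rows lexicographically by compound id before
clustering, so row order never changes the tree.

## Co-culture selective-toxicity classification

In the co-culture screen the two isogenic lines carry different
fluorophores, so one well yields two viability readouts. Per channel, the
compound I-scores are standardized,

$$Z = \frac{I - \mu}{\mathrm{s.d.}},$$

with $\mu$ and s.d. computed across all **compound** scores of that channel
for the whole screen (DMSO wells are excluded; they would otherwise shrink
the spread and inflate every Z). The transform is applied to I-scores
rather than raw fluorescence because only plate-normalized scores are
comparable across plates. The s.d. uses the sample ($n-1$) convention by
default with a population option, since either reading of "standard
deviation" is defensible; at screen scale ($n \approx 400$) the difference
is negligible.

Classification applies three threshold rules to the (GFP, RFP) Z pair:

| category | rule |
|---|---|
| dual-toxic | GFP $Z < -2.4$ **and** RFP $Z < -2.4$ |
| metastasis-selective | RFP $Z < -1$ **and** GFP $Z > -0.5$ |
| primary-selective | GFP $Z < -1$ **and** RFP $Z > -0.5$ |
| unclassified | otherwise |

The primary-selective rule is the mirror image of the metastasis-selective
one; this package states it explicitly as (GFP $Z < -1$, RFP $Z > -0.5$),
an interpretation imposed for symmetry where the rule is sometimes printed
ambiguously. The three regions are mutually exclusive by construction: a
selective call needs one channel above $-0.5$, a dual call needs both below
$-2.4$. Compounds deep in one channel but between $-2.4$ and $-1$ in the
other satisfy no rule and are reported unclassified rather than silently
dropped — they are visible in the output for manual review.

One behavioural consequence worth knowing: the spared-channel condition
$Z > -0.5$ is evaluated against that channel's own empirical spread. In a
screen where one channel carries no true effects, its Z-distribution is
pure between-compound noise (unit variance by construction), and a genuine
selective hit has roughly a 30% chance of dipping below $-0.5$ in the
spared channel by chance alone. In realistic screens, where both channels
contain active compounds that inflate the channel s.d., the spared-channel
margin widens and sensitivity rises above 95%. The planted-truth tests
exercise both regimes.

## Dose-response model

Viability is normalized to percent of the DMSO-control mean and fitted with
the four-parameter logistic

$$v(d) = \text{bottom} + \frac{\text{top} - \text{bottom}}
{1 + (d/\mathrm{IC}_{50})^{\text{hill}}},$$

parameterized on $\log_{10}$ dose and fitted by Levenberg–Marquardt least
squares (`minpack.lm`). Choices that matter:

* **Multi-start.** The IC50 is initialized at every tested dose and the
  Hill slope at 0.5, 1 and 2; the candidate with the lowest residual sum of
  squares wins. The 4PL surface has local minima when the curve is shallow
  or truncated, and a dose-grid of starts is the cheapest reliable cure.
* **Bounds.** bottom $\in [-10, 50]$, top $\in [50, 120]$, hill
  $\in (0, 10]$, $\log_{10}$IC50 within 3 decades of the tested range.
  These keep the asymptotes identified when the data only cover one limb of
  the curve.
* **Pooled replicates.** Triplicates enter as individual points rather than
  dose-wise means, so replicate scatter contributes to the RSS and to any
  downstream comparison of fits.
* **Censoring.** If the fitted IC50 exceeds the highest tested dose, or the
  mean viability never drops below 50%, the fit is reported as
  "IC50 greater than the top dose": the point estimate is set to the top
  dose and `ic50_censored` is raised. This mirrors the conventional
  "IC50 > X" reporting for inactive compounds and keeps fold-ratio
  arithmetic honest — a ratio involving a censored fit is flagged as a
  bound, not a point estimate.

The default simulated design is 9 three-fold dilutions from 10 µM in
triplicate — a standard plate layout when the true potency is unknown.
Under 5-percentage-point Gaussian noise the median relative IC50 recovery
error across the tested range is below 10%, and curves with true IC50 at or
below a third of the top dose are never censored; both are asserted in the
acceptance tests over 100 simulated curves.

## Expression analysis

Probe intensities are background-subtracted (nonpositive results floored at
1 a.u. so logs and ratios stay defined — the floor is far below any real
signal) and quantile-normalized across samples, delegating to limma's
implementation of the sorted-mean reference with tie averaging. After
normalization every column is an exact permutation of every other, which
the tests assert directly.

Cross-model concordance is the Pearson product-moment $r$ over all paired
probes. Differential regulation between two groups is a strict
more-than-twofold change of group means on the linear intensity scale: the
boundary ratio of exactly 2 is *not* selected. Means (not medians) are used
because groups here are small (2–3 arrays) and the generator's noise is
symmetric on the log scale; the strictness of the inequality is asserted at
the boundary.

Gene-set overrepresentation is the one-sided Fisher exact test: with $N$
measured genes, $n$ selected, a set of size $m$ and overlap $k$, the
p-value is the hypergeometric upper tail $P(X \ge k)$, computed via
`phyper` and verified in the tests against exhaustive combinatorial
enumeration for every table with $N \le 30$ and against `fisher.test`.
P-values across sets are Benjamini–Hochberg adjusted; significance is
called on the adjusted value at 0.05 by default, with a switch for the raw
p (both are always emitted, and the criterion used is recorded in the
result's attributes) — thresholding after an FDR step is the reading most
consistent with performing the correction at all.

The averaged-reference signature variant targets panels of metastatic
lines: the reference is the per-probe mean across lines, a line's
"elevated" probes are those strictly more than twofold above it, and each
line's elevated set is tested for overrepresentation. Probe-to-gene
collapse treats a gene as selected when any of its probes is selected; the
synthetic studies use a 1:1 probe–gene mapping.

## Xenograft growth metrics

Caliper length and width give the modified ellipsoidal volume
$V = \tfrac12 L W^2$ (mm³); records with $W > L$ are swapped with a warning
since the convention is length ≥ width. Weight is estimated from volume at
tissue density 1 g/cm³. The tumour-growth-inhibition ratio at day $d$ is

$$\frac{\Delta T}{\text{Average } \Delta C} =
\frac{V_T(d) - V_T(0)}{\overline{V_C(d) - V_C(0)}},$$

with the control average taken over all control animals still measured at
day $d$; animals withdrawn early simply drop out of later days (no
imputation). Arm summaries report mean ± s.e.m. (sd/√n, missing for
single-animal groups). Endpoint comparisons use the two-tailed
pooled-variance Student's t-test by default — matching the named test in
this field's reporting — with Welch as an option; each grafted tumour is
the experimental unit. The degenerate both-arms-constant-and-equal case
returns $t = 0, p = 1$ rather than erroring.

## Synthetic-data generators

The generators emulate the platform's four input types with planted ground
truth, and every test that claims "recovery" scores the pipeline against
that truth:

* **Co-culture screen** — 384-well plates, 16 DMSO wells per plate per
  channel, control signal 10,000 a.u., multiplicative Gaussian noise with
  SD 5% of the noise-free signal. Planted compounds have per-channel kill
  fractions; the default selective planting uses kill 0.95, an effect ~19
  noise-SDs deep, chosen because the spared-channel classification margin
  grows with the planted effect (see the Z-score discussion above). The
  truth category applies the classifier's own rules to the noise-free
  effects, with a flat (no-effect) channel contributing $Z = 0$.
* **Dose-response** — the 9-step three-fold triplicate design from 10 µM,
  additive Gaussian noise in viability percentage points.
* **Expression study** — log-normal baseline intensities (median ~200
  a.u.), a 4-fold elevation planted on 50 of 5,000 probes concentrated in
  one gene set, multiplicative log-normal noise at 10% CV, plus size-matched
  random decoy sets.
* **Growth study** — exponential volumes $V(t) = V_0 e^{rt}$ from
  $V_0 = 100$ mm³, caliper measurements every 2 days to day 10, arms of 6
  animals, log-normal measurement noise at 5% CV, and calipers back-solved
  under the common $W = L/2$ habitus so the volume formula inverts exactly.

Every generator is deterministic under a fixed seed. The noise models are
deliberately simple — Gaussian on signals, log-normal on intensities and
calipers — and the generators do **not** emulate plate-positional (edge)
effects, carry-over, probe cross-hybridization, batch structure beyond what
quantile normalization removes, or tumour growth deceleration. Passing the
planted-truth suites therefore demonstrates that the analytics are correct
and well-calibrated under the stated noise models, not that real screens
are free of those artefacts; on instrument data the DMSO-count validation
and the visible unclassified band are the intended guard rails.

Problem sizes used by the test and acceptance runs — 384-compound screens,
100 simulated dose-response curves, 5,000-probe expression studies, 1,000
simulated growth studies — were chosen as the smallest sizes at which the
recovery statistics are stable to well within their asserted tolerances.

## Known limitations

* The 4PL family cannot represent biphasic responses; no 5PL or Bliss/Loewe
  combination scoring is provided.
* Hit calling is single-dose by design; potency ranking belongs to the
  dose-response module.
* Enrichment is overrepresentation-only (no ranked/GSEA-style statistic).
* Growth analysis is cross-sectional per day; there is no longitudinal
  mixed-effects model, and attrition is handled by exclusion, not
  modelling.
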