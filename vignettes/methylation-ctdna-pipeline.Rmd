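---
title: "Methods: methylation ddPCR quantification, ctDNA calling and prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation ddPCR quantification, ctDNA calling and prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trimethr)
```

## The measurement problem

Tumor-agnostic liquid-biopsy assays detect circulating tumor DNA (ctDNA) by
targeting cancer-specific DNA methylation. The workflow this package
implements quantifies, in bisulfite-converted cell-free DNA (cfDNA) from
plasma, three gastrointestinal-cancer methylation markers — *C9orf50*,
*KCNQ5* and *CLIP4* — by methylation-specific droplet digital PCR (ddPCR),
and calls a plasma sample ctDNA positive when at least two of the three
markers each show more than one positive droplet (the TriMeth rule). Serial
samples across a perioperative protocol (baseline, after one chemotherapy
cycle, after preoperative chemotherapy, post-surgery) then feed survival
analytics: patients with detectable ctDNA after treatment are at sharply
elevated recurrence risk, so the sample call becomes a prognostic covariate.

The package covers the whole chain: droplet amplitudes →
control-derived thresholds → Poisson quantification → copies per mL plasma →
QC gates → sample calls → detection rates and dynamics → Kaplan–Meier /
log-rank / Cox / ROC → study design (events, sample size, simulated power),
plus generators for synthetic droplet plates and clinical cohorts with known
ground truth.

## Droplet quantification

**Thresholding.** ddPCR wells contain two fluorescence clusters (empty and
template-bearing droplets) plus "rain" in between. Each plate carries a
negative control (unmethylated DNA) and a positive control (fully methylated
DNA); one threshold per plate × channel is derived from them and applied to
every sample well on that plate. The rule, implemented in
`threshold_from_controls()`:

* negative centre $c_-$ = median of the negative-control amplitudes,
* positive centre $c_+$ = median of the upper cluster found by a
  deterministic two-means split of the positive control (centres initialised
  at the amplitude extremes, so no randomness),
* threshold $= \max\{c_- + 0.4\,(c_+ - c_-),\; c_- + 7\,\mathrm{MAD}_-\}$,

with the raw (unscaled) median absolute deviation. The 0.4 interpolation
places the cut well below the midpoint — conservative against rain, which
sits mostly in the lower part of the gap — while the MAD floor protects
against controls whose clusters sit unusually close. If the two centres are
separated by less than 4 negative-control MADs the plate is declared a
control failure rather than thresholded. The rule is deliberately
scale-equivariant: multiplying all amplitudes by a common gain moves the
threshold by the same factor and leaves droplet classifications unchanged.
Droplets count positive only when *strictly above* the threshold; boundary
ties count negative, so a single borderline droplet cannot create a call.

The duplex layout runs *C9orf50* + *KCNQ5* in one reaction and *CLIP4* + CF
in the other. Because both duplexes use both optical channels, the package's
layout convention is that each duplex group occupies its own plate
identifier; "one threshold per plate × channel" is then unambiguous.

**Poisson correction.** With $k$ of $n$ droplets positive, the mean copies
per droplet is $\lambda = -\ln(1 - k/n)$, correcting for multiply occupied
droplets. Copies per µL of reaction is $\lambda / V_d$ with droplet volume
$V_d = 0.85$ nL (the QX200 partition-volume convention; configurable in
`reaction_geometry()`), and copies per reaction scales by the 22 µL reaction
volume. Fully positive wells are reported as *saturated* with undefined
concentration — dilution-aware recovery is out of scope, and silently
converting saturation to a number would understate the load.

**Copies per mL plasma.** Only `template_volume` (2–8 µL) of the 22 µL
bisulfite eluate enters a reaction, and the eluate derives from a known
plasma volume (median 8 mL), so

$$\text{copies/mL} = \text{copies/reaction} \times
  \frac{V_\text{eluate}}{V_\text{template}} \Big/ V_\text{plasma}.$$

## Quality control

Three exclusion rules gate every sample (`qc_gate()`):

* **Leucocyte contamination** — the PBC assay (VDJ-rearranged IGH locus,
  B-cell specific) detects genomic DNA from lysed leucocytes. The study's
  numeric cutoff is not published; the package's default is *relative*:
  fail when PBC-derived copies exceed 10% of the CF-measured copies, which
  is robust to the absolute cfDNA amount. Configurable in `qc_config()`.
* **Low droplets** — fewer than 10,000 droplets in any of the sample's
  wells (applied per well; one bad well fails the sample).
* **No CF signal** — zero CF copies after bisulfite conversion, which makes
  the conversion recovery incomputable.

Purification efficiency is the percentage recovery of the CPP1 soybean
spike-in added before extraction (typical median 92%); bisulfite recovery is
CF copies after conversion divided by before (typical median 51%). The
recovery direction is after/before — the only direction consistent with a
median near 51% — even though informal descriptions sometimes state it the
other way around. Over-recovery (>100%) is flagged in the report but is not
an exclusion. QC-failed samples are *not evaluable* downstream — they are
neither positive nor negative and never enter detection rates or survival
models.

## Sample calling and detection summaries

`marker_positive()` requires more than one positive droplet (≥ 2) per
marker; `sample_call()` requires at least 2 of 3 markers positive. The call
is monotone (more droplets can never turn a positive sample negative) and
invariant under marker permutation. The TriMeth overall concentration is
reported as the *sum* of the three marker concentrations — the aggregate
that preserves the total count of methylated molecules. `detection_rate()`
reports per-timepoint positives over evaluable samples with integer-rounded
percentages; `cohort_dynamics()` classifies patients into the four
transition groups (neg→neg, neg→pos, pos→neg, pos→pos) between two
timepoints, dropping patients missing either call.

## Survival analytics

Endpoints are built from dates (`build_endpoints()`), in months
(days / 30.4375): RFS runs from inclusion to recurrence or cancer death; a
death from another cause without prior recurrence *censors* RFS at the death
date (the endpoint definition counts only cancer deaths, and a handful of
such deaths is expected in cohorts like this); OS runs to death from any
cause; otherwise patients are censored at the data cutoff. Deaths with
unknown cause count as cancer deaths for RFS — the conservative reading.

Kaplan–Meier estimation, Greenwood standard errors with log-transformed
confidence intervals, log-rank tests and Cox models are computed with the
`survival` package (`survfit`, `survdiff`, `coxph` with the Efron tie
approximation — accurate for small cohorts with tied months). Hazard ratios
are reported with Wald 95% CIs and p-values against the first factor level
as reference (code "not detected" first). The multivariable convention
mirrors two-stage clinical modelling: candidates with univariable p < 0.05
enter the joint model. Monotone-likelihood fits (no events in a level) are
returned flagged rather than raised as errors. Landmark survival defaults to
24 months. ROC analysis (`pROC`, fixed direction, trapezoidal handling of
ties, label = recurrence during follow-up) and Pearson chi-square tests
without continuity correction complete the analytics.

The tests cross-check these against independent oracles: a brute-force
product-limit computation, an exhaustive label-permutation log-rank oracle,
a hand-written Mann–Whitney AUC, and parameter-recovery simulations. At
n ≤ 10 the permutation null is discrete and the chi-square approximation to
the log-rank p-value is accurate in the tail but can deviate by several
hundredths near p ≈ 0.5; the oracle-agreement fixtures therefore probe the
decision-relevant tail region (p ≲ 0.1), where agreement is within 0.02.

## Study design

`schoenfeld_events()` computes the required number of events,
$d = (z_{1-\alpha/2} + z_{\beta})^2 / \{p(1-p)(\ln \text{HR})^2\}$, and
`required_n()` converts events to patients using exponential event
probabilities at a minimum follow-up: hazard $\ln 2 / 30$ months in the
ctDNA-negative arm, multiplied by HR = 5.4 in the positive arm, mixed by the
15% positivity. The follow-up horizon is not part of the published
assumption set; the package adopts 18 months (a reasonable minimum follow-up
for a perioperative cohort with ~2 years of surveillance), under which the
design returns exactly 52 patients. `simulate_power()` verifies the design
by Monte-Carlo: the empirical power at n = 52 comes out near 93%, *above*
the nominal 80% — Schoenfeld's formula uses the randomization fraction
$p(1-p)$, which is conservative when the event rates differ as strongly
between arms as they do at HR 5.4. With HR = 1 the rejection rate calibrates
to the nominal 5%.

## Synthetic data: what it emulates, and what it does not

`simulate_plate()` emits droplet-level tables in the same CSV dialect the
quantification stack reads: ~21,000 droplets per well (normal,
sd ≈ 900), two Gaussian amplitude clusters, per-plate control wells, the
duplex layout, and optional CPP1/PBC QC wells. Molecule loads are derived
from true copies/mL by inverting the volume chain; droplet occupancy is
binomial with the Poisson single-droplet rate, so quantification should
recover the truth within Poisson sampling error — and tests confirm a median
bias under 10% at 50 copies/mL.

**Rain model.** Rain droplets (default 0.5% of droplets) are drawn uniformly
in a band at 5–35% of the negative-to-positive separation. Real rain is
predominantly sub-threshold, and the 0.4 interpolation coefficient of the
threshold rule means this band never crosses the control-derived cut; a rain
band straddling the threshold would make every blank sample positive, which
real TriMeth plates do not do. The cost of this choice is that the generator
does not stress super-threshold rain artifacts; the strict-inequality
classification and the conservative 0.4 placement are the package's defences
there, but they are not exercised by the simulation. Rain that lands on an
occupied droplet makes it a false negative, as in real data.

`simulate_cohort()` draws serial ctDNA statuses with the configured
per-timepoint positivity (56/37/25/15% by default) through a Gaussian copula
on a shared latent tumor-burden variable (correlation 0.7), so marginals are
exact while statuses persist realistically across timepoints and all four
dynamics groups occur. Positive samples draw total methylated copies/mL from
a log-normal with median 30 and σ(log) = 1 — producing realistic single-digit
droplet counts near the calling boundary — split across the markers by
normalized Gamma weights, with *CLIP4* contributing in only 75% of positive
patients (its methylation is absent in a quarter of gastric/GEJ tumors).
Negative samples carry zero copies. QC failures are injected at the study's
~4.6% rate (11 of 240), uniformly over the three failure modes.

**Outcome model.** RFS is exponential with hazard
$h_0 \cdot 2.54^{s_1} \cdot 6.22^{s_2}$, where $h_0 = \ln 2/30$ months and
$s_1, s_2$ indicate positivity after one cycle and post-surgery. These
multipliers are *conditional* hazard ratios: because serial statuses are
correlated, the marginal univariable HR at one timepoint exceeds its
conditional value when the other effect is active. Recovery tests therefore
isolate one effect (the other multiplier set to 1) when checking that Cox
CIs cover the generator's truth. OS is recurrence followed by an exponential
post-recurrence survival (median 8 months), competing with an independent
other-cause death process (median 120 months) — which reproduces the
qualitative RFS/OS ordering and the occasional non-cancer death without
recurrence, without claiming the study's OS mechanism. Patients accrue
uniformly over an 18-month window and are censored administratively at the
data cutoff (2023-07-01).

What the generator does **not** emulate: covariate–status correlation
structure (covariates are drawn at the study's marginal frequencies,
independent of ctDNA status), plate-position effects, inter-assay
fluorescence drift, bisulfite-induced fragmentation of the markers
themselves, and super-threshold rain. Passing tests on synthetic data
therefore demonstrate that the *computational chain* is correct and
calibrated, not that the assay's biology behaves as modelled.

## Numerical choices and degenerate inputs

* Two-means amplitude split: Lloyd iterations from the range extremes,
  capped at 100 iterations; deterministic, no seed.
* MAD uses constant = 1 (raw median absolute deviation); a zero-MAD
  negative control is valid (the floor collapses to the centre).
* Amplitudes exactly at the threshold count negative.
* Saturated wells ($k = n$): reported, never converted.
* Empty wells, zero-margin contingency tables, single-level covariates, and
  one-class ROC labels are input errors with explicit messages; QC rows with
  missing metrics fail with reason `incomplete_qc` rather than erroring.
* Problem sizes in the test-suite simulations — 200 cohorts of 200 patients
  for CI coverage, 500 samples × 3 markers for plate recovery, 5,000
  replicates for power — were chosen so Monte-Carlo error is small relative
  to the tolerance being checked while the whole suite stays comfortably
  interactive.

## Known limitations

* The automatic thresholding procedure used by the original assay is
  described in prior methodological work and not fully specified here; the
  interpolation + MAD-floor rule is this package's own deterministic,
  scale-equivariant realisation of "objectively defined from the controls",
  not a byte-level reimplementation.
* No Poisson confidence intervals on concentrations, no multi-dye color
  compensation, no QuantaSoft binary parsing (CSV exports only).
* No time-varying-covariate Cox models and no competing-risks estimators;
  non-cancer deaths are handled by censoring RFS, which is the stated
  endpoint definition but not a competing-risks treatment.
* The leucocyte-contamination cutoff and the exact "non-measurable CF"
  definition are package conventions (documented above) because the source
  protocol leaves them unspecified.
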