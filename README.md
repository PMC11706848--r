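# trimethr

Methylation ddPCR quantification, ctDNA calling and prognostic analysis for
liquid biopsies in resectable gastric and gastroesophageal junction (GEJ)
cancer.

## What problem this solves

Patients resected for gastric/GEJ adenocarcinoma recur often, and surveillance
imaging detects recurrence late. Circulating tumor DNA (ctDNA) measured in
plasma during and after curative-intent treatment identifies patients with
minimal residual disease early. A tumor-agnostic way to detect ctDNA is
methylation-specific droplet digital PCR (ddPCR) against gastrointestinal
cancer methylation markers — here the TriMeth panel (*C9orf50*, *KCNQ5*,
*CLIP4*).

`trimethr` implements the complete analysis chain for such a study, for
anyone running or reanalysing a serial-plasma ddPCR methylation cohort:

1. **Quantification** (`quantify_droplets()`): droplet amplitudes → per-plate
   control-derived thresholds → Poisson correction
   `λ = −ln(1 − k/n)` → copies/µL → copies per mL plasma via the volume chain
   `copies/reaction × (V_eluate / V_template) / V_plasma`.
2. **QC** (`qc_gate()`): CPP1 spike-in purification efficiency, PBC
   leucocyte-contamination flag, bisulfite recovery from the CF assay,
   ≥10,000-droplet rule; failed samples become "not evaluable".
3. **Calling** (`call_samples()`): a marker is positive at >1 positive
   droplet; a sample is ctDNA positive when ≥2 of 3 markers are positive.
   Detection rates per timepoint and ctDNA dynamics groups.
4. **Prognosis** (`build_endpoints()`, `km_estimate()`, `logrank_test()`,
   `cox_univariable()`, `cox_multivariable()`, `roc_analysis()`):
   recurrence-free and overall survival with Kaplan–Meier landmark
   estimates, log-rank tests, Efron-tie Cox models with univariable
   screening, and ROC curves.
5. **Design** (`required_n()`, `simulate_power()`): Schoenfeld's event
   formula `d = (z_{1−α/2} + z_pow)² / {p(1−p)(ln HR)²}` converted to a
   patient count through exponential event probabilities, verified by
   Monte-Carlo power simulation.
6. **Synthetic data** (`simulate_plate()`, `simulate_cohort()`):
   droplet-level plates and clinical cohorts with known ground truth, so the
   full stack is testable end to end.

All user-facing functions take data frames and return tibbles; results have
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Simulate a 40-patient cohort with the default study-like conditions, run the
whole pipeline, and inspect the result:

```r
library(trimethr)

cfg    <- simulation_config(n_patients = 40)
cohort <- simulate_cohort(cfg, seed = 42)
qc     <- simulate_qc_table(cohort$samples, cfg, seed = 43)
plates <- simulate_plate(cohort$samples, cfg, seed = 44,
                         include_qc_wells = FALSE)

res <- run_pipeline(plates$droplets, cohort$samples, qc = qc,
                    clinical = cohort$patients, seed = 42)
res
#> <trimeth_pipeline>
#>   samples: 109 collected = 106 analyzed + 3 excluded
#>   wells: 254 (median 20987 droplets)
#> # A tibble: 4 × 4
#>   timepoint      n_positive n_evaluable rate_percent
#>   <fct>               <int>       <int>        <dbl>
#> 1 baseline               17          37           46
#> 2 after_1_cycle          13          30           43
#> 3 after_preop_ct          4          13           31
#> 4 post_surgery            7          26           27
#>   hazard ratios (ctDNA detected vs not):
#> # A tibble: 8 × 6
#>   timepoint      endpoint    hr ci_low ci_high p_value
#>   <chr>          <chr>    <dbl>  <dbl>   <dbl>   <dbl>
#> 1 baseline       RFS       2.61  1.06     6.44 0.0371
#> 2 baseline       OS        2.67  1.08     6.63 0.0337
#> 3 after_1_cycle  RFS       2.65  1.02     6.84 0.0446
#> 4 after_1_cycle  OS        1.07  0.443    2.58 0.881
#> 5 after_preop_ct RFS       3.11  0.679   14.2  0.144
#> 6 after_preop_ct OS        1.78  0.396    7.96 0.454
#> 7 post_surgery   RFS       8.52  1.95    37.2  0.00436
#> 8 post_surgery   OS        2.28  0.820    6.32 0.114
```

Reading the output: 109 plasma samples were simulated, 3 failed QC (injected
at the ~5% study-like rate) and never reach calling or survival stages.
Detection rates fall across treatment (46% → 27% here; at n = 40 the rates
scatter around the configured 56/37/25/15%). The Cox table shows the
postoperative ctDNA status carrying the largest recurrence hazard (HR 8.5,
CI 1.9–37 in this small run; the generator's conditional truth is 6.22).

The sample-size design reproduces its published figure exactly:

```r
required_n(design_assumptions())
#> # A tibble: 1 × 6
#>   events_exact event_prob_neg event_prob_pos event_prob n_exact     n
#> 1         21.6          0.340          0.894      0.423    51.1    52
```

22 events are required; at the 18-month follow-up horizon 42.3% of patients
are expected to event, giving 52 patients.

## Documentation

The methods vignette (`vignettes/methylation-ctdna-pipeline.Rmd`) documents
the thresholding rule, the QC conventions, the endpoint definitions, the
design calculation, the synthetic-data models and their limitations, and
every place where the package had to fix a convention the source protocol
leaves open.
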