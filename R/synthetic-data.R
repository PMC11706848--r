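#' Simulation configuration for synthetic plates and cohorts
#'
#' Central knob set for the synthetic-data generators. Defaults encode the
#' study conditions the analysis stack is meant to operate under: ~21,000
#' droplets per well, two-cluster amplitude distributions with a small
#' sub-threshold rain band, per-timepoint ctDNA positivity of 56/37/25/15%,
#' a ~5% sample QC-failure rate, spike-in recovery centred at 92% and
#' bisulfite recovery at 51%, and recurrence hazards scaled by ctDNA status
#' (conditional hazard ratios 2.54 for positivity after one chemotherapy
#' cycle and 6.22 post-surgery, on an exponential baseline with 30-month
#' median RFS).
#'
#' @param n_patients Cohort size. Default 86.
#' @param droplets List: `mean`, `sd`, `min` for per-well droplet counts.
#' @param amplitude List: negative/positive cluster means and sds,
#'   `rain_fraction` (fraction of droplets smeared into the rain band) and
#'   `rain_band` (band limits as fractions of the cluster separation).
#' @param positivity Named per-timepoint probability a patient is truly
#'   ctDNA positive.
#' @param sampling_prob Named per-timepoint probability a sample was
#'   collected.
#' @param status_correlation Gaussian-copula correlation of the latent tumor
#'   burden across timepoints (0 = independent, 1 = perfectly nested).
#' @param copies List: log-normal copies/mL model among true positives
#'   (`median`, `sdlog`), and `clip4_present_prob` — the probability the
#'   CLIP4 marker is methylated in a positive patient's tumor.
#' @param qc List: spike-in amount, recovery and contamination models.
#' @param qc_failure_rate Probability a sample fails QC. Default 0.046.
#' @param outcome List: RFS/OS generation (`median_rfs_neg` months,
#'   conditional `hr_after_1_cycle` and `hr_post_surgery`,
#'   `post_recurrence_median` months from recurrence to cancer death,
#'   `other_death_median` months for other-cause death, accrual window and
#'   `data_cutoff`).
#' @param plate_size Samples per simulated plate. Default 20.
#' @param control_lambda Mean copies/droplet in positive-control wells.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_patients = 86,
    droplets = list(mean = 20978, sd = 909, min = 1000),
    amplitude = list(neg_mean = 1000, neg_sd = 60, pos_mean = 9000,
                     pos_sd = 300, rain_fraction = 0.005,
                     rain_band = c(0.05, 0.35)),
    positivity = c(baseline = 0.56, after_1_cycle = 0.37,
                   after_preop_ct = 0.25, post_surgery = 0.15),
    sampling_prob = c(baseline = 84 / 89, after_1_cycle = 74 / 89,
                      after_preop_ct = 27 / 89, post_surgery = 55 / 89),
    status_correlation = 0.7,
    copies = list(median = 30, sdlog = 1.0, clip4_present_prob = 0.75),
    qc = list(spiked_cpp1 = 2000, purification_mean = 0.92,
              purification_sd = 0.09, bisulfite_mean = 0.51,
              bisulfite_sd = 0.09, cf_before_meanlog = log(3000),
              cf_before_sdlog = 0.8, pbc_background_fraction = 0.01,
              contamination_fraction = 0.25),
    qc_failure_rate = 11 / 240,
    outcome = list(median_rfs_neg = 30, hr_after_1_cycle = 2.54,
                   hr_post_surgery = 6.22, post_recurrence_median = 8,
                   other_death_median = 120,
                   accrual_start = as.Date("2020-02-04"),
                   accrual_end = as.Date("2021-08-26"),
                   data_cutoff = as.Date("2023-07-01")),
    plate_size = 20,
    control_lambda = 0.25) {
  stopifnot(all(positivity >= 0 & positivity <= 1),
            all(sampling_prob >= 0 & sampling_prob <= 1),
            qc_failure_rate >= 0 && qc_failure_rate <= 1,
            status_correlation >= 0 && status_correlation <= 1,
            amplitude$rain_fraction >= 0 && amplitude$rain_fraction < 1)
  if (!all(TIMEPOINTS %in% names(positivity))) {
    abort("positivity must name all four protocol timepoints")
  }
  structure(list(n_patients = n_patients, droplets = droplets,
                 amplitude = amplitude, positivity = positivity,
                 sampling_prob = sampling_prob,
                 status_correlation = status_correlation, copies = copies,
                 qc = qc, qc_failure_rate = qc_failure_rate,
                 outcome = outcome, plate_size = plate_size,
                 control_lambda = control_lambda),
            class = "simulation_config")
}

# Amplitudes for one well: k positive droplets, n - k negative, then a
# rain_fraction of droplets re-drawn uniformly in the rain band (a fraction
# of the negative-to-positive separation, below where the control-derived
# threshold falls). Rain hitting a positive droplet makes it a false
# negative, as in real data.
simulate_amplitudes <- function(n, k, amp) {
  x <- c(rnorm(k, amp$pos_mean, amp$pos_sd),
         rnorm(n - k, amp$neg_mean, amp$neg_sd))
  if (amp$rain_fraction > 0 && n > 0) {
    n_rain <- rbinom(1, n, amp$rain_fraction)
    if (n_rain > 0) {
      sep <- amp$pos_mean - amp$neg_mean
      idx <- sample.int(n, n_rain)
      x[idx] <- runif(n_rain, amp$neg_mean + amp$rain_band[1] * sep,
                      amp$neg_mean + amp$rain_band[2] * sep)
    }
  }
  x
}

draw_droplet_count <- function(n_wells, cfg) {
  pmax(cfg$droplets$min, round(rnorm(n_wells, cfg$droplets$mean,
                                     cfg$droplets$sd)))
}

# Mean copies per droplet for a well loaded with `copies_per_reaction`
# template copies: only n*Vd of the reaction volume is partitioned.
lambda_from_copies <- function(copies_per_reaction, geometry) {
  copies_per_reaction * geometry$droplet_volume / geometry$reaction_volume
}

#' Simulate droplet-level ddPCR plates for a set of samples
#'
#' Generates QuantaSoft-export-like droplet tables for the TriMeth duplex
#' layout: per sample one duplex well for C9orf50 (channel 1) + KCNQ5
#' (channel 2) and one for CLIP4 (channel 1) + CF (channel 2), plus
#' per-plate positive, negative and no-template control wells, and
#' optionally a QC plate with CPP1/PBC wells. Each duplex group is placed on
#' its own plate identifier so one threshold per plate x channel is
#' well-defined. Molecule loads are derived from the true copies/mL via the
#' inverse of the copies-per-mL chain; droplet occupancy is binomial with
#' the Poisson single-droplet rate, so the quantification stack should
#' recover the truth within Poisson sampling error.
#'
#' @param samples Tibble with `sample_id` and `copies_C9orf50`,
#'   `copies_KCNQ5`, `copies_CLIP4` (true copies per mL plasma); optional
#'   `cf_after_copies` (CF copies in the eluate; drawn from the QC model if
#'   absent), `template_volume`, `plasma_volume`, and `droplets_override`
#'   (forces the droplet count of that sample's wells, e.g. to inject
#'   low-droplet QC failures).
#' @param config A [simulation_config()].
#' @param seed Integer seed; output is deterministic given the seed.
#' @param geometry A [reaction_geometry()].
#' @param include_qc_wells Emit the CPP1/PBC QC plate. Default TRUE.
#' @return A list: `droplets` (droplet-level tibble), `truth` (per
#'   sample x target true copies/mL and per-reaction loads).
#' @export
simulate_plate <- function(samples, config = simulation_config(), seed = 1,
                           geometry = reaction_geometry(),
                           include_qc_wells = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  needed <- c("sample_id", paste0("copies_", TRIMETH_MARKERS))
  missing <- setdiff(needed, names(samples))
  if (length(missing) > 0) {
    abort(paste0("`samples` is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  set.seed(seed)
  s <- tibble::as_tibble(samples)
  n <- nrow(s)
  if (!"template_volume" %in% names(s)) {
    s$template_volume <- geometry$template_volume
  }
  if (!"plasma_volume" %in% names(s)) s$plasma_volume <- geometry$plasma_volume
  if (!"cf_after_copies" %in% names(s)) {
    s$cf_after_copies <- rlnorm(n, config$qc$cf_before_meanlog,
                                config$qc$cf_before_sdlog) *
      pmin(pmax(rnorm(n, config$qc$bisulfite_mean, config$qc$bisulfite_sd),
                0.05), 0.95)
  }
  if (!"droplets_override" %in% names(s)) s$droplets_override <- NA_real_

  duplexes <- list(A = c(ch1 = "C9orf50", ch2 = "KCNQ5"),
                   B = c(ch1 = "CLIP4", ch2 = "CF"))
  s$plate_index <- ceiling(seq_len(n) / config$plate_size)
  amp <- config$amplitude

  well_rows <- function(plate_id, well_id, sample_id, role, channel, target,
                        copies_per_reaction, n_droplets) {
    lam <- lambda_from_copies(copies_per_reaction, geometry)
    k <- rbinom(1, n_droplets, 1 - exp(-lam))
    tibble::tibble(plate_id = plate_id, well_id = well_id,
                   sample_id = sample_id, channel = channel, target = target,
                   role = role,
                   amplitude = simulate_amplitudes(n_droplets, k, amp))
  }

  out <- vector("list", 0)
  truth <- vector("list", 0)
  for (pi in unique(s$plate_index)) {
    block <- s[s$plate_index == pi, ]
    for (dx in names(duplexes)) {
      plate_id <- sprintf("P%02d_%s", pi, dx)
      targets <- duplexes[[dx]]
      # controls: positive (high load), negative and NTC (blank), per channel
      n_ctrl <- draw_droplet_count(3, config)
      ctrl <- purrr::map_dfr(seq_along(targets), function(ci) {
        ch <- names(targets)[ci]
        dplyr::bind_rows(
          well_rows(plate_id, "POS", NA_character_, "positive_control", ch,
                    targets[[ci]],
                    config$control_lambda * geometry$reaction_volume /
                      geometry$droplet_volume,
                    n_ctrl[1]),
          well_rows(plate_id, "NEG", NA_character_, "negative_control", ch,
                    targets[[ci]], 0, n_ctrl[2]),
          well_rows(plate_id, "NTC", NA_character_, "no_template_control", ch,
                    targets[[ci]], 0, n_ctrl[3])
        )
      })
      out[[length(out) + 1]] <- ctrl

      for (ri in seq_len(nrow(block))) {
        row <- block[ri, ]
        nd <- if (!is.na(row$droplets_override)) row$droplets_override else
          draw_droplet_count(1, config)
        well_id <- sprintf("%s_%s", row$sample_id, dx)
        for (ci in seq_along(targets)) {
          ch <- names(targets)[ci]
          tgt <- targets[[ci]]
          cpr <- if (tgt == "CF") {
            row$cf_after_copies * row$template_volume / geometry$eluate_volume
          } else {
            row[[paste0("copies_", tgt)]] * row$plasma_volume /
              (geometry$eluate_volume / row$template_volume)
          }
          out[[length(out) + 1]] <- well_rows(plate_id, well_id,
                                              row$sample_id, "sample", ch,
                                              tgt, cpr, nd)
          truth[[length(truth) + 1]] <- tibble::tibble(
            sample_id = row$sample_id, target = tgt,
            true_copies_per_ml = if (tgt == "CF") NA_real_ else
              row[[paste0("copies_", tgt)]],
            true_copies_per_reaction = cpr, n_droplets = nd)
        }
      }
    }
    if (include_qc_wells) {
      plate_id <- sprintf("P%02d_Q", pi)
      n_ctrl <- draw_droplet_count(2, config)
      qc_targets <- c(ch1 = "CPP1", ch2 = "PBC")
      ctrl <- purrr::map_dfr(seq_along(qc_targets), function(ci) {
        ch <- names(qc_targets)[ci]
        dplyr::bind_rows(
          well_rows(plate_id, "POS", NA_character_, "positive_control", ch,
                    qc_targets[[ci]],
                    config$control_lambda * geometry$reaction_volume /
                      geometry$droplet_volume,
                    n_ctrl[1]),
          well_rows(plate_id, "NEG", NA_character_, "negative_control", ch,
                    qc_targets[[ci]], 0, n_ctrl[2]))
      })
      out[[length(out) + 1]] <- ctrl
      for (ri in seq_len(nrow(block))) {
        row <- block[ri, ]
        nd <- if (!is.na(row$droplets_override)) row$droplets_override else
          draw_droplet_count(1, config)
        eff <- pmin(pmax(rnorm(1, config$qc$purification_mean,
                               config$qc$purification_sd), 0), 1.2)
        cpp1 <- config$qc$spiked_cpp1 * eff
        pbc <- config$qc$pbc_background_fraction *
          exp(config$qc$cf_before_meanlog)
        well_id <- sprintf("%s_Q", row$sample_id)
        out[[length(out) + 1]] <- well_rows(plate_id, well_id, row$sample_id,
                                            "sample", "ch1", "CPP1",
                                            cpp1 * geometry$template_volume /
                                              geometry$eluate_volume, nd)
        out[[length(out) + 1]] <- well_rows(plate_id, well_id, row$sample_id,
                                            "sample", "ch2", "PBC",
                                            pbc * geometry$template_volume /
                                              geometry$eluate_volume, nd)
      }
    }
  }
  list(droplets = dplyr::bind_rows(out), truth = dplyr::bind_rows(truth))
}

#' Simulate a clinical cohort with serial ctDNA statuses and outcomes
#'
#' Generates patients with covariates, serial true ctDNA statuses at the
#' four protocol timepoints, per-sample true marker concentrations, injected
#' QC failures, and recurrence/death dates driven by the status-dependent
#' hazards.
#'
#' Serial statuses share a latent per-patient tumor-burden variable through a
#' Gaussian copula (correlation `status_correlation`), so each timepoint's
#' marginal positivity matches its configured probability while statuses are
#' positively dependent across timepoints — all four dynamics groups occur.
#' The RFS hazard is exponential at ln2 / median on the baseline and is
#' multiplied by the configured conditional hazard ratios for positivity
#' after one cycle and post-surgery. OS is recurrence followed by an
#' exponential post-recurrence survival, competing with an independent
#' other-cause death process; deaths after the data cutoff are censored.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A list of tibbles: `patients` (clinical table with covariates and
#'   dates), `samples` (per collected sample: timepoint, true status, true
#'   per-marker copies/mL, injected QC failure type, volumes), and `truth`
#'   (per patient: statuses and uncensored event times in months).
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  n <- config$n_patients
  oc <- config$outcome
  patient_id <- sprintf("PT%03d", seq_len(n))

  # serial statuses via Gaussian copula on a shared latent burden
  rho <- config$status_correlation
  z_latent <- rnorm(n)
  status <- sapply(TIMEPOINTS, function(tp) {
    z <- rho * z_latent + sqrt(1 - rho^2) * rnorm(n)
    z < qnorm(config$positivity[[tp]])
  })
  colnames(status) <- TIMEPOINTS

  # outcomes from conditional status-dependent hazards
  h0 <- log(2) / oc$median_rfs_neg
  hazard <- h0 * oc$hr_after_1_cycle^status[, "after_1_cycle"] *
    oc$hr_post_surgery^status[, "post_surgery"]
  t_rfs <- rexp(n, hazard)
  t_cancer_death <- t_rfs + rexp(n, log(2) / oc$post_recurrence_median)
  t_other_death <- rexp(n, log(2) / oc$other_death_median)

  inclusion_date <- oc$accrual_start +
    round(runif(n) * as.numeric(oc$accrual_end - oc$accrual_start))
  follow_up <- as.numeric(oc$data_cutoff - inclusion_date) / DAYS_PER_MONTH

  rec_observed <- t_rfs < pmin(follow_up, t_other_death)
  t_death <- pmin(t_cancer_death, t_other_death)
  death_observed <- t_death < follow_up
  death_cause <- ifelse(t_cancer_death <= t_other_death, "cancer", "other")

  to_date <- function(m) inclusion_date + pmax(1, round(m * DAYS_PER_MONTH))
  patients <- tibble::tibble(
    patient_id = patient_id,
    inclusion_date = inclusion_date,
    age_group = sample(c("<65", ">=65"), n, TRUE, prob = c(0.48, 0.52)),
    sex = sample(c("female", "male"), n, TRUE, prob = c(0.16, 0.84)),
    performance_score = sample(c("0", "1-2"), n, TRUE, prob = c(0.59, 0.41)),
    tumor_location = sample(c("lower_esophagus", "GEJ", "stomach"), n, TRUE,
                            prob = c(0.26, 0.63, 0.11)),
    clinical_T = sample(c("cT1/T2", "cT3/T4"), n, TRUE, prob = c(0.3, 0.7)),
    clinical_N = sample(c("cN0", "cN+"), n, TRUE, prob = c(0.66, 0.34)),
    HER2 = sample(c("normal", "positive"), n, TRUE, prob = c(0.64, 0.36)),
    pathological_T = sample(c("ypT1/T2", "ypT3/T4"), n, TRUE,
                            prob = c(0.5, 0.5)),
    pathological_N = sample(c("ypN0", "ypN+"), n, TRUE, prob = c(0.6, 0.4)),
    TRG = sample(c("TRG1-2", "TRG3-5"), n, TRUE, prob = c(0.4, 0.6)),
    recurrence_date = dplyr::if_else(rec_observed, to_date(t_rfs),
                                     as.Date(NA)),
    death_date = dplyr::if_else(death_observed, to_date(t_death),
                                as.Date(NA)),
    death_cause = dplyr::if_else(death_observed, death_cause, NA_character_),
    data_cutoff = oc$data_cutoff
  )

  truth <- tibble::as_tibble(status) |>
    dplyr::rename_with(~ paste0("status_", .x)) |>
    dplyr::mutate(patient_id = patient_id,
                  true_rfs_months = t_rfs, true_os_months = t_death,
                  .before = 1)

  # per-sample table: which samples were collected, true copies, QC injections
  samples <- tidyr::expand_grid(patient_id = patient_id,
                                timepoint = TIMEPOINTS) |>
    dplyr::mutate(
      collected = runif(dplyr::n()) <
        config$sampling_prob[.data$timepoint],
      true_status = as.vector(t(status))) |>
    dplyr::filter(.data$collected) |>
    dplyr::select(-"collected") |>
    dplyr::mutate(sample_id = paste0(.data$patient_id, "_",
                                     .data$timepoint),
                  .before = 1)

  ns <- nrow(samples)
  cp <- config$copies
  total <- ifelse(samples$true_status,
                  rlnorm(ns, log(cp$median), cp$sdlog), 0)
  clip4_present <- runif(ns) < cp$clip4_present_prob
  w <- matrix(stats::rgamma(ns * 3, shape = 2), ncol = 3)
  w[, 3] <- w[, 3] * clip4_present
  w <- w / pmax(rowSums(w), .Machine$double.eps)
  samples$copies_C9orf50 <- total * w[, 1]
  samples$copies_KCNQ5 <- total * w[, 2]
  samples$copies_CLIP4 <- total * w[, 3]

  fail <- runif(ns) < config$qc_failure_rate
  fail_type <- rep("none", ns)
  fail_type[fail] <- sample(c("low_droplets", "leucocyte_contamination",
                              "no_cf_signal"), sum(fail), TRUE)
  samples$qc_fail_type <- fail_type
  samples$template_volume <- 8
  samples$plasma_volume <- pmin(pmax(rnorm(ns, 8, 1), 5), 10)

  list(patients = patients, samples = samples, truth = truth)
}

#' Simulate the sample-level QC table for a cohort
#'
#' Draws spike-in recovery, leucocyte contamination, CF before/after and
#' minimum droplet counts for each sample, honouring the QC failures injected
#' by [simulate_cohort()] (`qc_fail_type`): low-droplet samples get well
#' minima below 10,000, contaminated samples get PBC copies above the
#' relative cutoff, and no-CF-signal samples get zero CF after conversion.
#'
#' @param samples The `samples` tibble from [simulate_cohort()] (needs
#'   `sample_id`; `qc_fail_type` optional).
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A tibble ready for [qc_gate()]: `sample_id`,
#'   `spiked_cpp1_copies`, `measured_cpp1_copies`, `pbc_copies`, `cf_before`,
#'   `cf_after`, `min_droplets`, plus the `qc_fail_type` truth column.
#' @export
simulate_qc_table <- function(samples, config = simulation_config(),
                              seed = 1) {
  set.seed(seed)
  s <- tibble::as_tibble(samples)
  ns <- nrow(s)
  if (!"qc_fail_type" %in% names(s)) s$qc_fail_type <- "none"
  qc <- config$qc
  eff <- pmin(pmax(rnorm(ns, qc$purification_mean, qc$purification_sd),
                   0.05), 1.2)
  recov <- pmin(pmax(rnorm(ns, qc$bisulfite_mean, qc$bisulfite_sd),
                     0.05), 0.95)
  cf_before <- rlnorm(ns, qc$cf_before_meanlog, qc$cf_before_sdlog)
  out <- tibble::tibble(
    sample_id = s$sample_id,
    spiked_cpp1_copies = qc$spiked_cpp1,
    measured_cpp1_copies = qc$spiked_cpp1 * eff,
    pbc_copies = qc$pbc_background_fraction * cf_before,
    cf_before = cf_before,
    cf_after = cf_before * recov,
    min_droplets = pmax(config$droplets$min,
                        round(rnorm(ns, config$droplets$mean,
                                    config$droplets$sd))),
    qc_fail_type = s$qc_fail_type
  )
  low <- out$qc_fail_type == "low_droplets"
  out$min_droplets[low] <- round(runif(sum(low), 6000, 9500))
  cont <- out$qc_fail_type == "leucocyte_contamination"
  out$pbc_copies[cont] <- qc$contamination_fraction * out$cf_before[cont]
  nocf <- out$qc_fail_type == "no_cf_signal"
  out$cf_after[nocf] <- 0
  out
}
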