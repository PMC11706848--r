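small_cfg <- function(...) simulation_config(n_patients = 30, ...)

test_that("plate simulation is deterministic under a fixed seed", {
  sm <- tibble::tibble(sample_id = c("S1", "S2"),
                       copies_C9orf50 = c(0, 40), copies_KCNQ5 = c(0, 40),
                       copies_CLIP4 = c(0, 40))
  p1 <- simulate_plate(sm, small_cfg(), seed = 71)
  p2 <- simulate_plate(sm, small_cfg(), seed = 71)
  expect_identical(p1$droplets, p2$droplets)
  expect_identical(p1$truth, p2$truth)
  p3 <- simulate_plate(sm, small_cfg(), seed = 72)
  expect_false(identical(p1$droplets$amplitude, p3$droplets$amplitude))
})

test_that("blank samples yield zero positive droplets without rain", {
  cfg <- small_cfg()
  cfg$amplitude$rain_fraction <- 0
  sm <- tibble::tibble(sample_id = "BLANK", copies_C9orf50 = 0,
                       copies_KCNQ5 = 0, copies_CLIP4 = 0)
  pl <- simulate_plate(sm, cfg, seed = 73, include_qc_wells = FALSE)
  m <- quantify_droplets(pl$droplets)
  blanks <- m[m$role == "sample" & m$target %in% c("C9orf50", "KCNQ5",
                                                   "CLIP4"), ]
  expect_true(all(blanks$k_positive == 0))
})

test_that("default sub-threshold rain does not create positive droplets", {
  sm <- tibble::tibble(sample_id = "BLANK", copies_C9orf50 = 0,
                       copies_KCNQ5 = 0, copies_CLIP4 = 0)
  pl <- simulate_plate(sm, small_cfg(), seed = 74, include_qc_wells = FALSE)
  m <- quantify_droplets(pl$droplets)
  blanks <- m[m$role == "sample" & m$target %in% c("C9orf50", "KCNQ5",
                                                   "CLIP4"), ]
  expect_true(all(blanks$k_positive == 0))
})

test_that("simulated plates recover known concentrations", {
  sm <- tibble::tibble(sample_id = sprintf("S%03d", 1:60),
                       copies_C9orf50 = 50, copies_KCNQ5 = 50,
                       copies_CLIP4 = 50)
  pl <- simulate_plate(sm, simulation_config(), seed = 75,
                       include_qc_wells = FALSE)
  m <- quantify_droplets(pl$droplets)
  est <- m$copies_per_ml_plasma[m$role == "sample" &
                                  m$target %in% c("C9orf50", "KCNQ5",
                                                  "CLIP4")]
  expect_lt(abs(median(est) - 50) / 50, 0.10)
})

test_that("cohort simulation is deterministic and carries ground truth", {
  c1 <- simulate_cohort(small_cfg(), seed = 76)
  c2 <- simulate_cohort(small_cfg(), seed = 76)
  expect_identical(c1, c2)
  expect_true(all(c("status_baseline", "status_post_surgery",
                    "true_rfs_months", "true_os_months") %in%
                    names(c1$truth)))
  expect_true(all(c1$truth$true_rfs_months > 0 &
                    c1$truth$true_os_months > 0))
  # every collected sample has truth attached
  expect_true(all(!is.na(c1$samples$true_status)))
  expect_true(all(c1$samples$copies_C9orf50[!c1$samples$true_status] == 0))
})

test_that("per-timepoint positivity matches the configured marginals", {
  cfg <- simulation_config(
    n_patients = 500,
    sampling_prob = c(baseline = 1, after_1_cycle = 1, after_preop_ct = 1,
                      post_surgery = 1))
  co <- simulate_cohort(cfg, seed = 77)
  rates <- co$samples |>
    dplyr::group_by(timepoint) |>
    dplyr::summarise(rate = mean(true_status))
  expected <- cfg$positivity[rates$timepoint]
  # binomial 95% band at n = 500
  band <- 1.96 * sqrt(expected * (1 - expected) / 500)
  expect_true(all(abs(rates$rate - expected) < band + 0.01))
})

test_that("status transitions produce all four dynamics groups", {
  co <- simulate_cohort(simulation_config(n_patients = 500), seed = 78)
  calls <- co$samples |>
    dplyr::transmute(patient_id, timepoint,
                     call = ifelse(true_status, "positive", "negative"))
  dyn <- cohort_dynamics(calls, from = "after_1_cycle", to = "post_surgery")
  expect_true(all(table(dyn$dynamics) > 0))
})

test_that("summary distributions are stable across seeds", {
  totals <- function(seed) {
    co <- simulate_cohort(small_cfg(), seed = seed)
    x <- co$samples$copies_C9orf50 + co$samples$copies_KCNQ5 +
      co$samples$copies_CLIP4
    x[x > 0]
  }
  ks <- suppressWarnings(stats::ks.test(totals(79), totals(80)))
  expect_gt(ks$p.value, 0.01)
})

test_that("qc table honours injected failure types", {
  co <- simulate_cohort(simulation_config(n_patients = 150), seed = 81)
  qc <- simulate_qc_table(co$samples, seed = 82)
  expect_true(all(qc$min_droplets[qc$qc_fail_type == "low_droplets"] < 10000))
  expect_true(all(qc$cf_after[qc$qc_fail_type == "no_cf_signal"] == 0))
  cont <- qc$qc_fail_type == "leucocyte_contamination"
  expect_true(all(qc$pbc_copies[cont] > 0.1 * qc$cf_before[cont]))
})
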