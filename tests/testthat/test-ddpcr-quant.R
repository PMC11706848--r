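test_that("control-derived threshold follows the interpolation rule", {
  thr <- threshold_from_controls(fixture_neg_control(),
                                 fixture_pos_control())
  expect_equal(thr$neg_center, 1000)
  expect_equal(thr$pos_center, 9000)
  # 1000 + 0.4 * 8000; floor term 1000 + 7*40 = 1280 does not bind
  expect_equal(thr$threshold, 4200)
})

test_that("threshold guard rejects positive controls without an upper cluster", {
  expect_error(
    threshold_from_controls(fixture_neg_control(),
                            fixture_pos_control(upper = 1100)),
    "control failure")
  expect_error(threshold_from_controls(numeric(0), fixture_pos_control()),
               "at least one droplet")
})

test_that("zero-spread negative control still yields the interpolated threshold", {
  thr <- threshold_from_controls(rep(1000, 30), fixture_pos_control())
  expect_equal(thr$neg_mad, 0)
  expect_equal(thr$threshold, 4200)
})

test_that("droplet classification is a strict count above the threshold", {
  d <- fixture_droplet_table(sample_amps_ch1 = c(1000, 1050, 9000),
                             sample_amps_ch2 = c(1000, 4200.264, 900))
  thr <- plate_thresholds(d)
  counts <- classify_droplets(d, thr)
  s1 <- counts[counts$role == "sample" & counts$channel == "ch1", ]
  expect_equal(s1$k_positive, 1L)
  expect_equal(s1$n_total, 3L)
  # amplitude exactly at the threshold counts negative
  thr2 <- thr
  thr2$threshold <- c(4200.264, 4200.264)
  s2 <- classify_droplets(d, thr2)
  s2 <- s2[s2$role == "sample" & s2$channel == "ch2", ]
  expect_equal(s2$k_positive, 0L)
})

test_that("classification requires a threshold for every plate/channel", {
  d <- fixture_droplet_table()
  thr <- plate_thresholds(d)
  d2 <- d
  d2$plate_id <- "P2"
  expect_error(classify_droplets(d2, thr), "no threshold")
})

test_that("Poisson correction matches the closed form and handles edge cases", {
  m0 <- poisson_concentration(0, 20000)
  expect_equal(m0$lambda, 0)
  expect_equal(m0$copies_per_reaction, 0)

  m <- poisson_concentration(100, 20000)
  expect_equal(m$lambda, -log(1 - 100 / 20000))
  expect_equal(m$lambda, 0.0050125, tolerance = 1e-4)
  expect_equal(m$conc_per_ul_reaction, 5.897, tolerance = 1e-3)
  expect_equal(m$copies_per_reaction, 129.7, tolerance = 1e-3)

  sat <- poisson_concentration(15000, 15000)
  expect_true(sat$saturated)
  expect_true(is.na(sat$copies_per_reaction))

  expect_error(poisson_concentration(1, 0), "n_total")
  expect_error(poisson_concentration(5, 3), "k_positive")
})

test_that("Poisson estimator agrees with a Monte-Carlo partitioning oracle", {
  set.seed(401)
  # light version of the full-oracle check in the acceptance suite
  oracle <- mc_partition_estimate(M = 100, n = 20000, reps = 2000)
  expect_lt(abs(oracle - 100) / 100, 0.02)
  # the estimator itself inverts a typical draw consistently
  est <- -20000 * log(1 - 99 / 20000)
  expect_equal(est, poisson_concentration(99, 20000)$lambda * 20000)
})

test_that("copies per mL plasma follows the volume chain", {
  expect_equal(copies_per_ml_plasma(129.7), 129.7 * 2.75 / 8)
  expect_equal(copies_per_ml_plasma(129.7), 44.6, tolerance = 1e-3)
  expect_equal(copies_per_ml_plasma(0), 0)
  # template filling the whole eluate: scale factor collapses to 1/plasma
  expect_equal(copies_per_ml_plasma(100, template_volume = 22,
                                    eluate_volume = 22, plasma_volume = 8),
               100 / 8)
  expect_error(copies_per_ml_plasma(100, saturated = TRUE), "saturated")
})

test_that("lambda and concentrations are strictly increasing in k", {
  k <- 0:500
  m <- poisson_concentration(k, 20000)
  expect_true(all(diff(m$lambda) > 0))
  expect_true(all(diff(m$copies_per_reaction) > 0))
})

test_that("thresholding is scale-equivariant and classification invariant", {
  d <- fixture_droplet_table()
  for (fac in c(0.5, 3, 17)) {
    d2 <- d
    d2$amplitude <- d2$amplitude * fac
    thr1 <- plate_thresholds(d)
    thr2 <- plate_thresholds(d2)
    expect_equal(thr2$threshold, thr1$threshold * fac)
    c1 <- classify_droplets(d, thr1)
    c2 <- classify_droplets(d2, thr2)
    expect_equal(c1$k_positive, c2$k_positive)
    expect_equal(c1$n_total, c2$n_total)
  }
})

test_that("simulated wells recover their true load within Poisson error", {
  # wells simulated at a known copies/mL should fall inside the binomial
  # band implied by their true single-droplet rate ~95% of the time
  set.seed(402)
  n_wells <- 400
  geometry <- reaction_geometry()
  true_cpml <- 50
  cpr <- true_cpml * geometry$plasma_volume /
    (geometry$eluate_volume / geometry$template_volume)
  lam <- cpr * geometry$droplet_volume / geometry$reaction_volume
  n <- 20000
  k <- rbinom(n_wells, n, 1 - exp(-lam))
  est <- poisson_concentration(k, n)$copies_per_reaction
  band <- qbinom(c(0.025, 0.975), n, 1 - exp(-lam))
  inside <- k >= band[1] & k <= band[2]
  expect_gte(mean(inside), 0.93)
  expect_lt(abs(median(est) - cpr) / cpr, 0.05)
})

test_that("droplet CSV round-trips", {
  d <- fixture_droplet_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_droplet_csv(d, path)
  d2 <- read_droplet_csv(path)
  expect_equal(as.data.frame(d2), as.data.frame(d))
})
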