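month_date <- function(start, months) {
  as.Date(start) + round(months * 30.4375)
}

test_that("endpoints follow the RFS/OS definitions", {
  incl <- as.Date("2020-06-01")
  cutoff <- as.Date("2023-07-01")
  p <- tibble::tibble(
    patient_id = c("rec_then_death", "no_events", "other_cause_death"),
    inclusion_date = incl,
    recurrence_date = c(month_date(incl, 10), NA, NA),
    death_date = c(month_date(incl, 14), NA, month_date(incl, 12)),
    death_cause = c("cancer", NA, "other"),
    data_cutoff = cutoff)
  ep <- build_endpoints(p)

  rfs <- ep[ep$endpoint == "RFS", ]
  os <- ep[ep$endpoint == "OS", ]
  expect_equal(rfs$time_months[1], 10, tolerance = 0.01)
  expect_true(rfs$event[1])
  expect_equal(os$time_months[1], 14, tolerance = 0.01)
  expect_true(os$event[1])

  fu <- as.numeric(cutoff - incl) / 30.4375
  expect_equal(rfs$time_months[2], fu)
  expect_false(rfs$event[2])
  expect_false(os$event[2])

  # death from another cause without recurrence: RFS censored, OS event
  expect_equal(rfs$time_months[3], 12, tolerance = 0.01)
  expect_false(rfs$event[3])
  expect_true(os$event[3])

  bad <- p[1, ]
  bad$death_date <- cutoff + 30
  expect_error(build_endpoints(bad), "cutoff")
})

test_that("Kaplan-Meier matches the hand-computed product limit", {
  ep <- tibble::tibble(time_months = c(1, 2, 3, 4),
                       event = c(FALSE, TRUE, TRUE, FALSE))
  km <- km_estimate(ep, landmark_months = 3.5)
  steps <- tidy(km)
  expect_equal(steps$survival[steps$time_months == 2], 2 / 3)
  expect_equal(steps$survival[steps$time_months == 3], 1 / 3)
  expect_equal(landmark_survival(km)$survival, 1 / 3)

  all_cens <- tibble::tibble(time_months = 1:5, event = FALSE)
  expect_true(all(tidy(km_estimate(all_cens))$survival == 1))

  single <- tibble::tibble(time_months = 7, event = TRUE)
  expect_equal(min(tidy(km_estimate(single))$survival), 0)
})

test_that("Kaplan-Meier agrees with brute force on random small instances", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    ep <- tibble::tibble(time_months = round(rexp(n, 0.1), 1) + 0.1,
                         event = rbinom(n, 1, 0.7) == 1)
    if (!any(ep$event)) ep$event[1] <- TRUE
    km <- tidy(km_estimate(ep))
    oracle <- hand_km(ep$time_months, as.numeric(ep$event))
    got <- km$survival[km$n_event > 0]
    expect_equal(got[order(km$time_months[km$n_event > 0])], oracle$surv,
                 tolerance = 1e-10)
  }
})

test_that("landmark survival is invariant to subject order", {
  set.seed(52)
  ep <- tibble::tibble(time_months = rexp(40, 0.05),
                       event = rbinom(40, 1, 0.6) == 1,
                       grp = rep(c("a", "b"), 20))
  l1 <- landmark_survival(km_estimate(ep, group = "grp"))
  l2 <- landmark_survival(km_estimate(ep[sample.int(40), ], group = "grp"))
  expect_equal(l1, l2)
})

test_that("log-rank test: null identity, symmetry, and strong separation", {
  ep <- tibble::tibble(time_months = rep(c(2, 4, 6, 8), 2),
                       event = rep(c(TRUE, TRUE, FALSE, TRUE), 2),
                       grp = rep(c("a", "b"), each = 4))
  res <- logrank_test(ep, "grp")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  set.seed(53)
  ep2 <- tibble::tibble(time_months = c(rexp(20, 0.5), rexp(20, 0.05)),
                        event = TRUE, grp = rep(c("a", "b"), each = 20))
  r1 <- logrank_test(ep2, "grp")
  ep3 <- ep2
  ep3$grp <- ifelse(ep2$grp == "a", "b", "a")
  r2 <- logrank_test(ep3, "grp")
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)

  # complete separation at n=10: strongly significant
  sep <- tibble::tibble(time_months = c(1:5, 11:15), event = TRUE,
                        grp = rep(c("a", "b"), each = 5))
  expect_lt(logrank_test(sep, "grp")$p_value, 0.01)

  one <- ep[ep$grp == "a", ]
  expect_error(logrank_test(one, "grp"), "two non-empty groups")
})

test_that("log-rank p agrees with the exhaustive permutation oracle", {
  fixtures <- list(
    list(time = c(1, 2, 3, 4, 5, 11, 12, 13, 14, 15), event = rep(1, 10),
         g = rep(c("a", "b"), each = 5)),
    list(time = c(1, 2, 3, 4, 9, 12, 15, 18, 21, 24),
         event = c(1, 1, 1, 1, 1, 1, 1, 0, 1, 0),
         g = rep(c("a", "b"), c(4, 6))),
    list(time = c(2, 4, 5, 7, 9, 8, 13, 17, 21, 26),
         event = c(1, 1, 1, 1, 1, 1, 1, 0, 1, 0),
         g = rep(c("a", "b"), each = 5)))
  for (f in fixtures) {
    ep <- tibble::tibble(time_months = f$time, event = f$event == 1,
                         grp = f$g)
    p_pkg <- logrank_test(ep, "grp")$p_value
    p_perm <- perm_logrank_p(f$time, f$event, f$g)
    expect_lt(abs(p_pkg - p_perm), 0.02)
  }
})

test_that("Cox univariable: symmetry, degenerate inputs, and flags", {
  set.seed(54)
  ep <- tibble::tibble(
    time_months = c(rexp(30, 0.2), rexp(30, 0.05)),
    event = TRUE,
    status = factor(rep(c("neg", "pos"), each = 30),
                    levels = c("neg", "pos")))
  est <- cox_univariable(ep, "status")
  flipped <- ep
  flipped$status <- factor(ep$status, levels = c("pos", "neg"))
  est2 <- cox_univariable(flipped, "status")
  expect_equal(est$hr, 1 / est2$hr, tolerance = 1e-8)
  expect_equal(est$p_value, est2$p_value, tolerance = 1e-8)

  const <- ep
  const$status <- "neg"
  expect_error(cox_univariable(const, "status"), "no contrast")

  # monotone likelihood (no events in one level) is flagged, not a crash
  mono <- ep
  mono$event[mono$status == "pos"] <- FALSE
  est3 <- cox_univariable(mono, "status")
  expect_true(est3$flagged)
})

test_that("Cox recovers a known hazard ratio in simulation", {
  set.seed(55)
  reps <- 200
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    grp <- rbinom(500, 1, 0.5)
    ep <- tibble::tibble(
      time_months = rexp(500, 0.05 * ifelse(grp == 1, 2.5, 1)),
      event = TRUE,
      status = factor(ifelse(grp == 1, "pos", "neg"),
                      levels = c("neg", "pos")))
    est <- cox_univariable(ep, "status")
    covered[r] <- est$ci_low <= 2.5 && 2.5 <= est$ci_high
  }
  expect_gte(mean(covered), 0.93)
})

test_that("Cox bias shrinks at large n", {
  set.seed(56)
  log_hrs <- replicate(50, {
    grp <- rbinom(2000, 1, 0.5)
    ep <- tibble::tibble(
      time_months = rexp(2000, 0.05 * ifelse(grp == 1, 2, 1)),
      event = TRUE,
      status = factor(ifelse(grp == 1, "pos", "neg"),
                      levels = c("neg", "pos")))
    log(cox_univariable(ep, "status")$hr)
  })
  expect_lt(abs(exp(mean(log_hrs)) - 2) / 2, 0.05)
})

test_that("multivariable model enters exactly the screened covariates", {
  set.seed(57)
  n <- 300
  x_strong <- rbinom(n, 1, 0.5)
  x_noise <- rbinom(n, 1, 0.5)
  ep <- tibble::tibble(
    time_months = rexp(n, 0.05 * ifelse(x_strong == 1, 3, 1)),
    event = TRUE,
    strong = factor(ifelse(x_strong == 1, "yes", "no")),
    noise = factor(ifelse(x_noise == 1, "yes", "no")))
  screen_strong <- cox_univariable(ep, "strong")$p_value
  screen_noise <- cox_univariable(ep, "noise")$p_value
  expect_lt(screen_strong, 0.05)
  expect_gt(screen_noise, 0.05)

  mv <- cox_multivariable(ep, c("strong", "noise"))
  expect_equal(attr(mv, "entered"), "strong")
  # single qualifying covariate: multivariable reduces to univariable
  uv <- cox_univariable(ep, "strong")
  expect_equal(mv$hr, uv$hr, tolerance = 1e-10)

  expect_error(cox_multivariable(ep, "noise"), "no candidate")
})

test_that("ROC analysis: perfect separation, negation symmetry, MW oracle", {
  r <- roc_analysis(c(0.9, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)

  set.seed(58)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.4) == 1
  a1 <- roc_analysis(scores, labels)$auc
  a2 <- roc_analysis(-scores, labels)$auc
  expect_equal(a1, 1 - a2, tolerance = 1e-10)
  # dual route: Mann-Whitney with ties counted half
  tied <- round(scores, 1)
  expect_equal(roc_analysis(tied, labels)$auc,
               mann_whitney_auc(tied, labels), tolerance = 1e-10)

  expect_error(roc_analysis(scores, rep(TRUE, 60)), "both outcome classes")
})

test_that("ROC AUC is near 1/2 under the null", {
  set.seed(59)
  auc <- roc_analysis(rnorm(1000), rbinom(1000, 1, 0.5) == 1)$auc
  expect_lt(abs(auc - 0.5), 0.04)
})

test_that("chi-square association test matches closed forms", {
  r <- covariate_association(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r2 <- covariate_association(matrix(c(20, 0, 0, 20), 2))
  expect_equal(r2$statistic, 40) # Pearson without continuity correction
  expect_lt(r2$p_value, 0.001)

  m <- matrix(c(12, 5, 7, 20), 2)
  expect_equal(covariate_association(m)$statistic,
               covariate_association(t(m))$statistic)

  expect_error(covariate_association(matrix(c(5, 5, 0, 0), 2)),
               "zero-margin")
})
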