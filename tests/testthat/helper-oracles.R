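# Independent oracles used across test files. Each is deliberately naive and
# shares no code with the implementation it checks.

# Brute-force product-limit estimator: survival after each distinct event
# time, computed directly from the definition.
hand_km <- function(time, event) {
  ev_times <- sort(unique(time[event == 1]))
  surv <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ev_times, surv = surv)
}

# Exhaustive permutation distribution of the two-group log-rank statistic:
# every reassignment of the group labels (respecting group sizes), mid-p for
# the discrete null.
perm_logrank_p <- function(time, event, g) {
  g <- as.character(g)
  labels <- sort(unique(g))
  stopifnot(length(labels) == 2)
  obs <- survival::survdiff(
    survival::Surv(time, event) ~ g)$chisq
  n <- length(g)
  combs <- utils::combn(n, sum(g == labels[1]))
  stats <- apply(combs, 2, function(ix) {
    gg <- rep(labels[2], n)
    gg[ix] <- labels[1]
    survival::survdiff(survival::Surv(time, event) ~ gg)$chisq
  })
  mean(stats > obs + 1e-9) + 0.5 * mean(abs(stats - obs) <= 1e-9)
}

# Monte-Carlo partitioning oracle: distribute M molecules uniformly at random
# into n droplets, count occupied droplets, invert through the Poisson
# correction; returns the mean estimated total copies over `reps` repetitions.
mc_partition_estimate <- function(M, n, reps) {
  mean(replicate(reps, {
    k <- length(unique(sample.int(n, M, replace = TRUE)))
    -n * log(1 - k / n)
  }))
}

# Mann-Whitney AUC with ties counted half, straight from the definition.
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Fixed amplitude fixtures: negative control with median 1000 and raw MAD 40;
# positive control with clusters at exactly 1000 and 9000.
fixture_neg_control <- function() c(960, 1000, 1000, 1000, 1040, 1040, 960)
fixture_pos_control <- function(upper = 9000) {
  c(rep(1000, 50), rep(upper, 50))
}

# A minimal two-plate droplet table: controls plus one sample well per
# channel, amplitudes fixed, used for threshold/classification tests.
fixture_droplet_table <- function(sample_amps_ch1 = c(1000, 1050, 9000),
                                  sample_amps_ch2 = c(1000, 1000, 1000)) {
  mk <- function(well, role, ch, target, amps, sid = NA_character_) {
    tibble::tibble(plate_id = "P1", well_id = well, sample_id = sid,
                   channel = ch, target = target, role = role,
                   amplitude = amps)
  }
  dplyr::bind_rows(
    mk("NEG", "negative_control", "ch1", "C9orf50", fixture_neg_control()),
    mk("POS", "positive_control", "ch1", "C9orf50", fixture_pos_control()),
    mk("NEG", "negative_control", "ch2", "KCNQ5", fixture_neg_control()),
    mk("POS", "positive_control", "ch2", "KCNQ5", fixture_pos_control()),
    mk("S1_A", "sample", "ch1", "C9orf50", sample_amps_ch1, "S1"),
    mk("S1_A", "sample", "ch2", "KCNQ5", sample_amps_ch2, "S1")
  )
}

# Hand-made measurement table for call-level tests: one row per
# sample x marker, mirroring quantify_droplets() output columns.
fixture_measurements <- function(k_by_sample, copies = 10) {
  purrr::imap_dfr(k_by_sample, function(k, sid) {
    tibble::tibble(
      sample_id = sid, target = names(k),
      plate_id = "P1", well_id = paste0(sid, "_A"),
      channel = "ch1", role = "sample",
      k_positive = as.integer(k), n_total = 20000L, threshold = 4200,
      lambda = k / 20000,
      copies_per_reaction = copies * k,
      copies_per_ml_plasma = copies * k,
      saturated = FALSE)
  })
}
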