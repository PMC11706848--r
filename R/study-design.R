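#' Design assumptions for the log-rank sample-size calculation
#'
#' The design targets detection of a recurrence-free-survival difference
#' between postoperative ctDNA-positive and ctDNA-negative patients with a
#' two-group log-rank test. Defaults encode the study design: two-sided
#' alpha 0.05, power 0.80, hazard ratio 5.4 for recurrence in ctDNA-positive
#' patients, 15% postoperative ctDNA positivity, expected median RFS of 30
#' months in the ctDNA-negative group, and an 18-month minimum follow-up
#' under which the event probabilities are evaluated (exponential survival in
#' both arms).
#'
#' @param alpha Two-sided type-I error. Default 0.05.
#' @param power Target power. Default 0.80.
#' @param hr Hazard ratio between ctDNA-positive and -negative arms.
#'   Default 5.4.
#' @param prevalence Fraction ctDNA-positive. Default 0.15.
#' @param median_rfs_neg Median RFS (months) in the ctDNA-negative arm.
#'   Default 30.
#' @param min_follow_up Minimum follow-up (months) at which event
#'   probabilities are evaluated. Default 18.
#' @return A list of class `design_assumptions`.
#' @export
design_assumptions <- function(alpha = 0.05, power = 0.80, hr = 5.4,
                               prevalence = 0.15, median_rfs_neg = 30,
                               min_follow_up = 18) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) abort("power must be in (0, 1)")
  if (hr <= 0) abort("hr must be > 0")
  if (prevalence <= 0 || prevalence >= 1) abort("prevalence must be in (0, 1)")
  if (median_rfs_neg <= 0 || min_follow_up <= 0) {
    abort("median_rfs_neg and min_follow_up must be > 0")
  }
  structure(list(alpha = alpha, power = power, hr = hr,
                 prevalence = prevalence, median_rfs_neg = median_rfs_neg,
                 min_follow_up = min_follow_up),
            class = "design_assumptions")
}

#' Required events by Schoenfeld's formula
#'
#' Number of events needed for a two-sided log-rank test:
#' \deqn{d = \frac{(z_{1-\alpha/2} + z_{power})^2}{p(1-p)\,(\ln HR)^2}}
#' with allocation fraction \eqn{p} (here the ctDNA-positivity prevalence).
#' Symmetric in HR and 1/HR.
#'
#' @param assumptions A [design_assumptions()].
#' @return A tibble: `events_exact`, `events` (ceiling).
#' @examples
#' schoenfeld_events(design_assumptions())
#' @export
schoenfeld_events <- function(assumptions = design_assumptions()) {
  a <- assumptions
  if (a$hr == 1) abort("hr = 1 implies no detectable difference (infinite events)")
  z <- qnorm(1 - a$alpha / 2) + qnorm(a$power)
  d <- z^2 / (a$prevalence * (1 - a$prevalence) * log(a$hr)^2)
  tibble::tibble(events_exact = d, events = as.integer(ceiling(d)))
}

#' Required number of patients
#'
#' Converts the Schoenfeld event requirement into patients by dividing by the
#' overall event probability at the minimum follow-up, assuming exponential
#' RFS: hazard ln2 / median in the ctDNA-negative arm, multiplied by the HR
#' in the positive arm, mixed by prevalence.
#'
#' @param assumptions A [design_assumptions()].
#' @return A tibble: `events_exact`, `event_prob_neg`, `event_prob_pos`,
#'   `event_prob`, `n_exact`, `n`.
#' @examples
#' required_n(design_assumptions())$n # 52 under the default design
#' @export
required_n <- function(assumptions = design_assumptions()) {
  a <- assumptions
  d <- schoenfeld_events(a)$events_exact
  h_neg <- log(2) / a$median_rfs_neg
  p_neg <- 1 - exp(-h_neg * a$min_follow_up)
  p_pos <- 1 - exp(-h_neg * a$hr * a$min_follow_up)
  p_event <- (1 - a$prevalence) * p_neg + a$prevalence * p_pos
  if (p_event <= 0) abort("overall event probability is zero")
  tibble::tibble(events_exact = d, event_prob_neg = p_neg,
                 event_prob_pos = p_pos, event_prob = p_event,
                 n_exact = d / p_event, n = as.integer(ceiling(d / p_event)))
}

#' Monte-Carlo power of the design
#'
#' Simulates the design and reports the empirical rejection fraction of the
#' two-sided log-rank test. Each replicate draws group membership
#' Bernoulli(prevalence), exponential event times (negative-arm hazard
#' ln2 / median RFS, positive-arm hazard multiplied by the HR), applies
#' administrative censoring at the minimum follow-up, and tests at level
#' alpha. Replicates in which one arm happens to be empty cannot reject and
#' count as non-rejections.
#'
#' @param assumptions A [design_assumptions()].
#' @param n Patients per replicate; defaults to `required_n(assumptions)$n`.
#' @param reps Number of replicates (>= 1000 recommended for reporting).
#'   Default 5000.
#' @param seed Integer seed; the result is reproducible given the seed.
#' @return A tibble: `n`, `reps`, `rejections`, `power`.
#' @examples
#' simulate_power(design_assumptions(), reps = 200, seed = 1)
#' @export
simulate_power <- function(assumptions = design_assumptions(), n = NULL,
                           reps = 5000, seed = 1) {
  a <- assumptions
  n <- n %||% required_n(a)$n
  if (reps < 1) abort("reps must be >= 1")
  set.seed(seed)
  h_neg <- log(2) / a$median_rfs_neg
  rejections <- 0L
  for (r in seq_len(reps)) {
    pos <- rbinom(n, 1, a$prevalence)
    if (all(pos == 0) || all(pos == 1)) next
    t_event <- rexp(n, rate = h_neg * ifelse(pos == 1, a$hr, 1))
    time <- pmin(t_event, a$min_follow_up)
    event <- as.numeric(t_event <= a$min_follow_up)
    if (sum(event) == 0) next
    sd <- survival::survdiff(survival::Surv(time, event) ~ pos)
    p <- pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    if (p < a$alpha) rejections <- rejections + 1L
  }
  tibble::tibble(n = n, reps = as.integer(reps), rejections = rejections,
                 power = rejections / reps)
}
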