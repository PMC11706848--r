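#' Build recurrence-free and overall survival endpoints
#'
#' Constructs the two study endpoints from per-patient dates, both measured
#' from the date of inclusion and expressed in months (days / 30.4375):
#'
#' * RFS — event at the earliest of radiological/clinical recurrence or death
#'   from the cancer under study; a death from another cause without prior
#'   recurrence censors RFS at the death date (only cancer deaths count as
#'   RFS events).
#' * OS — event at death of any cause.
#'
#' Patients without an event are censored administratively at the data
#' cutoff.
#'
#' @param patients A data frame with one row per patient: `patient_id`,
#'   `inclusion_date`, optional `recurrence_date`, optional `death_date`,
#'   `death_cause` (`"cancer"`, `"other"` or `"unknown"`; `"unknown"` is
#'   treated as cancer for RFS, the conservative reading), and `data_cutoff`
#'   (a single date, or per-row). Dates may be `Date` or ISO-8601 strings.
#' @return A tibble with one row per patient x endpoint: `patient_id`,
#'   `endpoint` (`"RFS"`/`"OS"`), `time_months`, `event` (logical).
#' @examples
#' p <- tibble::tibble(patient_id = "P1",
#'   inclusion_date = as.Date("2020-03-01"),
#'   recurrence_date = as.Date("2021-01-01"),
#'   death_date = as.Date("2021-05-01"), death_cause = "cancer",
#'   data_cutoff = as.Date("2023-07-01"))
#' build_endpoints(p)
#' @export
build_endpoints <- function(patients) {
  needed <- c("patient_id", "inclusion_date", "data_cutoff")
  if (!all(needed %in% names(patients))) {
    abort("`patients` needs columns patient_id, inclusion_date, data_cutoff")
  }
  p <- tibble::as_tibble(patients)
  for (col in c("inclusion_date", "recurrence_date", "death_date",
                "data_cutoff")) {
    if (!col %in% names(p)) p[[col]] <- as.Date(NA)
    p[[col]] <- as.Date(p[[col]])
  }
  if (!"death_cause" %in% names(p)) p[[

"death_cause"]] <- NA_character_

  event_dates <- c(p$recurrence_date, p$death_date)
  if (any(event_dates > rep(p$data_cutoff, 2), na.rm = TRUE)) {
    abort("event date after data cutoff: check recurrence/death dates")
  }
  if (any(c(p$recurrence_date, p$death_date) <
          rep(p$inclusion_date, 2), na.rm = TRUE)) {
    abort("event date precedes inclusion date")
  }

  months <- function(from, to) as.numeric(to - from) / DAYS_PER_MONTH
  cancer_death <- !is.na(p$death_date) &
    (is.na(p$death_cause) | p$death_cause %in% c("cancer", "unknown"))

  purrr::pmap_dfr(
    list(p$patient_id, p$inclusion_date, p$recurrence_date, p$death_date,
         cancer_death, p$data_cutoff),
    function(id, incl, rec, death, cdeath, cutoff) {
      # RFS: recurrence or cancer death is an event; other-cause death
      # censors at death; otherwise censor at cutoff.
      rfs_candidates <- c(rec, if (cdeath) death)
      if (length(rfs_candidates) > 0 && any(!is.na(rfs_candidates))) {
        rfs_date <- min(rfs_candidates, na.rm = TRUE)
        rfs <- c(time = months(incl, rfs_date), event = 1)
      } else if (!is.na(death)) {
        rfs <- c(time = months(incl, death), event = 0)
      } else {
        rfs <- c(time = months(incl, cutoff), event = 0)
      }
      os <- if (!is.na(death)) {
        c(time = months(incl, death), event = 1)
      } else {
        c(time = months(incl, cutoff), event = 0)
      }
      tibble::tibble(patient_id = id, endpoint = c("RFS", "OS"),
                     time_months = unname(c(rfs["time"], os["time"])),
                     event = unname(c(rfs["event"], os["event"])) == 1)
    }
  )
}

check_endpoints <- function(endpoints) {
  if (!all(c("time_months", "event") %in% names(endpoints))) {
    abort("endpoints need columns time_months and event")
  }
  if (nrow(endpoints) == 0) abort("no subjects in endpoint table")
  if (any(endpoints$time_months <= 0)) abort("survival times must be > 0")
  invisible(endpoints)
}

#' Kaplan-Meier estimate with landmark survival
#'
#' Product-limit estimator (optionally per group) with Greenwood standard
#' errors and log-transformed 95% confidence intervals, plus the survival
#' probability read off at a fixed landmark time (24 months by default,
#' matching conventional landmark reporting for perioperative cohorts).
#'
#' @param endpoints Tibble with `time_months`, `event` (logical/0-1) and
#'   optionally the grouping column named by `group`.
#' @param group Optional name of a grouping column (e.g. ctDNA status).
#' @param landmark_months Landmark time(s) in months. Default 24.
#' @return An object of class `km_fit`: the underlying
#'   [survival::survfit()] fit plus a tidy step table and landmark tibble.
#'   Methods: [tidy()], [glance()], [autoplot()].
#' @export
km_estimate <- function(endpoints, group = NULL, landmark_months = 24) {
  check_endpoints(endpoints)
  endpoints <- tibble::as_tibble(endpoints)
  if (is.null(group)) {
    fit <- survival::survfit(
      survival::Surv(time_months, event) ~ 1, data = endpoints,
      conf.type = "log")
  } else {
    if (!group %in% names(endpoints)) {
      abort(sprintf("grouping column '%s' not found", group))
    }
    endpoints$.group <- factor(endpoints[[group]])
    fit <- survival::survfit(
      survival::Surv(time_months, event) ~ .group, data = endpoints,
      conf.type = "log")
  }
  steps <- summary(fit, censored = TRUE)
  strata <- if (is.null(steps$strata)) NULL else
    sub("^\\.group=", "", as.character(steps$strata))
  step_tbl <- tibble::tibble(
    group = strata %||% rep(NA_character_, length(steps$time)),
    time_months = steps$time, n_risk = steps$n.risk,
    n_event = steps$n.event, survival = steps$surv,
    std_err = steps$std.err, ci_low = steps$lower, ci_high = steps$upper)

  lmk <- summary(fit, times = landmark_months, extend = TRUE)
  lmk_strata <- if (is.null(lmk$strata)) NULL else
    sub("^\\.group=", "", as.character(lmk$strata))
  landmark_tbl <- tibble::tibble(
    group = lmk_strata %||% rep(NA_character_, length(lmk$time)),
    landmark_months = lmk$time, survival = lmk$surv,
    ci_low = lmk$lower, ci_high = lmk$upper)

  structure(list(fit = fit, steps = step_tbl, landmark = landmark_tbl,
                 group = group, n = nrow(endpoints),
                 n_event = sum(endpoints$event)),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> %d subjects, %d events%s\n", x$n, x$n_event,
              if (is.null(x$group)) "" else paste0(", grouped by ", x$group)))
  print(x$landmark)
  invisible(x)
}

#' @rdname km_estimate
#' @param x A `km_fit`.
#' @param ... Unused.
#' @export
tidy.km_fit <- function(x, ...) x$steps

#' @rdname km_estimate
#' @export
glance.km_fit <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n = x$n, n_event = x$n_event)[
    rep(1, nrow(x$landmark)), ], x$landmark)
}

#' Landmark survival from a Kaplan-Meier fit
#'
#' @param x A `km_fit`.
#' @return The landmark tibble (`group`, `landmark_months`, `survival`,
#'   `ci_low`, `ci_high`).
#' @export
landmark_survival <- function(x) {
  stopifnot(inherits(x, "km_fit"))
  x$landmark
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank test comparing the survival experience of
#' two groups; symmetric in group labels.
#'
#' @param endpoints Tibble with `time_months`, `event` and the grouping
#'   column.
#' @param group Name of the grouping column (must have exactly 2 observed
#'   levels, each non-empty).
#' @return A tibble: `statistic` (chi-square, 1 df), `df`, `p_value`,
#'   `n`, `n_event`.
#' @export
logrank_test <- function(endpoints, group) {
  check_endpoints(endpoints)
  if (!group %in% names(endpoints)) {
    abort(sprintf("grouping column '%s' not found", group))
  }
  g <- factor(endpoints[[group]])
  if (nlevels(droplevels(g)) != 2) {
    abort("log-rank test requires exactly two non-empty groups")
  }
  d <- tibble::tibble(time = endpoints$time_months,
                      event = as.numeric(endpoints$event),
                      g = droplevels(g))
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  tibble::tibble(statistic = sd$chisq, df = 1L,
                 p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                 n = nrow(d), n_event = sum(d$event))
}

#' Univariable Cox proportional-hazards fit
#'
#' Partial-likelihood fit with the Efron approximation for tied event times;
#' hazard ratios with Wald 95% confidence intervals and p-values, one row per
#' non-reference level of the covariate. The reference level is the first
#' factor level (for ctDNA status, code "not detected" first so "detected" is
#' reported against it).
#'
#' @param endpoints Tibble with `time_months`, `event` and the covariate
#'   column.
#' @param covariate Name of the covariate column.
#' @return A tibble of class `cox_estimates`: `term`, `level`, `hr`,
#'   `ci_low`, `ci_high`, `p_value`, `n`, `n_event`, `flagged` (TRUE when the
#'   fit is degenerate, e.g. no events in a level giving a monotone
#'   likelihood).
#' @export
cox_univariable <- function(endpoints, covariate) {
  cox_fit(endpoints, covariate)
}

#' Multivariable Cox model with univariable screening
#'
#' Mirrors the two-stage modelling convention: every candidate covariate is
#' first fit univariably; those with Wald p below `entry_p` (default 0.05)
#' enter a joint Cox model whose adjusted hazard ratios are reported.
#'
#' @param endpoints Tibble with `time_months`, `event` and candidate columns.
#' @param candidates Character vector of candidate covariate names.
#' @param entry_p Univariable p-value threshold for entry. Default 0.05.
#' @return A tibble of adjusted estimates (as [cox_univariable()]); the
#'   attribute `"screen"` holds the univariable screen table and
#'   `"entered"` the covariates that entered. Errors if no candidate passes.
#' @export
cox_multivariable <- function(endpoints, candidates, entry_p = 0.05) {
  screen <- purrr::map_dfr(candidates, function(v) {
    est <- cox_univariable(endpoints, v)
    tibble::tibble(term = v, min_p = min(est$p_value),
                   entered = min(est$p_value) < entry_p)
  })
  entered <- screen$term[screen$entered]
  if (length(entered) == 0) {
    abort(sprintf("no candidate covariate reached univariable p < %g",
                  entry_p))
  }
  out <- cox_fit(endpoints, entered)
  attr(out, "screen") <- screen
  attr(out, "entered") <- entered
  out
}

cox_fit <- function(endpoints, covariates) {
  check_endpoints(endpoints)
  missing <- setdiff(covariates, names(endpoints))
  if (length(missing) > 0) {
    abort(paste0("covariate not found: ", paste(missing, collapse = ", ")))
  }
  d <- tibble::as_tibble(endpoints)
  for (v in covariates) {
    if (!is.numeric(d[[v]])) {
      d[[v]] <- factor(d[[v]])
      if (nlevels(droplevels(d[[v]])) < 2) {
        abort(sprintf("covariate '%s' has no contrast (single level)", v))
      }
    } else if (length(unique(d[[v]])) < 2) {
      abort(sprintf("covariate '%s' has no contrast (constant)", v))
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time_months, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  s <- summary(fit)
  coefs <- s$coefficients
  ci <- s$conf.int
  terms_raw <- rownames(coefs)
  term_of <- function(nm) {
    hit <- covariates[startsWith(nm, sprintf("`%s`", covariates)) |
                        startsWith(nm, covariates)]
    if (length(hit) > 0) hit[which.max(nchar(hit))] else nm
  }
  term <- vapply(terms_raw, term_of, character(1))
  level <- mapply(function(nm, tm) {
    lv <- sub(sprintf("^`?%s`?", tm), "", nm)
    if (nzchar(lv)) lv else NA_character_
  }, terms_raw, term)
  se_huge <- coefs[, "se(coef)"] > 10
  out <- tibble::tibble(
    term = unname(term), level = unname(level),
    hr = unname(coefs[, "exp(coef)"]),
    ci_low = unname(ci[, "lower .95"]), ci_high = unname(ci[, "upper .95"]),
    p_value = unname(coefs[, "Pr(>|z|)"]),
    n = s$n, n_event = s$nevent,
    flagged = flagged | unname(se_huge))
  class(out) <- c("cox_estimates", class(out))
  attr(out, "fit") <- fit
  out
}

#' ROC analysis of a per-patient score
#'
#' Receiver-operating-characteristic curve and area under the curve for a
#' continuous score (e.g. methylated copies/mL of one marker, or the TriMeth
#' total) against a binary outcome label (recurrence during follow-up).
#' Higher scores are treated as more outcome-like (fixed direction), so
#' negating the scores maps the AUC to 1 - AUC; ties are handled by
#' trapezoidal interpolation (equivalently the Mann-Whitney statistic with
#' ties counted half).
#'
#' @param scores Numeric vector.
#' @param labels Logical (or 0/1) outcome vector; both classes must be
#'   present.
#' @return An object of class `roc_analysis` with the curve points
#'   (`tidy()`), the AUC (`glance()`, or `$auc`), and an [autoplot()] method.
#' @examples
#' r <- roc_analysis(c(0.9, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE))
#' glance(r)
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    abort("scores and labels must have the same length")
  }
  if (!any(labels) || all(labels)) {
    abort("both outcome classes must be present for ROC analysis")
  }
  r <- pROC::roc(response = labels, predictor = scores, direction = "<",
                 quiet = TRUE)
  curve <- tibble::tibble(
    threshold = r$thresholds,
    sensitivity = r$sensitivities,
    specificity = r$specificities) |>
    dplyr::arrange(.data$threshold)
  structure(list(curve = curve, auc = as.numeric(pROC::auc(r)),
                 n_positive = sum(labels), n_negative = sum(!labels)),
            class = "roc_analysis")
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat(sprintf("<roc_analysis> AUC %.3f (%d positives, %d negatives)\n",
              x$auc, x$n_positive, x$n_negative))
  invisible(x)
}

#' @rdname roc_analysis
#' @param x A `roc_analysis`.
#' @param ... Unused.
#' @export
tidy.roc_analysis <- function(x, ...) x$curve

#' @rdname roc_analysis
#' @export
glance.roc_analysis <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_positive = x$n_positive,
                 n_negative = x$n_negative)
}

#' Chi-square test of association for a contingency table
#'
#' Pearson chi-square test of independence without continuity correction,
#' for covariate-by-group count tables.
#'
#' @param counts A matrix (or data frame) of non-negative counts.
#' @return A tibble: `statistic`, `df`, `p_value`, `n`.
#' @examples
#' covariate_association(matrix(c(20, 0, 0, 20), 2))
#' @export
covariate_association <- function(counts) {
  m <- as.matrix(counts)
  if (any(m < 0) || sum(m) <= 0) {
    abort("counts must be non-negative with positive total")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("contingency table has a zero-margin row or column")
  }
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value), n = sum(m))
}
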