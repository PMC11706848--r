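#' Single-marker positivity
#'
#' A methylation marker is scored positive in a sample when more than one
#' positive droplet is detected, i.e. at least two droplets. Requiring two
#' droplets guards against isolated single-droplet noise.
#'
#' @param k_positive Integer vector of positive-droplet counts (>= 0).
#' @return Logical vector.
#' @examples
#' marker_positive(c(0, 1, 2, 10))
#' @export
marker_positive <- function(k_positive) {
  if (any(k_positive < 0, na.rm = TRUE)) abort("k_positive must be >= 0")
  k_positive > 1
}

#' TriMeth 2-of-3 sample call
#'
#' A plasma sample is called ctDNA positive when at least 2 of the 3
#' methylation markers (C9orf50, KCNQ5, CLIP4) each show more than one
#' positive droplet. The call is invariant under marker permutation and
#' monotone: extra positive droplets can never flip a positive call to
#' negative.
#'
#' @param marker_droplets Named integer vector (or list) of positive-droplet
#'   counts for the three TriMeth markers; names must cover C9orf50, KCNQ5
#'   and CLIP4.
#' @return `"positive"` or `"negative"`.
#' @examples
#' sample_call(c(C9orf50 = 2, KCNQ5 = 3, CLIP4 = 0))
#' sample_call(c(C9orf50 = 5, KCNQ5 = 1, CLIP4 = 1))
#' @export
sample_call <- function(marker_droplets) {
  k <- unlist(marker_droplets)
  missing <- setdiff(TRIMETH_MARKERS, names(k))
  if (length(missing) > 0 || anyNA(k[TRIMETH_MARKERS])) {
    abort(paste0("incomplete panel: missing marker measurement for ",
                 paste(c(missing, names(which(is.na(k[TRIMETH_MARKERS])))),
                       collapse = ", ")))
  }
  n_pos <- sum(marker_positive(k[TRIMETH_MARKERS]))
  if (n_pos >= 2) "positive" else "negative"
}

#' Call every sample in a measurement table
#'
#' Applies the TriMeth rule per sample: pivots a [quantify_droplets()]
#' measurement table to one row per sample, sums the three marker
#' concentrations into a TriMeth total (copies per mL plasma), and emits the
#' 2-of-3 call. If a QC report is supplied, QC-failed samples are retained
#' with `qc_pass = FALSE` and no call (they are "not evaluable", not
#' negative). A saturated marker well yields a positive marker (saturation is
#' overwhelming signal) but an `NA` concentration.
#'
#' @param measurements Output of [quantify_droplets()] (sample wells of the
#'   three TriMeth markers are used; other targets are ignored).
#' @param qc Optional QC report from [qc_gate()]/[qc_report()] with
#'   `sample_id` and `qc_pass`.
#' @param sample_sheet Optional tibble mapping `sample_id` to `patient_id`
#'   and `timepoint`, carried through to the output.
#'
#' @return A tibble with one row per sample: identifiers, per-marker droplet
#'   counts (`k_C9orf50`, ...), per-marker copies/mL (`cpml_C9orf50`, ...),
#'   `trimeth_copies_per_ml`, `qc_pass` and `call` (`"positive"`,
#'   `"negative"`, or NA when not evaluable).
#' @export
call_samples <- function(measurements, qc = NULL, sample_sheet = NULL) {
  m <- measurements |>
    dplyr::filter(.data$role == "sample",
                  .data$target %in% TRIMETH_MARKERS,
                  !is.na(.data$sample_id))
  if (nrow(m) == 0) abort("no TriMeth marker sample wells in measurements")
  wide <- m |>
    dplyr::select("sample_id", "target", "k_positive",
                  "copies_per_ml_plasma") |>
    tidyr::pivot_wider(names_from = "target",
                       values_from = c("k_positive", "copies_per_ml_plasma"),
                       names_glue = "{.value}_{target}") |>
    dplyr::rename_with(~ sub("^k_positive_", "k_", .x)) |>
    dplyr::rename_with(~ sub("^copies_per_ml_plasma_", "cpml_", .x))

  kcols <- paste0("k_", TRIMETH_MARKERS)
  ccols <- paste0("cpml_", TRIMETH_MARKERS)
  missing <- setdiff(kcols, names(wide))
  if (length(missing) > 0) {
    abort(paste0("incomplete panel: no measurements for ",
                 paste(sub("^k_", "", missing), collapse = ", ")))
  }
  wide$trimeth_copies_per_ml <- rowSums(as.matrix(wide[ccols]))
  wide$call <- purrr::pmap_chr(wide[kcols], function(...) {
    sample_call(setNames(c(...), TRIMETH_MARKERS))
  })

  wide$qc_pass <- TRUE
  if (!is.null(qc)) {
    idx <- match(wide$sample_id, qc$sample_id)
    wide$qc_pass <- !is.na(idx) & qc$qc_pass[idx]
    wide$call[!wide$qc_pass] <- NA_character_
    wide$trimeth_copies_per_ml[!wide$qc_pass] <- NA_real_
  }
  if (!is.null(sample_sheet)) {
    keep <- intersect(c("sample_id", "patient_id", "timepoint"),
                      names(sample_sheet))
    wide <- dplyr::left_join(wide, dplyr::distinct(sample_sheet[keep]),
                             by = "sample_id") |>
      dplyr::relocate(dplyr::any_of(c("patient_id", "timepoint")),
                      .after = "sample_id")
  }
  wide
}

#' Per-timepoint ctDNA detection rates
#'
#' Counts positive calls among evaluable (QC-passed, called) samples at each
#' timepoint. Each patient may contribute at most one evaluable sample per
#' timepoint; duplicates are an input error. The percentage is rounded to the
#' nearest integer, matching how serial detection rates are conventionally
#' reported.
#'
#' @param calls A call table (e.g. from [call_samples()]) with `patient_id`,
#'   `timepoint` and `call` columns.
#' @return A tibble per timepoint: `timepoint`, `n_positive`, `n_evaluable`,
#'   `rate_percent`.
#' @export
detection_rate <- function(calls) {
  needed <- c("patient_id", "timepoint", "call")
  if (!all(needed %in% names(calls))) {
    abort("`calls` must have columns patient_id, timepoint, call")
  }
  evaluable <- dplyr::filter(calls, !is.na(.data$call))
  dup <- evaluable |>
    dplyr::count(.data$patient_id, .data$timepoint) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate evaluable sample for patient/timepoint: ",
                 paste(dup$patient_id, dup$timepoint, sep = "@",
                       collapse = ", ")))
  }
  evaluable |>
    dplyr::mutate(timepoint = factor(.data$timepoint,
                                     levels = intersect(TIMEPOINTS,
                                                        unique(.data$timepoint)))) |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::summarise(
      n_positive = sum(.data$call == "positive"),
      n_evaluable = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(rate_percent = round(100 * .data$n_positive /
                                         .data$n_evaluable))
}

#' ctDNA dynamics group between two timepoints
#'
#' Classifies each patient by the transition of ctDNA status between two
#' timepoints: negative to negative, negative to positive, positive to
#' negative, positive to positive. Patients missing a call at either
#' timepoint are excluded (returned as NA), so group counts sum to the number
#' of patients with both calls.
#'
#' @param call_t1,call_t2 Character vectors of `"positive"`/`"negative"`
#'   calls (NA allowed) at the earlier and later timepoint.
#' @return A factor with levels `neg_to_neg`, `neg_to_pos`, `pos_to_neg`,
#'   `pos_to_pos` (NA when either call is missing).
#' @examples
#' dynamics_group(c("negative", "positive"), c("negative", "negative"))
#' @export
dynamics_group <- function(call_t1, call_t2) {
  ok_vals <- c("positive", "negative", NA)
  if (!all(call_t1 %in% ok_vals) || !all(call_t2 %in% ok_vals)) {
    abort("calls must be 'positive', 'negative' or NA")
  }
  lab <- function(x) ifelse(x == "positive", "pos", "neg")
  out <- ifelse(is.na(call_t1) | is.na(call_t2), NA_character_,
                paste0(lab(call_t1), "_to_", lab(call_t2)))
  factor(out, levels = c("neg_to_neg", "neg_to_pos", "pos_to_neg",
                         "pos_to_pos"))
}

#' Dynamics groups for a cohort call table
#'
#' @param calls Call table with `patient_id`, `timepoint`, `call`.
#' @param from,to The two timepoints to compare.
#' @return A tibble `patient_id`, `call_from`, `call_to`, `dynamics`
#'   (patients missing either call have `dynamics` NA).
#' @export
cohort_dynamics <- function(calls, from = "after_1_cycle",
                            to = "post_surgery") {
  wide <- calls |>
    dplyr::filter(.data$timepoint %in% c(from, to)) |>
    dplyr::select("patient_id", "timepoint", "call") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "call")
  for (tp in c(from, to)) if (!tp %in% names(wide)) wide[[tp]] <- NA_character_
  tibble::tibble(
    patient_id = wide$patient_id,
    call_from = wide[[from]],
    call_to = wide[[to]],
    dynamics = dynamics_group(wide[[from]], wide[[to]])
  )
}
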