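#' Run the full analysis pipeline
#'
#' Wires the stages together in the study's order: quantify -> QC -> call ->
#' detection/dynamics -> survival. Samples failing QC never reach the calling
#' or survival stages (they are retained in the call table as not evaluable).
#' Each stage's table is returned, and written as CSV when `out_dir` is
#' given, together with a run-metadata JSON (droplet counts, thresholds, QC
#' exclusions, package version, seed). Counts reconcile across stages:
#' collected = analyzed + excluded.
#'
#' @param droplets Droplet-level table (see [plate_thresholds()]).
#' @param sample_sheet Tibble linking `sample_id` to `patient_id`,
#'   `timepoint` and optionally `template_volume`, `plasma_volume`.
#' @param qc Optional pre-assembled QC input table for [qc_gate()]; if NULL
#'   and `spike_manifest`/`cf_before` are given, QC metrics are assembled
#'   from the measurements via [qc_report()]; if neither, all samples pass
#'   (with a note in the metadata).
#' @param spike_manifest,cf_before See [qc_report()].
#' @param clinical Optional clinical table for [build_endpoints()]; when
#'   NULL the survival stage is skipped and earlier stages still run.
#' @param geometry A [reaction_geometry()].
#' @param qc_configuration A [qc_config()].
#' @param landmark_months Landmark time for KM summaries. Default 24.
#' @param dynamics_from,dynamics_to Timepoints for the dynamics grouping.
#' @param out_dir Optional output directory for per-stage CSVs and
#'   `run_metadata.json`.
#' @param seed Seed recorded in the metadata (the pipeline itself is
#'   deterministic).
#' @return A list of class `trimeth_pipeline`: `thresholds`, `measurements`,
#'   `qc`, `calls`, `detection`, `dynamics`, `survival` (NULL or a list with
#'   `endpoints`, `hazards`, `km`), and `metadata`.
#' @export
run_pipeline <- function(droplets, sample_sheet, qc = NULL,
                         spike_manifest = NULL, cf_before = NULL,
                         clinical = NULL, geometry = reaction_geometry(),
                         qc_configuration = qc_config(),
                         landmark_months = 24,
                         dynamics_from = "after_1_cycle",
                         dynamics_to = "post_surgery",
                         out_dir = NULL, seed = NA_integer_) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  emit <- function(tbl, file) {
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      readr::write_csv(tbl, file.path(out_dir, file), progress = FALSE)
    }
    tbl
  }

  thresholds <- stage("quantify", plate_thresholds(droplets)) |>
    emit("thresholds.csv")
  measurements <- stage("quantify",
                        quantify_droplets(droplets, sample_sheet, geometry)) |>
    emit("measurements.csv")

  qc_note <- NULL
  qc_tbl <- stage("qc", {
    if (!is.null(qc)) {
      if (!"min_droplets" %in% names(qc)) {
        mins <- measurements |>
          dplyr::filter(.data$role == "sample", !is.na(.data$sample_id)) |>
          dplyr::group_by(.data$sample_id) |>
          dplyr::summarise(min_droplets = min(.data$n_total),
                           .groups = "drop")
        qc <- dplyr::left_join(qc, mins, by = "sample_id")
      }
      qc_gate(qc, qc_configuration)
    } else if (!is.null(spike_manifest) && !is.null(cf_before)) {
      qc_report(measurements, spike_manifest, cf_before, qc_configuration)
    } else {
      qc_note <- "no QC inputs supplied; all samples passed by default"
      ids <- unique(stats::na.omit(measurements$sample_id))
      tibble::tibble(sample_id = ids, qc_pass = TRUE, reasons = "")
    }
  }) |> emit("qc_report.csv")

  calls <- stage("call",
                 call_samples(measurements, qc_tbl, sample_sheet)) |>
    emit("calls.csv")
  detection <- stage("call", detection_rate(calls)) |>
    emit("detection_rates.csv")
  dynamics <- stage("call",
                    cohort_dynamics(calls, dynamics_from, dynamics_to)) |>
    emit("dynamics.csv")

  surv <- NULL
  if (!is.null(clinical)) {
    surv <- stage("survival", {
      endpoints <- build_endpoints(clinical)
      status_wide <- calls |>
        dplyr::select("patient_id", "timepoint", "call") |>
        tidyr::pivot_wider(names_from = "timepoint", values_from = "call")
      hazards <- purrr::map_dfr(
        intersect(TIMEPOINTS, names(status_wide)),
        function(tp) {
          purrr::map_dfr(c("RFS", "OS"), function(ep) {
            d <- endpoints |>
              dplyr::filter(.data$endpoint == ep) |>
              dplyr::inner_join(status_wide[c("patient_id", tp)],
                                by = "patient_id") |>
              dplyr::filter(!is.na(.data[[tp]])) |>
              dplyr::mutate(ctdna = factor(.data[[tp]],
                                           levels = c("negative",
                                                      "positive")))
            est <- tryCatch(cox_univariable(d, "ctdna"),
                            error = function(e) NULL)
            if (is.null(est)) return(NULL)
            dplyr::mutate(est, timepoint = tp, endpoint = ep, .before = 1)
          })
        })
      km <- purrr::map(
        stats::setNames(nm = intersect(TIMEPOINTS, names(status_wide))),
        function(tp) {
          d <- endpoints |>
            dplyr::filter(.data$endpoint == "RFS") |>
            dplyr::inner_join(status_wide[c("patient_id", tp)],
                              by = "patient_id") |>
            dplyr::filter(!is.na(.data[[tp]]))
          if (nrow(d) == 0 || length(unique(d[[tp]])) < 2) return(NULL)
          km_estimate(d, group = tp, landmark_months = landmark_months)
        })
      list(endpoints = emit(endpoints, "endpoints.csv"),
           hazards = emit(hazards, "hazard_ratios.csv"), km = km)
    })
  }

  sample_ids <- unique(stats::na.omit(measurements$sample_id[
    measurements$role == "sample"]))
  metadata <- list(
    package_version = as.character(utils::packageVersion("trimethr")),
    seed = seed,
    n_wells = dplyr::n_distinct(paste(droplets$plate_id, droplets$well_id)),
    droplets_per_well = {
      counts <- droplets |>
        dplyr::count(.data$plate_id, .data$well_id, .data$channel)
      list(median = median(counts$n), min = min(counts$n),
           max = max(counts$n))
    },
    thresholds = thresholds[c("plate_id", "channel", "threshold")],
    samples_collected = length(sample_ids),
    samples_excluded = sum(!qc_tbl$qc_pass),
    samples_analyzed = length(sample_ids) - sum(!qc_tbl$qc_pass),
    qc_note = qc_note,
    survival_stage_run = !is.null(clinical)
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(metadata, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  structure(list(thresholds = thresholds, measurements = measurements,
                 qc = qc_tbl, calls = calls, detection = detection,
                 dynamics = dynamics, survival = surv, metadata = metadata),
            class = "trimeth_pipeline")
}

#' @export
print.trimeth_pipeline <- function(x, ...) {
  m <- x$metadata
  cat("<trimeth_pipeline>\n")
  cat(sprintf("  samples: %d collected = %d analyzed + %d excluded\n",
              m$samples_collected, m$samples_analyzed, m$samples_excluded))
  cat(sprintf("  wells: %d (median %g droplets)\n", m$n_wells,
              m$droplets_per_well$median))
  print(x$detection)
  if (!is.null(x$survival)) {
    cat("  hazard ratios (ctDNA detected vs not):\n")
    print(dplyr::select(x$survival$hazards, "timepoint", "endpoint", "hr",
                        "ci_low", "ci_high", "p_value"))
  }
  invisible(x)
}
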