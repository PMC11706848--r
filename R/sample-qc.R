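#' Spike-in purification efficiency
#'
#' Percentage recovery of the CPP1 soybean spike-in after cfDNA extraction: a
#' fixed amount of CPP1 fragments is added to each plasma sample before
#' extraction, and the fraction recovered (measured by the CPP1 ddPCR assay)
#' estimates how efficiently the extraction retained DNA. Values above 100%
#' are possible (quantification noise) and are reported, not truncated.
#'
#' @param measured_cpp1 Copies of CPP1 measured after extraction (>= 0).
#' @param spiked_cpp1 Copies of CPP1 spiked in before extraction (> 0).
#' @return Percentage recovery (numeric, vectorised).
#' @examples
#' purification_efficiency(92, 100)
#' @export
purification_efficiency <- function(measured_cpp1, spiked_cpp1) {
  if (any(spiked_cpp1 <= 0, na.rm = TRUE)) abort("spiked_cpp1 must be > 0")
  if (any(measured_cpp1 < 0, na.rm = TRUE)) abort("measured_cpp1 must be >= 0")
  100 * measured_cpp1 / spiked_cpp1
}

#' Bisulfite conversion recovery
#'
#' Percentage of DNA surviving bisulfite conversion, measured with the
#' cytosine-free (CF) quantification assay before and after conversion:
#' 100 x after / before. Bisulfite chemistry degrades DNA, so recoveries
#' around 50% are typical for cfDNA.
#'
#' @param cf_before CF-assay copies before conversion (> 0).
#' @param cf_after CF-assay copies after conversion (>= 0).
#' @return Percentage recovery (numeric, vectorised).
#' @examples
#' bisulfite_recovery(100, 51)
#' @export
bisulfite_recovery <- function(cf_before, cf_after) {
  if (any(cf_before <= 0, na.rm = TRUE)) abort("cf_before must be > 0")
  if (any(cf_after < 0, na.rm = TRUE)) abort("cf_after must be >= 0")
  100 * cf_after / cf_before
}

#' QC gate configuration
#'
#' @param pbc_fraction_cutoff Leucocyte-contamination rule: fail when
#'   PBC-derived copies exceed this fraction of the CF-measured copies.
#'   A relative cutoff is robust to the amount of input DNA. Default 0.1.
#' @param min_droplets Minimum droplets per analyzable well. Default 10000.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(pbc_fraction_cutoff = 0.1, min_droplets = 10000L) {
  if (pbc_fraction_cutoff < 0) abort("pbc_fraction_cutoff must be >= 0")
  if (min_droplets < 0) abort("min_droplets must be >= 0")
  structure(list(pbc_fraction_cutoff = pbc_fraction_cutoff,
                 min_droplets = as.integer(min_droplets)),
            class = "qc_config")
}

#' Apply the sample exclusion rules
#'
#' Gates each plasma sample on the three exclusion criteria of the workflow:
#' leucocyte (genomic) DNA contamination, too few droplets in any of the
#' sample's wells, and a non-measurable CF signal after bisulfite conversion
#' (without which DNA recovery cannot be computed). A sample fails if any
#' rule triggers; every triggered rule is listed in `reasons`. Rows with a
#' missing required metric fail with reason `incomplete_qc`.
#'
#' @param qc A data frame with one row per sample and columns `sample_id`,
#'   `measured_cpp1_copies`, `spiked_cpp1_copies`, `pbc_copies`, `cf_before`,
#'   `cf_after`, `min_droplets` (the minimum droplet count over the sample's
#'   wells). `pbc_copies` and `cf_before` must be on the same copies scale.
#' @param config A [qc_config()].
#'
#' @return A tibble with the input identifiers plus `purification_efficiency`,
#'   `bisulfite_recovery` (percent), the logical flags
#'   `leucocyte_contamination`, `low_droplets`, `no_cf_signal`,
#'   `over_recovery`, and `qc_pass` with a semicolon-separated `reasons`
#'   string (empty when passing).
#' @examples
#' qc <- tibble::tibble(sample_id = "S1", measured_cpp1_copies = 92,
#'   spiked_cpp1_copies = 100, pbc_copies = 0, cf_before = 3000,
#'   cf_after = 1500, min_droplets = 20500)
#' qc_gate(qc)
#' @export
qc_gate <- function(qc, config = qc_config()) {
  needed <- c("sample_id", "measured_cpp1_copies", "spiked_cpp1_copies",
              "pbc_copies", "cf_before", "cf_after", "min_droplets")
  missing <- setdiff(needed, names(qc))
  if (length(missing) > 0) {
    abort(paste0("QC table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(qc)
  complete <- stats::complete.cases(
    out[c("measured_cpp1_copies", "spiked_cpp1_copies", "pbc_copies",
          "cf_before", "cf_after", "min_droplets")])

  out$purification_efficiency <- NA_real_
  out$purification_efficiency[complete] <- purification_efficiency(
    out$measured_cpp1_copies[complete], out$spiked_cpp1_copies[complete])
  out$bisulfite_recovery <- NA_real_
  out$bisulfite_recovery[complete] <- bisulfite_recovery(
    out$cf_before[complete], out$cf_after[complete])

  out$leucocyte_contamination <- complete &
    out$pbc_copies > config$pbc_fraction_cutoff * out$cf_before
  out$low_droplets <- complete & out$min_droplets < config$min_droplets
  out$no_cf_signal <- complete & out$cf_after <= 0
  out$over_recovery <- complete & !is.na(out$purification_efficiency) &
    out$purification_efficiency > 100

  reasons <- purrr::pmap_chr(
    list(complete, out$leucocyte_contamination, out$low_droplets,
         out$no_cf_signal),
    function(ok, leuco, lowd, nocf) {
      if (!ok) return("incomplete_qc")
      paste(c(if (leuco) "leucocyte_contamination",
              if (lowd) "low_droplets",
              if (nocf) "no_cf_signal"), collapse = ";")
    })
  out$qc_pass <- reasons == ""
  out$reasons <- reasons
  out
}

#' Assemble per-sample QC metrics from quantified wells
#'
#' Builds the [qc_gate()] input table from a measurement table produced by
#' [quantify_droplets()] (for PBC, CPP1 and CF-after copies and per-well
#' droplet counts), a spike-in manifest, and a CF-before table.
#'
#' @param measurements Output of [quantify_droplets()]; PBC/CPP1/CF wells are
#'   identified by their `target`.
#' @param spike_manifest Tibble `sample_id`, `spiked_cpp1_copies`.
#' @param cf_before Tibble `sample_id`, `cf_before` (copies before bisulfite
#'   conversion).
#' @param config A [qc_config()] passed through to [qc_gate()].
#'
#' @return The gated QC report tibble (see [qc_gate()]).
#' @export
qc_report <- function(measurements, spike_manifest, cf_before,
                      config = qc_config()) {
  samp <- measurements |>
    dplyr::filter(.data$role == "sample", !is.na(.data$sample_id))
  per_target <- function(tgt, col = "copies_per_reaction") {
    samp |>
      dplyr::filter(.data$target == tgt) |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(value = sum(.data[[col]]), .groups = "drop")
  }
  qc <- samp |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(min_droplets = min(.data$n_total), .groups = "drop") |>
    dplyr::left_join(dplyr::rename(per_target("CPP1"),
                                   measured_cpp1_copies = "value"),
                     by = "sample_id") |>
    dplyr::left_join(dplyr::rename(per_target("PBC"), pbc_copies = "value"),
                     by = "sample_id") |>
    dplyr::left_join(dplyr::rename(per_target("CF"), cf_after = "value"),
                     by = "sample_id") |>
    dplyr::left_join(tibble::as_tibble(spike_manifest), by = "sample_id") |>
    dplyr::left_join(tibble::as_tibble(cf_before), by = "sample_id")
  qc_gate(qc, config)
}
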