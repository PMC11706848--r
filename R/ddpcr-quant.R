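#' Derive a droplet-classification threshold from plate controls
#'
#' Places the positive/negative cut-off for one plate x channel from the
#' droplet signals of that plate's negative and positive control wells, so the
#' same objective threshold applies to every sample well measured alongside
#' them. The negative centre is the median amplitude of the negative control.
#' The positive centre is the median of the upper cluster found by a
#' deterministic two-means split of the positive-control amplitudes
#' (centres initialised at the minimum and maximum amplitude). The threshold is
#'
#' \deqn{\max\{c_{neg} + 0.4 (c_{pos} - c_{neg}),\; c_{neg} + 7\,\mathrm{MAD}_{neg}\}}
#'
#' where MAD is the raw (unscaled) median absolute deviation of the negative
#' control. The interpolation term places the cut conservatively below the
#' midpoint, guarding against rain; the MAD floor keeps it clear of the
#' negative cloud when the clusters sit close together. The rule is
#' scale-equivariant: multiplying every amplitude by a common factor scales
#' the threshold by the same factor.
#'
#' @param neg_amplitudes Numeric vector of negative-control droplet amplitudes.
#' @param pos_amplitudes Numeric vector of positive-control droplet amplitudes.
#' @param interpolation Fraction of the negative-to-positive separation at
#'   which the interpolated cut is placed. Default 0.4.
#' @param mad_multiplier Multiplier of the negative-control MAD for the floor
#'   term. Default 7.
#' @param min_separation_mads Control-failure guard: the positive and negative
#'   centres must be separated by more than this many negative-control MADs
#'   for the plate to be analyzable. Default 4.
#'
#' @return A list of class `channel_threshold` with elements `neg_center`,
#'   `pos_center`, `neg_mad`, `threshold` and `method`.
#' @examples
#' neg <- c(980, 1000, 1000, 1020, 1040, 960)
#' pos <- c(rep(1000, 50), rep(9000, 50))
#' threshold_from_controls(neg, pos)$threshold
#' @export
threshold_from_controls <- function(neg_amplitudes, pos_amplitudes,
                                    interpolation = 0.4, mad_multiplier = 7,
                                    min_separation_mads = 4) {
  if (length(neg_amplitudes) == 0 || length(pos_amplitudes) == 0) {
    abort("control wells must contain at least one droplet")
  }
  if (!all(is.finite(neg_amplitudes)) || !all(is.finite(pos_amplitudes))) {
    abort("control amplitudes must all be finite")
  }
  neg_center <- median(neg_amplitudes)
  neg_mad <- stats::mad(neg_amplitudes, constant = 1)

  split <- two_means_split(pos_amplitudes)
  pos_center <- median(pos_amplitudes[split$assignment == 2L])

  separation <- pos_center - neg_center
  if (separation <= 0 || separation <= min_separation_mads * neg_mad) {
    abort(paste0(
      "control failure: no detectable upper cluster in the positive control ",
      "(separation ", signif(separation, 4), " amplitude units, negative MAD ",
      signif(neg_mad, 4), "); plate not analyzable"
    ))
  }

  threshold <- max(neg_center + interpolation * separation,
                   neg_center + mad_multiplier * neg_mad)
  structure(
    list(neg_center = neg_center, pos_center = pos_center, neg_mad = neg_mad,
         threshold = threshold,
         method = sprintf(
           "two-means split; max(neg + %.2f*sep, neg + %g*MAD)",
           interpolation, mad_multiplier)),
    class = "channel_threshold"
  )
}

# Deterministic 1-d two-means (Lloyd) split with centres initialised at the
# range extremes. Returns cluster assignment (1 = lower, 2 = upper).
two_means_split <- function(x, max_iter = 100L) {
  centers <- range(x)
  if (centers[1] == centers[2]) {
    return(list(assignment = rep(2L, length(x)), centers = centers))
  }
  assignment <- rep(1L, length(x))
  for (i in seq_len(max_iter)) {
    new_assignment <- ifelse(abs(x - centers[2]) < abs(x - centers[1]), 2L, 1L)
    if (identical(new_assignment, assignment) && i > 1L) break
    assignment <- new_assignment
    for (k in 1:2) {
      if (any(assignment == k)) centers[k] <- mean(x[assignment == k])
    }
  }
  list(assignment = assignment, centers = centers)
}

#' Compute classification thresholds for every plate and channel
#'
#' Applies [threshold_from_controls()] to each plate x channel combination of
#' a droplet table, using that plate's negative- and positive-control wells.
#' One threshold per plate x channel is then shared by all sample wells, which
#' is how plate-wise objective thresholding is meant to be used: the controls
#' anchor the cut, the samples are classified against it.
#'
#' @param droplets A droplet-level data frame with columns `plate_id`,
#'   `well_id`, `channel`, `target`, `role` (one of `sample`,
#'   `positive_control`, `negative_control`, `no_template_control`) and
#'   `amplitude`.
#' @param ... Passed on to [threshold_from_controls()].
#'
#' @return A tibble with one row per plate x channel: `plate_id`, `channel`,
#'   `neg_center`, `pos_center`, `neg_mad`, `threshold`, `method`.
#' @export
plate_thresholds <- function(droplets, ...) {
  check_droplet_table(droplets)
  droplets |>
    dplyr::group_by(.data$plate_id, .data$channel) |>
    dplyr::group_modify(function(d, key) {
      neg <- d$amplitude[d$role == "negative_control"]
      pos <- d$amplitude[d$role == "positive_control"]
      if (length(neg) == 0 || length(pos) == 0) {
        abort(sprintf(
          "plate %s channel %s is missing a negative or positive control well",
          key$plate_id, key$channel))
      }
      thr <- threshold_from_controls(neg, pos, ...)
      tibble::tibble(neg_center = thr$neg_center, pos_center = thr$pos_center,
                     neg_mad = thr$neg_mad, threshold = thr$threshold,
                     method = thr$method)
    }) |>
    dplyr::ungroup()
}

#' Classify droplets against plate thresholds
#'
#' Counts, for every well x channel, the droplets strictly above the plate's
#' threshold. Amplitudes exactly equal to the threshold count as negative;
#' the strict inequality avoids inflating single-droplet calls from boundary
#' ties.
#'
#' @param droplets Droplet-level table (see [plate_thresholds()]); must also
#'   carry a `sample_id` column for sample wells.
#' @param thresholds Output of [plate_thresholds()] (or a compatible tibble
#'   with `plate_id`, `channel`, `threshold`).
#'
#' @return A tibble with one row per plate x well x channel: identifiers,
#'   `target`, `role`, `sample_id` (NA for control wells without one),
#'   `k_positive`, `n_total` and the `threshold` applied.
#' @export
classify_droplets <- function(droplets, thresholds) {
  check_droplet_table(droplets)
  if (!all(c("plate_id", "channel", "threshold") %in% names(thresholds))) {
    abort("`thresholds` must have columns plate_id, channel, threshold")
  }
  if (!"sample_id" %in% names(droplets)) droplets$sample_id <- NA_character_
  joined <- dplyr::left_join(droplets,
    dplyr::select(thresholds, "plate_id", "channel", "threshold"),
    by = c("plate_id", "channel"))
  if (anyNA(joined$threshold)) {
    missing <- joined |>
      dplyr::filter(is.na(.data$threshold)) |>
      dplyr::distinct(.data$plate_id, .data$channel)
    abort(paste0("no threshold available for plate/channel: ",
                 paste(missing$plate_id, missing$channel, sep = "/",
                       collapse = ", ")))
  }
  joined |>
    dplyr::group_by(.data$plate_id, .data$well_id, .data$channel,
                    .data$target, .data$role, .data$sample_id,
                    .data$threshold) |>
    dplyr::summarise(
      k_positive = sum(.data$amplitude > .data$threshold),
      n_total = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::relocate("threshold", .after = "n_total")
}

#' Poisson copy-number estimate from droplet counts
#'
#' Converts positive/total droplet counts into a mean copies-per-droplet rate
#' and absolute copy concentrations, the standard digital-PCR correction for
#' droplets that received more than one template molecule. With `k` of `n`
#' droplets positive,
#'
#' \deqn{\lambda = -\ln(1 - k/n)}
#'
#' copies per uL of reaction is \eqn{\lambda / V_d} (droplet volume
#' \eqn{V_d}), and copies per reaction scales by the reaction volume.
#' Fully positive wells are reported as saturated with undefined
#' concentrations rather than silently converted.
#'
#' @param k_positive Integer vector of positive-droplet counts.
#' @param n_total Integer vector of total droplet counts (> 0).
#' @param geometry A [reaction_geometry()].
#'
#' @return A tibble with columns `k_positive`, `n_total`, `lambda`,
#'   `conc_per_ul_reaction`, `copies_per_reaction`, `saturated`.
#' @examples
#' poisson_concentration(100, 20000)
#' @export
poisson_concentration <- function(k_positive, n_total,
                                  geometry = reaction_geometry()) {
  if (length(n_total) == 1) n_total <- rep(n_total, length(k_positive))
  if (length(k_positive) != length(n_total)) {
    abort("k_positive and n_total must have the same length")
  }
  if (any(n_total <= 0)) abort("n_total must be > 0")
  if (any(k_positive < 0) || any(k_positive > n_total)) {
    abort("k_positive must satisfy 0 <= k_positive <= n_total")
  }
  saturated <- k_positive == n_total & n_total > 0
  lambda <- ifelse(saturated, NA_real_, -log(1 - k_positive / n_total))
  conc <- lambda / geometry$droplet_volume
  tibble::tibble(
    k_positive = as.integer(k_positive), n_total = as.integer(n_total),
    lambda = lambda,
    conc_per_ul_reaction = conc,
    copies_per_reaction = conc * geometry$reaction_volume,
    saturated = saturated
  )
}

#' Convert copies per reaction to copies per millilitre plasma
#'
#' Scales a per-reaction copy number up to the full bisulfite eluate (only
#' `template_volume` of `eluate_volume` uL entered the reaction) and divides
#' by the plasma volume the cfDNA was extracted from:
#' copies/mL = copies_per_reaction x (eluate/template) / plasma.
#'
#' @param copies_per_reaction Numeric vector of per-reaction copy numbers.
#' @param geometry A [reaction_geometry()] supplying default volumes.
#' @param template_volume,eluate_volume,plasma_volume Optional per-sample
#'   overrides (vectors recycled against `copies_per_reaction`).
#' @param saturated Optional logical vector; any saturated measurement is an
#'   error, since a saturated well has no defined concentration (dilution-aware
#'   handling is out of scope).
#'
#' @return Numeric vector of copies per mL plasma.
#' @examples
#' copies_per_ml_plasma(129.7) # default 8 uL of 22 uL eluate, 8 mL plasma
#' @export
copies_per_ml_plasma <- function(copies_per_reaction,
                                 geometry = reaction_geometry(),
                                 template_volume = NULL,
                                 eluate_volume = NULL,
                                 plasma_volume = NULL,
                                 saturated = FALSE) {
  if (any(saturated, na.rm = TRUE)) {
    abort(paste0("saturated measurement has no defined concentration; ",
                 "dilution-aware handling is out of scope"))
  }
  template_volume <- template_volume %||% geometry$template_volume
  eluate_volume <- eluate_volume %||% geometry$eluate_volume
  plasma_volume <- plasma_volume %||% geometry$plasma_volume
  if (any(template_volume <= 0) || any(eluate_volume <= 0) ||
      any(plasma_volume <= 0)) {
    abort("volumes must be > 0")
  }
  if (any(copies_per_reaction < 0, na.rm = TRUE)) {
    abort("copies_per_reaction must be >= 0")
  }
  copies_per_reaction * (eluate_volume / template_volume) / plasma_volume
}

#' Quantify a droplet table end to end
#'
#' The full amplitude-to-concentration chain for one or more plates: derive
#' control-based thresholds per plate x channel, classify every well, apply
#' the Poisson correction, and express sample wells as copies per mL plasma.
#' Control wells are retained in the output (with `copies_per_ml_plasma` NA)
#' so QC can inspect them.
#'
#' @param droplets Droplet-level table (see [plate_thresholds()]).
#' @param sample_sheet Optional tibble with `sample_id` and any of
#'   `template_volume`, `plasma_volume` to override the geometry defaults per
#'   sample.
#' @param geometry A [reaction_geometry()].
#'
#' @return A tibble with one row per well x channel: identifiers, counts,
#'   threshold, `lambda`, `copies_per_reaction`, `copies_per_ml_plasma`,
#'   `saturated`.
#' @export
quantify_droplets <- function(droplets, sample_sheet = NULL,
                              geometry = reaction_geometry()) {
  thresholds <- plate_thresholds(droplets)
  counts <- classify_droplets(droplets, thresholds)
  meas <- dplyr::bind_cols(
    dplyr::select(counts, -"k_positive", -"n_total"),
    poisson_concentration(counts$k_positive, counts$n_total, geometry)
  )
  meas$template_volume <- geometry$template_volume
  meas$plasma_volume <- geometry$plasma_volume
  if (!is.null(sample_sheet)) {
    stopifnot("sample_id" %in% names(sample_sheet))
    overrides <- intersect(c("template_volume", "plasma_volume"),
                           names(sample_sheet))
    for (v in overrides) {
      idx <- match(meas$sample_id, sample_sheet$sample_id)
      meas[[v]] <- ifelse(!is.na(idx) & !is.na(sample_sheet[[v]][idx]),
                          sample_sheet[[v]][idx], meas[[v]])
    }
  }
  is_sample <- meas$role == "sample" & !meas$saturated
  meas$copies_per_ml_plasma <- NA_real_
  meas$copies_per_ml_plasma[is_sample] <- copies_per_ml_plasma(
    meas$copies_per_reaction[is_sample], geometry,
    template_volume = meas$template_volume[is_sample],
    plasma_volume = meas$plasma_volume[is_sample]
  )
  dplyr::select(meas, "sample_id", "target", "plate_id", "well_id", "channel",
                "role", "k_positive", "n_total", "threshold", "lambda",
                "copies_per_reaction", "copies_per_ml_plasma", "saturated")
}

check_droplet_table <- function(droplets) {
  needed <- c("plate_id", "well_id", "channel", "target", "role", "amplitude")
  missing <- setdiff(needed, names(droplets))
  if (length(missing) > 0) {
    abort(paste0("droplet table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(droplets) == 0) abort("droplet table is empty")
  if (!all(is.finite(droplets$amplitude))) {
    abort("all droplet amplitudes must be finite")
  }
  invisible(droplets)
}

#' Read / write droplet-level CSV exports
#'
#' The on-disk dialect mirrors a QuantaSoft-style amplitude export flattened
#' to one row per droplet: `plate_id, well_id, sample_id, channel, target,
#' role, amplitude`, with a header, UTF-8.
#'
#' @param path File path.
#' @return `read_droplet_csv()` returns a droplet tibble.
#' @export
read_droplet_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_droplet_table(d)
  d
}

#' @rdname read_droplet_csv
#' @param droplets Droplet tibble to write.
#' @export
write_droplet_csv <- function(droplets, path) {
  check_droplet_table(droplets)
  readr::write_csv(droplets, path, progress = FALSE)
  invisible(path)
}
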