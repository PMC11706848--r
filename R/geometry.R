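#' Reaction geometry for ddPCR absolute quantification
#'
#' Bundles the volumes that convert a per-droplet Poisson rate into copies per
#' millilitre plasma: the droplet volume, the ddPCR reaction volume, the
#' template volume loaded into the reaction, the bisulfite eluate volume the
#' template was drawn from, and the plasma volume the cell-free DNA was
#' extracted from.
#'
#' The droplet volume defaults to 0.85 nL, the QX200 partition-volume
#' convention. The reaction and eluate volumes default to 22 uL each; the
#' template volume (2-8 uL) and plasma volume (median 8 mL) are per-sample
#' properties and can be overridden per call or per row downstream.
#'
#' @param droplet_volume Droplet (partition) volume in uL. Default 0.00085.
#' @param reaction_volume Final ddPCR reaction volume in uL. Default 22.
#' @param template_volume Template DNA volume loaded into the reaction, in uL.
#'   Default 8.
#' @param eluate_volume Total bisulfite eluate volume in uL the template was
#'   taken from. Default 22.
#' @param plasma_volume Plasma volume in mL used for cfDNA extraction.
#'   Default 8.
#'
#' @return An object of class `reaction_geometry` (a named list of the five
#'   volumes).
#' @examples
#' reaction_geometry()
#' reaction_geometry(template_volume = 4, plasma_volume = 7.5)
#' @export
reaction_geometry <- function(droplet_volume = 0.00085,
                              reaction_volume = 22,
                              template_volume = 8,
                              eluate_volume = 22,
                              plasma_volume = 8) {
  vols <- c(droplet_volume = droplet_volume, reaction_volume = reaction_volume,
            template_volume = template_volume, eluate_volume = eluate_volume,
            plasma_volume = plasma_volume)
  if (any(!is.finite(vols)) || any(vols <= 0)) {
    abort("all reaction geometry volumes must be finite and > 0")
  }
  if (template_volume > eluate_volume) {
    abort("template_volume cannot exceed eluate_volume")
  }
  structure(as.list(vols), class = "reaction_geometry")
}

#' @export
print.reaction_geometry <- function(x, ...) {
  cat("<reaction_geometry>\n")
  cat(sprintf("  droplet volume:  %g uL\n", x$droplet_volume))
  cat(sprintf("  reaction volume: %g uL\n", x$reaction_volume))
  cat(sprintf("  template volume: %g uL of %g uL eluate\n",
              x$template_volume, x$eluate_volume))
  cat(sprintf("  plasma volume:   %g mL\n", x$plasma_volume))
  invisible(x)
}
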