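#' Fluorophore standard definition
#'
#' Describes the in-cell brightness standard used for copy-number
#' estimation. The default is the engineered nuclear pore carrying ~16
#' copies of GFP-Nup133; a fusion built from a brighter fluorophore divides
#' the prefactor by its brightness relative to EGFP (moxGFP is taken as
#' 1.47-fold brighter, giving the 16/1.47 ~ 10.9 prefactor).
#'
#' @param name label for the standard.
#' @param copies_per_standard fluorophore copies per standard particle
#'   (> 0; default 16).
#' @param relative_brightness_vs_gfp brightness of the measured fusion's
#'   fluorophore relative to EGFP (> 0; EGFP = 1, moxGFP = 1.47).
#' @return a `fluor_standard` list.
#' @export
fluor_standard <- function(name = "GFP-Nup133", copies_per_standard = 16,
                           relative_brightness_vs_gfp = 1) {
  if (copies_per_standard <= 0) stop("copies_per_standard must be > 0")
  if (relative_brightness_vs_gfp <= 0)
    stop("relative_brightness_vs_gfp must be > 0")
  structure(list(name = name, copies_per_standard = copies_per_standard,
                 relative_brightness_vs_gfp = relative_brightness_vs_gfp),
            class = "fluor_standard")
}

#' Estimate fluorophore copy number from ROI intensities
#'
#' `copies = (copies_per_standard / relative_brightness) * i_punctum /
#' i_nup`: with the 16-copy GFP standard this is `16 * I_punctum / I_Nup`,
#' and for a moxGFP fusion `16 / 1.47 ~ 10.9 * I_punctum / I_Nup`. Both ROI
#' intensities must be background-subtracted totals acquired under
#' identical imaging conditions.
#'
#' @param i_punctum background-subtracted total ROI intensity of the
#'   punctum (>= 0).
#' @param i_nup standard's background-subtracted total ROI intensity (> 0).
#' @param standard a [fluor_standard].
#' @param punctum_id identifier carried into the record.
#' @return a `copy_number_record` list: `punctum_id`, `i_punctum`, `i_nup`,
#'   `copies`, `standard`.
#' @export
estimate_copies <- function(i_punctum, i_nup, standard = fluor_standard(),
                            punctum_id = "punctum") {
  stopifnot(inherits(standard, "fluor_standard"))
  if (!is.finite(i_nup) || i_nup <= 0)
    stop("i_nup must be > 0 (measure the standard first)")
  if (!is.finite(i_punctum) || i_punctum < 0)
    stop("i_punctum must be >= 0; background subtraction should have ",
         "clamped negative totals")
  copies <- (standard$copies_per_standard /
               standard$relative_brightness_vs_gfp) * i_punctum / i_nup
  structure(list(punctum_id = punctum_id, i_punctum = i_punctum,
                 i_nup = i_nup, copies = copies, standard = standard$name),
            class = "copy_number_record")
}

#' Calibrate the fluorescence standard from pore images
#'
#' Measures the background-corrected total ROI intensity of each standard
#' particle (nuclear pore) via [roi_total_intensity()] and aggregates to
#' mean, SEM and n; the mean serves as `I_Nup` downstream. A hash of the
#' acquisition settings is recorded so that a mismatch with the punctum
#' measurements (which must use identical imaging conditions) is
#' detectable.
#'
#' @param pore_images list of [mc_image] (or matrix) pore crops, or one
#'   image with a list of centers.
#' @param centers list/matrix of `(x, y)` ROI centers, one per pore; when
#'   `NULL` each image's brightest-channel centroid is used.
#' @param roi_radius_px ROI radius, px.
#' @param bg_annulus background annulus `(inner, outer)` radii, px.
#' @param channel channel to measure (default: first).
#' @param acquisition config list describing the imaging settings; only
#'   hashed for provenance.
#' @return list with `i_nup` (mean), `sem`, `n`, `per_pore`,
#'   `acquisition_hash`.
#' @export
calibrate_standard <- function(pore_images, centers = NULL,
                               roi_radius_px = 5,
                               bg_annulus = roi_radius_px * c(1.5, 2.5),
                               channel = NULL, acquisition = list()) {
  if (is_mc_image(pore_images) || is.matrix(pore_images))
    pore_images <- list(pore_images)
  n <- length(pore_images)
  if (n == 0L) stop("no pore images supplied")
  vals <- vapply(seq_len(n), function(i) {
    img <- pore_images[[i]]
    m <- if (is_mc_image(img))
      get_channel(img, channel %||% names(img$channels)[1]) else img
    ctr <- if (!is.null(centers)) unlist(centers[[i]])
           else center_of_mass(m)
    roi_total_intensity(m, ctr, roi_radius_px, bg_annulus)
  }, numeric(1))
  if (all(vals <= 0)) stop("no measurable pores (all ROI totals are zero)")
  list(i_nup = mean(vals),
       sem = if (n >= 2) stats::sd(vals) / sqrt(n) else NA_real_,
       n = n, per_pore = vals,
       acquisition_hash = acquisition_hash(acquisition))
}

# order-independent digest of an acquisition-settings list; deliberately a
# plain checksum, only used to detect mismatched imaging conditions
acquisition_hash <- function(settings) {
  if (length(settings) == 0L) return("unspecified")
  s <- jsonlite::toJSON(settings[order(names(settings))], auto_unbox = TRUE)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_len(nchar(as.character(s))) %% 31 + 1)) %%
            0xFFFFFFFF)
}
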