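#' Axial localization quotient (LQ)
#'
#' The LQ places a marker along the cis-to-trans axis of a Golgi
#' mini-stack, defined by the centers of fluorescence mass of GM130 (cis,
#' LQ = 0 by definition) and GalT (trans, LQ = 1 by definition): the scalar
#' projection of the marker's displacement from GM130 onto the GM130-to-GalT
#' axis, divided by the squared axis length,
#' `lq = ((x - gm130) . (galt - gm130)) / |galt - gm130|^2`.
#'
#' Records whose reference axis is shorter than `min_axis_px` are rejected
#' (short axes amplify centroid noise); LQs outside `plausible` are flagged
#' but kept.
#'
#' @param x,gm130,galt numeric `(x, y)` centroids of the marker, the cis
#'   reference and the trans reference.
#' @param min_axis_px minimum admissible GM130-to-GalT distance, px
#'   (default 3).
#' @param plausible numeric `(lo, hi)` window outside which an LQ is
#'   flagged (default `c(-3, 3)`).
#' @param stack_id identifier carried into the record.
#' @return an `lq_record` list: `stack_id`, `lq`, `axis_length_px`,
#'   `accepted`, `flagged`, `reason`.
#' @export
compute_lq <- function(x, gm130, galt, min_axis_px = 3,
                       plausible = c(-3, 3), stack_id = "stack") {
  stopifnot(length(x) == 2, length(gm130) == 2, length(galt) == 2,
            all(is.finite(c(x, gm130, galt))))
  axis <- c(galt[1] - gm130[1], galt[2] - gm130[2])
  len <- sqrt(sum(axis^2))
  if (len < min_axis_px) {
    return(structure(list(stack_id = stack_id, lq = NA_real_,
                          axis_length_px = len, accepted = FALSE,
                          flagged = FALSE,
                          reason = sprintf("axis %.2f px < min_axis %.2f px",
                                           len, min_axis_px)),
                     class = "lq_record"))
  }
  disp <- c(x[1] - gm130[1], x[2] - gm130[2])
  # divide by sum(axis^2) rather than len^2 so the definitional anchors
  # (marker at gm130 -> 0, marker at galt -> 1) are exact in floating point
  lq <- sum(disp * axis) / sum(axis * axis)
  flagged <- lq < plausible[1] || lq > plausible[2]
  structure(list(stack_id = stack_id, lq = lq, axis_length_px = len,
                 accepted = TRUE, flagged = flagged,
                 reason = if (flagged)
                   sprintf("lq %.2f outside [%g, %g]", lq, plausible[1],
                           plausible[2]) else NA_character_),
            class = "lq_record")
}

#' Compute LQ records for a set of side-view mini-stacks
#'
#' Convenience wrapper: takes per-stack images containing the marker, the
#' cis reference and the trans reference channels, computes the three
#' centers of fluorescence mass and the LQ per stack.
#'
#' @param images list of [mc_image] objects (one per mini-stack).
#' @param marker,cis,trans channel names (defaults `"marker"`, `"gm130"`,
#'   `"galt"`).
#' @param ... passed to [compute_lq()].
#' @return list of `lq_record`s.
#' @export
lq_from_images <- function(images, marker = "marker", cis = "gm130",
                           trans = "galt", ...) {
  stopifnot(length(images) >= 1)
  lapply(seq_along(images), function(i) {
    img <- images[[i]]
    compute_lq(center_of_mass(get_channel(img, marker)),
               center_of_mass(get_channel(img, cis)),
               center_of_mass(get_channel(img, trans)),
               stack_id = sprintf("stack%04d", i), ...)
  })
}

#' Summarize LQ records
#'
#' Mean, SEM (`sd/sqrt(n)`) and n over accepted records, in the shape of an
#' LQ summary table row (Name, LQ, N, SEM); rejected records are counted
#' separately.
#'
#' @param records list of `lq_record` objects.
#' @param channel label for the summarized marker.
#' @return one-row data.frame: `channel`, `lq`, `n`, `sem`, `n_rejected`,
#'   `n_flagged`.
#' @export
summarize_lq <- function(records, channel = "marker") {
  if (inherits(records, "lq_record")) records <- list(records)
  stopifnot(all(vapply(records, inherits, logical(1), "lq_record")))
  acc <- vapply(records, `[[`, logical(1), "accepted")
  if (!any(acc)) stop("no accepted LQ records to summarize")
  lqs <- vapply(records[acc], `[[`, numeric(1), "lq")
  n <- length(lqs)
  data.frame(channel = channel, lq = mean(lqs), n = n,
             sem = if (n >= 2) stats::sd(lqs) / sqrt(n) else NA_real_,
             n_rejected = sum(!acc),
             n_flagged = sum(vapply(records[acc], `[[`, logical(1),
                                    "flagged")))
}
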