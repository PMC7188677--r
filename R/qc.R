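#' Convert an RGB (or grayscale) image to 8-bit grayscale
#'
#' Three-channel input is reduced by the unweighted channel mean (the
#' illumination is monochromatic laser light, so luminance weighting would be
#' arbitrary), then rounded and clipped to integer gray levels 0--255.
#' Already-grayscale 8-bit input passes through unchanged.
#'
#' @param image A numeric matrix (grayscale) or `height x width x 3` array.
#' @return An integer-valued matrix of gray levels in 0--255.
#' @export
rgb_to_gray8 <- function(image) {
  if (is.matrix(image)) {
    g <- image
  } else if (is.array(image) && length(dim(image)) == 3L) {
    nch <- dim(image)[3L]
    if (nch == 1L) {
      g <- image[, , 1L]
    } else if (nch == 3L) {
      g <- (image[, , 1L] + image[, , 2L] + image[, , 3L]) / 3
    } else {
      abort(sprintf("Unsupported channel count: %d (expect 1 or 3).", nch))
    }
  } else {
    abort("`image` must be a matrix or a 3-D array.")
  }
  round(pmin(pmax(g, 0), 255))
}

#' Exposure-validity mask
#'
#' Marks the pixels whose gray values carry quantifiable speckle information:
#' under-sampled pixels (gray value at or below `lower`, complete loss of
#' signal at insufficient laser power) and over-exposed pixels (gray value at
#' `upper`, saturated) are excluded. The mask is true where
#' `lower < I < upper`.
#'
#' @param frame An 8-bit grayscale frame (matrix).
#' @param lower,upper Gray-level thresholds (defaults 20 and 255).
#' @return A `validity_mask`: a logical matrix with the thresholds attached.
#' @export
validity_mask <- function(frame, lower = 20, upper = 255) {
  if (lower >= upper) abort("`lower` must be below `upper`.")
  if (lower < 0 || upper > 255) abort("Thresholds must lie within 0--255.")
  m <- frame > lower & frame < upper
  structure(m, lower = lower, upper = upper, class = c("validity_mask", "matrix"))
}

#' Validity mask for a whole stack
#'
#' Applies [validity_mask()] to the temporal mean frame, so the mask reflects
#' the illumination level of each pixel rather than single-frame speckle
#' excursions.
#'
#' @param stack A [speckle_stack()].
#' @inheritParams validity_mask
#' @return A `validity_mask`.
#' @export
stack_validity_mask <- function(stack, lower = 20, upper = 255) {
  validity_mask(apply(stack$frames, c(1, 2), mean), lower, upper)
}

#' Fraction of the field of view with quantifiable speckle
#'
#' @param mask A [validity_mask()] (or logical matrix).
#' @return The fraction of true pixels, in `[0, 1]`.
#' @export
resolved_fraction <- function(mask) {
  if (length(mask) == 0L) abort("`mask` must be non-empty.")
  mean(mask)
}

#' Reject motion-blurred frames
#'
#' Within-frame motion smears the speckle pattern and suppresses its spatial
#' contrast, so the whole-frame spatial speckle contrast (population sigma over
#' mean, masked pixels excluded) serves as a per-frame sharpness metric.
#' Frames whose metric falls below `rel_threshold` times the stack median are
#' rejected; the order of retained frames is preserved.
#'
#' @param stack A [speckle_stack()] with at least 3 frames.
#' @param rel_threshold Rejection cutoff as a fraction of the median metric.
#' @param mask Optional [validity_mask()]; invalid pixels are ignored.
#' @return A `qc_report`: retained/rejected indices, per-frame metric values,
#'   and the absolute threshold used. `tidy()` gives one row per frame.
#' @export
reject_motion_frames <- function(stack, rel_threshold = 0.5, mask = NULL) {
  nf <- n_frames(stack)
  if (nf < 3L) abort("Need at least 3 frames for motion QC.")
  keep <- if (is.null(mask)) TRUE else as.logical(mask)
  metric <- vapply(seq_len(nf), function(f) {
    v <- stack$frames[, , f][keep]
    m <- mean(v)
    if (m <= 0) return(0)
    sqrt(mean((v - m)^2)) / m
  }, numeric(1))
  threshold <- rel_threshold * median(metric)
  retained <- which(metric >= threshold)
  rejected <- setdiff(seq_len(nf), retained)
  if (length(retained) == 0L) {
    abort("All frames rejected; review `rel_threshold` or the input stack.")
  }
  structure(
    list(retained_indices = retained, rejected_indices = rejected,
         metric_values = metric, threshold_used = threshold,
         rel_threshold = rel_threshold),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d retained, %d rejected (metric < %.4g)\n",
              length(x$retained_indices), length(x$rejected_indices),
              x$threshold_used))
  invisible(x)
}

#' @rdname reject_motion_frames
#' @param x A `qc_report`.
#' @param ... Unused.
#' @export
tidy.qc_report <- function(x, ...) {
  nf <- length(x$metric_values)
  tibble(frame = seq_len(nf), metric = x$metric_values,
         retained = seq_len(nf) %in% x$retained_indices)
}

#' Apply a QC report to a stack
#'
#' @param stack A [speckle_stack()].
#' @param report A `qc_report` from [reject_motion_frames()].
#' @return The stack restricted to retained frames.
#' @export
apply_qc <- function(stack, report) keep_frames(stack, report$retained_indices)
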