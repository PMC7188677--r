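#' Speckle frame stacks
#'
#' A `speckle_stack` is a time-ordered stack of co-registered speckle frames
#' together with the acquisition metadata every downstream stage needs: the
#' camera exposure duration (the `T` of the speckle correlation model) and the
#' frame rate. Frames are stored as a `height x width x n_frames` numeric
#' array of gray levels (0--255 once 8-bit).
#'
#' @param frames Numeric array with dimensions `c(height, width, n_frames)`,
#'   or a matrix for a single frame.
#' @param exposure_T Exposure duration in seconds (> 0).
#' @param frame_rate Acquisition rate in frames per second.
#' @param meta Named list of free-form provenance (seed, ground-truth fields,
#'   blurred frame indices, ...).
#' @return An object of class `speckle_stack`.
#' @export
speckle_stack <- function(frames, exposure_T, frame_rate = 24, meta = list()) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    abort("`frames` must be a height x width x n_frames array.")
  }
  if (!is.numeric(exposure_T) || length(exposure_T) != 1L || exposure_T <= 0) {
    abort("`exposure_T` must be a single positive number (seconds).")
  }
  structure(
    list(frames = frames, exposure_T = exposure_T, frame_rate = frame_rate,
         meta = meta),
    class = "speckle_stack"
  )
}

#' @export
print.speckle_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<speckle_stack> %d x %d px, %d frames, exposure %.4g ms\n",
              d[1], d[2], d[3], 1e3 * x$exposure_T))
  invisible(x)
}

#' @export
dim.speckle_stack <- function(x) dim(x$frames)

#' Number of frames in a stack
#' @param stack A [speckle_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3L]

#' Subset a stack to selected frames
#'
#' Keeps the listed frames (in the given order) and records the selection in
#' the stack metadata, so downstream stages can prove they never consumed a
#' rejected frame.
#'
#' @param stack A [speckle_stack()].
#' @param indices Frame indices to retain (1-based).
#' @return A [speckle_stack()] with only the selected frames.
#' @export
keep_frames <- function(stack, indices) {
  nf <- n_frames(stack)
  if (any(indices < 1L | indices > nf)) abort("Frame indices out of range.")
  stack$frames <- stack$frames[, , indices, drop = FALSE]
  stack$meta$retained_indices <- as.integer(indices)
  stack
}

#' Per-pixel decorrelation-time fields
#'
#' A `tau_field` is a 2-D grid of decorrelation times \eqn{\tau_c} in seconds.
#' Finite values must be strictly positive; `Inf` marks static regions (no
#' motion, infinitely slow decorrelation).
#'
#' @param values Numeric matrix of decorrelation times (seconds).
#' @return A matrix of class `tau_field`.
#' @export
tau_field <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (any(is.na(values)) || any(values[is.finite(values)] <= 0)) {
    abort("All finite decorrelation times must be strictly positive.")
  }
  structure(values, class = c("tau_field", "matrix"))
}

#' @export
print.tau_field <- function(x, ...) {
  v <- x[is.finite(x)]
  cat(sprintf("<tau_field> %d x %d px; finite tau_c %.4g--%.4g ms; %.1f%% static\n",
              nrow(x), ncol(x),
              if (length(v)) 1e3 * min(v) else NA, if (length(v)) 1e3 * max(v) else NA,
              100 * mean(!is.finite(x))))
  invisible(x)
}
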