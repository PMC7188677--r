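#' Construct a contrast map from a K matrix
#'
#' Mostly useful for building maps from model-derived K values; the
#' processing schemes ([spatial_contrast()], [temporal_contrast()],
#' [noise_reduced_contrast()]) construct their maps directly.
#'
#' @param K Matrix of speckle contrast values (dimensionless, >= 0).
#' @param exposure_T Exposure duration in seconds.
#' @param scheme Provenance label.
#' @param valid Optional logical validity matrix (default: finite K).
#' @param window,n_frames_used Optional provenance fields.
#' @return A `contrast_map`.
#' @export
contrast_map <- function(K, exposure_T = NA_real_, scheme = "synthetic",
                         valid = NULL, window = NA_integer_,
                         n_frames_used = NA_integer_) {
  valid <- valid %||% is.finite(K)
  new_contrast_map(K, valid, scheme, window = window,
                   n_frames_used = n_frames_used, exposure_T = exposure_T)
}

new_contrast_map <- function(K, valid, scheme, window = NA_integer_,
                             n_frames_used = NA_integer_, exposure_T = NA_real_) {
  K[!valid] <- NA_real_
  structure(
    list(K = K, K_squared = K * K, valid = valid, scheme = scheme,
         window = window, n_frames_used = n_frames_used,
         exposure_T = exposure_T),
    class = "contrast_map"
  )
}

#' @export
print.contrast_map <- function(x, ...) {
  cat(sprintf("<contrast_map> %s, %d x %d px, exposure %.4g ms, mean K = %.4g\n",
              x$scheme, nrow(x$K), ncol(x$K), 1e3 * x$exposure_T,
              mean(x$K[x$valid], na.rm = TRUE)))
  invisible(x)
}

#' @export
as_tibble.contrast_map <- function(x, ...) {
  tibble(row = rep(seq_len(nrow(x$K)), ncol(x$K)),
         col = rep(seq_len(ncol(x$K)), each = nrow(x$K)),
         K = as.numeric(x$K), K_squared = as.numeric(x$K_squared),
         valid = as.logical(x$valid))
}

as_valid_matrix <- function(mask, dm) {
  if (is.null(mask)) return(matrix(TRUE, dm[1], dm[2]))
  m <- unclass(mask)
  attributes(m) <- list(dim = dim(mask))
  if (!all(dim(m) == dm)) abort("Mask shape must match the frame shape.")
  m
}

#' Spatial speckle contrast of a single frame
#'
#' At each pixel, \eqn{K = \sigma / \langle I \rangle} over the
#' `window x window` neighborhood, restricted to valid in-bounds pixels
#' (shrink-to-valid border: no padded intensities ever enter the statistic).
#' \eqn{\sigma} is the population (divide-by-N) standard deviation, matching
#' the moment-ratio definition of contrast. Pixels whose neighborhood holds
#' fewer than `window^2 / 2` valid members, whose mean intensity is zero, or
#' that are themselves masked, are marked invalid.
#'
#' @param frame A numeric matrix of speckle intensities (nonnegative).
#' @param window Odd window size in pixels (default 5).
#' @param mask Optional [validity_mask()].
#' @param exposure_T Exposure duration in seconds, recorded in the map.
#' @return A `contrast_map` (fields `K`, `K_squared`, `valid`, provenance).
#' @export
spatial_contrast <- function(frame, window = 5L, mask = NULL,
                             exposure_T = NA_real_) {
  if (window %% 2L == 0L || window < 3L) {
    abort("`window` must be an odd integer >= 3.")
  }
  valid <- as_valid_matrix(mask, dim(frame))
  res <- spatial_contrast_cpp(frame, valid, as.integer(window))
  ok <- valid & res$count >= window^2 / 2 & !is.na(res$K)
  new_contrast_map(res$K, ok, "spatial", window = as.integer(window),
                   exposure_T = exposure_T)
}

#' Temporal speckle contrast of a stack
#'
#' Per pixel, \eqn{K = \sigma / \langle I \rangle} across the selected frames
#' (population \eqn{\sigma}), trading temporal resolution for full spatial
#' resolution. Pixels that are masked or have zero mean are invalid.
#'
#' @param stack A [speckle_stack()].
#' @param frames Frame indices to use (default: all; a warning is issued
#'   outside the usual 40--80 frame range).
#' @param mask Optional [validity_mask()].
#' @return A `contrast_map`.
#' @export
temporal_contrast <- function(stack, frames = NULL, mask = NULL) {
  frames <- frames %||% seq_len(n_frames(stack))
  if (length(frames) < 2L) abort("Need at least 2 frames for temporal contrast.")
  if (length(frames) < 40L || length(frames) > 80L) {
    warn(sprintf("Temporal contrast typically uses 40--80 frames; got %d.",
                 length(frames)))
  }
  dm <- dim(stack$frames)[1:2]
  M <- matrix(stack$frames[, , frames], nrow = prod(dm))
  mu <- rowMeans(M)
  sdp <- sqrt(rowMeans((M - mu)^2))
  K <- matrix(ifelse(mu > 0, sdp / mu, NA_real_), dm[1], dm[2])
  valid <- as_valid_matrix(mask, dm) & matrix(mu > 0, dm[1], dm[2])
  new_contrast_map(K, valid, "temporal", n_frames_used = length(frames),
                   exposure_T = stack$exposure_T)
}

#' Noise-reduced speckle contrast
#'
#' Each selected frame is spatially processed ([spatial_contrast()]) and the
#' per-pixel mean of the per-frame K maps is taken; `K_squared` is the square
#' of that mean. Averaging many independent spatially processed frames
#' suppresses the sampling noise of the small-window estimate while retaining
#' single-frame spatial statistics.
#'
#' @param stack A [speckle_stack()].
#' @param window Odd spatial window size (default 5).
#' @param frames Frame indices (default: all; warns below 80 frames).
#' @param mask Optional [validity_mask()].
#' @param average One of `"K"` (default: average K maps, then square) or
#'   `"K2"` (average per-frame K-squared maps).
#' @return A `contrast_map`.
#' @export
noise_reduced_contrast <- function(stack, window = 5L, frames = NULL,
                                   mask = NULL, average = c("K", "K2")) {
  average <- match.arg(average)
  frames <- frames %||% seq_len(n_frames(stack))
  if (length(frames) == 0L) abort("No frames selected.")
  if (length(frames) < 80L) {
    warn(sprintf("Noise-reduced contrast typically averages >= 80 frames; got %d.",
                 length(frames)))
  }
  dm <- dim(stack$frames)[1:2]
  acc <- matrix(0, dm[1], dm[2])
  cnt <- matrix(0L, dm[1], dm[2])
  valid_any <- matrix(FALSE, dm[1], dm[2])
  win <- NA_integer_
  for (f in frames) {
    cm <- spatial_contrast(stack$frames[, , f], window, mask,
                           exposure_T = stack$exposure_T)
    win <- cm$window
    ok <- cm$valid & !is.na(cm$K)
    v <- if (average == "K") cm$K else cm$K_squared
    acc[ok] <- acc[ok] + v[ok]
    cnt[ok] <- cnt[ok] + 1L
    valid_any <- valid_any | ok
  }
  mean_map <- ifelse(cnt > 0, acc / cnt, NA_real_)
  K <- if (average == "K") mean_map else sqrt(mean_map)
  out <- new_contrast_map(K, valid_any, "noise_reduced", window = win,
                          n_frames_used = length(frames),
                          exposure_T = stack$exposure_T)
  if (average == "K2") out$K_squared <- ifelse(valid_any, mean_map, NA_real_)
  out
}
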