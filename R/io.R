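sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yaml")

#' Write a speckle stack to disk
#'
#' Frames go to a multi-page 8-bit grayscale TIFF; acquisition metadata
#' (exposure in ms, frame rate, frame count, seed, blurred-frame indices) to a
#' YAML sidecar next to it, so the exposure survives any TIFF dialect.
#'
#' @param stack A [speckle_stack()] (frames within 0--255).
#' @param path Output TIFF path; the sidecar is written as `<path>.yaml`
#'   (extension swapped).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  nf <- n_frames(stack)
  frames <- lapply(seq_len(nf), function(f) {
    round(pmin(pmax(stack$frames[, , f], 0), 255)) / 255
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 8L)
  meta <- list(exposure_ms = 1e3 * stack$exposure_T,
               frame_rate = stack$frame_rate,
               n_frames = nf,
               seed = stack$meta$seed,
               blurred_indices = stack$meta$blurred_indices)
  yaml::write_yaml(meta[!vapply(meta, is.null, logical(1))], sidecar_path(path))
  invisible(path)
}

#' Read a speckle stack from disk
#'
#' Reads a multi-page TIFF (RGB pages are converted to 8-bit grayscale via
#' [rgb_to_gray8()]) and its metadata. Exposure duration is taken from the
#' YAML sidecar or the `exposure_ms` argument; fitting is meaningless without
#' it, so a missing exposure is a hard error.
#'
#' @param path TIFF path.
#' @param metadata_path Sidecar path (default: `<path>.yaml`).
#' @param exposure_ms Exposure in milliseconds, overriding the sidecar.
#' @return A [speckle_stack()].
#' @export
read_stack <- function(path, metadata_path = NULL, exposure_ms = NULL) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  grays <- lapply(pages, rgb_to_gray8)
  dms <- vapply(grays, dim, integer(2))
  if (any(dms[1, ] != dms[1, 1]) || any(dms[2, ] != dms[2, 1])) {
    abort("Inconsistent page shapes in TIFF stack.")
  }
  meta <- list()
  mp <- metadata_path %||% sidecar_path(path)
  if (file.exists(mp)) meta <- yaml::read_yaml(mp)
  exposure_ms <- exposure_ms %||% meta$exposure_ms
  if (is.null(exposure_ms)) {
    abort("Exposure duration unavailable: provide `exposure_ms` or a sidecar.")
  }
  frames <- array(unlist(grays), dim = c(dms[1, 1], dms[2, 1], length(grays)))
  speckle_stack(frames, exposure_ms / 1e3,
                frame_rate = meta$frame_rate %||% NA_real_,
                meta = list(blurred_indices = meta$blurred_indices,
                            seed = meta$seed, source = path, quantized = TRUE))
}

#' Write a 2-D float map (contrast or inverse-tau) to disk
#'
#' 32-bit float TIFF storage is defined on `[0, 1]`, so values are stored
#' divided by a scale factor recorded in the YAML sidecar (along with scheme
#' and provenance); [read_map()] restores the original values. `NA` pixels
#' are stored as 0 with a validity page alongside.
#'
#' @param map A `contrast_map`, `inv_tau_map`, or numeric matrix.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  if (inherits(map, "contrast_map")) {
    values <- map$K; valid <- map$valid
    meta <- list(kind = "contrast", scheme = map$scheme, window = map$window,
                 n_frames_used = map$n_frames_used,
                 exposure_ms = 1e3 * map$exposure_T)
  } else if (inherits(map, "inv_tau_map")) {
    values <- map$inv_tau; valid <- map$valid
    meta <- list(kind = "inv_tau", exposure_ms = 1e3 * map$exposure_T,
                 assumed = map$assumed)
  } else {
    values <- map; valid <- is.finite(map)
    meta <- list(kind = "matrix")
  }
  sc <- max(values[valid & is.finite(values)], 1e-12)
  stored <- values / sc
  stored[!is.finite(stored)] <- 0
  stored <- pmin(pmax(stored, 0), 1)
  tiff::writeTIFF(list(stored, valid * 1), path, bits.per.sample = 32L)
  meta$scale <- sc
  meta <- meta[!vapply(meta, function(x) is.null(x) ||
                         (length(x) == 1 && is.na(x)), logical(1))]
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' @rdname write_map
#' @return `read_map()`: a list with `values` (NA where invalid), `valid`,
#'   and the sidecar `meta`.
#' @export
read_map <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- yaml::read_yaml(sidecar_path(path))
  values <- pages[[1]] * meta$scale
  valid <- pages[[2]] > 0.5
  values[!valid] <- NA_real_
  list(values = values, valid = valid, meta = meta)
}
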