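#' Simulation configuration
#'
#' Bundles the acquisition and detector parameters of the dynamic-speckle
#' forward model. Defaults emulate an 8-bit CCD operated so that the mean
#' speckle intensity sits well below saturation (speckle highlights reach
#' several times the mean, so a mean near a quarter of full range keeps
#' clipping rare).
#'
#' @param exposure_T Exposure duration in seconds (> 0).
#' @param n_frames Number of frames to record (>= 1).
#' @param substeps_per_exposure Number of field-evolution substeps spanning one
#'   exposure, or `NULL` to choose automatically: 20 substeps per
#'   `min(exposure_T, min(tau_c))`, so the substep duration is at most
#'   `min(tau_c)/20` and integration error is negligible.
#' @param rho Dynamic-light fraction \eqn{\rho \in [0,1]}: scalar or matrix the
#'   shape of the tau field. `1` means all detected light is dynamically
#'   scattered; `0` a purely static scatterer.
#' @param mean_intensity Target mean gray level (0--255 scale).
#' @param noise_floor Additive Gaussian detector-noise standard deviation in
#'   gray levels.
#' @param seed Optional RNG seed; when set, simulation is bit-reproducible.
#' @param quantize Clip to `[0, 255]` and round to integer gray levels
#'   (camera emulation). Turn off when checking statistical oracles.
#' @param frame_rate Frames per second recorded in the stack metadata.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(exposure_T, n_frames = 80L, substeps_per_exposure = NULL,
                       rho = 1, mean_intensity = 60, noise_floor = 0,
                       seed = NULL, quantize = TRUE, frame_rate = 24) {
  if (!is.numeric(exposure_T) || length(exposure_T) != 1L || exposure_T <= 0) {
    abort("`exposure_T` must be a single positive number of seconds.")
  }
  if (n_frames < 1L) abort("`n_frames` must be at least 1.")
  if (any(rho < 0 | rho > 1)) abort("`rho` must lie in [0, 1].")
  if (noise_floor < 0) abort("`noise_floor` must be nonnegative.")
  structure(
    list(exposure_T = exposure_T, n_frames = as.integer(n_frames),
         substeps_per_exposure = substeps_per_exposure, rho = rho,
         mean_intensity = mean_intensity, noise_floor = noise_floor,
         seed = seed, quantize = quantize, frame_rate = frame_rate),
    class = "sim_config"
  )
}

default_substeps <- function(exposure_T, tau) {
  fin <- tau[is.finite(tau)]
  if (length(fin) == 0L) return(1L)
  # substep duration <= min(T, tau_c)/20
  as.integer(ceiling(20 * max(1, exposure_T / min(fin))))
}

#' Simulate a dynamic-speckle stack
#'
#' Forward model of exposure-integrated dynamic speckle. Per pixel, a complex
#' circular-Gaussian field decorrelates exponentially with the pixel's
#' \eqn{\tau_c} (field autocorrelation \eqn{e^{-t/\tau_c}}, first-order
#' autoregressive update across substeps); dynamic and static components mix
#' with amplitudes \eqn{\sqrt{\rho}} and \eqn{\sqrt{1-\rho}}; the recorded
#' intensity is the substep-mean of the squared field magnitude over one
#' exposure, scaled to the target mean gray level, plus detector noise, then
#' optionally clipped and quantized to 8 bits. Frames are statistically
#' independent realizations of the dynamic field; the static field (and pixels
#' with `tau = Inf`) are drawn once per stack, so purely static scenes are
#' constant across frames. Pixels are mutually independent (fully developed
#' speckle, one speckle per pixel), so the expected spatial \eqn{K^2} follows
#' the speckle correlation model ([model_k_squared()]) with \eqn{\beta = 1}.
#'
#' @param tau A [tau_field()] (or numeric matrix) of decorrelation times in
#'   seconds; `Inf` marks static pixels.
#' @param cfg A [sim_config()]. `cfg$rho` must be a scalar or match `dim(tau)`.
#' @return A [speckle_stack()] carrying the ground truth (`tau`, `rho`, seed)
#'   in its metadata.
#' @export
simulate_stack <- function(tau, cfg) {
  if (!inherits(cfg, "sim_config")) abort("`cfg` must be a sim_config().")
  if (!is.matrix(tau)) abort("`tau` must be a matrix (tau_field).")
  tau <- tau_field(unclass(tau))
  rho <- cfg$rho
  if (length(rho) == 1L) rho <- matrix(rho, nrow(tau), ncol(tau))
  if (!all(dim(rho) == dim(tau))) {
    abort("`rho` field shape must match the tau field shape.")
  }
  nsub <- cfg$substeps_per_exposure %||% default_substeps(cfg$exposure_T, tau)
  dt <- cfg$exposure_T / nsub

  run <- function() {
    raw <- sim_stack_cpp(as.numeric(tau), as.numeric(rho),
                         cfg$n_frames, nsub, dt, cfg$mean_intensity)
    frames <- array(raw, dim = c(nrow(tau), ncol(tau), cfg$n_frames))
    if (cfg$noise_floor > 0) {
      frames <- frames + array(rnorm(length(frames), sd = cfg$noise_floor),
                               dim = dim(frames))
    }
    if (isTRUE(cfg$quantize)) frames <- round(pmin(pmax(frames, 0), 255))
    frames
  }
  frames <- if (is.null(cfg$seed)) run() else withr::with_seed(cfg$seed, run())

  speckle_stack(frames, cfg$exposure_T, cfg$frame_rate,
                meta = list(tau = tau, rho = rho, seed = cfg$seed,
                            substeps = nsub, quantized = isTRUE(cfg$quantize),
                            noise_floor = cfg$noise_floor,
                            mean_intensity = cfg$mean_intensity))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inject directional motion blur into selected frames
#'
#' Convolves the listed frames with a normalized horizontal box kernel of the
#' given extent, emulating the within-frame smearing caused by respiratory or
#' saccadic motion during an exposure. All other frames are untouched and the
#' ground-truth blurred indices are recorded in the stack metadata, so
#' motion-rejection QC can be scored against truth.
#'
#' @param stack A [speckle_stack()].
#' @param frame_indices Frames to blur (1-based). Empty vector is a no-op.
#' @param blur_px Kernel extent in pixels (> 0).
#' @return The blurred [speckle_stack()], with `meta$blurred_indices` set.
#' @export
inject_motion_blur <- function(stack, frame_indices, blur_px = 8) {
  if (blur_px <= 0) abort("`blur_px` must be positive.")
  nf <- n_frames(stack)
  frame_indices <- as.integer(frame_indices)
  if (any(frame_indices < 1L | frame_indices > nf)) {
    abort("`frame_indices` out of range.")
  }
  L <- max(2L, as.integer(round(blur_px)))
  quantized <- isTRUE(stack$meta$quantized)
  for (f in frame_indices) {
    fr <- stack$frames[, , f]
    blurred <- t(apply(fr, 1L, running_mean, width = L))
    if (quantized) blurred <- round(pmin(pmax(blurred, 0), 255))
    stack$frames[, , f] <- blurred
  }
  stack$meta$blurred_indices <-
    sort(unique(c(stack$meta$blurred_indices, frame_indices)))
  stack
}

# moving average with edge shrink (kernel renormalized over in-bounds support)
running_mean <- function(x, width) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  h1 <- (width - 1L) %/% 2L
  h2 <- width - 1L - h1
  lo <- pmax(1L, seq_len(n) - h1)
  hi <- pmin(n, seq_len(n) + h2)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
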