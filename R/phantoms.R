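#' Capillary-tube flow phantom
#'
#' Builds synthetic multi-exposure speckle stacks emulating a microcapillary
#' perfused at a series of controlled flow rates: a rectangular tube region is
#' fully dynamic with a decorrelation time inversely proportional to flow rate
#' (scatterer speed scales with volumetric rate, and \eqn{\tau_c \propto 1/v}),
#' while the background is a static scatterer. One stack is generated per
#' (flow rate, exposure) pair.
#'
#' The absolute \eqn{\tau_c} scale is a free parameter (`tau_at_baseline`, the
#' decorrelation time at the lowest flow rate): only ratios of decorrelation
#' times are physically meaningful in the phantom.
#'
#' @param flow_rates Positive flow rates (uL/min). Defaults to the seven rates
#'   of a syringe-pump protocol: 10, 15, 20, 30, 50, 75, 100.
#' @param exposures Exposure durations in seconds. Defaults to
#'   4.96, 8.97, 15.43 and 27 ms.
#' @param tau_at_baseline Tube decorrelation time (seconds) at the lowest flow
#'   rate; tube \eqn{\tau_c(Q) = \tau_{baseline} Q_0 / Q}.
#' @param dim Image height and width in pixels.
#' @param tube_rows Row indices forming the tube; default the middle half.
#' @param n_frames Frames per stack (default 80).
#' @param seed Base RNG seed; stack `i` uses `seed + i` so stacks are
#'   reproducible and mutually independent.
#' @param mean_intensity,noise_floor,quantize Detector settings, see
#'   [sim_config()].
#' @return A tibble with one row per stack: `flow_rate`, `exposure_s`,
#'   `tau_tube_s`, and a `stack` list-column of [speckle_stack()]s. The tube
#'   pixel mask is attached as attribute `tube_mask`.
#' @export
make_capillary_phantom <- function(flow_rates = c(10, 15, 20, 30, 50, 75, 100),
                                   exposures = c(4.96, 8.97, 15.43, 27) / 1e3,
                                   tau_at_baseline = 15e-3,
                                   dim = c(32L, 48L), tube_rows = NULL,
                                   n_frames = 80L, seed = NULL,
                                   mean_intensity = 60, noise_floor = 2,
                                   quantize = TRUE) {
  if (length(flow_rates) == 0L || length(exposures) == 0L) {
    abort("`flow_rates` and `exposures` must be non-empty.")
  }
  if (any(flow_rates <= 0)) abort("Flow rates must be positive.")
  h <- dim[1]; w <- dim[2]
  tube_rows <- tube_rows %||% seq.int(floor(h / 4) + 1L, floor(3 * h / 4))
  tube <- matrix(FALSE, h, w)
  tube[tube_rows, ] <- TRUE
  q0 <- min(flow_rates)

  grid <- expand.grid(exposure_s = exposures, flow_rate = flow_rates)[, 2:1]
  stacks <- vector("list", nrow(grid))
  tau_tube <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    q <- grid$flow_rate[i]
    tau_tube[i] <- tau_at_baseline * q0 / q
    tf <- matrix(Inf, h, w)
    tf[tube] <- tau_tube[i]
    rho <- matrix(0, h, w)
    rho[tube] <- 1
    cfg <- sim_config(grid$exposure_s[i], n_frames = n_frames, rho = rho,
                      mean_intensity = mean_intensity,
                      noise_floor = noise_floor,
                      seed = if (is.null(seed)) NULL else seed + i,
                      quantize = quantize)
    stacks[[i]] <- simulate_stack(tau_field(tf), cfg)
  }
  out <- tibble(flow_rate = grid$flow_rate, exposure_s = grid$exposure_s,
                tau_tube_s = tau_tube, stack = stacks)
  attr(out, "tube_mask") <- tube
  out
}

#' Laminar-vessel decorrelation-time phantom
#'
#' Builds a [tau_field()] holding one or more horizontal vessels with laminar
#' (parabolic) flow profiles: inside a vessel of radius R centered on a row,
#' speed follows \eqn{v(r) = v_{center}(1 - (r/R)^2)} and the decorrelation
#' time is \eqn{\tau_c = \lambda / (2\pi v)}. The no-slip wall (zero speed) and
#' the background are static (`Inf`). Where vessels overlap the faster flow
#' (smaller \eqn{\tau_c}) wins.
#'
#' @param dim Image height and width in pixels.
#' @param vessels Data frame (or tibble) with columns `center_row`, `radius`
#'   (pixels, >= 2) and `center_speed` (m/s).
#' @param wavelength Laser wavelength in meters (default 640 nm, a red diode).
#' @return A [tau_field()].
#' @export
make_vessel_phantom <- function(dim, vessels, wavelength = 640e-9) {
  vessels <- as.data.frame(vessels)
  if (any(vessels$radius < 2)) abort("Vessel radii must be >= 2 px.")
  if (any(vessels$center_speed <= 0)) abort("Center speeds must be positive.")
  h <- dim[1]; w <- dim[2]
  tf <- matrix(Inf, h, w)
  rows <- seq_len(h)
  for (k in seq_len(nrow(vessels))) {
    r <- abs(rows - vessels$center_row[k])
    inside <- r < vessels$radius[k]
    v <- vessels$center_speed[k] * (1 - (r[inside] / vessels$radius[k])^2)
    tau <- ifelse(v > 0, wavelength / (2 * pi * v), Inf)
    tf[inside, ] <- pmin(tf[inside, ], tau)
  }
  tau_field(tf)
}
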