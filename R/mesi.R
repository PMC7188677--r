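#' Speckle correlation model parameters
#'
#' The four-parameter state of the multi-exposure speckle correlation model:
#' speckle-averaging factor \eqn{\beta \in (0, 1]} (detector/speckle size
#' mismatch and polarization), dynamic-light fraction \eqn{\rho \in [0, 1]},
#' decorrelation time \eqn{\tau_c > 0} (seconds), and the exposure-independent
#' variance floor \eqn{\upsilon_n \ge 0} (experimental noise plus the nonzero
#' nonergodic variance of static speckle).
#'
#' @param beta,rho,tau_c,upsilon_n Model parameters, see Description.
#' @return A list of class `mesi_params`.
#' @export
mesi_params <- function(beta = 1, rho = 1, tau_c, upsilon_n = 0) {
  if (beta <= 0 || beta > 1) abort("`beta` must lie in (0, 1].")
  if (rho < 0 || rho > 1) abort("`rho` must lie in [0, 1].")
  if (tau_c <= 0) abort("`tau_c` must be positive.")
  if (upsilon_n < 0) abort("`upsilon_n` must be nonnegative.")
  structure(list(beta = beta, rho = rho, tau_c = tau_c, upsilon_n = upsilon_n),
            class = "mesi_params")
}

# (e^{-2x} + 2x - 1)/(2x^2): time-integrated contrast of a field with
# autocorrelation e^{-t/tau_c} (intensity correlation e^{-2t/tau_c}).
# Series branch avoids catastrophic cancellation at small x.
bracket_dyn <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-6
  xs <- x[small]
  out[small] <- 1 - (2 / 3) * xs + (1 / 3) * xs^2 - (2 / 15) * xs^3
  xl <- x[!small]
  out[!small] <- (exp(-2 * xl) + 2 * xl - 1) / (2 * xl^2)
  out
}

# (e^{-x} + x - 1)/x^2: the static/dynamic heterodyne cross term; -> 1/2 at 0.
bracket_cross <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-6
  xs <- x[small]
  out[small] <- 1 / 2 - xs / 6 + xs^2 / 24 - xs^3 / 120
  xl <- x[!small]
  out[!small] <- (exp(-xl) + xl - 1) / xl^2
  out
}

#' Speckle correlation model: expected K-squared at one exposure
#'
#' Evaluates the multi-exposure speckle correlation model
#' \deqn{K^2(T) = \beta\rho^2 \frac{e^{-2x} + 2x - 1}{2x^2}
#'   + 4\beta\rho(1-\rho) \frac{e^{-x} + x - 1}{x^2} + \upsilon_n,
#'   \quad x = T/\tau_c,}
#' the exposure-time-integrated speckle variance of a field whose
#' autocorrelation decays as \eqn{e^{-t/\tau_c}}, with speckle averaging
#' \eqn{\beta}, a static-scatterer cross term weighted by the dynamic fraction
#' \eqn{\rho}, and a constant noise/nonergodic floor \eqn{\upsilon_n}. With
#' \eqn{\beta = \rho = 1, \upsilon_n = 0} it reduces to the simplified model
#' \eqn{K^2 = (e^{-2x} + 2x - 1)/(2x^2)}. A series expansion is used for
#' \eqn{x < 10^{-6}}, where the closed form loses all precision; both terms
#' approach their instantaneous-exposure limits (1 and 1/2), so
#' \eqn{K^2 \to \beta\rho(2-\rho) + \upsilon_n} as \eqn{x \to 0}.
#'
#' @param T Exposure duration(s) in seconds (> 0). Vectorized.
#' @param tau_c Decorrelation time in seconds (> 0). Vectorized.
#' @param beta,rho,upsilon_n Remaining model parameters (defaults 1, 1, 0).
#' @param params Optionally a [mesi_params()], overriding the scalars.
#' @return Expected \eqn{K^2} (dimensionless).
#' @export
model_k_squared <- function(T, tau_c, beta = 1, rho = 1, upsilon_n = 0,
                            params = NULL) {
  if (!is.null(params)) {
    beta <- params$beta; rho <- params$rho
    tau_c <- params$tau_c; upsilon_n <- params$upsilon_n
  }
  if (any(T <= 0)) abort("Exposure `T` must be positive.")
  if (any(tau_c <= 0)) abort("`tau_c` must be positive.")
  x <- T / tau_c
  beta * rho^2 * bracket_dyn(x) +
    4 * beta * rho * (1 - rho) * bracket_cross(x) + upsilon_n
}

#' Attainable K-squared ceiling of the model
#'
#' The supremum of [model_k_squared()] as exposure shrinks to zero:
#' \eqn{\beta\rho(2-\rho) + \upsilon_n}. Observed \eqn{K^2} values at or above
#' this ceiling carry no resolvable motion information.
#'
#' @inheritParams model_k_squared
#' @return The \eqn{x \to 0} limit of \eqn{K^2}.
#' @export
k_squared_ceiling <- function(beta = 1, rho = 1, upsilon_n = 0) {
  beta * rho * (2 - rho) + upsilon_n
}

# vectorized bisection for x = T/tau_c on log scale; K^2 strictly decreasing in x
invert_x <- function(k2, beta, rho, upsilon_n, lo = 1e-12, hi = 1e12,
                     iters = 100L) {
  f <- function(x) beta * rho^2 * bracket_dyn(x) +
    4 * beta * rho * (1 - rho) * bracket_cross(x) + upsilon_n
  llo <- rep(log(lo), length(k2))
  lhi <- rep(log(hi), length(k2))
  for (i in seq_len(iters)) {
    mid <- (llo + lhi) / 2
    too_high <- f(exp(mid)) > k2   # K^2 too high -> x too small -> move lo up
    llo[too_high] <- mid[too_high]
    lhi[!too_high] <- mid[!too_high]
  }
  exp((llo + lhi) / 2)
}

#' Invert the speckle correlation model for the decorrelation time
#'
#' Solves \eqn{K^2 = } [model_k_squared()]`(T, tau_c)` for \eqn{\tau_c} with
#' the remaining parameters fixed, by bracketed bisection on \eqn{\log x}
#' exploiting the strict monotonicity of \eqn{K^2} in \eqn{x}; relative
#' tolerance better than \eqn{10^{-9}}.
#'
#' @param k_squared Observed \eqn{K^2}; must lie strictly between
#'   \eqn{\upsilon_n} and the \eqn{x \to 0} ceiling
#'   ([k_squared_ceiling()]). Vectorized.
#' @param T Exposure duration in seconds.
#' @param beta,rho,upsilon_n Fixed model parameters.
#' @return Decorrelation time(s) \eqn{\tau_c} in seconds.
#' @export
invert_k_squared <- function(k_squared, T, beta = 1, rho = 1, upsilon_n = 0) {
  if (T <= 0) abort("Exposure `T` must be positive.")
  ceil <- k_squared_ceiling(beta, rho, upsilon_n)
  if (any(k_squared <= upsilon_n) || any(k_squared >= ceil)) {
    abort(sprintf(
      "K^2 must lie strictly within the attainable interval (%.6g, %.6g).",
      upsilon_n, ceil))
  }
  T / invert_x(k_squared, beta, rho, upsilon_n)
}

#' Relative decorrelation time
#'
#' \eqn{\mathrm{relative}\ \tau = \tau_0 / \tau_c}: decorrelation time
#' normalized to a baseline condition, the unitless relative-flow estimate
#' (faster flow, shorter \eqn{\tau_c}, larger relative \eqn{\tau}).
#'
#' @param tau_0 Baseline decorrelation time (seconds, > 0).
#' @param tau_c Decorrelation time of the condition (seconds, > 0). Vectorized.
#' @return \eqn{\tau_0 / \tau_c}.
#' @export
relative_tau <- function(tau_0, tau_c) {
  if (any(tau_0 <= 0) || any(tau_c <= 0)) {
    abort("Decorrelation times must be positive.")
  }
  tau_0 / tau_c
}

#' Scatterer speed implied by a decorrelation time
#'
#' \eqn{v = \lambda / (2\pi\tau_c)}: the absolute speed of a scattering
#' particle is inversely proportional to the decorrelation time at fixed
#' wavelength.
#'
#' @param tau_c Decorrelation time in seconds (> 0). Vectorized.
#' @param wavelength Laser wavelength in meters (default 640 nm).
#' @return Speed in m/s.
#' @export
velocity_proxy <- function(tau_c, wavelength = 640e-9) {
  if (any(tau_c <= 0) || wavelength <= 0) {
    abort("`tau_c` and `wavelength` must be positive.")
  }
  wavelength / (2 * pi * tau_c)
}

#' Per-pixel inverse decorrelation-time map
#'
#' Inverts a contrast map pixelwise to \eqn{1/\tau_c}, the standard per-pixel
#' flow-rate estimate. Pixels whose \eqn{K^2} sits at or above the attainable
#' ceiling show no resolvable motion and map to 0; pixels at or below the
#' \eqn{\upsilon_n} floor are unresolvably fast or noise-dominated and are
#' marked in the `too_fast` companion mask (value `NA`).
#'
#' @param contrast A `contrast_map` with its exposure set.
#' @param beta,rho,upsilon_n Assumed model parameters for the single-exposure
#'   inversion (there is no way to estimate them from one exposure, so they
#'   are explicit inputs).
#' @return A list of class `inv_tau_map`: `inv_tau` (matrix, 1/seconds),
#'   `valid`, `too_fast`, `exposure_T`, and the assumed parameters.
#' @export
inverse_tau_map <- function(contrast, beta = 1, rho = 1, upsilon_n = 0) {
  if (!inherits(contrast, "contrast_map")) abort("`contrast` must be a contrast_map.")
  if (!is.finite(contrast$exposure_T)) {
    abort("Contrast map has no exposure metadata; inversion needs `T`.")
  }
  k2 <- contrast$K_squared
  valid <- contrast$valid & !is.na(k2)
  ceil <- k_squared_ceiling(beta, rho, upsilon_n)
  inv <- matrix(NA_real_, nrow(k2), ncol(k2))
  too_fast <- matrix(FALSE, nrow(k2), ncol(k2))
  at_ceiling <- valid & k2 >= ceil
  inv[at_ceiling] <- 0
  floor_hit <- valid & k2 <= upsilon_n
  too_fast[floor_hit] <- TRUE
  solvable <- valid & !at_ceiling & !floor_hit
  if (any(solvable)) {
    tau <- invert_k_squared(k2[solvable], contrast$exposure_T,
                            beta, rho, upsilon_n)
    inv[solvable] <- 1 / tau
  }
  structure(
    list(inv_tau = inv, valid = valid & !too_fast, too_fast = too_fast,
         exposure_T = contrast$exposure_T,
         assumed = list(beta = beta, rho = rho, upsilon_n = upsilon_n)),
    class = "inv_tau_map"
  )
}

#' @export
print.inv_tau_map <- function(x, ...) {
  cat(sprintf("<inv_tau_map> %d x %d px, exposure %.4g ms, mean 1/tau = %.4g /s\n",
              nrow(x$inv_tau), ncol(x$inv_tau), 1e3 * x$exposure_T,
              mean(x$inv_tau[x$valid], na.rm = TRUE)))
  invisible(x)
}
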