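#' Multi-exposure capillary flow workflow
#'
#' The end-to-end relative-flow pipeline for a controlled capillary
#' experiment: per-stack motion QC, noise-reduced contrast (5x5 spatial
#' window, averaged over retained frames), tube-ROI mean \eqn{K^2}, one
#' multi-exposure series per flow rate, a two-stage constrained fit, the
#' relative-tau table, and the relative-flow linearity regression.
#'
#' The fitting protocol: the baseline (lowest) flow rate is fit jointly for
#' \eqn{\beta}, \eqn{\tau_0} and \eqn{\upsilon_n} with \eqn{\rho} fixed at 1
#' (no static scatterer between optics and tube); every other rate is then
#' fit for \eqn{\tau_c} only, holding \eqn{\beta} (and by default
#' \eqn{\upsilon_n}, a detector property rather than a flow property) at the
#' baseline estimates.
#'
#' @param stacks A tibble with columns `flow_rate`, `exposure_s`, `stack`
#'   (list of [speckle_stack()]), e.g. from [make_capillary_phantom()].
#' @param tube_roi An `roi` covering the perfused tube; defaults to the
#'   phantom's `tube_mask` attribute.
#' @param window Spatial window (default 5).
#' @param refit_upsilon Also refit \eqn{\upsilon_n} at non-baseline rates
#'   (default `FALSE`).
#' @param qc_threshold Motion-rejection threshold for [reject_motion_frames()].
#' @param mask_lower,mask_upper Validity thresholds for [stack_validity_mask()].
#' @return A list of class `capillary_result`: `series` (per rate x exposure
#'   tibble of mean K^2), `baseline_fit`, `fits`, `table` (the relative-flow
#'   table, baseline row at 1), `linearity` ([linearity_regression()] output),
#'   and `qc` (retained frame counts).
#' @export
run_capillary_workflow <- function(stacks, tube_roi = NULL, window = 5L,
                                   refit_upsilon = FALSE, qc_threshold = 0.5,
                                   mask_lower = 20, mask_upper = 255) {
  tube_roi <- tube_roi %||% {
    tm <- attr(stacks, "tube_mask")
    if (is.null(tm)) abort("Provide `tube_roi` (no tube_mask attribute found).")
    roi_mask_spec(tm, "tube")
  }

  rows <- vector("list", nrow(stacks))
  for (i in seq_len(nrow(stacks))) {
    st <- stacks$stack[[i]]
    qc <- reject_motion_frames(st, qc_threshold)
    st <- apply_qc(st, qc)
    msk <- stack_validity_mask(st, mask_lower, mask_upper)
    cm <- withCallingHandlers(
      noise_reduced_contrast(st, window = window, mask = msk),
      warning = function(w) invokeRestart("muffleWarning"))
    obs <- roi_mean_k_squared(cm, tube_roi)
    rows[[i]] <- tibble(flow_rate = stacks$flow_rate[i],
                        exposure_s = stacks$exposure_s[i],
                        k_squared = obs$mean_k_squared,
                        k_squared_se = obs$se,
                        n_pixels = obs$n_pixels,
                        n_frames_retained = length(qc$retained_indices),
                        n_frames_rejected = length(qc$rejected_indices))
  }
  series <- dplyr::bind_rows(rows)

  q0 <- min(series$flow_rate)
  base <- series[series$flow_rate == q0, ]
  baseline_fit <- fit_mesi(
    multi_exposure_series(base$exposure_s, base$k_squared,
                          condition = q0),
    fix = c(rho = 1))
  beta0 <- baseline_fit$params$beta
  ups0 <- baseline_fit$params$upsilon_n
  tau0 <- baseline_fit$params$tau_c

  rates <- sort(unique(series$flow_rate))
  fits <- list()
  tau_hat <- numeric(length(rates))
  for (k in seq_along(rates)) {
    q <- rates[k]
    if (q == q0) {
      fits[[as.character(q)]] <- baseline_fit
      tau_hat[k] <- tau0
      next
    }
    sub <- series[series$flow_rate == q, ]
    fix <- if (refit_upsilon) c(rho = 1, beta = beta0)
           else c(rho = 1, beta = beta0, upsilon_n = ups0)
    f <- fit_mesi(multi_exposure_series(sub$exposure_s, sub$k_squared,
                                        condition = q),
                  fix = fix)
    fits[[as.character(q)]] <- f
    tau_hat[k] <- f$params$tau_c
  }

  table <- tibble(flow_rate = rates,
                  tau_c_s = tau_hat,
                  tau_c_ms = 1e3 * tau_hat,
                  relative_tau = relative_tau(tau0, tau_hat),
                  relative_flow = rates / q0)
  lin <- linearity_regression(table)

  structure(
    list(series = series, baseline_fit = baseline_fit, fits = fits,
         table = table, linearity = lin,
         qc = series[, c("flow_rate", "exposure_s", "n_frames_retained",
                         "n_frames_rejected")]),
    class = "capillary_result"
  )
}

#' @export
print.capillary_result <- function(x, ...) {
  cat(sprintf(
    "<capillary_result> %d rates x %d exposures; tau_0 = %.3g ms; linearity R^2 = %.4f\n",
    length(unique(x$series$flow_rate)), length(unique(x$series$exposure_s)),
    1e3 * x$baseline_fit$params$tau_c, x$linearity$r_squared))
  invisible(x)
}

#' Single-exposure retinal imaging workflow
#'
#' The in vivo processing chain for one stack: motion-artifact frame
#' rejection, exposure-validity masking, the three contrast schemes (spatial,
#' temporal, noise-reduced), a per-pixel inverse decorrelation-time map from
#' the noise-reduced contrast under stated model assumptions, and cross-
#' section profiles along requested line segments.
#'
#' @param stack A [speckle_stack()].
#' @param lines A list of [roi_line()]s to profile (may be empty).
#' @param beta,rho,upsilon_n Model assumptions for the single-exposure
#'   inversion ([inverse_tau_map()]).
#' @param window Spatial window (default 5).
#' @param section_width Perpendicular averaging width for profiles (pixels).
#' @param qc_threshold,mask_lower,mask_upper QC parameters.
#' @return A list of class `retina_result`: `qc`, `mask`, `spatial`,
#'   `temporal`, `noise_reduced` (contrast maps), `inv_tau`
#'   (an `inv_tau_map`), and `profiles` (list of `cross_section`).
#' @export
run_retina_workflow <- function(stack, lines = list(), beta = 1, rho = 1,
                                upsilon_n = 0, window = 5L, section_width = 3,
                                qc_threshold = 0.5, mask_lower = 20,
                                mask_upper = 255) {
  qc <- reject_motion_frames(stack, qc_threshold)
  clean <- apply_qc(stack, qc)
  msk <- stack_validity_mask(clean, mask_lower, mask_upper)
  quiet <- function(expr) withCallingHandlers(
    expr, warning = function(w) invokeRestart("muffleWarning"))
  spat <- spatial_contrast(clean$frames[, , 1], window, msk,
                           exposure_T = clean$exposure_T)
  temp <- quiet(temporal_contrast(clean, mask = msk))
  nred <- quiet(noise_reduced_contrast(clean, window = window, mask = msk))
  inv <- inverse_tau_map(nred, beta = beta, rho = rho, upsilon_n = upsilon_n)
  profiles <- lapply(lines, function(ln)
    extract_cross_section(inv, ln, width_px = section_width))
  names(profiles) <- vapply(lines, function(ln) ln$label, character(1))
  structure(
    list(qc = qc, mask = msk, spatial = spat, temporal = temp,
         noise_reduced = nred, inv_tau = inv, profiles = profiles),
    class = "retina_result"
  )
}

#' @export
print.retina_result <- function(x, ...) {
  cat(sprintf("<retina_result> %d/%d frames retained; %d profile(s)\n",
              length(x$qc$retained_indices), length(x$qc$metric_values),
              length(x$profiles)))
  invisible(x)
}
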