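#' Build a multi-exposure series
#'
#' The unit of MESI fitting: one ROI-mean \eqn{K^2} observation per exposure
#' duration for a single flow condition.
#'
#' @param exposure_s Exposure durations in seconds.
#' @param k_squared ROI-mean speckle variance at each exposure.
#' @param k_squared_se Optional standard errors (used as inverse-variance
#'   weights by [fit_mesi()]).
#' @param condition Optional condition label (e.g. flow rate in uL/min).
#' @return A tibble of class `multi_exposure_series`.
#' @export
multi_exposure_series <- function(exposure_s, k_squared, k_squared_se = NA_real_,
                                  condition = NA) {
  if (length(exposure_s) != length(k_squared)) {
    abort("`exposure_s` and `k_squared` must have equal length.")
  }
  if (any(k_squared < 0)) abort("All K^2 values must be nonnegative.")
  if (length(unique(exposure_s)) < 2L) {
    abort("Need at least 2 distinct exposures.")
  }
  out <- tibble(condition = condition, exposure_s = exposure_s,
                k_squared = k_squared, k_squared_se = k_squared_se)
  class(out) <- c("multi_exposure_series", class(out))
  out
}

# parameter transforms keeping the Levenberg-Marquardt solver unconstrained:
# tau_c and upsilon_n on log scale, beta and rho on logit scale
mesi_to_theta <- function(p, free) {
  th <- c(beta = stats::qlogis(min(p$beta, 1 - 1e-9)),
          rho = stats::qlogis(min(max(p$rho, 1e-9), 1 - 1e-9)),
          tau_c = log(p$tau_c),
          upsilon_n = log(max(p$upsilon_n, 1e-12)))
  th[free]
}

theta_to_mesi <- function(theta, fixed) {
  get <- function(name, trans) {
    if (name %in% names(fixed)) fixed[[name]]
    else trans(theta[[name]])
  }
  list(beta = get("beta", stats::plogis),
       rho = get("rho", stats::plogis),
       tau_c = get("tau_c", exp),
       upsilon_n = get("upsilon_n", exp))
}

#' Fit the speckle correlation model to a multi-exposure series
#'
#' Weighted least squares of observed \eqn{K^2} against [model_k_squared()]
#' over the free parameters, with bounds enforced by transformation
#' (\eqn{\log \tau_c}, \eqn{\log \upsilon_n}, logit \eqn{\beta} and
#' \eqn{\rho}) so the Levenberg-Marquardt solver runs unconstrained. Because
#' the objective can be multi-modal in \eqn{\log \tau_c} for sparse exposure
#' sets, the fit is multi-started over log-spaced \eqn{\tau_c} initial guesses
#' spanning `[0.1 min(T), 10 max(T)]` and the best residual kept.
#'
#' Weights are \eqn{1/\mathrm{se}^2} when `k_squared_se` is available, else
#' uniform. Non-convergence across all starts, or a degenerate series (all
#' \eqn{K^2} equal), is flagged via `converged = FALSE`, not an error.
#'
#' @param series A [multi_exposure_series()] (or data frame with columns
#'   `exposure_s`, `k_squared`, optionally `k_squared_se`).
#' @param fix Named numeric vector of parameters to hold constant, e.g.
#'   `c(rho = 1)` (no static scatter between optics and sample) or the
#'   baseline-condition protocol's `c(rho = 1, beta = ..., upsilon_n = ...)`.
#' @param init Optional [mesi_params()] giving starting values.
#' @param n_starts Number of log-spaced \eqn{\tau_c} starts (default 7).
#' @return A `mesi_fit`: fitted [mesi_params()], the fixed set, residual sum
#'   of squares, \eqn{R^2} of \eqn{K^2} vs the model, observation count, and a
#'   convergence flag. `tidy()` and `glance()` methods are provided.
#' @export
fit_mesi <- function(series, fix = c(rho = 1), init = NULL, n_starts = 7L) {
  df <- as.data.frame(series)
  if (nrow(df) < 2L) abort("Need at least 2 observations.")
  free <- setdiff(c("beta", "rho", "tau_c", "upsilon_n"), names(fix))
  if (length(free) == 0L) abort("At least one parameter must be free.")
  if (length(free) > nrow(df)) {
    abort("More free parameters than observations.")
  }
  fixed <- as.list(fix)
  Texp <- df$exposure_s
  k2 <- df$k_squared
  se <- df$k_squared_se
  w <- if (!is.null(se) && all(is.finite(se)) && all(se > 0)) 1 / se^2
       else rep(1, length(k2))
  sw <- sqrt(w)

  resid_fn <- function(theta) {
    p <- theta_to_mesi(setNames(theta, free), fixed)
    sw * (k2 - model_k_squared(Texp, p$tau_c, p$beta, p$rho, p$upsilon_n))
  }

  base_init <- list(beta = init$beta %||% 0.6, rho = init$rho %||% 0.95,
                    tau_c = init$tau_c %||% median(Texp),
                    upsilon_n = init$upsilon_n %||% max(1e-4, min(k2) / 10))
  tau_starts <- if ("tau_c" %in% free) {
    exp(seq(log(0.1 * min(Texp)), log(10 * max(Texp)), length.out = n_starts))
  } else base_init$tau_c

  best <- NULL
  for (ts in tau_starts) {
    st <- base_init
    st$tau_c <- ts
    theta0 <- mesi_to_theta(st, free)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = theta0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) abort("All fit starts failed.")

  p <- theta_to_mesi(setNames(best$par, free), fixed)
  ss_res <- best$deviance
  ss_tot <- sum(w * (k2 - stats::weighted.mean(k2, w))^2)
  degenerate <- ss_tot <= .Machine$double.eps * max(1, sum(w * k2^2))
  structure(
    list(params = mesi_params(p$beta, p$rho, p$tau_c, p$upsilon_n),
         fixed = names(fix),
         residual_ss = ss_res,
         r_squared_fit = if (degenerate) NA_real_ else 1 - ss_res / ss_tot,
         n_obs = nrow(df),
         converged = !degenerate && best$info %in% 1:4,
         series = tibble::as_tibble(df)),
    class = "mesi_fit"
  )
}

#' @export
print.mesi_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    paste0("<mesi_fit> tau_c = %.4g ms, beta = %.3f, rho = %.3f, ",
           "upsilon_n = %.4g\n  fixed: {%s}; R^2 = %.4f; converged: %s\n"),
    1e3 * p$tau_c, p$beta, p$rho, p$upsilon_n,
    paste(x$fixed, collapse = ", "), x$r_squared_fit, x$converged))
  invisible(x)
}

#' @rdname fit_mesi
#' @param x A `mesi_fit`.
#' @param ... Unused.
#' @export
tidy.mesi_fit <- function(x, ...) {
  tibble(term = c("beta", "rho", "tau_c", "upsilon_n"),
         estimate = c(x$params$beta, x$params$rho, x$params$tau_c,
                      x$params$upsilon_n),
         fixed = c("beta", "rho", "tau_c", "upsilon_n") %in% x$fixed)
}

#' @rdname fit_mesi
#' @export
glance.mesi_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared_fit, residual_ss = x$residual_ss,
         n_obs = x$n_obs, converged = x$converged)
}
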