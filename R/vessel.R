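#' ROI mean speckle variance
#'
#' Mean and standard error of \eqn{K^2} over the valid pixels of an ROI in a
#' contrast map: the observation a multi-exposure series is built from.
#'
#' @param contrast A `contrast_map`.
#' @param roi An [roi_rect()]/[roi_polygon()]/[roi_mask_spec()].
#' @return A one-row tibble: `mean_k_squared`, `se`, `n_pixels`.
#' @export
roi_mean_k_squared <- function(contrast, roi) {
  m <- roi_to_mask(roi, dim(contrast$K))
  sel <- m & contrast$valid & !is.na(contrast$K_squared)
  if (!any(sel)) abort("ROI overlaps no valid pixels.")
  v <- contrast$K_squared[sel]
  tibble(mean_k_squared = mean(v),
         se = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
         n_pixels = length(v))
}

#' Vessel cross-section profile
#'
#' Samples a 2-D map (typically an inverse decorrelation-time map) along a
#' line segment by bilinear interpolation at unit-pixel spacing, averaging
#' over `width_px` parallel offsets perpendicular to the segment, and fits a
#' least-squares quadratic \eqn{v = a p^2 + b p + c} to the profile. Laminar
#' flow in a vessel should give a downward-opening parabola (`a < 0`) with its
#' vertex at the vessel centerline; the opening direction is reported, not
#' assumed.
#'
#' @param map A numeric matrix, `inv_tau_map`, or `contrast_map`.
#' @param line An [roi_line()].
#' @param width_px Perpendicular averaging width in pixels (default 1).
#' @return A `cross_section`: `profile` tibble (`position`, `value`),
#'   `parabola_coeffs` (a, b, c), `r_squared`, `peak_position`,
#'   `opens_downward`, `degenerate`.
#' @export
extract_cross_section <- function(map, line, width_px = 1) {
  mat <- if (inherits(map, "inv_tau_map")) map$inv_tau
         else if (inherits(map, "contrast_map")) map$K
         else map
  if (line$kind != "line_segment") abort("`line` must be an roi_line().")
  d <- line$to - line$from
  len <- sqrt(sum(d^2))
  n <- floor(len) + 1L
  if (n < 3L) abort("Segment shorter than 3 samples.")
  u <- d / len
  perp <- c(-u[2], u[1])
  offsets <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = max(1, width_px))
  positions <- seq(0, len, by = 1)
  vals <- vapply(positions, function(p) {
    pts_r <- line$from[1] + p * u[1] + offsets * perp[1]
    pts_c <- line$from[2] + p * u[2] + offsets * perp[2]
    mean(interp_bilinear(mat, pts_r, pts_c), na.rm = TRUE)
  }, numeric(1))

  ok <- is.finite(vals)
  profile <- tibble(position = positions, value = vals)
  if (sum(ok) < 3L || var(vals[ok]) == 0) {
    return(structure(
      list(profile = profile, parabola_coeffs = c(a = NA, b = NA, c = NA),
           r_squared = NA_real_, peak_position = NA_real_,
           opens_downward = NA, degenerate = TRUE, label = line$label),
      class = "cross_section"))
  }
  fit <- lm(value ~ position + I(position^2), data = profile[ok, ])
  cf <- coef(fit)
  a <- unname(cf[3]); b <- unname(cf[2]); cc <- unname(cf[1])
  structure(
    list(profile = profile,
         parabola_coeffs = c(a = a, b = b, c = cc),
         r_squared = summary(fit)$r.squared,
         peak_position = if (a != 0) -b / (2 * a) else NA_real_,
         opens_downward = a < 0, degenerate = FALSE, label = line$label),
    class = "cross_section"
  )
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> %d samples; parabola R^2 = %.3f; vertex at %.2f px%s\n",
              nrow(x$profile), x$r_squared, x$peak_position,
              if (isTRUE(x$opens_downward)) " (opens downward)" else ""))
  invisible(x)
}

#' @rdname extract_cross_section
#' @param x A `cross_section`.
#' @param ... Unused.
#' @export
tidy.cross_section <- function(x, ...) x$profile

#' Paired pre/post comparison of per-vessel flow estimates
#'
#' Classical paired two-tailed t-test on matched per-vessel mean
#' \eqn{1/\tau_c} values (e.g. before and after an intervention expected to
#' abolish flow). Degenerate difference sets are reported rather than
#' erroring: identical pre/post gives `t = 0, p = 1`; a constant nonzero
#' difference gives infinite `t` and `p = 0`.
#'
#' @param pre,post Matched numeric vectors (equal length >= 2).
#' @return A one-row tibble: `mean_difference`, `t`, `p_value`, `df`, `n`.
#' @export
paired_pre_post_test <- function(pre, post) {
  if (length(pre) != length(post)) abort("`pre` and `post` must be matched.")
  if (length(pre) < 2L) abort("Need at least 2 pairs.")
  d <- pre - post
  n <- length(d)
  md <- mean(d)
  s <- sd(d)
  if (s == 0) {
    tstat <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
  } else {
    tstat <- md / (s / sqrt(n))
    p <- 2 * pt(-abs(tstat), df = n - 1)
  }
  tibble(mean_difference = md, t = tstat, p_value = p, df = n - 1, n = n)
}

#' Relative-flow linearity regression
#'
#' Ordinary least squares of relative decorrelation time
#' (\eqn{\tau_0/\tau_c}) on relative flow rate (\eqn{Q/Q_0}): if the
#' inverse-decorrelation-time flow proxy is faithful, the relationship is
#' linear with high \eqn{R^2}.
#'
#' @param table A data frame with columns `relative_tau` and `relative_flow`
#'   (e.g. from [run_capillary_workflow()]).
#' @return A one-row tibble of class `linearity_result`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
linearity_regression <- function(table) {
  df <- as.data.frame(table)
  if (nrow(df) < 3L) abort("Need at least 3 conditions.")
  if (var(df$relative_flow) == 0) abort("Degenerate: identical flow values.")
  fit <- lm(relative_tau ~ relative_flow, data = df)
  out <- tibble(slope = unname(coef(fit)[2]),
                intercept = unname(coef(fit)[1]),
                r_squared = summary(fit)$r.squared,
                n = nrow(df))
  class(out) <- c("linearity_result", class(out))
  out
}
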