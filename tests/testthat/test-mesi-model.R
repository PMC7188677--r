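test_that("the speckle correlation model matches its integral definition", {
  # frozen from the quadrature oracle: K^2 at x = 1 (beta = rho = 1, no noise)
  expect_equal(model_k_squared(1e-3, 1e-3), 0.5676676416, tolerance = 1e-9)
  for (x in c(0.01, 0.1, 1, 5, 20, 100)) {
    expect_equal(model_k_squared(x * 1e-3, 1e-3), oracle_k2_model(x),
                 tolerance = 1e-9)
    expect_equal(model_k_squared(x * 1e-3, 1e-3, beta = 0.7, rho = 0.6,
                                 upsilon_n = 0.02),
                 oracle_k2_model(x, 0.7, 0.6, 0.02), tolerance = 1e-9)
  }
})

test_that("model limits behave physically", {
  # instantaneous exposure: no blurring, K^2 -> 1
  expect_equal(model_k_squared(1e-15, 1), 1, tolerance = 1e-9)
  # rho = 0: static scene, K^2 is exactly the noise floor
  expect_identical(model_k_squared(1e-3, 1e-3, rho = 0, upsilon_n = 0.04), 0.04)
  # x -> 0 ceiling
  expect_equal(model_k_squared(1e-12, 1, beta = 0.8, rho = 0.6,
                               upsilon_n = 0.01),
               k_squared_ceiling(0.8, 0.6, 0.01), tolerance = 1e-9)
  expect_error(model_k_squared(-1, 1e-3), "positive")
  expect_error(model_k_squared(1e-3, 0), "positive")
})

test_that("the small-x series branch stays accurate where the closed form cannot", {
  # near the switchover the naive closed form loses ~5 digits to cancellation;
  # the series branch must agree with the quadrature oracle to full precision
  for (x in c(1e-8, 1e-7, 0.99e-6)) {
    expect_equal(model_k_squared(x, 1), oracle_k2_dynamic(x),
                 tolerance = 1e-12)
    expect_equal(model_k_squared(x, 1, rho = 0.5),
                 oracle_k2_model(x, rho = 0.5), tolerance = 1e-12)
  }
  # and the two branches join continuously at x = 1e-6 (to the level the
  # double-precision closed form permits)
  lo <- model_k_squared(0.999999e-6, 1)
  hi <- model_k_squared(1.000001e-6, 1)
  expect_lt(abs(hi - lo), 1e-4)
})

test_that("K^2 is strictly decreasing in T and increasing in tau_c", {
  Ts <- 10^seq(-5, 0, length.out = 40)
  expect_true(all(diff(model_k_squared(Ts, 5e-3)) < 0))
  taus <- 10^seq(-5, 0, length.out = 40)
  expect_true(all(diff(model_k_squared(5e-3, taus)) > 0))
  expect_true(all(diff(model_k_squared(Ts, 5e-3, beta = 0.8, rho = 0.7,
                                       upsilon_n = 0.01)) < 0))
})

test_that("inversion round-trips the model across four decades", {
  for (T in c(1e-3, 27e-3)) {
    taus <- 10^seq(log10(T / 100), log10(T * 100), length.out = 25)
    k2 <- model_k_squared(T, taus)
    back <- invert_k_squared(k2, T)
    expect_true(all(abs(back - taus) / taus < 1e-6))
  }
  # with nuisance parameters
  taus <- 10^seq(-4.5, -1.5, length.out = 15)
  k2 <- model_k_squared(10e-3, taus, beta = 0.8, rho = 0.9, upsilon_n = 0.02)
  back <- invert_k_squared(k2, 10e-3, beta = 0.8, rho = 0.9, upsilon_n = 0.02)
  expect_true(all(abs(back - taus) / taus < 1e-6))
})

test_that("inversion rejects unattainable K^2 and names the bounds", {
  expect_error(invert_k_squared(1.5, 1e-3), "attainable")
  expect_error(invert_k_squared(0.005, 1e-3, upsilon_n = 0.01), "attainable")
  # barely above the noise floor: tiny tau, monotone with neighbors
  k2s <- 0.01 + c(1e-9, 1e-6, 1e-3)
  taus <- invert_k_squared(k2s, 1e-3, upsilon_n = 0.01)
  expect_true(all(diff(taus) > 0))
})

test_that("fit recovers known parameters from a noiseless series", {
  truth <- mesi_params(beta = 0.8, rho = 1, tau_c = 3e-3, upsilon_n = 0.01)
  Ts <- c(4.96, 8.97, 15.43, 27) * 1e-3
  series <- multi_exposure_series(Ts, model_k_squared(Ts, params = truth))
  fit <- fit_mesi(series, fix = c(rho = 1))
  expect_true(fit$converged)
  expect_equal(fit$params$beta, 0.8, tolerance = 0.01)
  expect_equal(fit$params$tau_c, 3e-3, tolerance = 0.01)
  expect_equal(fit$params$upsilon_n, 0.01, tolerance = 0.01)
  expect_gt(fit$r_squared_fit, 0.9999)

  td <- tidy(fit)
  expect_equal(td$term, c("beta", "rho", "tau_c", "upsilon_n"))
  expect_true(td$fixed[td$term == "rho"])
  expect_equal(glance(fit)$n_obs, 4)
})

test_that("one-free-parameter fits are exact to solver tolerance", {
  Ts <- c(5, 15) * 1e-3
  k2 <- model_k_squared(Ts, 1e-3, beta = 0.9, upsilon_n = 0.005)
  fit <- fit_mesi(multi_exposure_series(Ts, k2),
                  fix = c(rho = 1, beta = 0.9, upsilon_n = 0.005))
  expect_equal(fit$params$tau_c, 1e-3, tolerance = 1e-6)
})

test_that("degenerate and invalid series are flagged, not fatal", {
  s <- multi_exposure_series(c(1e-3, 2e-3, 4e-3), rep(0.2, 3))
  fit <- fit_mesi(s, fix = c(rho = 1, upsilon_n = 0))
  expect_false(fit$converged)
  expect_error(multi_exposure_series(1e-3, 0.5), "2 distinct")
  expect_error(multi_exposure_series(c(1e-3, 2e-3), c(-0.1, 0.2)),
               "nonnegative")
  expect_error(fit_mesi(s, fix = c(beta = 1, rho = 1, tau_c = 1e-3,
                                   upsilon_n = 0)),
               "free")
})

test_that("relative tau and the velocity proxy follow their definitions", {
  expect_equal(relative_tau(2e-3, 2e-3), 1)
  expect_equal(relative_tau(8e-3, 2e-3), 4)
  expect_error(relative_tau(-1, 1), "positive")

  expect_equal(velocity_proxy(1e-3), 640e-9 / (2 * pi * 1e-3))
  expect_equal(velocity_proxy(1e-3), 1.0186e-4, tolerance = 1e-4)
  expect_equal(velocity_proxy(1e-3, wavelength = 1280e-9),
               2 * velocity_proxy(1e-3))
  expect_lt(velocity_proxy(1e6), 1e-12)  # static limit: speed -> 0
  expect_error(velocity_proxy(0), "positive")
})

test_that("inverse-tau maps invert valid pixels and flag the rest", {
  K <- matrix(sqrt(model_k_squared(25e-3, 5e-3)), 8, 8)
  cm <- contrast_map(K, exposure_T = 25e-3)
  inv <- inverse_tau_map(cm)
  expect_true(all(abs(inv$inv_tau - 200) < 1e-4))

  # ceiling (static background) maps to zero; floor maps to the fast mask
  K2 <- matrix(sqrt(0.5), 4, 4)
  K2[1, 1] <- sqrt(k_squared_ceiling(upsilon_n = 0.001))  # at the x->0 ceiling
  K2[2, 2] <- sqrt(0.0005)      # below the noise floor
  cm2 <- contrast_map(K2, exposure_T = 25e-3)
  inv2 <- inverse_tau_map(cm2, upsilon_n = 0.001)
  expect_equal(inv2$inv_tau[1, 1], 0)
  expect_true(inv2$too_fast[2, 2])
  expect_false(inv2$valid[2, 2])

  cm3 <- contrast_map(K, exposure_T = NA_real_)
  expect_error(inverse_tau_map(cm3), "exposure")
})
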