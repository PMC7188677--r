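test_that("static fully developed speckle is frozen in time with unit contrast", {
  tau <- matrix(Inf, 64, 64)
  cfg <- sim_config(10e-3, n_frames = 5, rho = 1, noise_floor = 0,
                    quantize = FALSE, seed = 11)
  st <- simulate_stack(tau, cfg)
  for (f in 2:5) expect_identical(st$frames[, , f], st$frames[, , 1])
  # exponential intensity statistics: K^2 of one frame near 1
  expect_lt(abs(global_k2(st$frames[, , 1]) - 1), 3 * sqrt(8 / 64^2))
  # exponential shape: sd ~ mean and P(I < mean) ~ 1 - 1/e
  fr <- st$frames[, , 1]
  expect_lt(abs(mean(fr < mean(fr)) - (1 - exp(-1))), 0.05)
})

test_that("a purely static scatterer is frame- and exposure-invariant", {
  tau <- matrix(1e-3, 16, 16)
  mk <- function(T) simulate_stack(tau, sim_config(
    T, n_frames = 3, rho = 0, noise_floor = 0, quantize = FALSE, seed = 5,
    substeps_per_exposure = 8))
  a <- mk(5e-3)
  b <- mk(50e-3)
  expect_identical(a$frames[, , 1], a$frames[, , 3])
  expect_identical(a$frames, b$frames)
})

test_that("simulated spatial K^2 matches the speckle correlation model", {
  for (x in c(0.1, 1, 5)) {
    st <- simulate_stack(matrix(1e-3, 64, 64),
                         sim_config(x * 1e-3, n_frames = 10, rho = 1,
                                    noise_floor = 0, quantize = FALSE,
                                    seed = 100 + round(10 * x)))
    s <- stack_k2_stats(st)
    expect_lt(abs(s$mean - model_k_squared(x * 1e-3, 1e-3)), 3.5 * s$se)
  }
})

test_that("measured contrast decreases monotonically with exposure", {
  k <- sapply(c(4.96, 8.97, 15.43, 27) * 1e-3, function(T) {
    st <- simulate_stack(matrix(10e-3, 48, 48),
                         sim_config(T, n_frames = 8, rho = 1, noise_floor = 0,
                                    quantize = FALSE, seed = 3))
    sqrt(stack_k2_stats(st)$mean)
  })
  expect_true(all(diff(k) < 0))
})

test_that("identical seeds give bit-identical stacks", {
  tau <- matrix(2e-3, 20, 20)
  cfg <- sim_config(5e-3, n_frames = 4, seed = 99, noise_floor = 1)
  expect_identical(simulate_stack(tau, cfg)$frames,
                   simulate_stack(tau, cfg)$frames)
  cfg2 <- sim_config(5e-3, n_frames = 4, seed = 100, noise_floor = 1)
  expect_false(identical(simulate_stack(tau, cfg)$frames,
                         simulate_stack(tau, cfg2)$frames))
})

test_that("simulate_stack validates configuration", {
  expect_error(sim_config(-1e-3), "positive")
  expect_error(sim_config(1e-3, n_frames = 0), "at least 1")
  expect_error(sim_config(1e-3, rho = 1.2), "\\[0, 1\\]")
  cfg <- sim_config(1e-3, rho = matrix(0.5, 4, 4))
  expect_error(simulate_stack(matrix(1e-3, 5, 5), cfg), "shape")
  expect_error(tau_field(matrix(-1, 2, 2)), "positive")
})

test_that("capillary phantom covers the rate-exposure grid with tau ~ 1/Q", {
  ph <- make_capillary_phantom(flow_rates = c(10, 100),
                               exposures = c(5e-3, 27e-3),
                               tau_at_baseline = 15e-3,
                               dim = c(12, 16), n_frames = 3, seed = 1)
  expect_equal(nrow(ph), 4)
  t10 <- unique(ph$tau_tube_s[ph$flow_rate == 10])
  t100 <- unique(ph$tau_tube_s[ph$flow_rate == 100])
  expect_equal(t100, t10 / 10)
  expect_true(all(vapply(ph$stack, n_frames, integer(1)) == 3L))
  # the standard protocol: 7 rates x 4 exposures -> 28 stacks of >= 80 frames
  ph7 <- make_capillary_phantom(dim = c(8, 8), n_frames = 80, seed = 2)
  expect_equal(nrow(ph7), 28)
  expect_error(make_capillary_phantom(flow_rates = numeric(0)), "non-empty")
})

test_that("capillary stacks at one rate differ only by RNG stream", {
  ph <- make_capillary_phantom(flow_rates = c(20, 20.000001),
                               exposures = 5e-3, dim = c(10, 12),
                               n_frames = 2, seed = 4)
  expect_equal(ph$tau_tube_s[1], ph$tau_tube_s[2], tolerance = 1e-6)
  expect_false(identical(ph$stack[[1]]$frames, ph$stack[[2]]$frames))
})

test_that("vessel phantom encodes a laminar parabola in tau_c", {
  v_for_tau1ms <- 640e-9 / (2 * pi * 1e-3)
  tf <- make_vessel_phantom(c(21, 30),
                            data.frame(center_row = 11, radius = 5,
                                       center_speed = v_for_tau1ms))
  # parabola apex: tau = lambda / (2 pi v_center) = 1 ms
  expect_equal(tf[11, 1], 1e-3, tolerance = 1e-9)
  # no-slip wall and background are static
  expect_identical(tf[16, 1], Inf)
  expect_identical(tf[1, 1], Inf)
  # half-radius: v = 0.75 v_center -> tau = 4/3 ms
  r <- 2.5
  expect_lt(tf[11 - 3, 1], tf[11 - 4, 1])  # monotone toward the wall
  # overlapping vessels take the faster (smaller tau) value
  tf2 <- make_vessel_phantom(c(21, 30),
                             data.frame(center_row = c(11, 12),
                                        radius = c(5, 5),
                                        center_speed = c(v_for_tau1ms,
                                                         10 * v_for_tau1ms)))
  expect_equal(tf2[12, 1], 1e-4, tolerance = 1e-9)
})

test_that("motion blur lowers frame contrast and is recorded as ground truth", {
  st <- simulate_stack(matrix(1e-3, 40, 40),
                       sim_config(1e-3, n_frames = 6, seed = 8,
                                  quantize = FALSE, noise_floor = 0))
  same <- inject_motion_blur(st, integer(0))
  expect_identical(same$frames, st$frames)

  blurred <- inject_motion_blur(st, c(2, 5), blur_px = 10)
  expect_identical(blurred$meta$blurred_indices, c(2L, 5L))
  expect_identical(blurred$frames[, , 1], st$frames[, , 1])
  k <- apply(blurred$frames, 3, function(f) sqrt(global_k2(f)))
  expect_lt(k[2], 0.5 * median(k))
  expect_lt(k[5], 0.5 * median(k))
  expect_error(inject_motion_blur(st, 99), "range")
  expect_error(inject_motion_blur(st, 1, blur_px = 0), "positive")
})
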