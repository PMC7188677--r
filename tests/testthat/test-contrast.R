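test_that("spatial contrast equals the brute-force double-loop oracle", {
  withr::with_seed(7, {
    frame <- matrix(runif(32 * 32, 0, 255), 32, 32)
    mask <- validity_mask(matrix(128, 32, 32))
    mask[sample(length(mask), 150)] <- FALSE
    for (w in c(3, 5, 7)) {
      got <- spatial_contrast(frame, w)
      ref <- brute_spatial_k(frame, w)
      ok <- got$valid
      expect_equal(got$K[ok], ref$K[ok], tolerance = 1e-13)
      gotm <- spatial_contrast(frame, w, mask)
      refm <- brute_spatial_k(frame, w, matrix(as.logical(mask), 32, 32))
      okm <- gotm$valid
      expect_equal(gotm$K[okm], refm$K[okm], tolerance = 1e-13)
      # validity rule: >= window^2/2 valid neighbors and valid center
      expect_true(all(refm$count[okm] >= w^2 / 2))
    }
  })
})

test_that("spatial contrast reproduces hand-computed window statistics", {
  # 5x5 window holding 1..25: mean 13, population sd sqrt(52)
  frame <- matrix(1:25, 5, 5)
  cm <- spatial_contrast(frame, 5)
  expect_equal(cm$K[3, 3], sqrt(52) / 13, tolerance = 1e-12)
  # uniform window: zero variance
  expect_equal(spatial_contrast(matrix(100, 7, 7), 5)$K[4, 4], 0)
  # corner neighborhoods of a 5x5 window have 9 < 12.5 members -> invalid
  expect_false(cm$valid[1, 1])
  expect_error(spatial_contrast(frame, 4), "odd")
})

test_that("contrast is invariant to intensity scaling", {
  withr::with_seed(12, frame <- matrix(rexp(400, 1 / 60), 20, 20))
  a <- spatial_contrast(frame, 5)
  b <- spatial_contrast(frame * 3.7, 5)
  expect_equal(a$K, b$K, tolerance = 1e-12)
})

test_that("temporal contrast uses per-pixel population statistics", {
  fr <- array(0, dim = c(4, 4, 2))
  fr[, , 1] <- 10; fr[, , 2] <- 30
  st <- speckle_stack(fr, 1e-3)
  cm <- quiet(temporal_contrast(st))
  expect_true(all(abs(cm$K - 0.5) < 1e-12))
  expect_equal(cm$K_squared, cm$K^2)
  expect_error(temporal_contrast(keep_frames(st, 1)), "2 frames")
})

test_that("temporal contrast of a static stack is zero; of fast frames ~ 1", {
  static <- simulate_stack(matrix(Inf, 16, 16),
                           sim_config(1e-3, n_frames = 45, rho = 1, seed = 2,
                                      noise_floor = 0, quantize = FALSE))
  expect_true(all(temporal_contrast(static)$K == 0))

  # T << tau_c: frames are independent exponential draws at each pixel
  fast <- simulate_stack(matrix(1, 24, 24),
                         sim_config(1e-4, n_frames = 60, rho = 1, seed = 3,
                                    noise_floor = 0, quantize = FALSE,
                                    substeps_per_exposure = 2))
  ktemp <- temporal_contrast(fast)$K
  expect_lt(abs(mean(ktemp) - 1), 0.1)
})

test_that("temporal and spatial contrast agree on ergodic simulations", {
  st <- simulate_stack(matrix(1e-3, 24, 24),
                       sim_config(1e-3, n_frames = 60, rho = 1, seed = 17,
                                  noise_floor = 0, quantize = FALSE))
  kt <- mean(temporal_contrast(st)$K)
  ks <- mean(apply(st$frames, 3, function(f) sqrt(global_k2(f))))
  expect_lt(abs(kt - ks) / ks, 0.05)
})

test_that("noise-reduced contrast averages per-frame K maps", {
  one <- simulate_stack(matrix(1e-3, 12, 12),
                        sim_config(1e-3, n_frames = 1, seed = 5))
  dup <- speckle_stack(array(one$frames[, , 1], dim = c(12, 12, 80)), 1e-3)
  nr <- noise_reduced_contrast(dup, 5)
  single <- spatial_contrast(dup$frames[, , 1], 5, exposure_T = 1e-3)
  expect_equal(nr$K, single$K, tolerance = 1e-12)
  expect_equal(nr$K_squared, single$K^2, tolerance = 1e-12)
  expect_equal(nr$n_frames_used, 80L)

  # averaging K^2 maps instead is exposed as an option and differs
  st <- simulate_stack(matrix(1e-3, 12, 12),
                       sim_config(1e-3, n_frames = 10, seed = 6,
                                  quantize = FALSE, noise_floor = 0))
  a <- quiet(noise_reduced_contrast(st, 5, average = "K"))
  b <- quiet(noise_reduced_contrast(st, 5, average = "K2"))
  expect_false(identical(a$K_squared, b$K_squared))
  expect_true(all(b$K_squared[b$valid] >= a$K_squared[a$valid] - 1e-12))
})

test_that("frame averaging shrinks the variance of the K estimate ~ 1/n", {
  st <- simulate_stack(matrix(1e-3, 16, 16),
                       sim_config(1e-3, n_frames = 32, seed = 9,
                                  quantize = FALSE, noise_floor = 0))
  inner <- function(m) m[5:12, 5:12]
  v1 <- var(as.numeric(inner(spatial_contrast(st$frames[, , 1], 5)$K)))
  vn <- var(as.numeric(inner(quiet(noise_reduced_contrast(st, 5))$K)))
  ratio <- vn / v1
  expect_lt(ratio, 3 / 32)   # close to 1/32, allow sampling slack
})
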