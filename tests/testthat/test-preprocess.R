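test_that("bending correction and baseline zeroing recover known offsets", {
  set.seed(61)
  cv <- make_sawtooth(noise_sd = 3)
  cv$force <- cv$force + 7   # constructed constant offset
  cc <- correct_curve(cv)
  m <- sum(cv$distance >= cc$baseline_range[1] &
             cv$distance <= cc$baseline_range[2])
  expect_equal(cc$baseline_offset, 7, tolerance = 4 * 3 / sqrt(m))
  # separation = distance - deflection
  expect_equal(cc$separation, cv$distance - cc$force / 100)

  # zero-deflection curve: separation equals distance
  flat <- force_curve(seq(0, 60, by = 0.1),
                      c(rep(30, 301), rep(0, 300)),
                      metadata = list(spring_constant = 1e12))
  ccf <- correct_curve(flat)
  expect_equal(ccf$separation, flat$distance, tolerance = 1e-9)

  # noiseless curve: rebased final plateau exactly 0
  cv0 <- make_sawtooth(noise_sd = 0)
  cc0 <- correct_curve(cv0)
  expect_equal(tail(cc0$force, 100), rep(0, 100), tolerance = 1e-12)
})

test_that("short or drop-free curves fall back to the final window", {
  z <- seq(0, 50, by = 0.1)
  ramp <- force_curve(z, 0.2 * z, metadata = list(spring_constant = 100))
  expect_warning(cc <- correct_curve(ramp), "final 20 nm")
  expect_equal(mean(cc$force[z > 30]), 0, tolerance = 1e-9)
})

test_that("rupture detection finds constructed drops at their indices", {
  # three large drops (~50, ~50, ~55 pN) in a noiseless sawtooth
  cv <- make_sawtooth(branches = data.frame(L = c(40, 90, 150),
                                            f_end = c(55, 55, 60)))
  cc <- correct_curve(cv)
  ev <- detect_ruptures(cc)
  truth <- attr(cv, "true_drops")
  expect_equal(nrow(ev), 3)
  expect_true(all(abs(ev$index - truth) <= 2))
  expect_equal(ev$force, c(55, 55, 60), tolerance = 2)
  expect_true(all(ev$drop > 35))
})

test_that("drops below the threshold are not reported", {
  # a shallow 8 pN step between two plateaus, then a detachment drop
  z <- seq(0, 80, by = 0.064)
  f <- ifelse(z < 20, 20, ifelse(z < 40, 12, ifelse(z < 60, 30, 0)))
  cv <- force_curve(z, f, metadata = list(spring_constant = 100))
  cc <- correct_curve(cv)
  ev <- detect_ruptures(cc, min_drop = 15)
  expect_false(any(abs(cc$separation[ev$index] - 20) < 2))
  # the same step clears a 5 pN threshold
  ev2 <- detect_ruptures(cc, min_drop = 5)
  expect_true(any(abs(cc$separation[ev2$index] - 20) < 2))
})

test_that("detection is idempotent under repeated denoising", {
  set.seed(14)
  cv <- make_sawtooth(branches = data.frame(L = c(40, 90, 150),
                                            f_end = c(55, 55, 60)),
                      noise_sd = 5)
  cc <- correct_curve(cv)
  ev1 <- detect_ruptures(cc)
  cc2 <- cc
  cc2$force <- denoise_tvd(cc$force)
  ev2 <- detect_ruptures(cc2)
  expect_equal(nrow(ev1), nrow(ev2))
  expect_true(all(abs(ev1$index - ev2$index) <= 3))
})

test_that("event forces are invariant to an added baseline offset", {
  set.seed(15)
  cv <- make_sawtooth(branches = data.frame(L = c(40, 90, 150),
                                            f_end = c(55, 55, 60)),
                      noise_sd = 5)
  ev1 <- detect_ruptures(correct_curve(cv))
  cv2 <- cv
  cv2$force <- cv2$force + 12
  ev2 <- detect_ruptures(correct_curve(cv2))
  expect_equal(nrow(ev1), nrow(ev2))
  expect_true(all(abs(ev1$force - ev2$force) <= 1))
})

test_that("low-force pass flags sub-threshold kinks separately", {
  cv <- make_sawtooth(branches = data.frame(L = c(33, 60, 90),
                                            f_end = c(18, 40, 45)))
  cc <- correct_curve(cv, min_drop = 12)
  ev <- detect_ruptures(cc, min_drop = 15, low_force_pass = TRUE)
  expect_true(any(ev$low_force))
  expect_true(any(!ev$low_force))
})
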