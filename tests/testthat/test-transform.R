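make_profile <- function(centers, weights = NULL, grid_max = 250,
                         sds = NULL, id = "synthetic") {
  grid <- seq(0, grid_max, by = 0.1)
  if (is.null(weights)) weights <- rep(1, length(centers))
  if (is.null(sds)) sds <- rep(2, length(centers))
  dens <- Reduce(`+`, Map(function(m, w, s) w * dnorm(grid, m, s),
                          centers, weights, sds))
  dens <- dens / (sum(dens) * 0.1)
  structure(list(grid = grid, density = dens, offset = 0,
                 n_points = 1000L, curve_id = id),
            class = "contour_profile")
}

test_that("a one-domain curve maps onto its two branch contour lengths", {
  tr <- rbind(transition_spec("S2S3", 62, 7e-5, 1.9),
              transition_spec("DETACH", 0, 2e-5, 0.5))
  m <- construct_model(tr, base_contour = 30)
  set.seed(19)
  cv <- simulate_curve(m, pulling_setup(noise_sd = 0))
  expect_identical(cv$events$label, c("S2S3", "DETACH"))
  pr <- to_contour_profile(correct_curve(cv))
  # local maxima of the profile density
  d <- pr$density
  peaks <- pr$grid[which(d > c(d[-1], 0) & d > c(0, d[-length(d)]) &
                           d > max(d) / 10)]
  expect_true(any(abs(peaks - 30) <= 1))
  expect_true(any(abs(peaks - 92) <= 1))
})

test_that("curves without enough usable points raise a classed exclusion", {
  z <- seq(0, 60, by = 0.1)
  low <- structure(list(separation = z, force = rep(3, length(z)),
                        baseline_offset = 0, baseline_range = c(40, 60),
                        source = NULL),
                   class = "corrected_curve")
  expect_error(to_contour_profile(low, curve_id = "weak"),
               class = "afm_exclusion")
  expect_error(to_contour_profile(low, curve_id = "weak"),
               "usable points")
})

test_that("profile densities integrate to one", {
  an <- fixture_analysis("ATP")
  step <- 0.1
  for (pr in an$profiles[1:30])
    expect_equal(sum(pr$density) * step, 1, tolerance = 1e-3)
  expect_equal(sum(an$template$density) * step, 1, tolerance = 1e-3)
})

test_that("two-pass alignment recovers constructed shifts to the grid step", {
  base <- c(33, 63.8, 125.6)
  shifts <- c(-7.3, 0, 4.1, 2.6, -3.9)
  profiles <- lapply(shifts, function(s) make_profile(base + s))
  res <- align_two_pass(profiles, seed = 11)
  off <- vapply(res$profiles, `[[`, 0, "offset")
  # each recovered offset undoes its shift up to one common constant
  resid <- off + shifts
  expect_lt(max(resid) - min(resid), 0.1 + 1e-9)
})

test_that("aligning an already-aligned set is a fixed point", {
  profiles <- replicate(4, make_profile(c(33, 63.8, 125.6)),
                        simplify = FALSE)
  res <- align_two_pass(profiles, seed = 5)
  expect_true(all(vapply(res$profiles, `[[`, 0, "offset") == 0))
})

test_that("alignment is equivariant under a common translation", {
  base <- c(33, 63.8, 125.6)
  set.seed(44)
  jit <- runif(6, -3, 3)
  mk <- function(c0) lapply(jit, function(s) make_profile(base + s + c0))
  r0 <- align_two_pass(mk(0), seed = 2)
  r9 <- align_two_pass(mk(9), seed = 2)
  p0 <- r0$template$grid[which.max(r0$template$density)]
  p9 <- r9$template$grid[which.max(r9$template$density)]
  expect_equal(p9 - p0, 9, tolerance = 0.2)
})

test_that("the template is robust to the seeded reference draw", {
  an <- fixture_analysis("ATP")
  profiles <- an$profiles[1:200]
  t1 <- align_two_pass(profiles, seed = 1)$template
  t2 <- align_two_pass(profiles, seed = 2)$template
  peak_near <- function(tpl, c0) {
    sel <- tpl$grid >= c0 - 8 & tpl$grid <= c0 + 8
    tpl$grid[sel][which.max(tpl$density[sel])]
  }
  for (c0 in c(33, 63.8, 125.6))
    expect_equal(peak_near(t1, c0), peak_near(t2, c0), tolerance = 1)
})

test_that("degenerate all-zero profiles are excluded from alignment", {
  good <- replicate(3, make_profile(c(40, 80)), simplify = FALSE)
  zero <- make_profile(c(40))
  zero$density <- zero$density * 0
  expect_message(res <- align_two_pass(c(good, list(zero)), seed = 1),
                 "degenerate")
  expect_identical(res$excluded, 4L)
})

test_that("Gaussian peak fits recover constructed increments", {
  tpl <- make_profile(c(30, 92), sds = c(5, 5))
  fits <- fit_increments(tpl, list(S2 = c(18, 42), S3 = c(80, 104)))
  expect_true(all(fits$peaks$reliable))
  inc <- fits$increments
  expect_equal(nrow(inc), 1)
  expect_equal(inc$mean, 62, tolerance = 0.1)
  expect_equal(inc$sd, sqrt(50), tolerance = 0.1)

  # a window with no peak inside is flagged unreliable
  fits2 <- fit_increments(tpl, list(S2 = c(18, 42), EMPTY = c(150, 174),
                                    S3 = c(80, 104)))
  expect_false(fits2$peaks$reliable[fits2$peaks$peak == "EMPTY"])
})

test_that("default peak windows follow the construct geometry", {
  m <- fixture_model("APO")
  w <- default_peak_windows(m)
  expect_equal(w$S1, c(33 - 12, 33 + 12))
  expect_equal(w$S2, c(63.8 - 12, 63.8 + 12))
  expect_equal(w$S3, c(125.6 - 12, 125.6 + 12))
  expect_equal(w$POST_FN3, c(155.6 - 12, 155.6 + 12))
})
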