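#' Transform a corrected curve into a contour-length density profile
#'
#' Every sample with force at or above `force_floor` is mapped to the
#' contour length of the WLC branch passing through it via
#' [wlc_inverse_contour()]; a Gaussian kernel density estimate
#' (bandwidth 1 nm by default) of the mapped points is evaluated on a
#' fixed uniform grid so that profiles from different curves can be
#' cross-correlated and superimposed.
#'
#' @param corrected A [correct_curve()] result.
#' @param persistence_length Persistence length in nm (default 0.4).
#' @param thermal_energy Thermal energy in pN nm (default 4.1).
#' @param bandwidth KDE bandwidth in nm (default 1).
#' @param grid_max Upper end of the contour-length grid in nm.
#' @param grid_step Grid spacing in nm (default 0.1).
#' @param force_floor Minimum usable force in pN (default 5); points below
#'   it are ill-conditioned for the inversion and are skipped.
#' @param min_points Minimum number of usable points (default 50); curves
#'   with fewer are rejected with a classed error (`afm_exclusion`) so
#'   that ensemble drivers can log and skip them.
#' @param curve_id Identifier stored in the profile.
#' @return An object of class `contour_profile` with fields `grid`,
#'   `density` (integrating to one), `offset` (0 until aligned),
#'   `n_points` and `curve_id`.
#' @export
to_contour_profile <- function(corrected, persistence_length = 0.4,
                               thermal_energy = 4.1, bandwidth = 1,
                               grid_max = 250, grid_step = 0.1,
                               force_floor = 5, min_points = 50,
                               curve_id = NA_character_) {
  stopifnot(inherits(corrected, "corrected_curve"))
  lc <- wlc_inverse_contour(corrected$force, corrected$separation,
                            persistence_length, thermal_energy,
                            floor = force_floor)
  lc <- lc[!is.na(lc) & lc <= grid_max]
  if (length(lc) < min_points) {
    cond <- structure(class = c("afm_exclusion", "error", "condition"),
                      list(message = paste0("curve ", curve_id, ": only ",
                                            length(lc), " usable points (< ",
                                            min_points, ")"),
                           call = NULL))
    stop(cond)
  }
  grid <- seq(0, grid_max, by = grid_step)
  dens <- binned_kde(lc, grid, bandwidth)
  structure(list(grid = grid, density = dens, offset = 0,
                 n_points = length(lc), curve_id = curve_id),
            class = "contour_profile")
}

#' @export
print.contour_profile <- function(x, ...) {
  cat("<contour_profile>", x$n_points, "points, grid [0,",
      max(x$grid), "] nm, offset", x$offset, "nm\n")
  invisible(x)
}

# Gaussian KDE on a fixed uniform grid via binning + discrete
# convolution with a truncated (5 sigma) Gaussian kernel, renormalized to
# integrate to one on the grid.
binned_kde <- function(points, grid, bandwidth) {
  step <- grid[2] - grid[1]
  counts <- tabulate(findInterval(points, grid - step / 2),
                     nbins = length(grid))
  half <- ceiling(5 * bandwidth / step)
  kern <- dnorm(seq(-half, half) * step, sd = bandwidth)
  dens <- as.numeric(stats::convolve(counts, rev(kern), type = "open"))
  dens <- dens[(half + 1):(half + length(grid))]
  dens <- pmax(dens, 0)
  dens / (sum(dens) * step)
}

# Shift a density vector by k grid steps (positive = toward larger Lc),
# zero padding.
shift_density <- function(d, k) {
  n <- length(d)
  out <- numeric(n)
  if (k >= 0) out[(1 + k):n] <- d[1:(n - k)]
  else out[1:(n + k)] <- d[(1 - k):n]
  out
}

#' Two-pass cross-correlation alignment of contour profiles
#'
#' Pass 1 aligns every profile to one profile drawn uniformly at random
#' (seeded, for reproducibility) by the integer grid shift within
#' `max_shift` nm minimizing the sum of squared density differences; the
#' mean of the aligned densities forms a first template. Pass 2 realigns
#' all original profiles to that template the same way. The two-step
#' procedure removes most of the bias introduced by the arbitrary choice
#' of the initial reference profile.
#'
#' @param profiles List of [to_contour_profile()] results on a common
#'   grid (at least 2). All-zero profiles are excluded with a message.
#' @param seed Integer seed for the reference draw.
#' @param max_shift Maximum shift magnitude in nm (default 20).
#' @return A list with `profiles` (offsets set, in nm), `template` (a
#'   `contour_profile` holding the pass-2 mean density), `reference_index`
#'   and `excluded` (indices of dropped profiles).
#' @export
align_two_pass <- function(profiles, seed = 1, max_shift = 20) {
  stopifnot(length(profiles) >= 2)
  grid <- profiles[[1]]$grid
  step <- grid[2] - grid[1]
  ok <- vapply(profiles, function(p) sum(p$density) > 0, logical(1))
  excluded <- which(!ok)
  if (length(excluded))
    message(length(excluded), " degenerate (all-zero) profile(s) excluded")
  idx <- which(ok)
  if (length(idx) < 2) stop("fewer than 2 usable profiles")
  ks <- as.integer(round(max_shift / step))

  ref_i <- idx[with_seed(seed, sample(length(idx), 1))]
  ref <- profiles[[ref_i]]$density
  k1 <- vapply(idx, function(i)
    .best_shift_cpp(profiles[[i]]$density, ref, ks), integer(1))
  aligned1 <- mapply(function(i, k) shift_density(profiles[[i]]$density, k),
                     idx, k1, SIMPLIFY = FALSE)
  template1 <- Reduce(`+`, aligned1) / length(aligned1)

  k2 <- vapply(idx, function(i)
    .best_shift_cpp(profiles[[i]]$density, template1, ks), integer(1))
  aligned2 <- mapply(function(i, k) shift_density(profiles[[i]]$density, k),
                     idx, k2, SIMPLIFY = FALSE)
  template2 <- Reduce(`+`, aligned2) / length(aligned2)

  for (j in seq_along(idx)) profiles[[idx[j]]]$offset <- k2[j] * step
  template <- structure(list(grid = grid,
                             density = template2 / (sum(template2) * step),
                             offset = 0, n_points = NA_integer_,
                             curve_id = "template"),
                        class = "contour_profile")
  list(profiles = profiles, template = template, reference_index = ref_i,
       excluded = excluded)
}

#' Default contour-length peak windows for a construct model
#'
#' Peak centres follow the expected branch contour lengths of the
#' construct: the S1 branch (base contour plus the small S0->S1 release),
#' then each successive branch after the kinase lobes and the Fn3 domain.
#'
#' @param model A [construct_model()].
#' @param half_width Window half width in nm (default 12).
#' @return Named list of `c(lo, hi)` windows in nm, in peak order
#'   (`S1`, `S2`, `S3`, `POST_FN3` when present).
#' @export
default_peak_windows <- function(model, half_width = 12) {
  bc <- branch_contours(model)
  tr <- model$transitions
  centres <- c()
  if ("S1S2" %in% tr$label) centres["S1"] <- bc[["S1S2"]]
  if ("S2S3" %in% tr$label) centres["S2"] <- bc[["S2S3"]]
  if ("FN3" %in% tr$label) {
    centres["S3"] <- bc[["FN3"]]
    centres["POST_FN3"] <- bc[["FN3"]] + tr$delta_contour[tr$label == "FN3"]
  } else if ("S2S3" %in% tr$label) {
    centres["S3"] <- bc[["S2S3"]] + tr$delta_contour[tr$label == "S2S3"]
  }
  lapply(as.list(centres), function(m) c(m - half_width, m + half_width))
}

#' Fit Gaussian peaks to a template profile and extract increments
#'
#' One Gaussian (amplitude, mean, sd) is fitted per window by
#' least squares on the template density; contour-length increments are
#' the differences of the means of consecutive peaks, with the increment
#' error combined from both peak standard deviations in quadrature.
#' Windows whose fit fails to converge, whose fitted mean leaves the
#' window, or whose sd exceeds the window width are flagged unreliable.
#'
#' @param template A `contour_profile`, typically the template from
#'   [align_two_pass()].
#' @param peak_windows Named list of `c(lo, hi)` windows in nm, in
#'   increasing peak order; see [default_peak_windows()].
#' @return A list with `peaks` (one row per window: mean, sd, amplitude,
#'   reliable) and `increments` (one row per consecutive reliable pair:
#'   name, mean, sd, and both peak means/sds). Kinase increments get the
#'   conventional names `L12` (S1-S2), `L23` (S2-S3), `FN3` (S3-POST_FN3).
#' @export
fit_increments <- function(template, peak_windows) {
  stopifnot(inherits(template, "contour_profile"), length(peak_windows) >= 1)
  grid <- template$grid
  dens <- template$density
  fits <- lapply(names(peak_windows), function(nm) {
    w <- peak_windows[[nm]]
    sel <- grid >= w[1] & grid <= w[2]
    x <- grid[sel]; y <- dens[sel]
    if (!length(x) || max(y) <= 0)
      return(data.frame(peak = nm, mean = NA, sd = NA, amplitude = NA,
                        reliable = FALSE))
    st <- list(a = max(y), m = x[which.max(y)], s = 3)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-(x - m)^2 / (2 * s^2)), start = st,
                        lower = c(a = 0, m = w[1], s = 0.2),
                        upper = c(a = Inf, m = w[2], s = diff(w)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(peak = nm, mean = NA, sd = NA, amplitude = NA,
                        reliable = FALSE))
    cf <- stats::coef(fit)
    ok <- cf[["s"]] < diff(w) && cf[["m"]] > w[1] + 1e-6 &&
      cf[["m"]] < w[2] - 1e-6 && cf[["a"]] > 1e-6
    data.frame(peak = nm, mean = cf[["m"]], sd = abs(cf[["s"]]),
               amplitude = cf[["a"]], reliable = ok)
  })
  peaks <- do.call(rbind, fits)
  rownames(peaks) <- NULL

  inc_name <- function(a, b) {
    key <- paste(a, b, sep = ">")
    switch(key, "S1>S2" = "L12", "S2>S3" = "L23", "S3>POST_FN3" = "FN3",
           paste0(a, "_", b))
  }
  incs <- list()
  for (i in seq_len(nrow(peaks) - 1)) {
    p1 <- peaks[i, ]; p2 <- peaks[i + 1, ]
    if (!isTRUE(p1$reliable) || !isTRUE(p2$reliable)) next
    incs[[length(incs) + 1]] <- data.frame(
      name = inc_name(p1$peak, p2$peak),
      mean = p2$mean - p1$mean,
      sd = sqrt(p1$sd^2 + p2$sd^2),
      peak1_mean = p1$mean, peak1_sd = p1$sd,
      peak2_mean = p2$mean, peak2_sd = p2$sd)
  }
  increments <- if (length(incs)) do.call(rbind, incs) else
    data.frame(name = character(), mean = numeric(), sd = numeric(),
               peak1_mean = numeric(), peak1_sd = numeric(),
               peak2_mean = numeric(), peak2_sd = numeric())
  rownames(increments) <- NULL
  list(peaks = peaks, increments = increments)
}
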