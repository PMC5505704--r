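#' Constant-velocity pulling setup
#'
#' Instrument parameters of a simulated (or recorded) AFM retraction.
#' Defaults: 800 nm/s retraction, 100 pN/nm cantilever spring constant
#' (typical for short bioLever-class cantilevers), 12500 samples/s (one
#' sample per 0.064 nm of piezo travel) and 5 pN Gaussian force noise, so
#' that ~10-15 pN events sit at the edge of the noise band.
#'
#' @param retraction_speed Piezo retraction speed in nm/s.
#' @param spring_constant Cantilever spring constant in pN/nm.
#' @param sampling_rate Samples per second.
#' @param noise_sd Gaussian force noise standard deviation in pN.
#' @param seed Optional integer seed recorded in curve metadata.
#' @return An object of class `pulling_setup`.
#' @export
pulling_setup <- function(retraction_speed = 800, spring_constant = 100,
                          sampling_rate = 12500, noise_sd = 5,
                          seed = NULL) {
  stopifnot(retraction_speed > 0, spring_constant > 0, sampling_rate > 0,
            noise_sd >= 0)
  structure(list(retraction_speed = retraction_speed,
                 spring_constant = spring_constant,
                 sampling_rate = sampling_rate, noise_sd = noise_sd,
                 seed = seed),
            class = "pulling_setup")
}

#' Construct a force curve object
#'
#' @param distance Piezo distance in nm (strictly increasing).
#' @param force Measured force in pN, same length as `distance`.
#' @param events Data frame with columns `index` (sample) and `label`
#'   (transition) — the truth log for synthetic curves, empty otherwise.
#' @param metadata Named list; for simulated curves contains the
#'   [pulling_setup()] fields plus `condition`, `characteristic`,
#'   `truncated`.
#' @param time Optional sample times in s.
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(distance, force, events = NULL, metadata = list(),
                        time = NULL) {
  stopifnot(length(distance) == length(force))
  if (length(distance) > 1 && any(diff(distance) <= 0))
    stop("piezo distance must be strictly increasing")
  if (is.null(events))
    events <- data.frame(index = integer(), label = character(),
                         stringsAsFactors = FALSE)
  structure(list(distance = distance, force = force, time = time,
                 events = events, metadata = metadata),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat("<force_curve>", length(x$force), "samples,",
      nrow(x$events), "logged events,",
      "condition:", x$metadata$condition %||% "unknown", "\n")
  invisible(x)
}

#' Simulate one constant-velocity pulling curve
#'
#' Monte-Carlo integration of the pulling experiment: at each time step
#' the piezo advances by `v * dt`, the cantilever deflection `d` solves
#' the force balance `k_c d = F_wlc(z - d; Lc)` by bisection, the
#' recorded force is `k_c d` plus Gaussian noise, and every live
#' transition fires with probability `1 - exp(-k0 exp(F dx / kT) dt)`.
#' Firing adds the transition's released contour length to `Lc`
#' (detachment ends the curve and is followed by a 30 nm zero-force
#' baseline tail). Kinase transitions fire in strict order; Fn3/Ig-like
#' domains and detachment compete by first passage throughout.
#'
#' @param model A calibrated [construct_model()].
#' @param setup A [pulling_setup()].
#' @param max_pull Maximum piezo travel in nm; if detachment has not fired
#'   by then the curve is truncated with a warning.
#' @return A [force_curve()] with the truth event log in `$events`.
#' @export
simulate_curve <- function(model, setup = pulling_setup(),
                           max_pull = 400) {
  stopifnot(inherits(model, "construct_model"),
            inherits(setup, "pulling_setup"))
  tr <- model$transitions
  if (anyNA(tr$intrinsic_rate))
    stop("model has uncalibrated transitions (intrinsic_rate is NA)")
  res <- .simulate_pull_cpp(tr$delta_contour, tr$intrinsic_rate,
                            tr$barrier_distance,
                            tr$label %in% kinase_labels,
                            tr$label == "DETACH",
                            model$base_contour,
                            setup$retraction_speed, setup$spring_constant,
                            setup$sampling_rate, setup$noise_sd,
                            0.4, 4.1, max_pull)
  if (res$truncated)
    warning("detachment did not fire within ", max_pull,
            " nm; curve truncated")
  events <- data.frame(index = res$event_index,
                       label = tr$label[res$event_transition],
                       stringsAsFactors = FALSE)
  md <- unclass(setup)
  md$condition <- model$condition
  md$characteristic <- TRUE
  md$truncated <- res$truncated
  cv <- force_curve(res$distance, res$force, events, md)
  cv$force_clean <- res$force_clean
  cv
}

# Non-characteristic contaminant curves: either a short-range adhesion
# peak detaching within the first ~10 nm, or an immediate detachment
# (noise-only trace).
simulate_contaminant <- function(setup, max_pull = 400) {
  dt <- 1 / setup$sampling_rate
  step <- setup$retraction_speed * dt
  n <- ceiling(max_pull / step)
  z <- (seq_len(n) - 1) * step
  f <- rnorm(n, 0, setup$noise_sd)
  kind <- if (runif(1) < 0.5) "adhesion" else "empty"
  if (kind == "adhesion") {
    z_off <- runif(1, 4, 10)
    amp <- runif(1, 40, 120)
    in_peak <- z < z_off
    f[in_peak] <- f[in_peak] + amp * (z[in_peak] / z_off)^2
  }
  md <- unclass(setup)
  md$condition <- "CONTAMINANT"
  md$characteristic <- FALSE
  md$truncated <- FALSE
  md$contaminant_kind <- kind
  force_curve(z, f, NULL, md)
}

#' Simulate an ensemble of pulling curves
#'
#' Generates `n` curves with independent per-curve seeds derived from the
#' master seed (identical master seed gives bit-identical ensembles). A
#' deterministic count `round(n * contamination_fraction)` of curves, at
#' seeded random positions, is replaced by non-characteristic contaminant
#' curves (adhesion peak or immediate detachment) to exercise the
#' fingerprint filter.
#'
#' @param model A calibrated [construct_model()].
#' @param n Number of curves (> 0).
#' @param setup A [pulling_setup()].
#' @param contamination_fraction Fraction in `[0, 1)` of non-characteristic
#'   curves.
#' @param seed Master seed (integer).
#' @param max_pull Maximum piezo travel in nm per curve.
#' @return A list of [force_curve()] objects.
#' @export
simulate_ensemble <- function(model, n, setup = pulling_setup(),
                              contamination_fraction = 0, seed = 1,
                              max_pull = 400) {
  if (!is.numeric(n) || n <= 0) stop("n must be a positive count")
  stopifnot(contamination_fraction >= 0, contamination_fraction < 1)
  n <- as.integer(n)
  plan <- with_seed(seed, {
    list(seeds = sample.int(.Machine$integer.max - 1L, n),
         contam = sample(n, round(contamination_fraction * n)))
  })
  lapply(seq_len(n), function(i) {
    with_seed(plan$seeds[i], {
      if (i %in% plan$contam) simulate_contaminant(setup, max_pull)
      else simulate_curve(model, setup, max_pull)
    })
  })
}
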