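#' Expected WLC-branch contour lengths for transition assignment
#'
#' Returns the contour length of the branch on which each transition's
#' rupture occurs (base contour plus everything released before it),
#' used to label detected events by where their pre-drop branch maps in
#' contour-length space. The sub-noise S0->S1 transition is omitted by
#' default (its drops are below the detection threshold); Ig-like
#' branches are collapsed into a generic `IG` ladder.
#'
#' @param model A [construct_model()].
#' @return Named numeric vector of branch contour lengths in nm.
#' @export
expected_branches <- function(model) {
  bc <- branch_contours(model)
  tr <- model$transitions
  out <- c()
  if ("S1S2" %in% tr$label) out["S1S2"] <- bc[["S1S2"]]
  if ("S2S3" %in% tr$label) out["S2S3"] <- bc[["S2S3"]]
  if ("FN3" %in% tr$label) out["FN3"] <- bc[["FN3"]]
  igs <- intersect(c("IG1", "IG2", "IGT"), tr$label)
  if (length(igs) && "FN3" %in% tr$label) {
    post <- bc[["FN3"]] + tr$delta_contour[tr$label == "FN3"]
    ig_d <- tr$delta_contour[tr$label %in% igs]
    ladder <- post + cumsum(c(0, head(ig_d, -1)))
    names(ladder) <- paste0("IG", seq_along(ladder))
    out <- c(out, ladder)
  }
  out
}

#' Label detected rupture events by their contour-length branch
#'
#' Each event's pre-drop branch contour length is computed by
#' [wlc_inverse_contour()] from its peak force and separation, shifted by
#' the curve's alignment offset if one is supplied, and matched to the
#' nearest expected branch within `tolerance`. The final event of a curve
#' whose force stays below 10 pN afterwards is labeled `DETACH`
#' regardless of branch (the tether can rupture from any state).
#' Unmatched events are labeled `UNASSIGNED`. Ig-like branches are
#' reported with the collapsed label `IG`. An optional `override`
#' function (event data frame in, label vector out) stands in for the
#' manual double-checking step of an interactive review; the automated
#' default applies no override.
#'
#' @param events A [detect_ruptures()] data frame.
#' @param corrected The matching [correct_curve()] result.
#' @param model A [construct_model()] providing the expected branch
#'   ladder (or pass `expected` directly).
#' @param expected Named vector of expected branch contour lengths in nm.
#' @param offset Alignment offset in nm to subtract from branch contour
#'   lengths (from [align_two_pass()]; 0 by default).
#' @param tolerance Maximum branch distance in nm for a match (default 14).
#' @param persistence_length,thermal_energy WLC constants.
#' @param override Optional function for label review.
#' @return The events data frame with `label` and `branch_lc` filled in.
#' @export
assign_transitions <- function(events, corrected, model = NULL,
                               expected = NULL, offset = 0,
                               tolerance = 14, persistence_length = 0.4,
                               thermal_energy = 4.1, override = NULL) {
  stopifnot(inherits(corrected, "corrected_curve"))
  if (is.null(expected)) {
    stopifnot(!is.null(model))
    expected <- expected_branches(model)
  }
  ev <- as.data.frame(events)
  if (!nrow(ev)) {
    ev$branch_lc <- numeric(0)
    return(ev)
  }
  ev$branch_lc <- wlc_inverse_contour(ev$force, ev$separation,
                                      persistence_length, thermal_energy,
                                      floor = 0.5) - offset
  labs <- rep("UNASSIGNED", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    if (is.na(ev$branch_lc[i])) next
    d <- abs(expected - ev$branch_lc[i])
    j <- which.min(d)
    if (d[j] <= tolerance) {
      l <- names(expected)[j]
      labs[i] <- if (grepl("^IG", l)) "IG" else l
    }
  }
  # final event followed only by baseline-level force -> detachment
  last <- which.max(ev$index)
  after <- corrected$force[seq(min(ev$index[last] + 5,
                                   length(corrected$force)),
                               length(corrected$force))]
  if (length(after) && median(after) < 10) labs[last] <- "DETACH"
  ev$label <- labs
  if (!is.null(override)) ev$label <- override(ev)
  ev
}

#' Filter curves for the characteristic unfolding fingerprint
#'
#' Accepts curves showing the characteristic pattern: at least
#' `min_kinase_events` labeled kinase transitions (S1->S2 / S2->S3) and
#' all event branch contour lengths within the total tether bound of the
#' construct. Rejection reasons are returned per curve.
#'
#' @param labeled_events List of [assign_transitions()] data frames, one
#'   per curve.
#' @param model The [construct_model()] defining the tether bound.
#' @param min_kinase_events Minimum number of kinase-region events
#'   (default 2).
#' @param slack Extra allowance in nm on the total tether bound.
#' @return A list with `accepted` (logical vector) and `reasons`
#'   (character vector, empty string for accepted curves).
#' @export
fingerprint_filter <- function(labeled_events, model,
                               min_kinase_events = 2, slack = 20) {
  lc_max <- model$base_contour + sum(model$transitions$delta_contour) + slack
  res <- vapply(labeled_events, function(ev) {
    if (!nrow(ev)) return("no rupture events detected")
    nk <- sum(ev$label %in% c("S1S2", "S2S3"))
    if (nk < min_kinase_events)
      return(sprintf("only %d kinase-region event(s)", nk))
    if (any(!is.na(ev$branch_lc) & ev$branch_lc > lc_max))
      return("branch contour length exceeds construct tether bound")
    ""
  }, character(1))
  list(accepted = res == "", reasons = res)
}

#' Rupture-force statistics for one transition
#'
#' Builds the force histogram, and extracts the most probable rupture
#' force either from a maximum-likelihood Bell-Evans fit of the unbinned
#' forces (`mode_method = "BELL_EVANS"`, loading rate fixed at its
#' measured value) or as the argmax of a 1 pN-bandwidth Gaussian kernel
#' density estimate (`"KDE_1PN"`, used where the force distribution
#' deviates from the single-barrier Bell-Evans shape, as for S2->S3).
#'
#' @param forces Rupture forces in pN for one transition.
#' @param transition Transition label (bookkeeping only).
#' @param mode_method `"BELL_EVANS"` or `"KDE_1PN"`.
#' @param loading_rate Median pre-rupture loading rate in pN/s (required
#'   for the Bell-Evans fit).
#' @param bin_width Histogram bin width in pN (default 5).
#' @param thermal_energy Thermal energy in pN nm.
#' @return An object of class `force_stats`: `transition`, `n`,
#'   `histogram` ([histogram_table()]), `fit` (a `bell_evans_params` or
#'   `NULL`), `mode` (pN), `mode_method`, `low_n` flag.
#' @export
force_stats <- function(forces, transition = "UNASSIGNED",
                        mode_method = c("BELL_EVANS", "KDE_1PN"),
                        loading_rate = NULL, bin_width = 5,
                        thermal_energy = 4.1) {
  mode_method <- match.arg(mode_method)
  stopifnot(length(forces) >= 5, all(is.finite(forces)))
  low_n <- length(forces) < 30
  if (low_n)
    warning("only ", length(forces), " forces for ", transition,
            " (< 30); statistics flagged low-n")
  breaks <- seq(0, ceiling(max(forces) / bin_width + 1) * bin_width,
                by = bin_width)
  counts <- tabulate(findInterval(forces, breaks), nbins = length(breaks) - 1)
  hist <- histogram_table(head(breaks, -1), counts, quantity = "force_pN",
                          condition = transition, bandwidth = bin_width)
  fit <- NULL
  if (mode_method == "BELL_EVANS") {
    stopifnot(!is.null(loading_rate), loading_rate > 0)
    fit <- bell_evans_fit(forces, loading_rate, thermal_energy)
    mode <- bell_evans_mode(fit, thermal_energy)
  } else {
    d <- density(forces, bw = 1, n = 2048,
                 from = max(0, min(forces) - 5), to = max(forces) + 5)
    mode <- d$x[which.max(d$y)]
  }
  structure(list(transition = transition, n = length(forces),
                 histogram = hist, fit = fit, mode = mode,
                 mode_method = mode_method, loading_rate = loading_rate,
                 forces = forces, low_n = low_n),
            class = "force_stats")
}

#' @export
print.force_stats <- function(x, ...) {
  cat("<force_stats>", x$transition, " n =", x$n, " mode =",
      signif(x$mode, 4), "pN (", x$mode_method, ")\n")
  invisible(x)
}

#' Normalize rupture forces across datasets by the Fn3 anchor
#'
#' Forces recorded with different cantilevers are only comparable after
#' rescaling; since Fn3 unfolding is insensitive to all ligand
#' conditions, its most probable unfolding force anchors the scale. Every
#' force in dataset *i* is multiplied by
#' `reference Fn3 mode / dataset-i Fn3 mode`. Each dataset's Fn3 mode
#' must be built only from curves that detached after Fn3 unfolding.
#'
#' @param datasets Named list (by condition); each element is a list with
#'   `fn3_mode` (pN) and `forces`, a named list of force vectors per
#'   transition.
#' @param reference Name of the reference dataset.
#' @return A list with `datasets` (forces and `fn3_mode` rescaled) and
#'   `scale_factors`. Datasets lacking an Fn3 mode are dropped with a
#'   warning.
#' @export
normalize_by_fn3 <- function(datasets, reference) {
  stopifnot(reference %in% names(datasets))
  has_fn3 <- vapply(datasets, function(d)
    !is.null(d$fn3_mode) && is.finite(d$fn3_mode), logical(1))
  if (!has_fn3[[reference]])
    stop("reference dataset has no Fn3 mode")
  if (any(!has_fn3)) {
    warning("dataset(s) without Fn3 stats excluded: ",
            paste(names(datasets)[!has_fn3], collapse = ", "))
    datasets <- datasets[has_fn3]
  }
  ref_mode <- datasets[[reference]]$fn3_mode
  sf <- vapply(datasets, function(d) ref_mode / d$fn3_mode, numeric(1))
  out <- mapply(function(d, s) {
    d$forces <- lapply(d$forces, function(f) f * s)
    d$fn3_mode <- d$fn3_mode * s
    d
  }, datasets, sf, SIMPLIFY = FALSE)
  list(datasets = out, scale_factors = sf)
}

#' Assemble a force-distance heatmap from corrected curves
#'
#' Raw samples of all curves are binned on a `bins x bins` grid (750 per
#' axis by default, matching the ensemble-overlay resolution used for
#' visualizing the characteristic pattern). Curves are first aligned in
#' force-distance space by a horizontal shift that moves each curve's
#' Fn3 rupture position — or, failing that, its last rupture — onto the
#' ensemble median.
#'
#' @param corrected_curves List of [correct_curve()] results.
#' @param labeled_events Optional list of [assign_transitions()] frames
#'   (needed for landmark alignment; without it no alignment is applied).
#' @param force_range `c(lo, hi)` in pN.
#' @param distance_range `c(lo, hi)` in nm.
#' @param bins Bins per axis (default 750).
#' @param align Align curves by their Fn3/last-rupture landmark.
#' @return An object of class `heatmap_grid`: `counts` (distance bins in
#'   rows, force bins in columns), `distance_breaks`, `force_breaks`,
#'   `n_in_range`.
#' @export
build_heatmap <- function(corrected_curves, labeled_events = NULL,
                          force_range = c(0, 300),
                          distance_range = c(0, 300), bins = 750,
                          align = !is.null(labeled_events)) {
  counts <- matrix(0L, nrow = bins, ncol = bins)
  db <- seq(distance_range[1], distance_range[2], length.out = bins + 1)
  fb <- seq(force_range[1], force_range[2], length.out = bins + 1)
  if (!length(corrected_curves))
    return(structure(list(counts = counts, distance_breaks = db,
                          force_breaks = fb, n_in_range = 0L),
                     class = "heatmap_grid"))
  shifts <- numeric(length(corrected_curves))
  if (align && !is.null(labeled_events)) {
    landmark <- vapply(seq_along(corrected_curves), function(i) {
      ev <- labeled_events[[i]]
      if (!nrow(ev)) return(NA_real_)
      j <- which(ev$label == "FN3")
      if (length(j)) ev$separation[j[1]] else ev$separation[nrow(ev)]
    }, numeric(1))
    med <- median(landmark, na.rm = TRUE)
    shifts <- ifelse(is.na(landmark), 0, med - landmark)
  }
  lin <- lapply(seq_along(corrected_curves), function(i) {
    cc <- corrected_curves[[i]]
    x <- cc$separation + shifts[i]
    y <- cc$force
    keep <- x >= distance_range[1] & x < distance_range[2] &
      y >= force_range[1] & y < force_range[2]
    if (!any(keep)) return(integer(0))
    ix <- pmin(findInterval(x[keep], db, rightmost.closed = TRUE), bins)
    iy <- pmin(findInterval(y[keep], fb, rightmost.closed = TRUE), bins)
    ix + (iy - 1L) * bins
  })
  lin <- unlist(lin)
  total <- length(lin)
  if (total)
    counts <- matrix(tabulate(lin, nbins = bins * bins), nrow = bins)
  structure(list(counts = counts, distance_breaks = db, force_breaks = fb,
                 n_in_range = total),
            class = "heatmap_grid")
}
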