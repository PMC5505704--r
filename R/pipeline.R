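#' Pipeline run configuration
#'
#' Collects every tunable parameter of the analysis chain with its
#' default. All values are plain scalars, so a configuration serializes
#' cleanly to JSON/YAML and a fixed configuration plus seed reproduces a
#' run exactly.
#'
#' @param ... Overrides of the defaults listed below.
#' @return An object of class `run_config` (a named list):
#' \describe{
#'   \item{persistence_length, thermal_energy}{WLC constants: 0.4 nm,
#'     4.1 pN nm.}
#'   \item{force_floor}{Minimum force transformed to contour length
#'     (5 pN).}
#'   \item{min_drop}{Rupture detection threshold (15 pN).}
#'   \item{bandwidth_nm, bandwidth_pn}{KDE bandwidths: 1 nm in contour
#'     length space, 1 pN in force space.}
#'   \item{grid_max, grid_step}{Contour-length grid (250 nm, 0.1 nm).}
#'   \item{max_shift}{Alignment search range (±20 nm).}
#'   \item{peak_half_width}{Gaussian fit window half width (12 nm).}
#'   \item{bin_width_pn}{Force histogram bin width (5 pN).}
#'   \item{min_points}{Minimum usable points per curve (50).}
#'   \item{condition, n_curves, contamination, seed}{Simulation preset
#'     controls.}
#'   \item{retraction_speed, spring_constant, sampling_rate, noise_sd}{
#'     Pulling setup (800 nm/s, 100 pN/nm, 12500 /s, 5 pN).}
#'   \item{heatmap, heatmap_bins}{Whether to build the force-distance
#'     heatmap, and its per-axis bin count (750).}
#'   \item{write_curves}{Also write every simulated curve to disk
#'     (off by default; ensembles are large).}
#' }
#' @export
run_config <- function(...) {
  defaults <- list(
    persistence_length = 0.4, thermal_energy = 4.1,
    force_floor = 5, min_drop = 15,
    bandwidth_nm = 1, bandwidth_pn = 1,
    grid_max = 250, grid_step = 0.1,
    max_shift = 20, peak_half_width = 12,
    bin_width_pn = 5, min_points = 50,
    condition = "APO", n_curves = 500, contamination = 0, seed = 1,
    retraction_speed = 800, spring_constant = 100,
    sampling_rate = 12500, noise_sd = 5,
    heatmap = FALSE, heatmap_bins = 750,
    write_curves = FALSE)
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  structure(modifyList(defaults, overrides), class = "run_config")
}

config_setup <- function(config) {
  pulling_setup(config$retraction_speed, config$spring_constant,
                config$sampling_rate, config$noise_sd)
}

#' Analyze one ensemble of force curves
#'
#' Runs the full per-dataset chain: bending/baseline correction, rupture
#' detection, transition assignment, fingerprint filtering,
#' contour-length transformation, two-pass alignment, Gaussian increment
#' fitting, and per-transition rupture-force statistics (Bell-Evans fit
#' at the measured median loading rate; KDE mode additionally, and as the
#' primary mode for S2->S3, whose force distribution deviates from the
#' single-barrier shape). Fn3 statistics use only curves that detached
#' after Fn3 unfolding, as required for cross-dataset normalization.
#'
#' @param curves List of [force_curve()] objects.
#' @param model The [construct_model()] describing the construct (used
#'   for expected branch windows; for measured data, a preset of the
#'   matching condition).
#' @param config A [run_config()].
#' @return A list of class `ensemble_analysis`: per-curve results
#'   (`corrected`, `events`), filter outcome, alignment (`profiles`,
#'   `template`), `increments`, `stats` (per transition), `counts` at
#'   each stage, `exclusions` log, and optionally `heatmap`.
#' @export
analyze_ensemble <- function(curves, model, config = run_config()) {
  stopifnot(length(curves) >= 2, inherits(model, "construct_model"))
  exclusions <- character()

  corrected <- vector("list", length(curves))
  events <- vector("list", length(curves))
  for (i in seq_along(curves)) {
    cc <- tryCatch(suppressWarnings(correct_curve(curves[[i]],
                                                  min_drop = config$min_drop)),
                   error = function(e) e)
    if (inherits(cc, "error")) {
      exclusions <- c(exclusions,
                      sprintf("curve %d: correction failed (%s)", i,
                              conditionMessage(cc)))
      next
    }
    corrected[[i]] <- cc
    ev <- detect_ruptures(cc, min_drop = config$min_drop)
    events[[i]] <- assign_transitions(ev, cc, model,
                                      persistence_length =
                                        config$persistence_length,
                                      thermal_energy = config$thermal_energy)
  }
  usable <- which(!vapply(corrected, is.null, logical(1)))

  filt <- fingerprint_filter(events[usable], model)
  accepted <- usable[filt$accepted]
  reasons <- filt$reasons[!filt$accepted]
  if (length(reasons))
    exclusions <- c(exclusions,
                    sprintf("curve %d: rejected by fingerprint filter (%s)",
                            usable[!filt$accepted], reasons))

  profiles <- list()
  profile_curve <- integer()
  for (i in accepted) {
    pr <- tryCatch(
      to_contour_profile(corrected[[i]],
                         persistence_length = config$persistence_length,
                         thermal_energy = config$thermal_energy,
                         bandwidth = config$bandwidth_nm,
                         grid_max = config$grid_max,
                         grid_step = config$grid_step,
                         force_floor = config$force_floor,
                         min_points = config$min_points,
                         curve_id = as.character(i)),
      afm_exclusion = function(e) e)
    if (inherits(pr, "afm_exclusion")) {
      exclusions <- c(exclusions, conditionMessage(pr))
      next
    }
    profiles[[length(profiles) + 1]] <- pr
    profile_curve <- c(profile_curve, i)
  }

  alignment <- NULL
  increments <- NULL
  if (length(profiles) >= 2) {
    alignment <- align_two_pass(profiles, seed = config$seed,
                                max_shift = config$max_shift)
    increments <- fit_increments(alignment$template,
                                 default_peak_windows(model,
                                                      config$peak_half_width))
  }

  stats_out <- transition_force_stats(events, corrected, accepted, config)

  counts <- c(input = length(curves), corrected = length(usable),
              accepted = length(accepted), profiled = length(profiles))

  heat <- NULL
  if (isTRUE(config$heatmap) && length(accepted))
    heat <- build_heatmap(corrected[accepted], events[accepted],
                          bins = config$heatmap_bins)

  structure(list(corrected = corrected, events = events,
                 accepted = accepted, filter = filt,
                 profiles = if (is.null(alignment)) profiles else
                   alignment$profiles,
                 template = alignment$template,
                 increments = increments, stats = stats_out,
                 counts = counts, exclusions = exclusions,
                 heatmap = heat, profile_curve = profile_curve,
                 model = model, config = config),
            class = "ensemble_analysis")
}

# Per-transition rupture-force statistics from labeled events of the
# accepted curves. Fn3 restricted to curves with DETACH after FN3.
transition_force_stats <- function(events, corrected, accepted, config) {
  samples <- list()   # transition -> list(forces, rates)
  add <- function(tr, f, r) {
    e <- samples[[tr]] %||% list(forces = numeric(), rates = numeric())
    e$forces <- c(e$forces, f)
    e$rates <- c(e$rates, r)
    samples[[tr]] <<- e
  }
  for (i in accepted) {
    ev <- events[[i]]
    if (!nrow(ev)) next
    cc <- corrected[[i]]
    md <- cc$source$metadata
    dt <- 1 / (md$sampling_rate %||%
                 (length(cc$force) / max(cc$source$distance) *
                    md$retraction_speed))
    fn3_ok <- any(ev$label == "FN3") &&
      any(ev$label == "DETACH" &
            ev$index > suppressWarnings(min(ev$index[ev$label == "FN3"])))
    for (k in seq_len(nrow(ev))) {
      lab <- ev$label[k]
      if (lab %in% c("UNASSIGNED")) next
      if (lab == "FN3" && !fn3_ok) next
      lo <- if (k > 1) ev$index[k - 1] + 2 else 1
      r <- loading_rate_at(cc$force, ev$index[k], dt, lo)
      add(lab, ev$force[k], r)
    }
  }
  out <- list()
  for (tr in names(samples)) {
    f <- samples[[tr]]$forces
    if (length(f) < 5) next
    r <- median(samples[[tr]]$rates, na.rm = TRUE)
    method <- if (tr == "S2S3") "KDE_1PN" else "BELL_EVANS"
    st <- tryCatch(
      suppressWarnings(force_stats(f, tr, method,
                                   loading_rate = if (is.finite(r)) r else 1,
                                   bin_width = config$bin_width_pn,
                                   thermal_energy = config$thermal_energy)),
      error = function(e) NULL)
    if (is.null(st)) next
    # secondary mode by the other method, for comparison
    st$kde_mode <- if (method == "KDE_1PN") st$mode else {
      d <- density(f, bw = config$bandwidth_pn, n = 2048)
      d$x[which.max(d$y)]
    }
    if (method == "KDE_1PN" && length(f) >= 30 && is.finite(r)) {
      be <- tryCatch(bell_evans_fit(f, r, config$thermal_energy),
                     error = function(e) NULL)
      if (!is.null(be)) {
        st$fit <- be
        st$bell_evans_mode <- bell_evans_mode(be, config$thermal_energy)
      }
    }
    out[[tr]] <- st
  }
  out
}

#' Run the full pipeline
#'
#' Simulates (or reads) an ensemble per condition, analyzes each with
#' [analyze_ensemble()], optionally normalizes forces across conditions
#' by the Fn3 anchor, and writes histogram tables, increment tables,
#' heatmaps and a machine-readable JSON summary.
#'
#' @param config A [run_config()]. For preset runs, `condition`,
#'   `n_curves`, `contamination` and `seed` control the simulation.
#' @param manifest Optional path to a dataset manifest
#'   ([read_manifest()]); when given, curves are read from disk instead
#'   of simulated and grouped by condition.
#' @param outdir Optional output directory; created if missing. When
#'   `NULL` nothing is written.
#' @return A list of class `pipeline_report`: `analyses` (one
#'   [analyze_ensemble()] result per condition), `normalization` (when
#'   more than one condition), and `summary` (the JSON-ready list).
#' @export
run_full <- function(config = run_config(), manifest = NULL,
                     outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  setup <- config_setup(config)

  if (is.null(manifest)) {
    conds <- config$condition
    model <- condition_preset(config$condition, setup)
    ensembles <- stats::setNames(list(
      simulate_ensemble(model, config$n_curves, setup,
                        contamination_fraction = config$contamination,
                        seed = config$seed)), config$condition)
    models <- stats::setNames(list(model), config$condition)
    reference <- config$condition
  } else {
    mf <- read_manifest(manifest)
    if (!nrow(mf$entries)) stop("empty manifest")
    conds <- unique(mf$entries$condition)
    ensembles <- lapply(stats::setNames(conds, conds), function(cd) {
      lapply(mf$entries$path[mf$entries$condition == cd], read_curve)
    })
    models <- lapply(stats::setNames(conds, conds), condition_preset,
                     setup = setup)
    reference <- if (!is.na(mf$reference_condition))
      mf$reference_condition else conds[1]
  }

  analyses <- lapply(stats::setNames(names(ensembles), names(ensembles)),
                     function(cd) {
    analyze_ensemble(ensembles[[cd]], models[[cd]], config)
  })

  normalization <- NULL
  if (length(analyses) > 1) {
    sets <- lapply(analyses, function(an) {
      fn3 <- an$stats[["FN3"]]
      list(fn3_mode = if (!is.null(fn3)) fn3$mode else NA_real_,
           forces = lapply(an$stats, function(s) s$forces))
    })
    normalization <- tryCatch(normalize_by_fn3(sets, reference),
                              error = function(e) {
                                warning(conditionMessage(e))
                                NULL
                              })
  }

  summary <- list(
    seed = config$seed,
    config = unclass(config),
    conditions = lapply(analyses, function(an) {
      list(counts = as.list(an$counts),
           increments = if (!is.null(an$increments))
             an$increments$increments else NULL,
           peaks = if (!is.null(an$increments)) an$increments$peaks else
             NULL,
           modes = lapply(an$stats, function(s)
             list(transition = s$transition, n = s$n,
                  mode = s$mode, mode_method = s$mode_method,
                  kde_mode = s$kde_mode,
                  loading_rate = s$loading_rate,
                  low_n = s$low_n)),
           n_excluded = length(an$exclusions))
    }),
    scale_factors = if (!is.null(normalization))
      as.list(normalization$scale_factors) else NULL)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (cd in names(analyses)) {
      an <- analyses[[cd]]
      for (tr in names(an$stats))
        write_histogram(an$stats[[tr]]$histogram,
                        file.path(outdir,
                                  sprintf("force_histogram_%s_%s.tsv",
                                          tr, cd)))
      if (!is.null(an$template)) {
        ht <- contour_histogram(an$template)
        write_histogram(ht, file.path(outdir,
                                      sprintf("contour_profile_%s.tsv", cd)))
      }
      if (!is.null(an$increments))
        utils::write.table(an$increments$increments,
                           file.path(outdir,
                                     sprintf("increments_%s.tsv", cd)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(an$heatmap))
        write_heatmap(an$heatmap,
                      file.path(outdir, sprintf("heatmap_%s.tsv", cd)))
      if (isTRUE(config$write_curves) && is.null(manifest)) {
        cdir <- file.path(outdir, paste0("curves_", cd))
        dir.create(cdir, showWarnings = FALSE)
        for (i in seq_along(ensembles[[cd]]))
          write_curve(ensembles[[cd]][[i]],
                      file.path(cdir, sprintf("curve_%05d.tsv", i)))
      }
      writeLines(an$exclusions,
                 file.path(outdir, sprintf("exclusions_%s.log", cd)))
    }
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }

  structure(list(analyses = analyses, normalization = normalization,
                 summary = summary),
            class = "pipeline_report")
}

# Integer-count rendering of a template profile in the source-data
# histogram layout (1 nm bins, counts proportional to density).
contour_histogram <- function(template, bin = 1, scale = 1000) {
  grid <- template$grid
  step <- grid[2] - grid[1]
  edges <- seq(min(grid), max(grid), by = bin)
  idx <- findInterval(grid, edges)
  mass <- vapply(seq_along(edges), function(i)
    sum(template$density[idx == i]) * step, numeric(1))
  histogram_table(edges, as.integer(round(mass * scale)),
                  quantity = "contour_length_nm",
                  condition = "template", bandwidth = bin)
}
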