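test_that("noiseless curve labels match the truth log exactly", {
  m <- fixture_model("APO")
  set.seed(401)
  setup <- pulling_setup(noise_sd = 0)
  cv <- NULL
  for (i in 1:60) {
    cand <- simulate_curve(m, setup)
    if (all(c("S1S2", "S2S3", "FN3") %in% cand$events$label)) {
      cv <- cand
      break
    }
  }
  expect_false(is.null(cv))
  cc <- correct_curve(cv)
  ev <- assign_transitions(detect_ruptures(cc, min_drop = 10), cc, m)
  want <- cv$events[cv$events$label != "S0S1", ]
  matched <- vapply(seq_len(nrow(want)), function(k) {
    hit <- which(abs(ev$index - want$index[k]) <= 3)
    length(hit) == 1 &&
      ev$label[hit] == sub("^IG[12T]$", "IG", want$label[k])
  }, logical(1))
  expect_true(all(matched))
  # the final event is the detachment
  expect_identical(ev$label[which.max(ev$index)], "DETACH")
})

test_that("automated assignment reaches 95% accuracy on a noisy ensemble", {
  curves <- fixture_ensemble("APO")
  an <- fixture_analysis("APO")
  n_ok <- 0; n_tot <- 0
  for (i in seq_along(curves)) {
    ev <- an$events[[i]]
    if (is.null(ev) || !nrow(ev)) next
    tru <- curves[[i]]$events
    # one-to-one matching, closest truth/detection pairs first
    pairs <- expand.grid(k = seq_len(nrow(tru)), j = seq_len(nrow(ev)))
    pairs$d <- abs(tru$index[pairs$k] - ev$index[pairs$j])
    pairs <- pairs[pairs$d <= 25, ]
    pairs <- pairs[order(pairs$d), ]
    used_t <- rep(FALSE, nrow(tru)); used_e <- rep(FALSE, nrow(ev))
    for (r in seq_len(nrow(pairs))) {
      k <- pairs$k[r]; j <- pairs$j[r]
      if (used_t[k] || used_e[j]) next
      used_t[k] <- TRUE; used_e[j] <- TRUE
      n_tot <- n_tot + 1
      want <- sub("^IG[12T]$", "IG", tru$label[k])
      if (ev$label[j] == want) n_ok <- n_ok + 1
    }
  }
  expect_gt(n_tot, 1000)
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("fingerprint filter rejects contaminants and keeps clean curves", {
  m <- fixture_model("APO")
  setup0 <- pulling_setup(noise_sd = 0)
  cfg_events <- function(cv, min_drop) {
    cc <- correct_curve(cv, min_drop = min_drop)
    assign_transitions(detect_ruptures(cc, min_drop = min_drop), cc, m)
  }

  # contaminant-only input: nothing shows the characteristic pattern
  contam <- lapply(1:20, function(i) {
    set.seed(7000 + i)
    afmunfold:::simulate_contaminant(pulling_setup())
  })
  ev_c <- lapply(contam, function(cv) {
    cc <- suppressWarnings(correct_curve(cv))
    assign_transitions(detect_ruptures(cc), cc, m)
  })
  filt_c <- fingerprint_filter(ev_c, m)
  expect_identical(sum(filt_c$accepted), 0L)
  expect_true(all(nzchar(filt_c$reasons)))

  # clean noiseless ensemble: every curve showing the pattern is kept
  clean <- simulate_ensemble(m, 28, setup0, seed = 501)
  clean <- Filter(function(cv) {
    ev <- cv$events
    if (!all(c("S1S2", "S2S3") %in% ev$label)) return(FALSE)
    first_flank <- suppressWarnings(
      min(ev$index[ev$label %in% c("FN3", "IG1", "IG2", "IGT")]))
    first_flank > ev$index[ev$label == "S2S3"]
  }, clean)
  expect_gte(length(clean), 20)
  ev_k <- lapply(clean, cfg_events, min_drop = 10)
  filt_k <- fingerprint_filter(ev_k, m)
  expect_identical(mean(filt_k$accepted), 1)
})

test_that("a 30%-contaminated ensemble is accepted at about 70%", {
  m <- fixture_model("ATP")
  curves <- simulate_ensemble(m, 600, pulling_setup(noise_sd = 0),
                              contamination_fraction = 0.3, seed = 88)
  evs <- lapply(curves, function(cv) {
    cc <- suppressWarnings(correct_curve(cv, min_drop = 10))
    assign_transitions(detect_ruptures(cc, min_drop = 10), cc, m)
  })
  filt <- fingerprint_filter(evs, m)
  expect_equal(mean(filt$accepted), 0.7, tolerance = 0.03 / 0.7)
})

test_that("force statistics extract the most probable rupture force", {
  set.seed(91)
  p <- bell_evans_params(0.01, 0.5, 80)
  f <- bell_evans_rvs(5000, p)
  st <- force_stats(f, "FN3", "BELL_EVANS", loading_rate = 80)
  expect_equal(st$mode, 56.44, tolerance = 2)
  expect_identical(st$n, 5000L)
  expect_equal(sum(st$histogram$count), 5000L)
  expect_false(st$low_n)

  # KDE mode of a symmetric unimodal sample sits at its centre
  g <- rnorm(4000, 120, 6)
  stk <- force_stats(g, "S2S3", "KDE_1PN")
  expect_equal(stk$mode, 120, tolerance = 1)

  expect_warning(force_stats(rnorm(12, 50, 5), "S1S2", "KDE_1PN"),
                 "low-n")
})

test_that("S2->S3 modes under RLC vs apo differ by the calibrated gap", {
  an_apo <- fixture_analysis("APO")
  rlc_m <- fixture_model("RLC")
  rlc_curves <- simulate_ensemble(rlc_m, 300, default_setup(), seed = 515)
  an_rlc <- analyze_ensemble(rlc_curves, rlc_m, run_config())
  gap <- an_rlc$stats$S2S3$mode - an_apo$stats$S2S3$mode
  expect_equal(gap, 30, tolerance = 3)
})

test_that("Fn3 normalization recovers synthetic miscalibrations", {
  ref <- list(fn3_mode = 100,
              forces = list(S1S2 = c(28, 31, 33), FN3 = c(95, 102)))
  same <- normalize_by_fn3(list(a = ref, b = ref), "a")
  expect_equal(unname(same$scale_factors), c(1, 1))

  # a 1.2x force miscalibration is undone
  mis <- list(fn3_mode = 100 * 1.2,
              forces = lapply(ref$forces, function(f) f * 1.2))
  fix <- normalize_by_fn3(list(a = ref, b = mis), "a")
  expect_equal(unname(fix$scale_factors["b"]), 1 / 1.2, tolerance = 0.02)
  expect_equal(fix$datasets$b$forces$S1S2, ref$forces$S1S2,
               tolerance = 1e-9)

  # idempotence
  twice <- normalize_by_fn3(fix$datasets, "a")
  expect_equal(unname(twice$scale_factors), c(1, 1), tolerance = 1e-9)

  # datasets without Fn3 statistics are dropped with a warning
  none <- list(fn3_mode = NA_real_, forces = list(S1S2 = c(30, 31)))
  expect_warning(out <- normalize_by_fn3(list(a = ref, b = none), "a"),
                 "excluded")
  expect_identical(names(out$datasets), "a")
})

test_that("heatmaps conserve sample counts on the 750x750 grid", {
  z <- seq(0.1, 100, length.out = 1000)
  cc <- structure(list(separation = z, force = 0.9 * z,
                       baseline_offset = 0, baseline_range = c(80, 100),
                       source = NULL),
                  class = "corrected_curve")
  hm <- build_heatmap(list(cc), force_range = c(0, 150),
                      distance_range = c(0, 150))
  expect_identical(dim(hm$counts), c(750L, 750L))
  expect_identical(sum(hm$counts), 1000L)
  expect_identical(hm$n_in_range, 1000L)

  empty <- build_heatmap(list(cc), force_range = c(500, 600),
                         distance_range = c(500, 600))
  expect_identical(sum(empty$counts), 0L)
})

test_that("the apo heatmap shows three rupture ridges in the kinase region", {
  an <- fixture_analysis("APO")
  acc <- an$accepted
  hm <- build_heatmap(an$corrected[acc], an$events[acc],
                      force_range = c(10, 120), distance_range = c(10, 120))
  # coarse-grain 750 -> 75, threshold at the 90th percentile of occupied
  # cells, and count connected components in the unfolding band
  coarse <- matrix(0, 75, 75)
  for (i in 1:75) for (j in 1:75)
    coarse[i, j] <- sum(hm$counts[(10 * i - 9):(10 * i),
                                  (10 * j - 9):(10 * j)])
  thr <- quantile(coarse[coarse > 0], 0.90)
  active <- which(coarse >= thr, arr.ind = TRUE)
  # single-linkage clustering of active cells (chebyshev distance <= 1.5)
  lab <- seq_len(nrow(active))
  repeat {
    changed <- FALSE
    for (a in seq_len(nrow(active))) for (b in seq_len(nrow(active))) {
      if (lab[a] != lab[b] &&
          max(abs(active[a, ] - active[b, ])) <= 1.5) {
        lab[lab == max(lab[a], lab[b])] <- min(lab[a], lab[b])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # components whose distance span lies in the kinase band (20-100 nm)
  dist_of <- function(i) 10 + (i - 0.5) * (120 - 10) / 75
  comp <- unique(lab)
  in_band <- vapply(comp, function(cmp) {
    d <- dist_of(active[lab == cmp, 1])
    max(d) >= 15 && min(d) <= 105
  }, logical(1))
  expect_identical(sum(in_band), 3L)
})
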