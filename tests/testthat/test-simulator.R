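test_that("degenerate single-detachment model gives one monotone WLC rise", {
  tr <- transition_spec("DETACH", 0, 1e-10, 5)
  m <- construct_model(tr, base_contour = 30, condition = "APO")
  set.seed(3)
  cv <- simulate_curve(m, pulling_setup(noise_sd = 0))
  expect_equal(cv$events$label, "DETACH")
  body <- cv$force_clean[seq_len(cv$events$index[1] - 1)]
  expect_true(all(diff(body) > -1e-9))   # no unfolding drops
  expect_gt(max(body), 20)               # barrier loaded before rupture
})

test_that("noiseless drop count equals the truth log", {
  m <- fixture_model("APO")
  set.seed(8)
  cv <- simulate_curve(m, pulling_setup(noise_sd = 0))
  # count discrete falls of the clean force > 2 pN in one sample step
  drops <- sum(diff(cv$force_clean) < -2)
  fired <- sum(cv$events$label != "DETACH") + 1   # detach drop included
  # S0S1 releases so little length that its drop can be < 2 pN
  expect_lte(abs(drops - fired), 1)
})

test_that("single-transition ensembles reproduce the Bell-Evans mode", {
  # k0 = 0.01/s, dx = 0.5 nm unfolding transition, detachment far above
  tr <- rbind(transition_spec("S1S2", 30, 0.01, 0.5),
              transition_spec("DETACH", 0, 1e-12, 0.15))
  m <- construct_model(tr, base_contour = 30)
  setup <- pulling_setup(noise_sd = 0)
  curves <- suppressWarnings(
    simulate_ensemble(m, 2000, setup, seed = 77, max_pull = 150))
  f <- unlist(lapply(curves, function(cv) {
    i <- cv$events$index[cv$events$label == "S1S2"]
    if (length(i)) cv$force_clean[max(i - 1, 1)] else NULL
  }))
  expect_gt(length(f), 1900)
  meas <- afmunfold:::measured_event_stats(curves)
  pred <- bell_evans_mode(bell_evans_params(0.01, 0.5, meas$S1S2$rate))
  d <- density(f, bw = 2)
  expect_equal(d$x[which.max(d$y)], pred, tolerance = 3)
})

test_that("ensembles are deterministic and allocate contamination exactly", {
  m <- fixture_model("APO")
  setup <- pulling_setup()
  e1 <- simulate_ensemble(m, 10, setup, seed = 123)
  e2 <- simulate_ensemble(m, 10, setup, seed = 123)
  expect_identical(e1, e2)
  expect_true(all(vapply(e1, function(cv) cv$metadata$characteristic,
                         logical(1))))
  e3 <- simulate_ensemble(m, 200, setup, contamination_fraction = 0.3,
                          seed = 9)
  contam <- sum(!vapply(e3, function(cv) cv$metadata$characteristic,
                        logical(1)))
  expect_identical(contam, 60L)
  expect_error(simulate_ensemble(m, 0, setup), "positive count")
})

test_that("released contour length is conserved through a full unfold", {
  # make detachment effectively unreachable until everything has unfolded
  m <- fixture_model("APO")
  m$transitions$intrinsic_rate[m$transitions$label == "DETACH"] <- 1e-14
  setup <- pulling_setup(noise_sd = 0)
  set.seed(31)
  cv <- suppressWarnings(simulate_curve(m, setup, max_pull = 380))
  done <- setdiff(m$transitions$label, "DETACH")
  expect_true(all(done %in% cv$events$label))
  total <- m$base_contour +
    sum(m$transitions$delta_contour[m$transitions$label %in% done])
  sep <- cv$distance - cv$force_clean / setup$spring_constant
  keep <- cv$force_clean >= 30 &
    seq_along(sep) > max(cv$events$index[cv$events$label %in% done])
  lc <- wlc_inverse_contour(cv$force_clean[keep], sep[keep])
  expect_equal(median(lc, na.rm = TRUE), total, tolerance = 2)
})

test_that("mechanical hierarchy: kinase < Fn3 < Ig rupture forces", {
  # tether detachment races Fn3 near 100 pN, so Ig-like domains rarely
  # unfold in standard ensembles (as observed); suppress detachment to
  # reveal the full mechanical ladder of the construct itself
  m <- fixture_model("APO")
  m$transitions$intrinsic_rate[m$transitions$label == "DETACH"] <- 1e-14
  curves <- suppressWarnings(
    simulate_ensemble(m, 60, pulling_setup(noise_sd = 0), seed = 902,
                      max_pull = 380))
  med <- function(lab) {
    f <- unlist(lapply(curves, function(cv) {
      i <- cv$events$index[cv$events$label %in% lab]
      if (length(i)) cv$force_clean[pmax(i - 1, 1)] else NULL
    }))
    median(f)
  }
  expect_lt(med("S1S2"), med("FN3"))
  expect_lt(med("FN3"), med(c("IG1", "IG2", "IGT")))
  # detachment-limited ensembles show the rarity of Ig unfolding
  std <- fixture_ensemble("APO")
  n_ig <- sum(unlist(lapply(std, function(cv)
    cv$events$label %in% c("IG1", "IG2", "IGT"))))
  expect_lt(n_ig / length(std), 0.05)
})

test_that("condition presets encode the ligand signatures", {
  cacam <- condition_preset("CA_CAM", calibrate = FALSE)
  expect_false("S0S1" %in% cacam$transitions$label)

  apo <- condition_preset("APO", calibrate = FALSE)
  atp <- condition_preset("ATP", calibrate = FALSE)
  tr_apo <- apo$transitions
  tr_atp <- atp$transitions
  i <- tr_apo$label == "S1S2"
  expect_identical(tr_apo[!i, c("delta_contour", "barrier_distance",
                                "target_mode")],
                   tr_atp[!i, c("delta_contour", "barrier_distance",
                                "target_mode")])
  expect_identical(tr_apo$intrinsic_rate[!i], tr_atp$intrinsic_rate[!i])
  expect_false(tr_apo$intrinsic_rate[i] == tr_atp$intrinsic_rate[i])
  expect_equal(tr_atp$target_mode[i] - tr_apo$target_mode[i], 30)

  # kinase and flanking-domain contour increments of the apo preset
  d <- setNames(tr_apo$delta_contour, tr_apo$label)
  expect_equal(unname(d["S1S2"]), 30.8)
  expect_equal(unname(d["S2S3"]), 61.8)
  expect_equal(unname(d[c("FN3", "IG1", "IG2", "IGT")]), rep(30, 4))

  # RLC raises only the large-lobe stability
  rlc <- condition_preset("RLC", calibrate = FALSE)
  expect_equal(rlc$transitions$target_mode[rlc$transitions$label == "S2S3"],
               60)
  expect_error(condition_preset("XTP"))
})

test_that("simulated curves respect the declared invariants", {
  curves <- fixture_ensemble("APO")[1:50]
  for (cv in curves) {
    expect_true(all(diff(cv$distance) > 0))
    expect_identical(length(cv$distance), length(cv$force))
    expect_true(!is.unsorted(cv$events$index))
  }
})
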