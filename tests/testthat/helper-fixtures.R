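# Shared fixtures, built once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

default_setup <- function(noise_sd = 5)
  pulling_setup(noise_sd = noise_sd)

# Calibrated preset (cached across test files through the package's own
# per-session preset cache as well).
fixture_model <- function(condition) {
  cached(paste0("model_", condition),
         condition_preset(condition, default_setup()))
}

# The two study ensembles used by the acceptance-style checks.
fixture_ensemble <- function(condition, n = 500, seed = 4242, noise_sd = 5) {
  key <- paste("ens", condition, n, seed, noise_sd, sep = "_")
  cached(key, {
    m <- fixture_model(condition)
    simulate_ensemble(m, n, default_setup(noise_sd), seed = seed)
  })
}

fixture_analysis <- function(condition, n = 500, seed = 4242) {
  key <- paste("an", condition, n, seed, sep = "_")
  cached(key, {
    m <- fixture_model(condition)
    analyze_ensemble(fixture_ensemble(condition, n, seed), m, run_config())
  })
}

# A hand-built noiseless two-branch sawtooth (no simulator): WLC branch of
# contour length L1 up to force f1, instantaneous drop onto branch L2,
# loaded until f2, drop to baseline, then flat zero tail. Returns the
# force_curve plus the true drop sample indices.
make_sawtooth <- function(branches = data.frame(L = c(33, 63.8),
                                                f_end = c(30, 30)),
                          spring_constant = 100, step = 0.064,
                          tail_nm = 30, noise_sd = 0) {
  dist <- numeric(0); force <- numeric(0); drops <- integer(0)
  z <- 0
  for (b in seq_len(nrow(branches))) {
    L <- branches$L[b]; fe <- branches$f_end[b]
    wp <- wlc_params(contour_length = L)
    repeat {
      d <- 0
      for (i in 1:60) d <- wlc_force(max(min(z - d, L * 0.999), 0), wp) /
          spring_constant
      f <- d * spring_constant
      dist <- c(dist, z); force <- c(force, f)
      z <- z + step
      if (f >= fe) break
    }
    drops <- c(drops, length(force))
  }
  nt <- ceiling(tail_nm / step)
  dist <- c(dist, z + (seq_len(nt) - 1) * step)
  force <- c(force, rep(0, nt))
  if (noise_sd > 0) force <- force + rnorm(length(force), 0, noise_sd)
  cv <- force_curve(dist, force,
                    metadata = list(retraction_speed = 800,
                                    spring_constant = spring_constant,
                                    sampling_rate = 12500,
                                    noise_sd = noise_sd,
                                    condition = "APO"))
  attr(cv, "true_drops") <- drops
  cv
}

# Independent inverse-WLC oracle: plain-R Marko-Siggia + uniroot over Lc.
oracle_inverse_lc <- function(f, x, p = 0.4, kT = 4.1) {
  ms <- function(L) (kT / p) * (0.25 / (1 - x / L)^2 - 0.25 + x / L) - f
  stats::uniroot(ms, c(x + 1e-3, 10 * x), tol = 1e-12)$root
}

# Independent TVD oracle: box-constrained dual QP solved with L-BFGS-B.
oracle_tvd <- function(y, lam) {
  n <- length(y)
  D <- diff(diag(n))
  fn <- function(u) {
    v <- as.vector(t(D) %*% u)
    0.5 * sum(v^2) - sum(u * (D %*% y))
  }
  gr <- function(u) as.vector(D %*% (t(D) %*% u)) - as.vector(D %*% y)
  o <- optim(rep(0, n - 1), fn, gr, method = "L-BFGS-B",
             lower = -lam, upper = lam,
             control = list(maxit = 10000, factr = 10))
  y - as.vector(t(D) %*% o$par)
}
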