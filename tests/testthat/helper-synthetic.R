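# Shared fixtures: a noiseless single-subject study and its exact input
# function, built once per test run. A coarser fine-grid (5 s) keeps the
# compartment fits fast; forward and inverse models share the grid, so
# self-inversion checks are unaffected.

test_dt <- 1 / 12

noiseless_config <- function(...) {
  cohort_config(n_subjects = 1, noise_scale = 0, dt = test_dt, seed = 99,
                ...)
}

.cache <- new.env()

noiseless_subject <- function() {
  if (is.null(.cache$subj)) {
    .cache$subj <- simulate_subject(noiseless_config(), 1)
  }
  .cache$subj
}

# truth input of the noiseless subject's baseline scan, discretized
noiseless_input <- function() {
  if (is.null(.cache$di)) {
    s <- noiseless_subject()
    .cache$di <- discretize_input(s$conditions$baseline$blood$truth$input,
                                  s$schedule, test_dt)
  }
  .cache$di
}

# trapezoidal frame averaging, written independently of the package internals
frame_avg_oracle <- function(y, dt, schedule) {
  cum <- cumsum(c(0, (head(y, -1) + tail(y, -1)) / 2 * dt))
  i0 <- round(schedule$start / dt) + 1L
  i1 <- round(schedule$end / dt) + 1L
  (cum[i1] - cum[i0]) / schedule$duration
}

# small brute-force oracle for the occupancy plot: exhaustive 2-D grid
# search over (occupancy, V_ND) minimizing the sum of squared residuals
grid_search_lassen <- function(vt_base, vt_block,
                               occ_grid = seq(0, 1.5, by = 0.005),
                               vnd_grid = seq(-1, 8, by = 0.005)) {
  d <- vt_base - vt_block
  best <- c(NA, NA, Inf)
  for (occ in occ_grid) {
    # residuals are linear in vnd for fixed occ; still scan exhaustively
    sse <- vapply(vnd_grid,
                  function(v) sum((d - occ * (vt_base - v))^2), numeric(1))
    i <- which.min(sse)
    if (sse[i] < best[3]) best <- c(occ, vnd_grid[i], sse[i])
  }
  list(occupancy = best[1], vnd = best[2], sse = best[3])
}
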