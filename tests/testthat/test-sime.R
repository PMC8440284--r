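test_that("constrained fit is inactive at the true K1/k2 and binds away from it", {
  s <- noiseless_subject()
  fs <- s$schedule
  di <- noiseless_input()
  tac <- s$conditions$baseline$tacs[, "whole_brain"]
  w <- tac_weights(tac, fs)

  free <- fit_wnlls(tac, di, fs, weights = w, dt = test_dt)
  at_truth <- fit_constrained_2tcm(tac, di, fs, s$truth$vnd, weights = w,
                                   dt = test_dt)
  expect_lt(at_truth$rss, free$rss + 1e-10)
  expect_equal(at_truth$params[["k2"]],
               at_truth$params[["K1"]] / s$truth$vnd, tolerance = 1e-12)

  far <- fit_constrained_2tcm(tac, di, fs, s$truth$vnd * 2, weights = w,
                              dt = test_dt)
  expect_gt(far$rss, at_truth$rss * 100)

  expect_error(fit_constrained_2tcm(tac, di, fs, -1), "positive")
  expect_error(fit_constrained_2tcm(tac, di, fs, 0), "positive")
})

test_that("single-region RSS profile is minimized at the generating K1/k2", {
  s <- noiseless_subject()
  fs <- s$schedule
  di <- noiseless_input()
  tac <- s$conditions$baseline$tacs[, "thalamus"]
  w <- tac_weights(tac, fs)
  grid <- seq(s$truth$vnd - 0.5, s$truth$vnd + 0.5, by = 0.05)
  prof <- vapply(grid, function(v) {
    fit_constrained_2tcm(tac, di, fs, v, weights = w, dt = test_dt)$rss
  }, numeric(1))
  i <- which.min(prof)
  expect_lt(abs(grid[i] - s$truth$vnd), 0.051)
  # unimodal around the truth: strictly decreasing then increasing
  expect_true(all(diff(prof[1:i]) < 0))
  expect_true(all(diff(prof[i:length(prof)]) > 0))
})

test_that("SIME sweep finds the common K1/k2 on a noiseless subject", {
  reg <- default_region_table()[c(1, 8, 10, 11), ]
  cfg <- cohort_config(n_subjects = 1, regions = reg, true_vnd = 2.0,
                       noise_scale = 0, dt = test_dt, seed = 77)
  s <- simulate_subject(cfg, 1)
  di <- discretize_input(s$conditions$baseline$blood$truth$input, cfg$schedule,
                         test_dt)
  grid <- seq(1.80, 2.20, by = 0.01)
  res <- sime_vnd(as.list(as.data.frame(s$conditions$baseline$tacs)), di,
                  cfg$schedule, grid = grid, dt = test_dt)
  expect_equal(res$vnd, 2.00, tolerance = 1e-9)
  expect_false(res$flat_profile)
  expect_equal(res$grid[which.min(res$rss)], res$vnd)

  # off-grid truth resolves to an adjacent grid point
  cfg2 <- cohort_config(n_subjects = 1, regions = reg, true_vnd = 1.995,
                        noise_scale = 0, dt = test_dt, seed = 77)
  s2 <- simulate_subject(cfg2, 1)
  di2 <- discretize_input(s2$conditions$baseline$blood$truth$input,
                          cfg2$schedule, test_dt)
  res2 <- sime_vnd(as.list(as.data.frame(s2$conditions$baseline$tacs)), di2,
                   cfg2$schedule, grid = grid, dt = test_dt)
  expect_true(res2$vnd %in% c(1.99, 2.00))
})

test_that("refining the grid never increases the minimum pooled RSS", {
  reg <- default_region_table()[c(1, 10, 11), ]
  cfg <- cohort_config(n_subjects = 1, regions = reg, true_vnd = 2.0,
                       noise_scale = 0, dt = test_dt, seed = 78)
  s <- simulate_subject(cfg, 1)
  di <- discretize_input(s$conditions$baseline$blood$truth$input,
                         cfg$schedule, test_dt)
  tacs <- as.list(as.data.frame(s$conditions$baseline$tacs))
  coarse <- sime_vnd(tacs, di, cfg$schedule, grid = seq(1.9, 2.1, by = 0.1),
                     dt = test_dt)
  fine <- sime_vnd(tacs, di, cfg$schedule, grid = seq(1.9, 2.1, by = 0.05),
                   dt = test_dt)
  expect_lte(min(fine$rss), min(coarse$rss) + 1e-12)
  expect_error(sime_vnd(tacs[1:2], di, cfg$schedule), "at least 3")
  expect_error(sime_vnd(tacs, di, cfg$schedule, grid = c(-1, 1)), "positive")
})

test_that("SIME violates gracefully when regions do not share K1/k2", {
  # heterogeneous regional K1/k2: the estimate is a compromise within the
  # regional range, away from some regions' truth
  reg <- default_region_table()[c(1, 8, 10, 11), ]
  cfg <- cohort_config(n_subjects = 1, regions = reg, true_vnd = 2.0,
                       regional_vnd_sd = 0.25, noise_scale = 0,
                       dt = test_dt, seed = 79)
  s <- simulate_subject(cfg, 1)
  vnds <- s$truth$params$vnd
  expect_gt(max(vnds) - min(vnds), 0.2)  # heterogeneity realized
  di <- discretize_input(s$conditions$baseline$blood$truth$input,
                         cfg$schedule, test_dt)
  res <- sime_vnd(as.list(as.data.frame(s$conditions$baseline$tacs)), di,
                  cfg$schedule, grid = seq(1.0, 3.5, by = 0.05), dt = test_dt)
  expect_gte(res$vnd, min(vnds) - 0.05)
  expect_lte(res$vnd, max(vnds) + 0.05)
})

test_that("SIME uses only the baseline scan", {
  reg <- default_region_table()[c(1, 10, 11), ]
  cfg <- cohort_config(n_subjects = 1, regions = reg, true_vnd = 2.0,
                       noise_scale = 0, dt = test_dt, seed = 80)
  s <- simulate_subject(cfg, 1)
  s_tampered <- s
  s_tampered$conditions$blocking$tacs[] <- 0  # destroy the blocking scan
  di <- discretize_input(s$conditions$baseline$blood$truth$input,
                         cfg$schedule, test_dt)
  grid <- seq(1.9, 2.1, by = 0.05)
  r1 <- sime_vnd(as.list(as.data.frame(s$conditions$baseline$tacs)), di,
                 cfg$schedule, grid = grid, dt = test_dt)
  r2 <- sime_vnd(as.list(as.data.frame(s_tampered$conditions$baseline$tacs)),
                 di, cfg$schedule, grid = grid, dt = test_dt)
  expect_identical(r1$rss, r2$rss)
  expect_identical(r1$vnd, r2$vnd)
})

test_that("SIME-vs-Lassen comparison reproduces the published subject table", {
  tab <- pbr28_individual_vnd()
  cmp <- compare_sime_lassen(tab$sime_vnd, tab$lassen_2tcm_vnd,
                             subjects = tab$subject)
  # subject #305: (1.24 - 5.55)/5.55 = -78%
  expect_equal(format_percent(cmp$table$rel_diff_pct[tab$subject == "#305"]),
               -78L)
  expect_equal(cmp$sime_mean, 1.16, tolerance = 1e-9)
  expect_equal(round(cmp$sime_sd_pop, 2), 0.28)
  expect_equal(cmp$rel_diff_mean, -45, tolerance = 0.5)
  expect_equal(cmp$rel_diff_sd_pop, 22, tolerance = 0.5)
  # paired t on the printed columns: t = -2.52 on 6 df (closed form below)
  d <- tab$sime_vnd - tab$lassen_2tcm_vnd
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(cmp$ttest$t, t_oracle, tolerance = 1e-12)
  expect_equal(t_oracle, -2.52, tolerance = 0.005)
  expect_equal(cmp$ttest$df, 6)

  ident <- compare_sime_lassen(tab$sime_vnd, tab$sime_vnd)
  expect_equal(ident$rel_diff_mean, 0)
  expect_equal(ident$ttest$p, 1)
})
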