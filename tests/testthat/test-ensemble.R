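test_that("sample_params draws uniformly within the ranges", {
  rng <- param_ranges()
  m <- sample_params(1000, rng, seed = 2)
  expect_equal(nrow(m), 1000)
  for (nm in names(rng)) {
    expect_true(all(m[[nm]] >= rng[[nm]][1] & m[[nm]] <= rng[[nm]][2]))
  }
  # uniform moments for d on (0.5, 1.5)
  sd_u <- 1 / sqrt(12)
  expect_lt(abs(mean(m$d) - 1.0), 4 * sd_u / sqrt(1000))
  # reproducibility and near-degenerate ranges
  expect_identical(sample_params(50, rng, seed = 7), sample_params(50, rng, seed = 7))
  tiny <- param_ranges(a = c(0.1, 0.1 + 1e-9))
  md <- sample_params(20, tiny, seed = 1)
  expect_true(all(md$a >= 0.1 & md$a <= 0.1 + 1e-9))
  expect_error(param_ranges(a = c(1, -1)), "low < high")
})

test_that("detect_green_events classifies flat trajectories", {
  fs <- const_forcing(5001)
  tr <- structure(data.frame(time = fs$time, v = rep(-0.8, 5001), N = 0),
                  timestep = 1, class = c("trajectory", "data.frame"))
  expect_equal(nrow(detect_green_events(tr)), 0)
  tr$v <- rep(0.8, 5001)
  ev <- detect_green_events(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, 5000)
  expect_equal(ev$end, 0)
})

test_that("detect_green_events recovers engineered millennial green windows", {
  # noiseless run forced green in exactly three separated windows
  times <- seq(40000, 0, by = -10)
  r <- rep(-2, length(times))
  for (w in list(c(36000, 30000), c(24000, 18000), c(12000, 6000))) {
    r[times <= w[1] & times >= w[2]] <- 2
  }
  fs <- forcing_series(times, r, rep(0, length(times)))
  p <- passthrough_params(d = 1, tau_v = 20, tau_N = 20, sigma = 0)
  tr <- simulate_trajectory(p, fs, spinup = 500)
  ev <- detect_green_events(tr)
  expect_equal(nrow(ev), 3)
  for (i in seq_len(3)) {
    w <- list(c(36000, 30000), c(24000, 18000), c(12000, 6000))[[i]]
    expect_lt(abs(ev$start[i] - w[1]), 500)  # within smooth_window / 2
    expect_lt(abs(ev$end[i] - w[2]), 500)
  }
})

test_that("green intervals separated by a short gap are merged", {
  times <- seq(20000, 0, by = -10)
  r <- rep(-2, length(times))
  r[times <= 16000 & times >= 12000] <- 2
  r[times <= 11000 & times >= 7000] <- 2  # gap of 1000 < merge_gap
  fs <- forcing_series(times, r, rep(0, length(times)))
  p <- passthrough_params(d = 1, tau_v = 20, tau_N = 20, sigma = 0)
  tr <- simulate_trajectory(p, fs, spinup = 500)
  expect_equal(nrow(detect_green_events(tr, merge_gap = 2000)), 1)
  expect_equal(nrow(detect_green_events(tr, merge_gap = 200)), 2)
})

test_that("short green blips are dropped by the duration filter", {
  times <- seq(20000, 0, by = -10)
  r <- rep(-2, length(times))
  r[times <= 15000 & times >= 14200] <- 2  # 800-yr blip
  r[times <= 9000 & times >= 4000] <- 2    # real event
  fs <- forcing_series(times, r, rep(0, length(times)))
  p <- passthrough_params(d = 1, tau_v = 20, tau_N = 20, sigma = 0)
  tr <- simulate_trajectory(p, fs, spinup = 500)
  ev <- detect_green_events(tr, smooth_window = 200, min_duration = 2000,
                            merge_gap = 2000)
  expect_equal(nrow(ev), 1)
  expect_lt(ev$start[1], 10000)
})

test_that("screening flags members by exact green-episode count", {
  fs <- annual_forcing()
  # a member whose background rainfall never goes positive is implausible
  dry <- data.frame(member_id = 1, a = -3, b = 0, c = 0, d = 1,
                    tau_v = 20, tau_N = 5, sigma = 0.3)
  scr <- screen_ensemble(dry, fs, base_seed = 1, store_thin = 0)
  expect_equal(scr$members$n_green, 0)
  expect_false(scr$members$plausible)
  # the tuned truth member shows exactly six episodes and passes
  ts <- annual_truth_study()
  tm <- data.frame(member_id = 1, a = ts$params$a, b = ts$params$b,
                   c = ts$params$c, d = ts$params$d, tau_v = ts$params$tau_v,
                   tau_N = ts$params$tau_N, sigma = ts$params$sigma)
  scr2 <- screen_ensemble(tm, ts$forcing, base_seed = ts$seed - 1, store_thin = 0)
  expect_equal(scr2$members$n_green, 6)
  expect_true(scr2$members$plausible)
})

test_that("screening results do not depend on member evaluation order", {
  fs <- annual_forcing()
  m <- sample_params(20, seed = 3)
  scr <- screen_ensemble(m, fs, base_seed = 9, store_thin = 0)
  perm <- sample(20)
  scr_p <- screen_ensemble(m[perm, ], fs, base_seed = 9, store_thin = 0)
  ord <- order(scr_p$members$member_id)
  expect_equal(scr_p$members$n_green[ord], scr$members$n_green)
  expect_equal(scr_p$members$plausible[ord], scr$members$plausible)
})

test_that("screening retains a non-trivial fraction on the default fixture", {
  fs <- annual_forcing()
  m <- sample_params(150, seed = 8)
  scr <- screen_ensemble(m, fs, base_seed = 80, store_thin = 0,
                         window = c(230000, 20000))
  frac <- mean(scr$members$plausible)
  expect_gt(frac, 0)
  expect_lt(frac, 1)
})

test_that("the Holocene extension records collapse, green event and flags", {
  ts <- annual_truth_study()
  tm <- data.frame(member_id = 1, a = ts$params$a, b = ts$params$b,
                   c = ts$params$c, d = ts$params$d, tau_v = ts$params$tau_v,
                   tau_N = ts$params$tau_N, sigma = ts$params$sigma)
  scr <- screen_ensemble(tm, ts$forcing, base_seed = ts$seed - 1, store_thin = 50)
  ext <- extend_holocene(scr, ts$forcing)
  m <- ext$members
  expect_true(m$plausible)
  # six Pleistocene episodes plus the Holocene one make seven in total
  tr <- simulate_trajectory(ts$params, ts$forcing, seed = ts$seed)
  n_total <- nrow(detect_green_events(tr, window = c(230000, 0)))
  expect_equal(n_total, 7)
  expect_false(is.na(m$holocene_green_start))
  # collapse time matches the independently scanned sign change of r
  truth_sel <- holocene_collapse(ts$events_scan, green_at_start = TRUE)
  expect_lt(abs(m$collapse_t_star - truth_sel$t_star), 100)
  expect_false(m$never_leaves_green)
  # a member whose rainfall stays positive through the Holocene never leaves green
  stay <- data.frame(member_id = 1, a = 1.5, b = -1, c = 0.1, d = 1,
                     tau_v = 20, tau_N = 5, sigma = 0.2)
  fs <- annual_forcing()
  scr2 <- screen_ensemble(stay, fs, base_seed = 4, store_thin = 0)
  ext2 <- extend_holocene(scr2, fs)
  expect_true(is.na(ext2$members$collapse_t_star) || ext2$members$never_leaves_green)
})

test_that("dropping never-collapse members leaves the sensitivity unchanged", {
  fs <- annual_forcing()
  m <- sample_params(60, seed = 12)
  scr <- screen_ensemble(m, fs, base_seed = 12, store_thin = 0)
  ext <- extend_holocene(scr, fs)
  ss_all <- ensemble_sensitivity(ext, include_never_green = TRUE)
  ss_dropped <- ensemble_sensitivity(ext, include_never_green = FALSE)
  expect_identical(ss_all$count, ss_dropped$count)
  expect_identical(ss_all$smoothed, ss_dropped$smoothed)
})

test_that("replicate_experiment reruns the pipeline reproducibly", {
  fs <- annual_forcing()
  r1 <- replicate_experiment(3, n_members = 40, forcing = fs, base_seed = 5)
  expect_length(r1$ss, 3)
  for (ss in r1$ss) {
    expect_s3_class(ss, "sensitivity_series")
    expect_identical(ss$bin_start, r1$ss[[1]]$bin_start)
  }
  r2 <- replicate_experiment(3, n_members = 40, forcing = fs, base_seed = 5)
  expect_identical(r1$peak_bin, r2$peak_bin)
  expect_identical(r1$ss[[2]]$count, r2$ss[[2]]$count)
  expect_error(replicate_experiment(1, n_members = 10, forcing = fs), "2 replicates")
})

test_that("correlation_subset ranks a member against its own trace first", {
  fs <- annual_forcing()
  m <- sample_params(30, seed = 17)
  scr <- screen_ensemble(m, fs, base_seed = 17, store_thin = 20)
  obs <- data.frame(time = scr$v_time, value = scr$v[, 12])
  top <- correlation_subset(scr, obs, k = 5, plausible_only = FALSE)
  expect_equal(top$member_id[1], 12)
  expect_equal(top$r_squared[1], 1, tolerance = 1e-12)
  # pure-noise observations still fill k
  set.seed(1)
  obs_noise <- data.frame(time = scr$v_time, value = rnorm(length(scr$v_time)))
  top_n <- correlation_subset(scr, obs_noise, k = 10, plausible_only = FALSE)
  expect_equal(nrow(top_n), 10)
  expect_error(correlation_subset(scr, obs, k = 500, plausible_only = FALSE), "exceeds")
})

test_that("member CSV export carries the screening columns", {
  fs <- annual_forcing()
  m <- sample_params(10, seed = 23)
  scr <- screen_ensemble(m, fs, base_seed = 23, store_thin = 0)
  ext <- extend_holocene(scr, fs)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_members_csv(ext, path)
  back <- read.csv(path)
  expect_named(back, c("member_id", "a", "b", "c", "d", "tau_v", "tau_N",
                       "sigma", "seed", "n_green_230_20", "plausible",
                       "collapse_t_star_yrBP", "never_leaves_green"))
  expect_equal(nrow(back), 10)
})
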