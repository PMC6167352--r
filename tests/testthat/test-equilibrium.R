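test_that("potential matches hand-computed values and rejects d = 0", {
  expect_equal(potential(0, 0, 2), 0)
  # 0.5 - ln(cosh(1)) evaluated independently
  expect_equal(potential(1, 0, 1), 0.06621917, tolerance = 1e-6)
  expect_error(potential(0.5, 0.1, 0), "d = 0")
})

test_that("potential and min_potential_state obey the mirror symmetry", {
  set.seed(4)
  for (i in 1:40) {
    v <- runif(1, -1.5, 1.5)
    r <- runif(1, -2, 2)
    d <- runif(1, 0.05, 2)
    expect_equal(potential(v, r, d), potential(-v, -r, d), tolerance = 1e-14)
    expect_equal(min_potential_state(-r, d), -min_potential_state(r, d),
                 tolerance = 1e-10)
  }
})

test_that("min_potential_state matches the fixed-point oracle and sign rule", {
  expect_equal(min_potential_state(0.5, 1), bisect_root(0.5, 1), tolerance = 1e-9)
  expect_equal(min_potential_state(0.5, 1), 0.8812254, tolerance = 1e-6)
  expect_equal(min_potential_state(-0.5, 1), -0.8812254, tolerance = 1e-6)
  expect_equal(min_potential_state(0, 0.8), 0)
  set.seed(9)
  for (i in 1:30) {
    r <- runif(1, -1.5, 1.5)
    d <- runif(1, 0.05, 2)
    m <- min_potential_state(r, d)
    if (r != 0) expect_identical(sign(m), sign(r))
    # confirmed as the argmin by brute-force grid search
    expect_equal(m, brute_argmin_U(r, d), tolerance = 2e-3)
  }
})

test_that("threshold_times finds sign flips of the background rainfall", {
  fs <- forcing_from_r(c(0.2, 0.1, -0.1, -0.3), times = c(3000, 2000, 1000, 0))
  p <- passthrough_params()
  ev <- threshold_times(p, fs)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$t_star, 1000)
  expect_equal(ev$direction, "collapse")
  # constant background rainfall: no events
  expect_equal(nrow(threshold_times(p, const_forcing(10, P = 0.3))), 0)
  # onset labelling
  ev2 <- threshold_times(p, forcing_from_r(c(-0.2, 0.1, 0.3), times = c(2000, 1000, 0)))
  expect_equal(ev2$direction, "onset")
  expect_equal(ev2$t_star, 1000)
})

test_that("sign-rule events equal potential-argmin crossings on random draws", {
  # scaled-down version of the full equivalence check in the acceptance suite
  set.seed(14)
  rng <- param_ranges()
  for (i in 1:20) {
    spec <- synthetic_forcing_spec(window = c(20000, 0), timestep = 100,
                                   modulation_t_max = runif(1, 0, 20000))
    fs <- make_forcing(spec)
    p <- model_params(runif(1, rng$a[1], rng$a[2]), runif(1, rng$b[1], rng$b[2]),
                      runif(1, rng$c[1], rng$c[2]), runif(1, rng$d[1], rng$d[2]),
                      20, 5, 0.3)
    ev <- threshold_times(p, fs)
    s <- brute_green_side(background_rainfall(p, fs), p$d)
    flip <- which(s[-1] != s[-length(s)]) + 1L
    expect_identical(ev$t_star, fs$time[flip])
    expect_identical(ev$direction, ifelse(s[flip], "onset", "collapse"))
  }
})

test_that("holocene_collapse applies the first-after-last-onset rule", {
  ev <- data.frame(t_star = c(14700, 7000, 5000, 2000),
                   direction = c("onset", "collapse", "onset", "collapse"))
  sel <- holocene_collapse(ev)
  expect_equal(sel$t_star, 2000)
  expect_false(sel$never_leaves_green)
  # rule = "first" takes the earliest collapse instead
  expect_equal(holocene_collapse(ev, rule = "first")$t_star, 7000)
  # green at window start, no onset inside: first collapse counts
  ev2 <- data.frame(t_star = 5500, direction = "collapse")
  expect_equal(holocene_collapse(ev2, green_at_start = TRUE)$t_star, 5500)
  expect_true(is.na(holocene_collapse(ev2, green_at_start = FALSE)$t_star))
  # onset with no later collapse: never leaves green
  ev3 <- data.frame(t_star = 14700, direction = "onset")
  sel3 <- holocene_collapse(ev3)
  expect_true(sel3$never_leaves_green)
  expect_true(is.na(sel3$t_star))
})

test_that("sensitivity bins threshold times into left-closed century bins", {
  ss <- sensitivity(c(6050, 6120, 5950), window = c(15000, 0))
  expect_equal(sum(ss$count), 3)
  expect_equal(ss$count[ss$bin_start == 6200], 1)  # 6120 in (6100, 6200]
  expect_equal(ss$count[ss$bin_start == 6100], 1)  # 6050
  expect_equal(ss$count[ss$bin_start == 6000], 1)  # 5950
  # the older edge is included, the younger excluded
  ss2 <- sensitivity(c(6100, 6000), window = c(15000, 0))
  expect_equal(ss2$count[ss2$bin_start == 6100], 1)
  expect_equal(ss2$count[ss2$bin_start == 6000], 1)
})

test_that("sensitivity handles empty input and NA members", {
  ss <- sensitivity(numeric(0))
  expect_true(all(ss$count == 0))
  expect_true(all(ss$smoothed == 0))
  ss2 <- sensitivity(c(NA, 7050, NA))
  expect_equal(sum(ss2$count), 1)
  expect_error(sensitivity(7050, window = c(15000, 0), bin_width = 130), "divide")
})

test_that("sensitivity counts are order-invariant and binomially spread", {
  set.seed(31)
  t_star <- runif(400, 0.0001, 1000)  # uniform over 10 bins of a 1 ka window
  s1 <- sensitivity(t_star, window = c(1000, 0))
  s2 <- sensitivity(sample(t_star), window = c(1000, 0))
  expect_identical(s1$count, s2$count)
  expect_equal(sum(s1$count), 400)
  expect_true(all(abs(s1$count - 40) <= 4 * sqrt(400 / 10)))
})

test_that("the 3-point running mean truncates at the edges", {
  ss <- sensitivity(c(14950, 14950, 14850), window = c(15000, 0))
  # first bin averages over itself and one neighbour only
  expect_equal(ss$smoothed[1], (2 + 1) / 2)
  expect_equal(ss$smoothed[2], (2 + 1 + 0) / 3)
  expect_equal(length(ss$smoothed), length(ss$count))
})
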