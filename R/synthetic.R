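#' Specification for synthetic forcing
#'
#' Describes an analytic stand-in for the two real drivers: a quasi-periodic
#' eccentricity-modulated precession signal built from two sinusoids near
#' the 23.7- and 22.4-kyr precession periods, and a glacial-interglacial CO2
#' cycle shaped as an asymmetric sawtooth (slow glacial decline, fast
#' deglacial rise) between ~190 and ~280 ppm.  The beat of the two
#' precession terms under a 100-kyr amplitude modulation produces discrete
#' humid windows, which is the structural feature the real orbital forcing
#' contributes; a real orbital solution can always be supplied to
#' [load_forcing()] instead.
#'
#' @param window `c(oldest, youngest)` years BP (default `c(230000, 0)`).
#' @param timestep Output grid spacing in years (default 1).
#' @param precession_periods Data frame with columns `period` (yr),
#'   `amplitude`, `phase` (radians); defaults anchor a joint precession
#'   minimum (wet phase) near 12 ka BP, mimicking the early-Holocene
#'   insolation maximum.
#' @param modulation `c(period, depth)`: amplitude modulation
#'   `1 - depth*(0.5 - 0.5*cos(2*pi*(t - t_max)/period))`, default 100-kyr
#'   period and depth 0.5.
#' @param modulation_t_max Years BP at which the modulation envelope peaks
#'   (default 5000).
#' @param co2 List with `period` (yr), `low`/`high` (ppm), `rise_fraction`
#'   (fraction of the cycle spent in the fast deglacial rise) and
#'   `termination` (years BP at which the rise completes); defaults give a
#'   190-280 ppm cycle terminating at 10 ka BP.
#' @return A list of class `synthetic_forcing_spec`.
#' @export
synthetic_forcing_spec <- function(window = c(230000, 0), timestep = 1,
                                   precession_periods = NULL,
                                   modulation = c(period = 100000, depth = 0.5),
                                   modulation_t_max = 5000,
                                   co2 = list(period = 100000, low = 190, high = 280,
                                              rise_fraction = 0.1, termination = 10000)) {
  if (is.null(precession_periods)) {
    t0 <- 12000  # joint minimum of both terms: wet early Holocene
    precession_periods <- data.frame(
      period = c(23700, 22400),
      amplitude = c(0.035, 0.02),
      phase = c(-pi / 2 - 2 * pi * t0 / 23700, -pi / 2 - 2 * pi * t0 / 22400))
  }
  window <- sort(as.numeric(window), decreasing = TRUE)
  if (any(precession_periods$amplitude < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  if (co2$low > co2$high) stop("co2 low must not exceed high", call. = FALSE)
  if (window[1] <= window[2]) stop("window oldest must exceed youngest", call. = FALSE)
  structure(list(window = window, timestep = timestep,
                 precession_periods = precession_periods,
                 modulation = modulation, modulation_t_max = modulation_t_max,
                 co2 = co2),
            class = "synthetic_forcing_spec")
}

# Asymmetric sawtooth CO2 in ppm at times t (years BP).
sawtooth_co2 <- function(t, co2) {
  per <- co2$period
  f <- co2$rise_fraction
  x <- (t - co2$termination) %% per  # years before the nearest termination
  rise <- x < f * per
  out <- numeric(length(t))
  out[rise] <- co2$low + (co2$high - co2$low) * (1 - x[rise] / (f * per))
  out[!rise] <- co2$high - (co2$high - co2$low) * ((per - x[!rise]) / ((1 - f) * per))
  out
}

#' Generate a synthetic forcing series
#'
#' Deterministically evaluates the analytic drivers of a
#' [synthetic_forcing_spec()] on its time grid:
#' `P(t) = m(t) * sum_i amp_i * sin(2*pi*t/T_i + phase_i)` with `m(t)` the
#' eccentricity-like modulation envelope, and CO2 the asymmetric sawtooth
#' converted to radiative forcing by [co2_to_forcing()].
#'
#' @param spec A [synthetic_forcing_spec()].
#' @return A [forcing_series()].
#' @export
make_forcing <- function(spec = synthetic_forcing_spec()) {
  stopifnot(inherits(spec, "synthetic_forcing_spec"))
  t <- seq(spec$window[1], spec$window[2], by = -spec$timestep)
  pp <- spec$precession_periods
  P <- numeric(length(t))
  for (i in seq_len(nrow(pp))) {
    P <- P + pp$amplitude[i] * sin(2 * pi * t / pp$period[i] + pp$phase[i])
  }
  m <- 1 - spec$modulation[["depth"]] *
    (0.5 - 0.5 * cos(2 * pi * (t - spec$modulation_t_max) / spec$modulation[["period"]]))
  P <- m * P
  co2 <- sawtooth_co2(t, spec$co2)
  forcing_series(t, P, co2_to_forcing(co2))
}

#' Write synthetic driver tables to CSV
#'
#' Writes the raw driver tables (`time_ka,precession` and `time_ka,co2_ppm`)
#' for a spec, thinned to `sample_every` years, in the format accepted by
#' [load_forcing()] — a round-trip fixture generator.
#'
#' @param spec A [synthetic_forcing_spec()].
#' @param precession_path,co2_path Output CSV paths.
#' @param sample_every Table resolution in years (default 500).
#' @return Invisibly, the two paths.
#' @export
write_synthetic_tables <- function(spec, precession_path, co2_path,
                                   sample_every = 500) {
  t <- seq(spec$window[1], spec$window[2], by = -sample_every)
  fs <- make_forcing(synthetic_forcing_spec(
    window = spec$window, timestep = sample_every,
    precession_periods = spec$precession_periods,
    modulation = spec$modulation, modulation_t_max = spec$modulation_t_max,
    co2 = spec$co2))
  utils::write.csv(data.frame(time_ka = t / 1000, precession = fs$P),
                   precession_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(time_ka = t / 1000, co2_ppm = sawtooth_co2(t, spec$co2)),
                   co2_path, row.names = FALSE, quote = FALSE)
  invisible(c(precession_path, co2_path))
}

#' Derive a 500-yr binned proxy-state table from a trajectory
#'
#' Bins the smoothed vegetation cover and classifies each bin as `"wet"`
#' (mean smoothed v above `wet_threshold`), `"dry"` (below `dry_threshold`)
#' or `"moderate"`, emulating a subjective hydroclimate classification of a
#' proxy record.
#'
#' @param traj A `trajectory`.
#' @param record_id Identifier for the output record.
#' @param bin Bin width in years (default 500).
#' @param wet_threshold,dry_threshold Classification cuts on smoothed v
#'   (defaults 0.3 and -0.3).
#' @param smooth_window Boxcar width in years before binning (default 500).
#' @param region,lat,lon Metadata columns for the output table.
#' @param window Optional `c(oldest, youngest)` years BP restriction.
#' @return Data frame with columns
#'   `record_id,region,lat,lon,bin_start_yrBP,state`.
#' @export
states_from_trajectory <- function(traj, record_id = "synthetic-1", bin = 500,
                                   wet_threshold = 0.3, dry_threshold = -0.3,
                                   smooth_window = 500, region = "Synthetic",
                                   lat = 20, lon = 10, window = NULL) {
  dt <- attr(traj, "timestep")
  if (is.null(dt)) dt <- abs(traj$time[2] - traj$time[1])
  time <- traj$time
  v <- traj$v
  if (!is.null(window)) {
    window <- sort(as.numeric(window), decreasing = TRUE)
    keep <- time <= window[1] & time >= window[2]
    time <- time[keep]; v <- v[keep]
  }
  k <- max(1L, as.integer(round(smooth_window / dt)))
  if (k %% 2L == 0L) k <- k + 1L
  vs <- running_mean(v, k)
  bin_start <- bin * ceiling(time / bin)
  agg <- tapply(vs, bin_start, mean)
  bins <- as.numeric(names(agg))
  ord <- order(bins, decreasing = TRUE)
  bins <- bins[ord]; agg <- as.numeric(agg)[ord]
  state <- ifelse(agg > wet_threshold, "wet", ifelse(agg < dry_threshold, "dry", "moderate"))
  data.frame(record_id = record_id, region = region, lat = lat, lon = lon,
             bin_start_yrBP = bins, state = state, stringsAsFactors = FALSE)
}

# Count green episodes of the truth member for a candidate offset a.
truth_event_count <- function(a, truth, forcing, seed, window, detector) {
  p <- model_params(a, truth$b, truth$c, truth$d, truth$tau_v, truth$tau_N, truth$sigma)
  traj <- simulate_trajectory(p, forcing, seed = seed)
  nrow(detect_green_events(traj, detector$smooth_window, detector$min_duration,
                           detector$merge_gap, window = window))
}

#' Build a ground-truth study: forcing, truth member, proxy trace and states
#'
#' Generates everything needed to exercise the full pipeline against a known
#' answer.  The background offset `a` of the supplied truth parameters is
#' tuned — by a coarse scan followed by bisection on the green-episode count,
#' which grows with `a` — until the truth member shows exactly
#' `n_events_target` green episodes inside the screening window.  The
#' function then emits the truth trajectory over the full window, a noisy
#' proxy trace (truth `v` plus white noise, standing in for a Ba/Al record),
#' one or more 500-yr binned proxy-state records derived from replicate
#' noise realisations of the truth member, and the ground-truth threshold
#' times of the tuned member obtained by an independent coarse-grid scan of
#' the background-rainfall sign.
#'
#' @param spec A [synthetic_forcing_spec()].
#' @param truth A [model_params()]; its `a` is used as the centre of the
#'   tuning scan.
#' @param n_events_target Required green-episode count in `window`
#'   (default 6).
#' @param window Screening window (default `c(230000, 20000)`).
#' @param seed RNG seed for the truth member's noise stream.
#' @param proxy_noise_sd White-noise s.d. added to `v` for the proxy trace;
#'   `NULL` (default) uses 30% of the signal s.d.
#' @param proxy_every Proxy-trace sampling interval in years (default 100).
#' @param n_records Number of replicate proxy-state records (default 3).
#' @param detector Green-episode detector overrides (see
#'   [detect_green_events()]).
#' @param max_iter Maximum tuning evaluations before giving up (default 60).
#' @return List of class `truth_study`: `forcing`, `params` (tuned),
#'   `trajectory`, `proxy` (`time`, `value`), `states` (multi-record proxy
#'   table), `truth_collapse_dates` (named per record, from the generator's
#'   own states), `events_scan` (independent coarse-scan threshold times,
#'   columns `t_star`, `direction`), `seed`.
#' @export
make_truth_study <- function(spec = synthetic_forcing_spec(), truth,
                             n_events_target = 6L, window = c(230000, 20000),
                             seed = 101L, proxy_noise_sd = NULL,
                             proxy_every = 100, n_records = 3L,
                             detector = list(), max_iter = 60L) {
  stopifnot(inherits(truth, "model_params"))
  det <- utils::modifyList(
    list(smooth_window = 1000, min_duration = 2000, merge_gap = 2000), detector)
  forcing <- make_forcing(spec)
  window <- sort(as.numeric(window), decreasing = TRUE)

  cnt <- function(a) truth_event_count(a, truth, forcing, seed, window, det)
  # coarse scan around the supplied a, then bisect the bracketing interval
  lo <- truth$a - 2.5; hi <- truth$a + 2.5
  grid <- seq(lo, hi, length.out = 21L)
  counts <- vapply(grid, cnt, integer(1))
  used <- length(grid)
  # first crossing of the target from below: the episode count grows with a
  # on this branch, so bisection is well posed; staying on the low-a side
  # keeps the background rainfall generally negative (episodic green state)
  br <- which(counts[-length(counts)] < n_events_target &
              counts[-1] >= n_events_target)
  if (length(br) > 0L) {
    i <- br[1L]
    if (counts[i + 1L] == n_events_target) {
      a_star <- grid[i + 1L]
    } else {
      a_lo <- grid[i]; a_hi <- grid[i + 1L]
      a_star <- NA_real_
      while (used < max_iter) {
        mid <- (a_lo + a_hi) / 2
        cm <- cnt(mid); used <- used + 1L
        if (cm == n_events_target) { a_star <- mid; break }
        if (cm < n_events_target) a_lo <- mid else a_hi <- mid
      }
      if (is.na(a_star)) stop("tuning failed to reach the target count in ",
                              max_iter, " evaluations; spec infeasible", call. = FALSE)
    }
  } else if (any(counts == n_events_target)) {
    a_star <- grid[which(counts == n_events_target)[1L]]
  } else {
    stop("cannot bracket the target green-episode count; spec infeasible", call. = FALSE)
  }
  params <- model_params(a_star, truth$b, truth$c, truth$d,
                         truth$tau_v, truth$tau_N, truth$sigma)
  traj <- simulate_trajectory(params, forcing, seed = seed)

  # noisy proxy trace on a coarse grid
  idx <- seq(1L, nrow(traj), by = as.integer(round(proxy_every / spec$timestep)))
  if (is.null(proxy_noise_sd)) proxy_noise_sd <- 0.3 * stats::sd(traj$v)
  set.seed(as.integer(seed) + 500000L)
  proxy <- data.frame(time = traj$time[idx],
                      value = traj$v[idx] + stats::rnorm(length(idx), 0, proxy_noise_sd))

  # replicate proxy-state records: same parameters, independent noise streams
  states <- NULL
  truth_dates <- numeric(0)
  for (r in seq_len(n_records)) {
    tr <- if (r == 1L) traj else
      simulate_trajectory(params, forcing, seed = seed + 1000L * r)
    st <- states_from_trajectory(tr, record_id = sprintf("truth-%02d", r),
                                 window = c(15000, 0))
    states <- rbind(states, st)
    truth_dates[sprintf("truth-%02d", r)] <-
      suppressWarnings(date_collapse(st$state, st$bin_start_yrBP))
  }
  states <- read_proxy_states(states)

  # independent ground truth for threshold times: direct coarse scan of the
  # background-rainfall sign at 10-yr resolution
  scan_t <- seq(window[1], 0, by = -10)
  r_scan <- background_rainfall(params,
                                stats::approx(forcing$time, forcing$P, scan_t)$y,
                                stats::approx(forcing$time, forcing$F, scan_t)$y)
  s <- r_scan >= 0
  flip <- which(s[-1] != s[-length(s)]) + 1L
  events_scan <- data.frame(t_star = scan_t[flip],
                            direction = ifelse(s[flip], "onset", "collapse"),
                            stringsAsFactors = FALSE)

  structure(list(forcing = forcing, params = params, trajectory = traj,
                 proxy = proxy, states = states,
                 truth_collapse_dates = truth_dates,
                 events_scan = events_scan, seed = as.integer(seed),
                 window = window, detector = det),
            class = "truth_study")
}
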