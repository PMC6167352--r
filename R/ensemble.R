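#' Uniform sampling ranges for the seven model parameters
#'
#' Each parameter of [model_params()] is drawn uniformly from a (low, high)
#' interval.  The defaults are engineering choices spanning the regime where
#' precession minima and high CO2 favour the green state: the background
#' offset `a` is generally negative (the green state must not be the
#' default condition), `b` is negative so that precession minima are wet,
#' `c` is positive so that high CO2 is wet, and `d` brackets the
#' moderate-feedback range around 1.
#'
#' @param a,b,c,d,tau_v,tau_N,sigma Length-2 numeric `c(low, high)` ranges.
#' @return A named list of class `param_ranges`.
#' @export
param_ranges <- function(a = base::c(-2.0, 0.5), b = base::c(-40, 0),
                         c = base::c(0, 1.0), d = base::c(0.5, 1.5),
                         tau_v = base::c(5, 100), tau_N = base::c(1, 20),
                         sigma = base::c(0.1, 2.0)) {
  # base::c in the defaults: the argument named `c` would otherwise shadow
  # the concatenation function during default evaluation
  rg <- list(a = a, b = b, c = c, d = d, tau_v = tau_v, tau_N = tau_N, sigma = sigma)
  for (nm in names(rg)) {
    r <- rg[[nm]]
    if (!is.numeric(r) || length(r) != 2L || anyNA(r) || r[1] >= r[2]) {
      stop(sprintf("range for '%s' must be numeric c(low, high) with low < high", nm),
           call. = FALSE)
    }
  }
  if (rg$tau_v[1] <= 0 || rg$tau_N[1] <= 0) {
    stop("timescale ranges must be positive", call. = FALSE)
  }
  if (rg$sigma[1] < 0) stop("sigma range must be non-negative", call. = FALSE)
  structure(rg, class = "param_ranges")
}

#' Draw an ensemble of parameter settings
#'
#' Each of the `n` members gets all seven parameters drawn independently and
#' uniformly from the given ranges; the draw is reproducible for a fixed
#' seed.
#'
#' @param n Number of members (>= 1).
#' @param ranges A [param_ranges()].
#' @param seed Integer RNG seed.
#' @return Data frame with `member_id` and one column per parameter.
#' @export
sample_params <- function(n, ranges = param_ranges(), seed = 1L) {
  if (!inherits(ranges, "param_ranges")) ranges <- do.call(param_ranges, ranges)
  n <- as.integer(n)
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  set.seed(as.integer(seed))
  out <- data.frame(member_id = seq_len(n))
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    out[[nm]] <- stats::runif(n, r[1], r[2])
  }
  out
}

# Coerce row i of a parameter data frame to model_params.
row_params <- function(members, i) {
  model_params(members$a[i], members$b[i], members$c[i], members$d[i],
               members$tau_v[i], members$tau_N[i], members$sigma[i])
}

#' Detect green episodes in a trajectory
#'
#' A green episode is a maximal interval in which the boxcar-smoothed
#' vegetation cover exceeds 0.  Detection proceeds in four steps: smooth `v`
#' over `smooth_window` years (centred boxcar, truncated at the edges); mark
#' times with smoothed `v > 0`; merge green intervals separated by gaps
#' shorter than `merge_gap` years; and drop episodes shorter than
#' `min_duration` years.  The defaults target millennial-scale humid
#' periods (sapropel-like features) and suppress noise flicker.
#'
#' @param traj A `trajectory` from [simulate_trajectory()].
#' @param smooth_window Boxcar width in years (default 1000).
#' @param min_duration Minimum episode duration in years (default 2000).
#' @param merge_gap Merge gaps shorter than this many years (default 2000).
#' @param window Optional `c(oldest, youngest)` years BP restricting the
#'   analysis; default is the whole trajectory.
#' @return Data frame with columns `start`, `end` (years BP, start older
#'   than end), one row per episode, ordered oldest first.
#' @export
detect_green_events <- function(traj, smooth_window = 1000, min_duration = 2000,
                                merge_gap = 2000, window = NULL) {
  stopifnot(inherits(traj, "trajectory") || is.data.frame(traj))
  dt <- attr(traj, "timestep")
  if (is.null(dt)) dt <- abs(traj$time[2] - traj$time[1])
  time <- traj$time
  v <- traj$v
  if (!is.null(window)) {
    window <- sort(as.numeric(window), decreasing = TRUE)
    if (window[1] > max(time) || window[2] < min(time)) {
      stop("analysis window extends beyond the trajectory", call. = FALSE)
    }
    keep <- time <= window[1] & time >= window[2]
    time <- time[keep]
    v <- v[keep]
  }
  k <- max(1L, as.integer(round(smooth_window / dt)))
  if (k %% 2L == 0L) k <- k + 1L  # centred window
  green <- running_mean(v, k) > 0
  runs_to_events(green, time, dt, min_duration, merge_gap)
}

# Turn a logical green mask over a decreasing-BP time axis into merged,
# duration-filtered (start, end) intervals.
runs_to_events <- function(green, time, dt, min_duration, merge_gap) {
  r <- rle(green)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- data.frame(start = time[starts[r$values]], end = time[ends[r$values]])
  if (nrow(ev) > 1L) {
    merged <- ev[1L, , drop = FALSE]
    for (i in 2L:nrow(ev)) {
      gap <- merged$end[nrow(merged)] - ev$start[i]  # BP years between events
      if (gap < merge_gap) {
        merged$end[nrow(merged)] <- ev$end[i]
      } else {
        merged <- rbind(merged, ev[i, ])
      }
    }
    ev <- merged
  }
  if (nrow(ev) > 0L) {
    dur <- ev$start - ev$end + dt
    ev <- ev[dur >= min_duration, , drop = FALSE]
  }
  rownames(ev) <- NULL
  ev
}

#' Screen an ensemble by green-episode count
#'
#' Simulates every member over the supplied forcing with its own seed
#' (`base_seed + member_id`), detects green episodes inside the screening
#' window, and flags as "not implausible" exactly those members whose
#' episode count equals `required_events` — the number of observed green
#' episodes (sapropels) over the last two glacial cycles.
#'
#' @param members Parameter data frame from [sample_params()] (or any data
#'   frame with the seven parameter columns and `member_id`).
#' @param forcing A [forcing_series()]; must cover `window`.
#' @param required_events Exact episode count required (default 6).
#' @param window Screening window `c(oldest, youngest)` years BP
#'   (default `c(230000, 20000)`).
#' @param base_seed Base RNG seed; member `i` uses `base_seed + i` unless
#'   the member table already carries a `seed` column, which then takes
#'   precedence (used to screen a reference member under the exact noise
#'   stream it was constructed with).
#' @param detector Named list of overrides for [detect_green_events()]
#'   (`smooth_window`, `min_duration`, `merge_gap`).
#' @param store_thin Store each member's vegetation series thinned to every
#'   `store_thin`-th point (for later correlation against observations);
#'   `0` disables storage.
#' @param spinup Spin-up years passed to [simulate_trajectory()].
#' @param verbose Emit a progress line every `10000` members.
#' @return A list of class `ensemble_screen` with elements `members` (the
#'   input plus `seed`, `n_green`, `plausible`), `green_events` (list of
#'   per-member episode tables), `v` (matrix of stored vegetation series,
#'   one column per member; `NULL` if disabled), `v_time`, `forcing`,
#'   `window`, `detector`, `base_seed`, `spinup`.
#' @export
screen_ensemble <- function(members, forcing, required_events = 6L,
                            window = c(230000, 20000), base_seed = 1L,
                            detector = list(), store_thin = 100L,
                            spinup = 1000, verbose = FALSE) {
  stopifnot(inherits(forcing, "forcing_series"))
  det <- utils::modifyList(
    list(smooth_window = 1000, min_duration = 2000, merge_gap = 2000), detector)
  n <- nrow(members)
  n_green <- integer(n)
  seeds <- if (!is.null(members$seed)) as.integer(members$seed) else
    as.integer(base_seed) + members$member_id
  green_events <- vector("list", n)
  store <- store_thin > 0L
  v_idx <- if (store) seq(1L, nrow(forcing), by = as.integer(store_thin)) else integer()
  vmat <- if (store) matrix(NA_real_, length(v_idx), n) else NULL
  for (i in seq_len(n)) {
    p <- row_params(members, i)
    traj <- simulate_trajectory(p, forcing, seed = seeds[i], spinup = spinup)
    ev <- detect_green_events(traj, det$smooth_window, det$min_duration,
                              det$merge_gap, window = window)
    green_events[[i]] <- ev
    n_green[i] <- nrow(ev)
    if (store) vmat[, i] <- traj$v[v_idx]
    if (verbose && i %% 10000L == 0L) {
      message(sprintf("screened %d/%d members; %d retained so far",
                      i, n, sum(n_green[seq_len(i)] == required_events)))
    }
  }
  members$seed <- seeds
  members$n_green <- n_green
  members$plausible <- n_green == as.integer(required_events)
  structure(list(members = members, green_events = green_events,
                 v = vmat, v_time = if (store) forcing$time[v_idx] else NULL,
                 forcing = forcing, window = window, detector = det,
                 base_seed = as.integer(base_seed), spinup = spinup),
            class = "ensemble_screen")
}

#' @export
print.ensemble_screen <- function(x, ...) {
  cat(sprintf("<ensemble_screen> %d members, %d plausible (%.1f%%) in %s-%s yr BP\n",
              nrow(x$members), sum(x$members$plausible),
              100 * mean(x$members$plausible),
              format(x$window[1], big.mark = ","), format(x$window[2], big.mark = ",")))
  invisible(x)
}

#' Extend plausible members through the Holocene
#'
#' Re-integrates every plausible member over the full forcing (Pleistocene
#' screening window plus Holocene) with its original seed, so the
#' Pleistocene part of the run and its noise stream are reproduced exactly
#' and the stream simply continues to present.  For each member it records
#' the first Holocene green episode, the collapse threshold time selected by
#' [holocene_collapse()], and whether the member never leaves the green
#' state before present.
#'
#' @param screened An `ensemble_screen` from [screen_ensemble()].
#' @param forcing Full-range [forcing_series()] covering both the screening
#'   window and the Holocene; its old edge must match the screening forcing.
#' @param holocene_window `c(oldest, youngest)` years BP (default
#'   `c(15000, 0)`).
#' @param rule Collapse-selection rule, see [holocene_collapse()].
#' @return The input object with its `members` table gaining
#'   `holocene_green_start`, `holocene_green_end`, `collapse_t_star`,
#'   `never_leaves_green` (all `NA` for implausible members), plus a stored
#'   full-range `v` matrix for plausible members.
#' @export
extend_holocene <- function(screened, forcing, holocene_window = c(15000, 0),
                            rule = "after_last_onset") {
  stopifnot(inherits(screened, "ensemble_screen"), inherits(forcing, "forcing_series"))
  m <- screened$members
  n <- nrow(m)
  m$holocene_green_start <- NA_real_
  m$holocene_green_end <- NA_real_
  m$collapse_t_star <- NA_real_
  m$never_leaves_green <- NA
  det <- screened$detector
  store_thin <- if (!is.null(screened$v)) {
    max(1L, as.integer(round((screened$v_time[1] - screened$v_time[2]) /
                             attr(forcing, "timestep"))))
  } else 0L
  store <- store_thin > 0L
  v_idx <- if (store) seq(1L, nrow(forcing), by = store_thin) else integer()
  vmat <- if (store) matrix(NA_real_, length(v_idx), n) else NULL
  hw <- sort(as.numeric(holocene_window), decreasing = TRUE)
  for (i in which(m$plausible)) {
    p <- row_params(m, i)
    traj <- simulate_trajectory(p, forcing, seed = m$seed[i], spinup = screened$spinup)
    ev_holo <- detect_green_events(traj, det$smooth_window, det$min_duration,
                                   det$merge_gap, window = hw)
    if (nrow(ev_holo) > 0L) {
      m$holocene_green_start[i] <- ev_holo$start[1]
      m$holocene_green_end[i] <- ev_holo$end[1]
    }
    events <- threshold_times(p, forcing)
    r_at_start <- background_rainfall(
      p, forcing$P[which.min(abs(forcing$time - hw[1]))],
      forcing$F[which.min(abs(forcing$time - hw[1]))])
    sel <- holocene_collapse(events, window = hw,
                             green_at_start = r_at_start >= 0, rule = rule)
    m$collapse_t_star[i] <- sel$t_star
    m$never_leaves_green[i] <- sel$never_leaves_green
    if (store) vmat[, i] <- traj$v[v_idx]
  }
  screened$members <- m
  screened$holocene_window <- hw
  if (store) {
    screened$v <- vmat
    screened$v_time <- forcing$time[v_idx]
  }
  screened$forcing <- forcing
  screened
}

#' Sensitivity series of a screened-and-extended ensemble
#'
#' Convenience wrapper building the collapse-direction simulated-sensitivity
#' series from the `collapse_t_star` column of an extended ensemble.
#'
#' @param screened Output of [extend_holocene()].
#' @param window,bin_width Passed to [sensitivity()].
#' @param include_never_green Also pass members flagged `never_leaves_green`
#'   (their `t_star` is `NA`, so the series is unchanged; exposed to make
#'   that exclusion property directly testable).
#' @return A `sensitivity_series`.
#' @export
ensemble_sensitivity <- function(screened, window = c(15000, 0), bin_width = 100,
                                 include_never_green = TRUE) {
  m <- screened$members
  keep <- m$plausible
  if (!include_never_green) keep <- keep & !(m$never_leaves_green %in% TRUE)
  sensitivity(m$collapse_t_star[keep], window = window, bin_width = bin_width)
}

#' Replicate the whole screening experiment
#'
#' Repeats draw-parameters / screen / extend / sensitivity with independent
#' parameter and noise draws per replicate, to check that the temporal
#' structure of the sensitivity series is robust to sampling variability.
#'
#' @param n_replicates Number of replicates (default 20, >= 2).
#' @param n_members Ensemble size per replicate.
#' @param forcing Full-range [forcing_series()].
#' @param ranges A [param_ranges()].
#' @param base_seed Base seed; replicate i derives its own disjoint seed
#'   block `base_seed + (i - 1) * (n_members + 1)`.
#' @param window,required_events,detector Passed to [screen_ensemble()].
#' @param holocene_window,bin_width Passed to [extend_holocene()] /
#'   [sensitivity()].
#' @return List of class `replicate_experiment` with `ss` (list of
#'   sensitivity series), `peak_bin` (years BP of each replicate's smoothed
#'   maximum) and `peak_spread_bins` (range of peak locations in bins).
#' @export
replicate_experiment <- function(n_replicates = 20L, n_members, forcing,
                                 ranges = param_ranges(), base_seed = 1L,
                                 window = c(230000, 20000), required_events = 6L,
                                 detector = list(), holocene_window = c(15000, 0),
                                 bin_width = 100) {
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 2L) stop("need at least 2 replicates", call. = FALSE)
  ss <- vector("list", n_replicates)
  peak <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    seed_r <- as.integer(base_seed) + (r - 1L) * (as.integer(n_members) + 1L)
    members <- sample_params(n_members, ranges, seed = seed_r)
    scr <- screen_ensemble(members, forcing, required_events = required_events,
                           window = window, base_seed = seed_r,
                           detector = detector, store_thin = 0L)
    ext <- extend_holocene(scr, forcing, holocene_window = holocene_window)
    ss[[r]] <- ensemble_sensitivity(ext, window = holocene_window, bin_width = bin_width)
    sm <- ss[[r]]$smoothed
    peak[r] <- ss[[r]]$bin_start[which.max(sm)]
  }
  structure(list(ss = ss, peak_bin = peak,
                 peak_spread_bins = diff(range(peak)) / bin_width),
            class = "replicate_experiment")
}

#' Select the members best correlated with an observed proxy series
#'
#' Interpolates each member's stored vegetation series onto the observation
#' grid and ranks members by squared Pearson correlation with the
#' observations (a Ba/Al-like proxy trace).  Members with a constant
#' vegetation series get R-squared 0.  Ties are broken by member id; the
#' selection always fills `k`.
#'
#' @param screened An `ensemble_screen` with stored `v` (see `store_thin`),
#'   or a list with elements `v` (matrix, time by member), `v_time` and
#'   `members`.
#' @param observed Data frame with columns `time` (years BP) and `value`.
#' @param k Number of members to select (default 1500).
#' @param plausible_only Restrict the ranking to plausible members
#'   (default TRUE).
#' @return Data frame with `member_id` and `r_squared`, best first, `k` rows.
#' @export
correlation_subset <- function(screened, observed, k = 1500L, plausible_only = TRUE) {
  if (is.null(screened$v)) stop("no stored vegetation series; rerun with store_thin > 0", call. = FALSE)
  vt <- screened$v_time
  ot <- observed$time
  if (max(ot) > max(vt) || min(ot) < min(vt)) {
    observed <- observed[ot <= max(vt) & ot >= min(vt), , drop = FALSE]
    ot <- observed$time
  }
  if (length(ot) < 3L) stop("observations do not overlap the stored trajectories", call. = FALSE)
  ids <- screened$members$member_id
  cols <- seq_along(ids)
  if (plausible_only) {
    cols <- cols[screened$members$plausible]
    ids <- ids[screened$members$plausible]
  }
  k <- as.integer(k)
  if (k > length(ids)) stop("k exceeds the number of candidate members", call. = FALSE)
  r2 <- vapply(cols, function(j) {
    vj <- stats::approx(vt, screened$v[, j], xout = ot)$y
    if (anyNA(vj) || stats::sd(vj) == 0 || stats::sd(observed$value) == 0) return(0)
    stats::cor(vj, observed$value)^2
  }, numeric(1))
  ord <- order(-r2, ids)
  data.frame(member_id = ids[ord[seq_len(k)]], r_squared = r2[ord[seq_len(k)]])
}

#' Write an ensemble member table to CSV
#'
#' Columns: `member_id`, the seven parameters, `seed`, `n_green_230_20`,
#' `plausible`, `collapse_t_star_yrBP`, `never_leaves_green`.
#'
#' @param screened An `ensemble_screen` (optionally extended).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_members_csv <- function(screened, path) {
  m <- screened$members
  out <- data.frame(member_id = m$member_id, a = m$a, b = m$b, c = m$c, d = m$d,
                    tau_v = m$tau_v, tau_N = m$tau_N, sigma = m$sigma,
                    seed = m$seed, n_green_230_20 = m$n_green,
                    plausible = m$plausible,
                    collapse_t_star_yrBP = if (!is.null(m$collapse_t_star)) m$collapse_t_star else NA,
                    never_leaves_green = if (!is.null(m$never_leaves_green)) m$never_leaves_green else NA)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
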