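# Numerically stable log(cosh(x)): |x| + log1p(exp(-2|x|)) - log(2).
logcosh <- function(x) {
  ax <- abs(x)
  ax + log1p(exp(-2 * ax)) - log(2)
}

#' Equilibrium potential of the noiseless model
#'
#' The scalar potential whose minima are the stable states of the noiseless
#' vegetation model:
#' \deqn{U(v) = v^2/2 - \ln\cosh(r + dv)/d,}
#' with \eqn{r = a + bP + cF} the background rainfall.  Critical points of `U`
#' are exactly the fixed points `v = tanh(r + dv)`.
#'
#' @param v Vegetation value(s).
#' @param r Background rainfall `a + bP + cF`.
#' @param d Feedback strength; must be non-zero.
#' @return Potential value(s), vectorised over `v` and `r`.
#' @export
potential <- function(v, r, d) {
  if (any(d == 0)) stop("potential is undefined for d = 0", call. = FALSE)
  v^2 / 2 - logcosh(r + d * v) / d
}

# Fixed points of v = tanh(r + d v) on [-1.5, 1.5], located by sign-change
# scan plus uniroot refinement.
fixed_points <- function(r, d, lower = -1.5, upper = 1.5, n_scan = 601L) {
  f <- function(v) tanh(r + d * v) - v
  grid <- seq(lower, upper, length.out = n_scan)
  fg <- f(grid)
  roots <- grid[fg == 0]
  flip <- which(fg[-1] * fg[-n_scan] < 0)
  for (i in flip) {
    roots <- c(roots, stats::uniroot(f, c(grid[i], grid[i + 1L]), tol = 1e-12)$root)
  }
  sort(unique(roots))
}

#' Minimum-potential vegetation state
#'
#' The global minimiser of the equilibrium potential [potential()] over
#' \eqn{[-1.5, 1.5]}.  For \eqn{r \ne 0} the global minimum lies on the same
#' side of `v = 0` as `r`, which is why threshold times can equivalently be
#' detected from sign changes of the background rainfall alone
#' (see [threshold_times()]).
#'
#' @param r Background rainfall (scalar or vector).
#' @param d Feedback strength (> 0).
#' @return The minimising vegetation state(s).
#' @export
min_potential_state <- function(r, d) {
  if (length(d) != 1L || d <= 0) stop("d must be a positive scalar", call. = FALSE)
  vapply(r, function(ri) {
    cand <- fixed_points(ri, d)
    if (length(cand) == 0L) return(0)  # cannot occur for |r| <= atanh(1.5) range, defensive
    u <- potential(cand, ri, d)
    best <- cand[u == min(u)]
    if (length(best) > 1L) {
      # exact tie (r == 0, bistable): pick the non-negative state, matching
      # the sgn(0) = + convention
      best <- best[which.max(sign(best))]
    }
    best
  }, numeric(1))
}

#' Threshold (tipping) times of a parameter setting
#'
#' A threshold time is a grid time `t*` at which the minimum-potential state
#' crosses `v = 0`, i.e. where the sign of the background rainfall
#' \eqn{r(t) = a + bP(t) + cF(t)} differs from the previous step:
#' \deqn{\mathrm{sgn}(r_{t^*}) \ne \mathrm{sgn}(r_{t^*-\Delta t}).}
#' Crossings where `r` turns positive are onsets (desert to green); where it
#' turns negative, collapses (green to desert).  `sgn(0)` is treated as
#' positive.
#'
#' @param params A [model_params()].
#' @param forcing A [forcing_series()].
#' @return Data frame with columns `t_star` (years BP, on the forcing grid)
#'   and `direction` (`"onset"` or `"collapse"`); zero rows if the sign never
#'   changes.
#' @export
threshold_times <- function(params, forcing) {
  stopifnot(inherits(forcing, "forcing_series"))
  r <- background_rainfall(params, forcing)
  s <- r >= 0  # sgn(0) treated as positive
  n <- length(s)
  flip <- which(s[-1L] != s[-n]) + 1L
  data.frame(
    t_star = forcing$time[flip],
    direction = ifelse(s[flip], "onset", "collapse"),
    stringsAsFactors = FALSE
  )
}

#' Select a member's Holocene collapse time
#'
#' Reduces a member's list of threshold events within a window to the single
#' collapse time used by the sensitivity metric: the first collapse-direction
#' crossing after the member's last onset crossing (or, if the member is
#' already green at the start of the window and shows no onset, its first
#' collapse).  Members that turn green and never collapse again before
#' present are flagged `never_leaves_green`.
#'
#' @param events Data frame from [threshold_times()].
#' @param window `c(oldest, youngest)` years BP (default `c(15000, 0)`).
#' @param green_at_start Is the minimum-potential state green (r > 0) at the
#'   window's old edge?  Needed to interpret windows with no onset event.
#' @param rule `"after_last_onset"` (default) or `"first"` (first collapse in
#'   the window regardless of later onsets).
#' @return List with `t_star` (years BP or `NA`) and `never_leaves_green`
#'   (logical).
#' @export
holocene_collapse <- function(events, window = c(15000, 0), green_at_start = FALSE,
                              rule = c("after_last_onset", "first")) {
  rule <- match.arg(rule)
  window <- sort(as.numeric(window), decreasing = TRUE)
  ev <- events[events$t_star <= window[1] & events$t_star >= window[2], , drop = FALSE]
  onsets <- ev$t_star[ev$direction == "onset"]
  collapses <- ev$t_star[ev$direction == "collapse"]
  ever_green <- green_at_start || length(onsets) > 0L
  if (!ever_green) {
    return(list(t_star = NA_real_, never_leaves_green = FALSE))
  }
  if (rule == "after_last_onset" && length(onsets) > 0L) {
    last_onset <- min(onsets)  # youngest onset
    collapses <- collapses[collapses < last_onset]
  }
  if (length(collapses) == 0L) {
    return(list(t_star = NA_real_, never_leaves_green = TRUE))
  }
  list(t_star = max(collapses), never_leaves_green = FALSE)
}

# Running mean over a centred window of k points; edges use the available
# neighbours only (window truncated, never padded).
running_mean <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  half <- (k - 1L) %/% 2L
  cs0 <- c(0, cumsum(x))
  i <- seq_len(n)
  hi <- pmin(n, i + half)
  lo <- pmax(1L, i - half)
  (cs0[hi + 1L] - cs0[lo]) / (hi - lo + 1L)
}

#' Simulated-sensitivity series
#'
#' Counts, per century bin, the ensemble members whose selected threshold
#' time falls in that bin: `SS(t) = n(t* = t)`.  Bins are left-closed,
#' right-open in years BP and labelled by their older edge, so a bin starting
#' at 6100 covers times `6100 >= t > 6000`.  A 3-point running average is
#' appended; at the edges it averages over the available neighbours.
#'
#' @param t_star Numeric vector of one selected threshold time per member
#'   (years BP); `NA` for members with no event.
#' @param window `c(oldest, youngest)` years BP; must be a whole number of
#'   bins (default `c(15000, 0)`).
#' @param bin_width Bin width in years (default 100).
#' @return Data frame of class `sensitivity_series` with columns
#'   `bin_start`, `count`, `smoothed`.
#' @export
sensitivity <- function(t_star, window = c(15000, 0), bin_width = 100) {
  window <- sort(as.numeric(window), decreasing = TRUE)
  span <- window[1] - window[2]
  if (span %% bin_width != 0) stop("bin_width must divide the window length", call. = FALSE)
  bin_start <- seq(window[1], window[2] + bin_width, by = -bin_width)
  t <- t_star[!is.na(t_star)]
  t <- t[t <= window[1] & t > window[2]]
  idx <- bin_width * ceiling(t / bin_width)
  counts <- table(factor(idx, levels = bin_start))
  out <- data.frame(bin_start = bin_start, count = as.integer(counts))
  out$smoothed <- running_mean(out$count, 3L)
  class(out) <- c("sensitivity_series", "data.frame")
  out
}

#' Write a sensitivity series to CSV
#'
#' Columns `bin_start_yrBP,count,smoothed`.
#'
#' @param ss A `sensitivity_series` from [sensitivity()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(ss, path) {
  out <- data.frame(bin_start_yrBP = ss$bin_start, count = ss$count, smoothed = ss$smoothed)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
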