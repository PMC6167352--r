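#' Convert a CO2 concentration to radiative forcing
#'
#' Radiative forcing relative to the preindustrial atmosphere, using the
#' standard logarithmic approximation \eqn{F = 5.35 \ln(\mathrm{CO_2}/278)}
#' W m\eqn{^{-2}}, with 278 ppm as the preindustrial concentration.
#'
#' @param co2 Numeric vector of CO2 concentrations in ppm; all values must be
#'   strictly positive.
#' @return Numeric vector of radiative forcing in W m\eqn{^{-2}}; 0 at
#'   278 ppm.
#' @examples
#' co2_to_forcing(278)        # 0
#' co2_to_forcing(c(190, 556))
#' @export
co2_to_forcing <- function(co2) {
  if (!is.numeric(co2) || anyNA(co2)) {
    stop("`co2` must be numeric with no missing values", call. = FALSE)
  }
  if (any(co2 <= 0)) {
    stop("CO2 concentrations must be strictly positive", call. = FALSE)
  }
  5.35 * log(co2 / 278)
}

#' Construct a forcing series
#'
#' A `forcing_series` holds the two external drivers of the vegetation model
#' on a shared, regularly spaced time axis in years before present (BP),
#' ordered from oldest to youngest (strictly decreasing BP).
#'
#' @param time Integer-stepped years BP, strictly decreasing.
#' @param P Climatic precession (dimensionless, eccentricity-modulated
#'   \eqn{\epsilon \sin \varpi}) at each time.
#' @param F_wm2 Radiative forcing in W m\eqn{^{-2}} relative to preindustrial
#'   at each time.
#' @return A data frame of class `forcing_series` with columns `time`, `P`,
#'   `F` and a `timestep` attribute (years).
#' @export
forcing_series <- function(time, P, F_wm2) {
  if (length(time) < 2L) stop("a forcing series needs at least two points", call. = FALSE)
  if (length(P) != length(time) || length(F_wm2) != length(time)) {
    stop("`P` and `F_wm2` must match `time` in length", call. = FALSE)
  }
  if (anyNA(time) || anyNA(P) || anyNA(F_wm2)) {
    stop("forcing series must not contain missing values", call. = FALSE)
  }
  dtv <- diff(time)
  if (any(dtv >= 0)) stop("`time` must be strictly decreasing (oldest to youngest years BP)", call. = FALSE)
  step <- unique(dtv)
  if (length(step) != 1L) stop("`time` must be regularly spaced", call. = FALSE)
  out <- data.frame(time = as.numeric(time), P = as.numeric(P), F = as.numeric(F_wm2))
  attr(out, "timestep") <- as.numeric(-step)
  class(out) <- c("forcing_series", "data.frame")
  out
}

#' @export
print.forcing_series <- function(x, ...) {
  cat(sprintf("<forcing_series> %d points, %s-%s yr BP, timestep %g yr\n",
              nrow(x), format(x$time[1], big.mark = ","),
              format(x$time[nrow(x)], big.mark = ","), attr(x, "timestep")))
  cat(sprintf("  P in [%.4g, %.4g]; F in [%.4g, %.4g] W m-2\n",
              min(x$P), max(x$P), min(x$F), max(x$F)))
  invisible(x)
}

# Read a two-column driver table (data frame or CSV path) and return it in
# years BP.  The time unit is taken from the header (`time_ka`, `time_yrBP`
# or `time_yr`) unless `time_unit` is given explicitly; it is never guessed
# from the magnitude of the values.
read_driver_table <- function(x, time_unit = NULL, what = "driver") {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x) || ncol(x) < 2L) {
    stop(sprintf("%s table must be a two-column data frame or CSV path", what), call. = FALSE)
  }
  tname <- names(x)[1L]
  if (is.null(time_unit)) {
    time_unit <- switch(tname,
      time_ka = "ka", time_yrBP = "yrBP", time_yr = "yrBP",
      stop(sprintf(
        "cannot infer time unit of %s table from column name '%s'; pass time_unit = \"ka\" or \"yrBP\"",
        what, tname), call. = FALSE))
  }
  time_unit <- match.arg(time_unit, c("ka", "yrBP"))
  t <- as.numeric(x[[1L]])
  v <- as.numeric(x[[2L]])
  if (anyNA(t) || anyNA(v)) stop(sprintf("%s table contains missing values", what), call. = FALSE)
  if (nrow(x) < 2L) stop(sprintf("%s table needs at least two rows", what), call. = FALSE)
  if (time_unit == "ka") t <- t * 1000
  if (any(diff(t) == 0) || (is.unsorted(t) && is.unsorted(rev(t)))) {
    stop(sprintf("%s table times must be strictly monotone", what), call. = FALSE)
  }
  data.frame(time = t, value = v)
}

#' Load the two drivers onto a common annual grid
#'
#' Reads a precession table and a CO2 table (each two columns: time and
#' value), linearly interpolates both onto a shared regular grid spanning
#' their temporal overlap, and converts CO2 to radiative forcing via
#' [co2_to_forcing()].  No extrapolation is performed: the output grid is
#' clipped to the overlap of the two inputs.
#'
#' @param precession Data frame or CSV path with columns `time_ka` (or
#'   `time_yrBP`) and `precession`.
#' @param co2 Data frame or CSV path with columns `time_ka` (or `time_yrBP`)
#'   and `co2_ppm`.
#' @param timestep Output grid spacing in years (default 1, the model
#'   timestep).
#' @param time_unit Optional explicit time unit (`"ka"` or `"yrBP"`) applied
#'   to both tables, overriding header-based detection.
#' @return A [forcing_series()].
#' @export
load_forcing <- function(precession, co2, timestep = 1, time_unit = NULL) {
  pr <- read_driver_table(precession, time_unit, "precession")
  cc <- read_driver_table(co2, time_unit, "co2")
  if (any(cc$value <= 0)) stop("CO2 concentrations must be strictly positive", call. = FALSE)
  oldest <- min(max(pr$time), max(cc$time))
  youngest <- max(min(pr$time), min(cc$time))
  if (oldest <= youngest) stop("precession and co2 tables do not overlap in time", call. = FALSE)
  grid <- seq(oldest, youngest, by = -timestep)
  P <- stats::approx(pr$time, pr$value, xout = grid)$y
  co2_i <- stats::approx(cc$time, cc$value, xout = grid)$y
  forcing_series(grid, P, co2_to_forcing(co2_i))
}

#' Restrict a forcing series to a time window
#'
#' @param forcing A [forcing_series()].
#' @param window Numeric `c(oldest, youngest)` in years BP.
#' @return The forcing series clipped to `window` (inclusive).
#' @export
clip_forcing <- function(forcing, window) {
  stopifnot(inherits(forcing, "forcing_series"), length(window) == 2L)
  window <- sort(as.numeric(window), decreasing = TRUE)
  keep <- forcing$time <= window[1] & forcing$time >= window[2]
  if (sum(keep) < 2L) stop("window does not cover at least two forcing points", call. = FALSE)
  forcing_series(forcing$time[keep], forcing$P[keep], forcing$F[keep])
}

#' Write a forcing series to CSV
#'
#' Columns `time_yrBP,P,F_Wm2`.
#'
#' @param forcing A [forcing_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_forcing_csv <- function(forcing, path) {
  stopifnot(inherits(forcing, "forcing_series"))
  out <- data.frame(time_yrBP = forcing$time, P = forcing$P, F_Wm2 = forcing$F)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
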