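#' Model parameters
#'
#' The seven tunable scalars of the idealised vegetation-rainfall model.
#' Rainfall is the dimensionless quantity
#' \deqn{R = a + bP + cF + dv + N,}
#' where `P` is climatic precession, `F` the CO2 radiative forcing
#' (W m\eqn{^{-2}}), `v` the vegetation cover in \eqn{[-1, 1]} (green
#' shrubland at +1, yellow desert at -1) and `N` a red-noise soil-moisture
#' term.  Vegetation relaxes towards `tanh(R)` on the timescale `tau_v`;
#' the noise is an AR(1) process with timescale `tau_N` and amplitude
#' parameter `sigma`.
#'
#' @param a Background-rainfall offset (dimensionless).
#' @param b Precession coefficient (dimensionless); negative values make
#'   precession minima (Northern-Hemisphere summer insolation maxima) wet.
#' @param c Radiative-forcing coefficient (per W m\eqn{^{-2}}).
#' @param d Vegetation-rainfall feedback strength (dimensionless).
#' @param tau_v Vegetation timescale in years (> 0).
#' @param tau_N Soil-moisture (noise) timescale in years (> 0).
#' @param sigma Noise scaling (dimensionless, >= 0).
#' @return A named list of class `model_params`.
#' @export
model_params <- function(a, b, c, d, tau_v, tau_N, sigma) {
  p <- list(a = a, b = b, c = c, d = d, tau_v = tau_v, tau_N = tau_N, sigma = sigma)
  bad <- !vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
  if (any(bad)) stop("all parameters must be finite scalars: ",
                     paste(names(p)[bad], collapse = ", "), call. = FALSE)
  if (tau_v <= 0 || tau_N <= 0) stop("tau_v and tau_N must be positive", call. = FALSE)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> ", paste(sprintf("%s=%.4g", names(x), unlist(x)), collapse = ", "), "\n")
  invisible(x)
}

#' Dimensionless rainfall
#'
#' Evaluates `R = a + b P + c F + d v + N`.
#'
#' @param params A [model_params()].
#' @param P,F_wm2 Precession and radiative forcing values.
#' @param v Vegetation cover.
#' @param N Red-noise state.
#' @return Rainfall `R` (dimensionless), vectorised over the inputs.
#' @seealso [background_rainfall()] for the external part `a + bP + cF` alone.
#' @export
rainfall <- function(params, P, F_wm2, v, N) {
  background_rainfall(params, P, F_wm2) + params$d * v + N
}

#' Background (external) rainfall
#'
#' The vegetation- and noise-independent part of the rainfall,
#' \eqn{r(t) = a + b P(t) + c F(t)}.  Its sign determines on which side of
#' `v = 0` the minimum of the equilibrium potential lies, so its zero
#' crossings define the threshold times of the model.
#'
#' @param params A [model_params()].
#' @param P,F_wm2 Precession and radiative forcing; either scalars, vectors,
#'   or omitted when `P` is a [forcing_series()].
#' @return Numeric vector of background rainfall.
#' @export
background_rainfall <- function(params, P, F_wm2 = NULL) {
  if (inherits(P, "forcing_series")) {
    F_wm2 <- P$F
    P <- P$P
  }
  params$a + params$b * P + params$c * F_wm2
}

#' One forward-Euler step of the coupled system
#'
#' Advances vegetation and noise by one timestep `dt`:
#' \deqn{v_{k+1} = v_k + (dt/\tau_v)\,[\tanh(a + bP_k + cF_k + dv_k + N_k) - v_k]}
#' \deqn{N_{k+1} = N_k - N_k\,dt/\tau_N + \sqrt{dt}\,\sigma W_k/\tau_N}
#' where `W_k` is a unit-normal draw supplied by the caller.
#'
#' @param v,N Current vegetation and noise state.
#' @param P,F_wm2 Forcing values at the current step.
#' @param params A [model_params()].
#' @param dt Timestep in years; must not exceed `min(tau_v, tau_N)`.
#' @param W Unit-normal noise draw (default 0).
#' @return List with elements `v` and `N` for the next step.
#' @export
step_model <- function(v, N, P, F_wm2, params, dt = 1, W = 0) {
  if (dt > min(params$tau_v, params$tau_N)) {
    stop("dt must not exceed min(tau_v, tau_N) for a stable explicit step", call. = FALSE)
  }
  R <- rainfall(params, P, F_wm2, v, N)
  list(v = v + dt / params$tau_v * (tanh(R) - v),
       N = N - N * dt / params$tau_N + sqrt(dt) * params$sigma * W / params$tau_N)
}

#' Simulate a vegetation trajectory
#'
#' Integrates the stochastic vegetation-rainfall model forward in calendar
#' time over a forcing series, using an explicit scheme with the forcing's
#' own timestep.  The run is deterministic given `(params, forcing, seed)`.
#'
#' A spin-up of `spinup` years is integrated first with the forcing held at
#' its oldest value and is discarded; it removes the transient from the
#' arbitrary initial condition.  By default the initial vegetation state is
#' the noiseless equilibrium (minimum-potential state) under the oldest
#' forcing value, obtained by root-finding, and `N0 = 0`.
#'
#' @param params A [model_params()].
#' @param forcing A [forcing_series()].
#' @param seed Integer RNG seed for the noise stream.
#' @param v0,N0 Initial states; `v0 = NULL` (default) uses the noiseless
#'   equilibrium at the first forcing value.
#' @param spinup Spin-up length in years (default 1000), discarded.
#' @param engine `"cpp"` (default, compiled) or `"r"` (reference R loop);
#'   both consume the identical noise stream and produce identical output.
#' @param store_rainfall Also store the deterministic rainfall component
#'   `R_det = a + bP + cF + d v` (noise term excluded) as a column.
#' @return A data frame of class `trajectory` with columns `time`, `v`, `N`
#'   (and optionally `R_det`) and attributes `params` and `timestep`.
#' @export
simulate_trajectory <- function(params, forcing, seed = 1L, v0 = NULL, N0 = 0,
                                spinup = 1000, engine = c("cpp", "r"),
                                store_rainfall = FALSE) {
  stopifnot(inherits(params, "model_params"), inherits(forcing, "forcing_series"))
  engine <- match.arg(engine)
  dt <- attr(forcing, "timestep")
  if (dt > min(params$tau_v, params$tau_N)) {
    stop("forcing timestep exceeds min(tau_v, tau_N); explicit stepping unstable", call. = FALSE)
  }
  n <- nrow(forcing)
  if (n < 2L) stop("forcing window is empty", call. = FALSE)
  n_spin <- as.integer(round(spinup / dt))
  if (params$d > 0 && is.null(v0)) {
    r0 <- background_rainfall(params, forcing$P[1], forcing$F[1])
    v0 <- min_potential_state(r0, params$d)
  } else if (is.null(v0)) {
    v0 <- 0
  }
  set.seed(as.integer(seed))
  W <- stats::rnorm(n_spin + n - 1L)

  if (engine == "cpp") {
    res <- .sim_core_cpp(forcing$P, forcing$F, params$a, params$b, params$c,
                         params$d, params$tau_v, params$tau_N, params$sigma,
                         dt, v0, N0, W, n_spin)
  } else {
    res <- sim_core_r(forcing$P, forcing$F, params, dt, v0, N0, W, n_spin)
  }
  out <- data.frame(time = forcing$time, v = res$v, N = res$N)
  if (store_rainfall) {
    out$R_det <- background_rainfall(params, forcing) + params$d * res$v
  }
  attr(out, "params") <- params
  attr(out, "timestep") <- dt
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("trajectory", "data.frame")
  out
}

# Pure-R reference integrator; mirrors the compiled core step for step.
sim_core_r <- function(P, F_wm2, params, dt, v0, N0, W, n_spin) {
  n <- length(P)
  v <- numeric(n); N <- numeric(n)
  vk <- v0; Nk <- N0
  rv <- dt / params$tau_v
  rN <- dt / params$tau_N
  sN <- sqrt(dt) * params$sigma / params$tau_N
  w <- 1L
  if (n_spin > 0L) {
    for (k in seq_len(n_spin)) {
      R <- params$a + params$b * P[1] + params$c * F_wm2[1] + params$d * vk + Nk
      v_next <- vk + rv * (tanh(R) - vk)
      Nk <- Nk - Nk * rN + sN * W[w]; w <- w + 1L
      vk <- v_next
    }
  }
  v[1] <- vk; N[1] <- Nk
  for (k in seq_len(n - 1L)) {
    R <- params$a + params$b * P[k] + params$c * F_wm2[k] + params$d * vk + Nk
    v_next <- vk + rv * (tanh(R) - vk)
    Nk <- Nk - Nk * rN + sN * W[w]; w <- w + 1L
    vk <- v_next
    v[k + 1L] <- vk; N[k + 1L] <- Nk
  }
  list(v = v, N = N)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d points, %s-%s yr BP; v in [%.3f, %.3f]\n",
              nrow(x), format(x$time[1], big.mark = ","),
              format(x$time[nrow(x)], big.mark = ","), min(x$v), max(x$v)))
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Columns `time_yrBP,v,N`; `thin` keeps every `thin`-th step to make
#' 230-kyr annual runs manageable on disk.
#'
#' @param traj A `trajectory` from [simulate_trajectory()].
#' @param path Output file path.
#' @param thin Keep every `thin`-th point (default 1 = all).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, thin = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- seq(1L, nrow(traj), by = as.integer(thin))
  out <- data.frame(time_yrBP = traj$time[idx], v = traj$v[idx], N = traj$N[idx])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
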