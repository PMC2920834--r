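# Overdamped Langevin generator (Euler-Maruyama) for the ion-in-channel model.

#' Generator configuration
#'
#' Parameters of the overdamped Langevin integrator. Defaults give fast basin
#' hopping at desk scale: diffusion constants are not meant to reproduce real
#' ion/side-chain kinetics (kinetics are not an analysis target), only the
#' stationary distribution, which depends on the potential and temperature
#' alone.
#'
#' The chi1 dihedral is not coupled to the potential; it relaxes as an
#' Ornstein-Uhlenbeck fluctuation about `chi1_mean` with stationary standard
#' deviation `chi1_sigma` and correlation time `chi1_tau`.
#'
#' @param temperature temperature in K.
#' @param D_z,D_xy diffusion coefficients along the channel axis and in the
#'   lateral plane (A^2/ps).
#' @param D_chi rotamer diffusion coefficient (deg^2/ps).
#' @param dt time step (ps).
#' @param steps number of integration steps.
#' @param stride output every `stride` steps (frame count is
#'   `floor(steps/stride) + 1`, including the initial state).
#' @param seed integer seed; fully determines the trajectory.
#' @param z0,chi0,x0,y0 initial state (A, degrees).
#' @param chi1_mean,chi1_sigma,chi1_tau chi1 OU parameters (degrees, ps).
#' @param chi1_0 initial chi1 (degrees).
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(temperature = 300, D_z = 0.1, D_xy = 0.1,
                             D_chi = 25, dt = 0.01, steps = 5e6, stride = 100,
                             seed = 1, z0 = -4.0, chi0 = 0, x0 = 0, y0 = 0,
                             chi1_mean = -68, chi1_sigma = 5, chi1_tau = 10,
                             chi1_0 = -68) {
  stopifnot(temperature >= 0, D_z > 0, D_xy > 0, D_chi > 0, dt > 0,
            steps >= 1, stride >= 1, chi1_sigma >= 0, chi1_tau > 0)
  structure(list(temperature = temperature, D_z = D_z, D_xy = D_xy,
                 D_chi = D_chi, dt = dt, steps = as.double(steps),
                 stride = as.integer(stride), seed = as.double(seed),
                 z0 = z0, chi0 = chi0, x0 = x0, y0 = y0,
                 chi1_mean = chi1_mean, chi1_sigma = chi1_sigma,
                 chi1_tau = chi1_tau, chi1_0 = chi1_0),
            class = "generator_config")
}

# drift sanity check: the deterministic displacement per step must stay well
# below the narrowest well (invariant: < 0.2 * smallest well width)
.check_drift <- function(pot, cfg) {
  zg <- seq(pot$wall$onset_lo, pot$wall$onset_hi, by = 0.05)
  chig <- seq(0, 355, by = 5)
  g <- cpp_potential_grad(unclass(pot), rep(zg, length(chig)),
                          rep(chig, each = length(zg)),
                          numeric(length(zg) * length(chig)),
                          numeric(length(zg) * length(chig)))
  kT <- kBT(cfg$temperature)
  if (cfg$temperature == 0) kT <- kBT(300) # T -> 0 limit: mobility kept finite
  drift_z <- cfg$D_z / kT * max(abs(g[, 1])) * cfg$dt
  min_width <- min(pot$z_gaussians$sigma[pot$z_gaussians$amp < 0])
  if (drift_z > 0.2 * min_width)
    stop("time step too large: max drift per step ",
         format(drift_z, digits = 3), " A exceeds 0.2 * smallest well width (",
         format(0.2 * min_width, digits = 3), " A); reduce dt")
  invisible(TRUE)
}

#' Simulate an unbiased Langevin trajectory
#'
#' Integrates the overdamped Langevin equation
#' `q <- q - (D_q/kBT) dU/dq dt + sqrt(2 D_q dt) N(0,1)` for each coordinate.
#' chi2 is wrapped periodically to `[0, 360)`, z is reflected at the walls,
#' and chi1 follows its Ornstein-Uhlenbeck process. The output is bit-stable
#' given the seed.
#'
#' At `temperature = 0` the noise term vanishes and the update reduces to
#' gradient descent (mobility is evaluated at 300 K to keep it finite), which
#' is useful for checking descent into stationary points.
#'
#' @param pot a `channel_potential`.
#' @param cfg a `generator_config`.
#' @return a `cv_trajectory`: data frame with columns `time_ps`, `x`, `y`,
#'   `z`, `chi1_deg` (in (-180, 180]) and `chi2_deg` (in \[0, 360)), with the
#'   generator seed and config attached as attributes.
#' @export
simulate_trajectory <- function(pot, cfg = generator_config()) {
  stopifnot(inherits(pot, "channel_potential"),
            inherits(cfg, "generator_config"))
  .check_drift(pot, cfg)
  res <- if (cfg$temperature == 0) {
    .simulate_t0(pot, cfg)
  } else {
    cpp_simulate(unclass(pot), unclass(cfg))
  }
  fr <- as.data.frame(res$frames)
  new_cv_trajectory(fr, seed = cfg$seed, config = cfg)
}

# T = 0 limit: deterministic gradient descent with the 300 K mobility
.simulate_t0 <- function(pot, cfg) {
  kT <- kBT(300)
  n <- floor(cfg$steps / cfg$stride) + 1
  out <- matrix(0, n, 6,
                dimnames = list(NULL, c("time_ps", "x", "y", "z",
                                        "chi1_deg", "chi2_deg")))
  z <- cfg$z0; chi <- cfg$chi0 %% 360; x <- cfg$x0; y <- cfg$y0
  out[1, ] <- c(0, x, y, z, cfg$chi1_0, chi)
  fr <- 1
  for (step in seq_len(cfg$steps)) {
    g <- cpp_potential_grad(unclass(pot), z, chi, x, y)
    z <- min(max(z - cfg$D_z / kT * g[1, 1] * cfg$dt, pot$z_min), pot$z_max)
    chi <- (chi - cfg$D_chi / kT * g[1, 2] * cfg$dt) %% 360
    x <- x - cfg$D_xy / kT * g[1, 3] * cfg$dt
    y <- y - cfg$D_xy / kT * g[1, 4] * cfg$dt
    if (step %% cfg$stride == 0) {
      fr <- fr + 1
      out[fr, ] <- c(step * cfg$dt, x, y, z, cfg$chi1_mean, chi)
    }
  }
  list(frames = out)
}

#' @export
#' @method simulate channel_potential
simulate.channel_potential <- function(object, nsim = 1, seed = NULL, ...,
                                       cfg = generator_config()) {
  if (!is.null(seed)) cfg$seed <- seed
  if (nsim == 1) return(simulate_trajectory(object, cfg))
  lapply(seq_len(nsim), function(i) {
    ci <- cfg
    ci$seed <- cfg$seed + i - 1
    simulate_trajectory(object, ci)
  })
}

new_cv_trajectory <- function(df, seed = NA, config = NULL, meta = list()) {
  stopifnot(is.data.frame(df))
  structure(df, seed = seed, config = config, meta = meta,
            class = c("cv_trajectory", "data.frame"))
}

#' @export
print.cv_trajectory <- function(x, ...) {
  cat(sprintf("CV trajectory: %d frames, %.1f ps, seed %s\n",
              nrow(x), max(x$time_ps), format(attr(x, "seed"))))
  cat(sprintf("  z range [%.2f, %.2f] A; chi2 circular mean %.1f deg\n",
              min(x$z), max(x$z), circular_mean(x$chi2_deg)))
  invisible(x)
}

#' @export
plot.cv_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time_ps, x$z, type = "l", xlab = "time (ps)",
                 ylab = "z (A)", col = "steelblue", ...)
  graphics::plot(x$time_ps, x$chi2_deg, type = "l", xlab = "time (ps)",
                 ylab = expression(chi[2] * " (deg)"), col = "grey40", ...)
  invisible(x)
}
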