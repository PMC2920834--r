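# Anchor placement for contact analysis.  Anchors are fixed 3D points
# standing in for residue interaction partners; the site-c anchors are placed
# by solving an inverse problem: given a target contact frequency within the
# cutoff, find the radial distance from the channel axis at which the
# stationary site-c ion distribution yields that frequency.

# stationary z-density of the ion restricted to a z interval, including the
# rotamer partition factor (lateral modes separate exactly)
.site_z_density <- function(pot, z_lo, z_hi, temperature = 300, dz = 0.01) {
  z <- seq(z_lo, z_hi, by = dz)
  chi <- seq(0, 359, by = 1)
  kT <- kBT(temperature)
  u <- cpp_potential(unclass(pot), rep(z, length(chi)),
                     rep(chi, each = length(z)),
                     numeric(length(z) * length(chi)),
                     numeric(length(z) * length(chi)))
  m <- matrix(u, length(z), length(chi))
  w <- rowSums(exp(-(m - min(m)) / kT))
  list(z = z, density = w / (sum(w) * dz), dz = dz)
}

# P(|ion - anchor| <= cutoff) under (z-density) x (isotropic lateral Gaussian);
# the lateral radial miss distance follows a scaled noncentral chi-square
.contact_probability <- function(zdens, anchor, cutoff, sigma_xy) {
  d_lat2 <- anchor[1]^2 + anchor[2]^2
  dz2 <- (zdens$z - anchor[3])^2
  inside <- dz2 < cutoff^2
  p_lat <- numeric(length(zdens$z))
  rho2 <- pmax(cutoff^2 - dz2[inside], 0)
  p_lat[inside] <- pchisq(rho2 / sigma_xy^2, df = 2,
                          ncp = d_lat2 / sigma_xy^2)
  sum(p_lat * zdens$density) * zdens$dz
}

#' Solve the anchor distance for a target contact frequency
#'
#' Finds the radial distance `d` from the channel axis (anchor at
#' `(d, 0, anchor_z)`) such that the probability of the ion lying within
#' `cutoff` of the anchor equals `target_freq` under the stationary site-c
#' distribution (Boltzmann in z restricted to the site, including the rotamer
#' partition factor, times the lateral Gaussian of width
#' `sqrt(kBT / k_xy)`). The probability is computed by numerical quadrature
#' (noncentral chi-square lateral law integrated over the z density) and is
#' monotone decreasing in `d`.
#'
#' @param target_freq target contact frequency as a fraction in (0, 1].
#' @param cutoff contact cutoff radius (Angstrom).
#' @param pot a `channel_potential`.
#' @param temperature temperature in K.
#' @param anchor_z z position of the anchor (Angstrom).
#' @param site_range z interval of the conditioning site (defaults to the
#'   site-c interval `[z_min, -12]`).
#' @return distance in Angstrom. If the target exceeds the attainable maximum
#'   (the value at `d = 0`; the Gaussian tails make exactly 1 unattainable),
#'   an error reports the attainable interval.
#' @export
solve_anchor_distance <- function(target_freq, cutoff = 2.5,
                                  pot = build_default_potential(),
                                  temperature = 300, anchor_z = -15,
                                  site_range = c(pot$z_min, pot$switch$zT)) {
  stopifnot(target_freq > 0, target_freq <= 1, cutoff > 0)
  sigma_xy <- sqrt(kBT(temperature) / pot$k_xy)
  zdens <- .site_z_density(pot, site_range[1], site_range[2], temperature)
  pfun <- function(d)
    .contact_probability(zdens, c(d, 0, anchor_z), cutoff, sigma_xy)
  p0 <- pfun(0)
  if (target_freq > p0)
    stop(sprintf(
      "target frequency %.4f unattainable; attainable interval is (0, %.6f]",
      target_freq, p0))
  if (target_freq == p0) return(0)
  d_hi <- cutoff + 10 * sigma_xy
  while (pfun(d_hi) > target_freq) d_hi <- d_hi * 2
  uniroot(function(d) pfun(d) - target_freq, c(0, d_hi),
          tol = 1e-8)$root
}

#' Predicted contact probability of an anchor under the site-c law
#'
#' Quadrature prediction used both to place anchors and as the reference the
#' Monte-Carlo (trajectory) contact frequencies converge to.
#'
#' @param anchor length-3 anchor position (Angstrom).
#' @inheritParams solve_anchor_distance
#' @return probability in \[0, 1\].
#' @export
predict_contact_probability <- function(anchor, cutoff = 2.5,
                                        pot = build_default_potential(),
                                        temperature = 300,
                                        site_range = c(pot$z_min,
                                                       pot$switch$zT)) {
  sigma_xy <- sqrt(kBT(temperature) / pot$k_xy)
  zdens <- .site_z_density(pot, site_range[1], site_range[2], temperature)
  .contact_probability(zdens, anchor, cutoff, sigma_xy)
}

#' Default anchor set
#'
#' Places the five residue anchors: Asp3.32 at `(0.5, 0, -5)` (site a) and
#' Asp2.50 at `(0.5, 0, -15)` (site c; essentially certain contact at the
#' 2.5 Angstrom cutoff under the default lateral distribution), and Ser7.46,
#' Asn7.45, Ser3.39 at radial distances from `(0, 0, -15)` solved so their
#' predicted site-c contact frequencies are 41%, 18% and 10% respectively.
#'
#' @param pot a `channel_potential`.
#' @param cfg a `generator_config` (provides the temperature).
#' @param cutoff contact cutoff radius (Angstrom).
#' @return an object of class `anchor_set`: list with `points` (5 x 3 matrix),
#'   `cutoff`, and `predicted` (quadrature-predicted site-c frequencies).
#' @export
default_anchor_set <- function(pot = build_default_potential(),
                               cfg = generator_config(), cutoff = 2.5) {
  targets <- c(Ser7.46 = 0.41, Asn7.45 = 0.18, Ser3.39 = 0.10)
  azimuth <- c(Ser7.46 = 90, Asn7.45 = 210, Ser3.39 = 330) * pi / 180
  zc <- -15
  d <- vapply(targets, solve_anchor_distance, 0, cutoff = cutoff, pot = pot,
              temperature = cfg$temperature, anchor_z = zc)
  pts <- rbind(
    Asp3.32 = c(0.5, 0, -5),
    Asp2.50 = c(0.5, 0, zc),
    Ser7.46 = c(d[1] * cos(azimuth[1]), d[1] * sin(azimuth[1]), zc),
    Asn7.45 = c(d[2] * cos(azimuth[2]), d[2] * sin(azimuth[2]), zc),
    Ser3.39 = c(d[3] * cos(azimuth[3]), d[3] * sin(azimuth[3]), zc))
  colnames(pts) <- c("x", "y", "z")
  pred <- c(Asp2.50 = predict_contact_probability(pts["Asp2.50", ], cutoff,
                                                  pot, cfg$temperature),
            targets)
  structure(list(points = pts, cutoff = cutoff, predicted = pred),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat("Anchor set (cutoff", x$cutoff, "A):\n")
  print(round(x$points, 3))
  cat("predicted site-c contact frequencies:\n")
  print(round(x$predicted, 4))
  invisible(x)
}
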