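# Channel potential construction.
#
# The model energy is
#   U(z, chi, x, y) = V_z(z) + (1 - s(z)) V_ab(chi) + s(z) V_c(chi)
#                     + 1/2 k_xy (x^2 + y^2) + wall(z)
# with the logistic switch s(z) = 1 / (1 + exp((z - z_T)/lambda)), so s -> 1
# deep in the channel (z << z_T, site c regime) and s -> 0 above the switch
# (a/b regime).  V_z is a sum of Gaussian wells/bumps on z, V_ab and V_c are
# 360-degree-periodic sums of wrapped Gaussian wells on the rotamer
# coordinate.  Free parameters are solved numerically at build time so the
# stationary points of the surface hit the construction targets; an
# independent dense-grid scan re-verifies them.

# ---- low-level R-side evaluators (used by the construction solver only; all
# ---- runtime evaluation goes through the compiled code) ----

.gauss_sum <- function(x, center, sigma, amp) {
  v <- numeric(length(x))
  for (i in seq_along(center)) {
    u <- (x - center[i]) / sigma[i]
    v <- v + amp[i] * exp(-0.5 * u * u)
  }
  v
}

.wall_term <- function(z, onset_lo, onset_hi, kappa) {
  lo <- pmax(0, onset_lo - z)
  hi <- pmax(0, z - onset_hi)
  kappa * (lo^4 + hi^4)
}

.chi_curve_value <- function(chi, curve) {
  v <- rep(curve$cshift, length(chi))
  for (i in seq_along(curve$center)) {
    d0 <- (chi - curve$center[i]) %% 360
    d0[d0 > 180] <- d0[d0 > 180] - 360
    for (k in -1:1) {
      d <- d0 + 360 * k
      v <- v + curve$amp[i] * exp(-0.5 * (d / curve$sigma[i])^2)
    }
  }
  v
}

.switch_s <- function(z, zT, lambda) 1 / (1 + exp((z - zT) / lambda))

# solve the two well depths of a periodic rotamer curve so that the secondary
# minimum sits `offset` above the primary one and the (direct) saddle sits
# `barrier` above the primary minimum
.solve_chi_curve <- function(primary, secondary, sigma, offset, barrier) {
  grid <- seq(0, 359.75, by = 0.25)
  near <- function(chi, center, width) {
    d <- (chi - center) %% 360
    d[d > 180] <- d[d > 180] - 360
    abs(d) <= width
  }
  lo_w <- near(grid, primary, 40)
  hi_w <- near(grid, secondary, 40)
  # direct path between the two minima (both in [0, 180] by construction)
  path <- grid >= min(primary, secondary) & grid <= max(primary, secondary)
  resid <- function(w) {
    curve <- list(center = c(primary, secondary), sigma = c(sigma, sigma),
                  amp = -abs(w), cshift = 0)
    v <- .chi_curve_value(grid, curve)
    m_lo <- min(v[lo_w]); m_hi <- min(v[hi_w]); sad <- max(v[path])
    c((m_hi - m_lo) - offset, (sad - m_lo) - barrier)
  }
  sol <- pracma::fsolve(resid, c(barrier, barrier - offset))
  w <- abs(sol$x)
  curve <- list(center = c(primary, secondary), sigma = c(sigma, sigma),
                amp = -w, cshift = 0)
  curve$cshift <- -min(.chi_curve_value(grid, curve)[lo_w])
  curve
}

# effective 1D profile min_chi U(z, chi, 0, 0) given z-Gaussian amplitudes
.effective_profile <- function(z, amps, spec, vab, vc) {
  vzr <- .gauss_sum(z, spec$z_center, spec$z_sigma, amps) +
    .wall_term(z, spec$wall_onset[1], spec$wall_onset[2], spec$wall_kappa)
  s <- .switch_s(z, spec$switch_z, spec$switch_lambda)
  m <- outer(1 - s, vab) + outer(s, vc)
  mmin <- m[cbind(seq_along(z), max.col(-m, ties.method = "first"))]
  vzr + mmin
}

# fixed-rotamer ridge U(z, chi0, 0, 0): what a path crossing the switch on one
# rotamer branch actually pays (a connected path cannot jump between branches
# at the crossing without paying the high mixture saddle)
.branch_ridge <- function(z, chi0, amps, spec, vab_fun, vc_fun) {
  vzr <- .gauss_sum(z, spec$z_center, spec$z_sigma, amps) +
    .wall_term(z, spec$wall_onset[1], spec$wall_onset[2], spec$wall_kappa)
  s <- .switch_s(z, spec$switch_z, spec$switch_lambda)
  vzr + (1 - s) * vab_fun(chi0) + s * vc_fun(chi0)
}

#' Construct the channel potential
#'
#' Builds the 2D-plus-lateral model potential of an ion in a channel coupled
#' to a periodic rotamer coordinate. Three binding sites sit on the channel
#' axis (defaults: a at -5.0, b at -7.5, c at -15.0 Angstrom) and the relative
#' stability of the two rotamer states (0 and 100 degrees) toggles at the
#' switch position (default -12.0 Angstrom). Gaussian well/bump amplitudes are
#' solved numerically so that the stationary points of the constructed surface
#' match the requested targets; the result is re-verified by an independent
#' dense-grid scan and construction aborts if any stationary value is off by
#' more than 0.1 kcal/mol (0.2 Angstrom / 2 degrees for positions).
#'
#' Energetic targets (kcal/mol): sites a and b at equal depth (0), site c
#' `site_c_depth` below them; an a-b saddle at `barrier_ab`; a b-c crossing
#' saddle at `barrier_bc` above b, realized as the minimax level of the
#' cheapest connected 2D path between the basins (a path cannot jump between
#' rotamer branches at the switch); a rotamer barrier of `rotamer_barrier_ab` from the 0
#' degree state in the a/b regime and `rotamer_barrier_c` from the 100 degree
#' state in the c regime, with the disfavored rotamer state offset by
#' `rotamer_offset_ab` / `rotamer_offset_c`.
#'
#' @param site_z named vector of site centers on z (Angstrom), names a, b, c.
#' @param switch_z rotamer switch position z_T (Angstrom).
#' @param switch_lambda switch width lambda (Angstrom).
#' @param chi_lo,chi_hi rotamer minima (degrees); chi periodic on 360.
#' @param chi_sigma width of the rotamer Gaussian wells (degrees).
#' @param rotamer_barrier_ab,rotamer_barrier_c rotamer barriers from the
#'   favored state in each regime (kcal/mol).
#' @param rotamer_offset_ab,rotamer_offset_c energy of the disfavored rotamer
#'   state above the favored one, per regime (kcal/mol).
#' @param barrier_ab a-b saddle height above the b minimum (kcal/mol).
#' @param barrier_bc b-c crossing saddle height above the b minimum, measured
#'   as the 2D minimax-path level (kcal/mol).
#' @param site_c_depth depth of site c below sites a/b (kcal/mol).
#' @param well_sigma named widths of the three z wells (Angstrom).
#' @param saddle_sigma named widths of the two z bump Gaussians (Angstrom).
#' @param well_depth_b depth scale of the b well (kcal/mol); fixes the overall
#'   basin-to-plateau scale, the remaining amplitudes are solved.
#' @param k_xy lateral harmonic stiffness (kcal/mol/A^2).
#' @param z_min,z_max reflecting wall positions (Angstrom).
#' @param wall_onset onsets (low, high) of the smooth quartic confinement.
#' @param wall_kappa quartic wall stiffness (kcal/mol/A^4).
#' @param verify run the independent stationary-point verification scan.
#' @return an object of class `channel_potential`.
#' @export
channel_potential <- function(site_z = c(a = -5.0, b = -7.5, c = -15.0),
                              switch_z = -12.0, switch_lambda = 0.5,
                              chi_lo = 0, chi_hi = 100, chi_sigma = 20,
                              rotamer_barrier_ab = 3.0, rotamer_barrier_c = 4.0,
                              rotamer_offset_ab = 2.5, rotamer_offset_c = 1.8,
                              barrier_ab = 1.0, barrier_bc = 3.0,
                              site_c_depth = 1.5,
                              well_sigma = c(a = 0.8, b = 0.8, c = 1.4),
                              saddle_sigma = c(ab = 0.4, bc = 1.0),
                              well_depth_b = 2.5,
                              k_xy = 2.4, z_min = -18, z_max = 0,
                              wall_onset = c(-16.5, -1.0), wall_kappa = 40,
                              verify = TRUE) {
  stopifnot(all(c("a", "b", "c") %in% names(site_z)),
            switch_lambda > 0, chi_sigma > 0, k_xy > 0, z_min < z_max)

  chi_ab <- .solve_chi_curve(chi_lo, chi_hi, chi_sigma,
                             rotamer_offset_ab, rotamer_barrier_ab)
  chi_c <- .solve_chi_curve(chi_hi, chi_lo, chi_sigma,
                            rotamer_offset_c, rotamer_barrier_c)

  z_sad_ab <- mean(site_z[c("a", "b")])
  spec <- list(
    z_center = c(site_z[["a"]], site_z[["b"]], site_z[["c"]], z_sad_ab, switch_z),
    z_sigma = c(well_sigma[["a"]], well_sigma[["b"]], well_sigma[["c"]],
                saddle_sigma[["ab"]], saddle_sigma[["bc"]]),
    wall_onset = wall_onset, wall_kappa = wall_kappa,
    switch_z = switch_z, switch_lambda = switch_lambda)

  chi_grid <- seq(0, 359, by = 1)
  vab_g <- .chi_curve_value(chi_grid, chi_ab)
  vc_g <- .chi_curve_value(chi_grid, chi_c)

  win <- function(center, half) seq(center - half, center + half, by = 0.005)
  zw <- list(a = win(site_z[["a"]], 0.8), b = win(site_z[["b"]], 0.8),
             c = win(site_z[["c"]], 0.8), ab = win(z_sad_ab, 0.6),
             bc = seq(site_z[["c"]], site_z[["b"]], by = 0.005))
  vab_fun <- function(chi) .chi_curve_value(chi, chi_ab)
  vc_fun <- function(chi) .chi_curve_value(chi, chi_c)

  # The b -> c minimax level is the cheaper of two connected routes:
  #  A: cross on the chi_lo branch, flip the rotamer inside site c
  #  B: flip inside a/b, cross on the chi_hi branch
  resid <- function(x) {
    amps <- c(-abs(x[1]), -well_depth_b, -abs(x[2]), x[3], x[4])
    e <- lapply(zw[c("a", "b", "c", "ab")], .effective_profile, amps = amps,
                spec = spec, vab = vab_g, vc = vc_g)
    eb <- min(e$b)
    ridge_lo <- max(.branch_ridge(zw$bc, chi_lo, amps, spec,
                                  vab_fun, vc_fun))
    ridge_hi <- max(.branch_ridge(zw$bc, chi_hi, amps, spec,
                                  vab_fun, vc_fun))
    route_a <- max(ridge_lo, min(e$c) + rotamer_barrier_c)
    route_b <- max(eb + rotamer_barrier_ab, ridge_hi)
    c(min(e$a) - eb,
      max(e$ab) - eb - barrier_ab,
      min(e$c) - eb + site_c_depth,
      min(route_a, route_b) - eb - barrier_bc)
  }
  sol <- pracma::fsolve(resid, c(well_depth_b, well_depth_b + site_c_depth,
                                 0, 2))
  if (max(abs(resid(sol$x))) > 1e-6)
    stop("potential construction solver did not converge (max residual ",
         format(max(abs(resid(sol$x)))), " kcal/mol)")
  amps <- c(-abs(sol$x[1]), -well_depth_b, -abs(sol$x[2]), sol$x[3], sol$x[4])

  # normalize so the b minimum of the effective profile sits at 0
  spec0 <- spec
  e_b <- min(.effective_profile(zw$b, amps, spec0, vab_g, vc_g))

  pot <- structure(list(
    site_z = site_z,
    z_gaussians = list(center = unname(spec$z_center),
                       sigma = unname(spec$z_sigma), amp = unname(amps)),
    z_shift = -e_b,
    wall = list(onset_lo = wall_onset[1], onset_hi = wall_onset[2],
                kappa = wall_kappa),
    switch = list(zT = switch_z, lambda = switch_lambda),
    chi_ab = chi_ab, chi_c = chi_c,
    chi_states = c(lo = chi_lo, hi = chi_hi),
    k_xy = k_xy, z_min = z_min, z_max = z_max,
    targets = list(barrier_ab = barrier_ab, barrier_bc = barrier_bc,
                   site_c_depth = site_c_depth,
                   rotamer_barrier_ab = rotamer_barrier_ab,
                   rotamer_barrier_c = rotamer_barrier_c,
                   rotamer_offset_ab = rotamer_offset_ab,
                   rotamer_offset_c = rotamer_offset_c)),
    class = "channel_potential")

  if (verify) {
    tab <- .verify_potential(pot)
    attr(pot, "stationary_table") <- tab
  }
  pot
}

#' Default channel potential
#'
#' Returns (and caches) the default potential whose stationary points encode
#' the model's reference energetics: sites a/b at 0 kcal/mol (z = -5.0/-7.5),
#' site c at -1.5 (z = -15.0), a-b saddle +1.0, b-c crossing saddle +2.75 on
#' the minimum-energy path, rotamer barriers 3.0 (a/b regime, from 0 degrees)
#' and 4.0 kcal/mol (c regime, from 100 degrees).
#'
#' @return a `channel_potential` object with its verified stationary table
#'   attached as attribute `"stationary_table"`.
#' @export
build_default_potential <- function() {
  if (is.null(.pkg_cache$default_potential))
    .pkg_cache$default_potential <- channel_potential()
  .pkg_cache$default_potential
}

.pkg_cache <- new.env(parent = emptyenv())

# independent verification: dense-grid scan of the assembled potential through
# the compiled evaluator (not the solver's R-side arithmetic)
.verify_potential <- function(pot) {
  zg <- seq(pot$z_min, pot$z_max, by = 0.005)
  chig <- seq(0, 359.5, by = 0.5)
  nz <- length(zg); nc <- length(chig)
  u <- cpp_potential(unclass(pot), rep(zg, nc), rep(chig, each = nz),
                     numeric(nz * nc), numeric(nz * nc))
  m <- matrix(u, nz, nc)
  eff <- m[cbind(seq_len(nz), max.col(-m, ties.method = "first"))]

  loc_min <- function(center, half) {
    w <- which(zg >= center - half & zg <= center + half)
    i <- w[which.min(eff[w])]
    c(z = zg[i], value = eff[i])
  }
  loc_max <- function(lo, hi) {
    w <- which(zg >= lo & zg <= hi)
    i <- w[which.max(eff[w])]
    c(z = zg[i], value = eff[i])
  }
  sz <- pot$site_z
  a <- loc_min(sz[["a"]], 0.8); b <- loc_min(sz[["b"]], 0.8)
  cc <- loc_min(sz[["c"]], 0.8)
  mid_ab <- mean(sz[c("a", "b")])
  sab <- loc_max(mid_ab - 0.6, mid_ab + 0.6)
  # the b->c crossing is a 2D feature: measure it as the minimax saddle on a
  # fine grid (independent of the route formula used by the solver)
  fg <- true_fes(pot, fes_grid_spec(z = seq(pot$z_min, pot$z_max, by = 0.05),
                                    chi = seq(0, 357.5, by = 2.5)))
  mm <- minimax_barrier(fg,
                        from = region_mask(fg, sz[["b"]] + c(-1, 1),
                                           pot$chi_states[["lo"]], 30),
                        to = region_mask(fg, sz[["c"]] + c(-1, 1),
                                         pot$chi_states[["hi"]], 30))
  sbc <- c(z = mm$saddle_z, value = mm$barrier + b[["value"]])

  # rotamer scans in the two pure regimes
  chif <- seq(0, 359.9, by = 0.1)
  scan_chi <- function(z0, primary, secondary) {
    v <- cpp_potential(unclass(pot), rep(z0, length(chif)), chif,
                       numeric(length(chif)), numeric(length(chif)))
    dmin <- function(center) {
      d <- (chif - center) %% 360; d[d > 180] <- d[d > 180] - 360
      w <- which(abs(d) <= 40)
      i <- w[which.min(v[w])]
      c(chi = chif[i], value = v[i])
    }
    p <- dmin(primary); s <- dmin(secondary)
    path <- chif >= min(primary, secondary) & chif <= max(primary, secondary)
    sad <- max(v[path])
    list(primary = p, secondary = s,
         barrier = sad - p[["value"]], offset = s[["value"]] - p[["value"]])
  }
  st <- pot$chi_states
  ab_scan <- scan_chi(sz[["b"]], st[["lo"]], st[["hi"]])
  c_scan <- scan_chi(sz[["c"]], st[["hi"]], st[["lo"]])

  tg <- pot$targets
  tab <- data.frame(
    feature = c("min_a", "min_b", "min_c", "saddle_ab", "saddle_bc",
                "rot_min_ab", "rot_alt_ab", "rot_barrier_ab", "rot_offset_ab",
                "rot_min_c", "rot_alt_c", "rot_barrier_c", "rot_offset_c"),
    z = c(a[["z"]], b[["z"]], cc[["z"]], sab[["z"]], sbc[["z"]],
          sz[["b"]], sz[["b"]], NA, NA, sz[["c"]], sz[["c"]], NA, NA),
    chi = c(NA, NA, NA, NA, NA,
            ab_scan$primary[["chi"]], ab_scan$secondary[["chi"]], NA, NA,
            c_scan$primary[["chi"]], c_scan$secondary[["chi"]], NA, NA),
    value = c(a[["value"]], b[["value"]], cc[["value"]], sab[["value"]],
              sbc[["value"]],
              ab_scan$primary[["value"]], ab_scan$secondary[["value"]],
              ab_scan$barrier, ab_scan$offset,
              c_scan$primary[["value"]] - cc[["value"]],
              c_scan$secondary[["value"]] - cc[["value"]],
              c_scan$barrier, c_scan$offset),
    target = c(0, 0, -tg$site_c_depth, tg$barrier_ab, tg$barrier_bc,
               0, tg$rotamer_offset_ab, tg$rotamer_barrier_ab,
               tg$rotamer_offset_ab,
               0, tg$rotamer_offset_c, tg$rotamer_barrier_c,
               tg$rotamer_offset_c),
    stringsAsFactors = FALSE)

  pos_target <- c(pot$site_z[["a"]], pot$site_z[["b"]], pot$site_z[["c"]],
                  mean(pot$site_z[c("a", "b")]), pot$switch$zT)
  pos_tol <- c(0.2, 0.2, 0.2, 0.3, 1.0)
  dv <- abs(tab$value - tab$target)
  if (any(dv > 0.1))
    stop("potential verification failed: stationary value for '",
         tab$feature[which.max(dv)], "' is ",
         format(tab$value[which.max(dv)], digits = 4), " (target ",
         tab$target[which.max(dv)], ")")
  dz <- abs(tab$z[1:5] - pos_target)
  if (any(dz > pos_tol))
    stop("potential verification failed: stationary position for '",
         tab$feature[which.max(dz)], "' is ", tab$z[which.max(dz)],
         " (target ", pos_target[which.max(dz)], ")")
  chi_target <- c(pot$chi_states[["lo"]], pot$chi_states[["hi"]],
                  pot$chi_states[["hi"]], pot$chi_states[["lo"]])
  dchi <- abs((tab$chi[c(6, 7, 10, 11)] - chi_target + 180) %% 360 - 180)
  if (any(dchi > 2))
    stop("potential verification failed: rotamer minimum off by ",
         format(max(dchi), digits = 3), " degrees")
  tab
}

#' Evaluate the channel potential
#'
#' @param pot a `channel_potential`.
#' @param z,chi,x,y coordinates (Angstrom / degrees); recycled to a common
#'   length. `z` must lie within the walls.
#' @return energy in kcal/mol.
#' @export
potential_energy <- function(pot, z, chi, x = 0, y = 0) {
  stopifnot(inherits(pot, "channel_potential"))
  n <- max(length(z), length(chi), length(x), length(y))
  z <- rep_len(z, n); chi <- rep_len(chi, n)
  x <- rep_len(x, n); y <- rep_len(y, n)
  if (any(z < pot$z_min | z > pot$z_max))
    stop("z outside the wall domain [", pot$z_min, ", ", pot$z_max, "]")
  cpp_potential(unclass(pot), z, chi, x, y)
}

#' Analytic gradient of the channel potential
#'
#' @inheritParams potential_energy
#' @return matrix with columns `dz`, `dchi`, `dx`, `dy` (kcal/mol per
#'   Angstrom or degree).
#' @export
potential_gradient <- function(pot, z, chi, x = 0, y = 0) {
  stopifnot(inherits(pot, "channel_potential"))
  n <- max(length(z), length(chi), length(x), length(y))
  z <- rep_len(z, n); chi <- rep_len(chi, n)
  x <- rep_len(x, n); y <- rep_len(y, n)
  if (any(z < pot$z_min | z > pot$z_max))
    stop("z outside the wall domain [", pot$z_min, ", ", pot$z_max, "]")
  g <- cpp_potential_grad(unclass(pot), z, chi, x, y)
  colnames(g) <- c("dz", "dchi", "dx", "dy")
  g
}

#' @export
print.channel_potential <- function(x, ...) {
  cat("Channel potential: 3 z-wells + switch-coupled periodic rotamer\n")
  cat(sprintf("  sites (A): a = %.2f, b = %.2f, c = %.2f; switch z_T = %.2f (lambda %.2f)\n",
              x$site_z[["a"]], x$site_z[["b"]], x$site_z[["c"]],
              x$switch$zT, x$switch$lambda))
  cat(sprintf("  rotamer states: %g / %g degrees; k_xy = %.2f kcal/mol/A^2; walls [%g, %g]\n",
              x$chi_states[["lo"]], x$chi_states[["hi"]], x$k_xy,
              x$z_min, x$z_max))
  tab <- attr(x, "stationary_table")
  if (!is.null(tab)) {
    cat("  verified stationary table (kcal/mol):\n")
    print(tab, digits = 3, row.names = FALSE)
  }
  invisible(x)
}
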