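# Well-tempered metadynamics over (z, chi2): bias deposition, free-energy
# reconstruction, replica averaging with error maps, and basin/barrier
# extraction on the reconstructed grid.

#' Well-tempered metadynamics parameters
#'
#' @param w0 initial Gaussian height (kcal/mol).
#' @param sigma_z,sigma_chi Gaussian widths along z (Angstrom) and chi
#'   (degrees; deposited Gaussians are periodic in chi).
#' @param stride deposition stride tau_G (integrator steps).
#' @param gamma bias factor gamma = (T + DeltaT)/T, > 1; heights decay as
#'   `w0 exp(-V/(kB DeltaT))` with `DeltaT = (gamma - 1) T`. As gamma grows
#'   the scheme approaches standard (constant-height) metadynamics.
#' @param temperature temperature T (K).
#' @return an object of class `wt_params`.
#' @export
wt_params <- function(w0 = 0.12, sigma_z = 0.5, sigma_chi = 10, stride = 500,
                      gamma = 10, temperature = 300) {
  stopifnot(w0 > 0, sigma_z > 0, sigma_chi > 0, stride >= 1, gamma > 1,
            temperature > 0)
  structure(list(w0 = w0, sigma_z = sigma_z, sigma_chi = sigma_chi,
                 stride = as.integer(stride), gamma = gamma,
                 temperature = temperature), class = "wt_params")
}

#' Empty bias state
#'
#' Holds the deposited Gaussians (centers, heights) and evaluates the running
#' bias anywhere via [bias_value()].
#'
#' @param params a `wt_params`.
#' @return an object of class `bias_state`.
#' @export
new_bias_state <- function(params = wt_params()) {
  structure(list(z = numeric(0), chi = numeric(0), h = numeric(0),
                 params = params), class = "bias_state")
}

#' Deposit a well-tempered Gaussian
#'
#' Adds a Gaussian at `(z, chi)` with height `w0 exp(-V(z,chi)/(kB DeltaT))`,
#' where `V` is the bias accumulated so far and `DeltaT = (gamma - 1) T`. The
#' first deposit anywhere has height exactly `w0`; heights at a revisited
#' point are non-increasing.
#'
#' @param state a `bias_state`.
#' @param z,chi deposition center (Angstrom, degrees).
#' @return the updated `bias_state`.
#' @export
deposit <- function(state, z, chi) {
  p <- state$params
  v <- bias_value(state, z, chi)
  h <- p$w0 * exp(-v / (.kB * (p$gamma - 1) * p$temperature))
  state$z <- c(state$z, z)
  state$chi <- c(state$chi, chi %% 360)
  state$h <- c(state$h, h)
  state
}

#' Evaluate the accumulated bias
#'
#' Exact sum over all deposited Gaussians with periodic chi wrapping.
#'
#' @param state a `bias_state`.
#' @param z,chi evaluation points (recycled to a common length).
#' @return bias in kcal/mol (`bias_value`), or a list with `value`, `dz`,
#'   `dchi` (`bias_gradient`).
#' @export
bias_value <- function(state, z, chi) {
  n <- max(length(z), length(chi))
  z <- rep_len(z, n); chi <- rep_len(chi, n)
  if (!length(state$z)) return(numeric(n))
  p <- state$params
  cpp_bias_value(state$z, state$chi, state$h, p$sigma_z, p$sigma_chi, z, chi)
}

#' @rdname bias_value
#' @export
bias_gradient <- function(state, z, chi) {
  n <- max(length(z), length(chi))
  z <- rep_len(z, n); chi <- rep_len(chi, n)
  p <- state$params
  if (!length(state$z))
    return(list(value = numeric(n), dz = numeric(n), dchi = numeric(n)))
  cpp_bias_value_grad(state$z, state$chi, state$h, p$sigma_z, p$sigma_chi,
                      z, chi)
}

#' @export
print.bias_state <- function(x, ...) {
  cat(sprintf("Bias state: %d Gaussians (w0 %.3g, gamma %g)", length(x$z),
              x$params$w0, x$params$gamma))
  if (length(x$h))
    cat(sprintf("; heights [%.4g, %.4g] kcal/mol", min(x$h), max(x$h)))
  cat("\n")
  invisible(x)
}

#' Free-energy-surface grid specification
#'
#' Default: 181 z nodes on \[-18, 0\] (0.1 Angstrom) by 72 chi nodes on
#' \[0, 360) (5 degrees, periodic).
#'
#' @param z,chi grid node vectors (uniform spacing; chi periodic on 360).
#' @return list with `z` and `chi` node vectors.
#' @export
fes_grid_spec <- function(z = seq(-18, 0, length.out = 181),
                          chi = seq(0, 355, by = 5)) {
  stopifnot(length(z) > 2, length(chi) > 2,
            diff(range(diff(z))) < 1e-9, diff(range(diff(chi))) < 1e-9)
  list(z = z, chi = chi)
}

new_fes_grid <- function(z, chi, f, error = NULL, n_replicas = 1L) {
  structure(list(z = z, chi = chi, F = f, error = error,
                 n_replicas = n_replicas), class = "fes_grid")
}

#' Run one well-tempered metadynamics replica
#'
#' Langevin dynamics on `U + V(s, t)` over the collective variables
#' `(z, chi2)`, depositing a periodic Gaussian every `params$stride` steps.
#' During integration the bias force is interpolated from an incrementally
#' maintained grid; deposit heights use the exact Gaussian sum. The run is
#' deterministic given the config seed. A coverage check verifies that the
#' biased walker visited both z regimes and both rotamer basins; if not, a
#' warning reports the coverage.
#'
#' @param pot a `channel_potential`.
#' @param params a `wt_params` (its temperature overrides the config's).
#' @param cfg a `generator_config`; the metadynamics default is 2e6 steps.
#' @param grid the FES grid used for the bias force interpolation.
#' @return list with `trajectory` (a `cv_trajectory`) and `bias` (a
#'   `bias_state`), plus `coverage` counts.
#' @export
run_wtmetad <- function(pot, params = wt_params(),
                        cfg = generator_config(steps = 2e6, stride = 200),
                        grid = fes_grid_spec()) {
  stopifnot(inherits(pot, "channel_potential"), inherits(params, "wt_params"),
            inherits(cfg, "generator_config"))
  cfg$temperature <- params$temperature
  .check_drift(pot, cfg)
  res <- cpp_wtmetad(unclass(pot), unclass(cfg), params$w0, params$sigma_z,
                     params$sigma_chi, params$stride, params$gamma,
                     grid$z, grid$chi)
  traj <- new_cv_trajectory(as.data.frame(res$frames), seed = cfg$seed,
                            config = cfg)
  state <- new_bias_state(params)
  state$z <- res$dep_z; state$chi <- res$dep_chi; state$h <- res$dep_h
  zT <- pot$switch$zT
  st <- pot$chi_states
  dchi_lo <- abs((traj$chi2_deg - st[["lo"]] + 180) %% 360 - 180)
  dchi_hi <- abs((traj$chi2_deg - st[["hi"]] + 180) %% 360 - 180)
  coverage <- c(z_above = sum(traj$z > zT), z_below = sum(traj$z <= zT),
                chi_lo = sum(dchi_lo <= 30), chi_hi = sum(dchi_hi <= 30),
                z_crossings = sum(diff(traj$z > zT) != 0))
  if (any(coverage[1:4] == 0))
    warning("incomplete coverage of the (z, chi) space: ",
            paste(names(coverage), coverage, sep = "=", collapse = ", "))
  list(trajectory = traj, bias = state, coverage = coverage)
}

#' Reconstruct the free-energy surface from the accumulated bias
#'
#' Well-tempered estimator from the final bias:
#' `F(s) = -(gamma/(gamma - 1)) V(s, t_end)`, evaluated on the grid by the
#' exact Gaussian sum and shifted so `min F = 0`.
#'
#' @param state a `bias_state`.
#' @param grid an FES grid spec.
#' @return an object of class `fes_grid`.
#' @export
fes_from_bias <- function(state, grid = fes_grid_spec()) {
  p <- state$params
  v <- if (length(state$z))
    cpp_bias_grid(state$z, state$chi, state$h, p$sigma_z, p$sigma_chi,
                  grid$z, grid$chi)
  else matrix(0, length(grid$z), length(grid$chi))
  f <- -(p$gamma / (p$gamma - 1)) * v
  f <- f - min(f)
  new_fes_grid(grid$z, grid$chi, f)
}

#' Exact free-energy surface of a potential on a grid
#'
#' Evaluates `min over (x, y) of U(z, chi, x, y) = U(z, chi, 0, 0)` on the
#' grid and shifts the minimum to zero — the ground truth the metadynamics
#' reconstruction is judged against.
#'
#' @param pot a `channel_potential`.
#' @param grid an FES grid spec.
#' @return an `fes_grid`.
#' @export
true_fes <- function(pot, grid = fes_grid_spec()) {
  nz <- length(grid$z); nc <- length(grid$chi)
  u <- cpp_potential(unclass(pot), rep(grid$z, nc), rep(grid$chi, each = nz),
                     numeric(nz * nc), numeric(nz * nc))
  f <- matrix(u, nz, nc)
  new_fes_grid(grid$z, grid$chi, f - min(f))
}

#' Replica mean and error map
#'
#' The free energy is defined up to a constant per replica, so replicas are
#' first aligned by subtracting each one's mean over the alignment region
#' (default: the site-b basin cells), then the per-cell mean and standard
#' deviation are computed and the mean re-shifted to `min = 0`.
#'
#' @param runs list of >= 2 `fes_grid`s on identical grids.
#' @param align_mask logical matrix selecting the alignment cells; default is
#'   the site-b basin (z in \[-8.5, -6.5\], chi within 25 degrees of 0).
#' @return an `fes_grid` with `F` the aligned mean, `error` the per-cell
#'   replica standard deviation, and `n_replicas` set.
#' @export
replica_statistics <- function(runs, align_mask = NULL) {
  stopifnot(length(runs) >= 2)
  g1 <- runs[[1]]
  for (r in runs[-1])
    if (!isTRUE(all.equal(r$z, g1$z)) || !isTRUE(all.equal(r$chi, g1$chi)))
      stop("replica grids do not match")
  if (is.null(align_mask))
    align_mask <- region_mask(g1, z_range = c(-8.5, -6.5), chi_center = 0,
                              chi_halfwidth = 25)
  stopifnot(any(align_mask))
  mats <- lapply(runs, function(r) r$F - mean(r$F[align_mask]))
  arr <- simplify2array(mats)
  fmean <- apply(arr, c(1, 2), mean)
  ferr <- apply(arr, c(1, 2), sd)
  new_fes_grid(g1$z, g1$chi, fmean - min(fmean), error = ferr,
               n_replicas = length(runs))
}

#' Logical region mask on an FES grid
#'
#' @param fes an `fes_grid`.
#' @param z_range z interval (inclusive), or `NULL` for all z.
#' @param chi_center,chi_halfwidth circular chi window (degrees), or `NULL`
#'   for all chi.
#' @return logical matrix of dim (length(z), length(chi)).
#' @export
region_mask <- function(fes, z_range = NULL, chi_center = NULL,
                        chi_halfwidth = 30) {
  zin <- if (is.null(z_range)) rep(TRUE, length(fes$z))
         else fes$z >= z_range[1] & fes$z <= z_range[2]
  cin <- if (is.null(chi_center)) rep(TRUE, length(fes$chi))
         else abs((fes$chi - chi_center + 180) %% 360 - 180) <= chi_halfwidth
  outer(zin, cin, FUN = "&")
}

#' Default basin and region masks for the three binding sites
#'
#' Basins are site windows crossed with the regime-favored rotamer window;
#' regions split the surface at the switch position.
#'
#' @param fes an `fes_grid`.
#' @param pot the `channel_potential` (site centers and switch position).
#' @return named list of logical masks: `a`, `b`, `c` (basins), `ab_region`,
#'   `c_region`.
#' @export
default_basin_masks <- function(fes, pot = build_default_potential()) {
  sz <- pot$site_z; zT <- pot$switch$zT
  st <- pot$chi_states
  list(
    a = region_mask(fes, sz[["a"]] + c(-1.2, 1.2), st[["lo"]], 30),
    b = region_mask(fes, sz[["b"]] + c(-1.2, 1.2), st[["lo"]], 30),
    c = region_mask(fes, sz[["c"]] + c(-1.5, 1.5), st[["hi"]], 30),
    ab_region = region_mask(fes, c(zT + 1e-9, max(fes$z))),
    c_region = region_mask(fes, c(min(fes$z), zT)))
}

# 1D quadratic sub-cell refinement; returns c(delta, value_correction)
.quad_refine <- function(fm, f0, fp) {
  den <- fm - 2 * f0 + fp
  if (!is.finite(den) || den <= 0) return(c(0, 0))
  delta <- 0.5 * (fm - fp) / den
  delta <- max(-0.5, min(0.5, delta))
  c(delta, -0.125 * (fm - fp)^2 / den)
}

#' Locate basin minima on an FES grid
#'
#' Grid-cell argmin per region mask, refined to sub-cell precision by
#' quadratic interpolation along each axis (chi periodic).
#'
#' @param fes an `fes_grid`.
#' @param masks named list of logical masks (see [default_basin_masks()]).
#' @return data frame with columns `region`, `z`, `chi`, `value`.
#' @export
find_basins <- function(fes, masks) {
  if (is.matrix(masks)) masks <- list(region = masks)
  stopifnot(length(masks) >= 1)
  nz <- length(fes$z); nc <- length(fes$chi)
  dz <- fes$z[2] - fes$z[1]; dc <- fes$chi[2] - fes$chi[1]
  out <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    if (!any(m)) stop("empty mask for region '", nm, "'")
    fm <- fes$F
    fm[!m] <- Inf
    i0 <- which.min(fm)
    ij <- arrayInd(i0, dim(fm))
    i <- ij[1]; j <- ij[2]
    rz <- if (i > 1 && i < nz)
      .quad_refine(fes$F[i - 1, j], fes$F[i, j], fes$F[i + 1, j])
    else c(0, 0)
    jm <- if (j == 1) nc else j - 1
    jp <- if (j == nc) 1 else j + 1
    rc <- .quad_refine(fes$F[i, jm], fes$F[i, j], fes$F[i, jp])
    data.frame(region = nm, z = fes$z[i] + rz[1] * dz,
               chi = (fes$chi[j] + rc[1] * dc) %% 360,
               value = fes$F[i, j] + rz[2] + rc[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Minimax-path barrier between two basins on an FES grid
#'
#' Exact on the grid: cells are activated in order of increasing free energy
#' on the 8-connected grid graph (chi-periodic edges) and merged with a
#' union-find structure; the level at which the two basin cells join is the
#' minimax path maximum, and the cell whose activation joins them is the
#' saddle. The barrier is measured from the `from` basin cell (so barriers
#' from the two sides differ exactly by the basin offset while the saddle
#' level is identical).
#'
#' @param fes an `fes_grid`.
#' @param from,to basin specifications: a `c(z, chi)` point (snapped to the
#'   nearest cell) or a logical mask (its argmin cell is used).
#' @param mask optional logical matrix restricting the path to a region.
#' @return list with `barrier` (kcal/mol above the `from` cell), `level`
#'   (saddle free energy), `saddle_z`, `saddle_chi`, `from_value`,
#'   `to_value`.
#' @export
minimax_barrier <- function(fes, from, to, mask = NULL) {
  nz <- length(fes$z); nc <- length(fes$chi)
  fm <- fes$F
  if (is.null(mask)) mask <- matrix(TRUE, nz, nc)
  cell_of <- function(spec) {
    if (is.matrix(spec) && is.logical(spec)) {
      f2 <- fm; f2[!(spec & mask)] <- Inf
      return(which.min(f2))
    }
    i <- which.min(abs(fes$z - spec[1]))
    j <- which.min(abs((fes$chi - spec[2] + 180) %% 360 - 180))
    (j - 1) * nz + i
  }
  a <- cell_of(from); b <- cell_of(to)
  if (a == b) stop("basins are not distinct")
  if (!mask[a] || !mask[b]) stop("basin cell outside the region mask")
  ord <- order(fm)
  ord <- ord[mask[ord]]
  parent <- seq_len(nz * nc)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  active <- logical(nz * nc)
  for (cell in ord) {
    active[cell] <- TRUE
    i <- (cell - 1) %% nz + 1
    j <- (cell - 1) %/% nz + 1
    for (di in -1:1) {
      ii <- i + di
      if (ii < 1 || ii > nz) next
      for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        jj <- j + dj
        if (jj < 1) jj <- nc else if (jj > nc) jj <- 1
        nb <- (jj - 1) * nz + ii
        if (active[nb]) {
          ra <- find(cell); rb <- find(nb)
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
    if (active[a] && active[b] && find(a) == find(b)) {
      ij <- c((cell - 1) %% nz + 1, (cell - 1) %/% nz + 1)
      return(list(barrier = fm[cell] - fm[a], level = fm[cell],
                  saddle_z = fes$z[ij[1]], saddle_chi = fes$chi[ij[2]],
                  from_value = fm[a], to_value = fm[b]))
    }
  }
  stop("disconnected sampled region: basins never join within the mask")
}

#' Rotamer-flip barrier within a z region
#'
#' Minimax barrier between the two rotamer basins of an FES restricted to a z
#' region, measured from the region's global minimum.
#'
#' @param fes an `fes_grid`.
#' @param region logical region mask (e.g. `default_basin_masks(...)$ab_region`).
#' @param chi_centers the two rotamer states (degrees).
#' @param chi_halfwidth half-width of the rotamer windows (degrees).
#' @return as [minimax_barrier()], with `barrier` measured from the region's
#'   global minimum.
#' @export
rotamer_barrier <- function(fes, region, chi_centers = c(0, 100),
                            chi_halfwidth = 30) {
  m1 <- region & region_mask(fes, NULL, chi_centers[1], chi_halfwidth)
  m2 <- region & region_mask(fes, NULL, chi_centers[2], chi_halfwidth)
  res <- minimax_barrier(fes, m1, m2, mask = region)
  gm <- min(fes$F[region])
  res$barrier <- res$level - gm
  res$from_value <- gm
  res
}

#' @export
print.fes_grid <- function(x, ...) {
  cat(sprintf("FES grid: %d x %d (z x chi), F range [0, %.2f] kcal/mol",
              length(x$z), length(x$chi), max(x$F)))
  if (!is.null(x$error))
    cat(sprintf("; %d replicas, median error %.3f kcal/mol",
                x$n_replicas, stats::median(x$error)))
  cat("\n")
  invisible(x)
}

#' @export
summary.fes_grid <- function(object, pot = build_default_potential(), ...) {
  masks <- default_basin_masks(object, pot)
  basins <- find_basins(object, masks[c("a", "b", "c")])
  bc <- minimax_barrier(object, masks$b, masks$c)
  rot_ab <- rotamer_barrier(object, masks$ab_region)
  rot_c <- rotamer_barrier(object, masks$c_region)
  out <- list(basins = basins,
              barrier_bc = bc$barrier, saddle_bc_z = bc$saddle_z,
              rotamer_barrier_ab = rot_ab$barrier,
              rotamer_barrier_c = rot_c$barrier,
              site_c_advantage = min(basins$value[basins$region %in%
                                                    c("a", "b")]) -
                basins$value[basins$region == "c"])
  if (!is.null(object$error)) {
    basin_cells <- masks$a | masks$b | masks$c
    out$basin_error_max <- max(object$error[basin_cells])
    out$basin_error_median <- stats::median(object$error[basin_cells])
  }
  class(out) <- "summary.fes_grid"
  out
}

#' @export
print.summary.fes_grid <- function(x, ...) {
  cat("FES summary\n  basins:\n")
  print(x$basins, digits = 3, row.names = FALSE)
  cat(sprintf("  b->c barrier: %.2f kcal/mol (saddle z %.2f A)\n",
              x$barrier_bc, x$saddle_bc_z))
  cat(sprintf("  rotamer barriers: a/b %.2f, c %.2f kcal/mol\n",
              x$rotamer_barrier_ab, x$rotamer_barrier_c))
  cat(sprintf("  site c below a/b by %.2f kcal/mol\n", x$site_c_advantage))
  if (!is.null(x$basin_error_max))
    cat(sprintf("  basin replica error: median %.3f, max %.3f kcal/mol\n",
                x$basin_error_median, x$basin_error_max))
  invisible(x)
}

#' @export
plot.fes_grid <- function(x, what = c("F", "error"), levels = seq(0, 8, 1),
                          ...) {
  what <- match.arg(what)
  m <- if (what == "F") x$F else x$error
  if (is.null(m)) stop("no error map on this FES grid")
  graphics::filled.contour(
    x$z, x$chi, m, levels = c(levels, max(m, max(levels) + 1)),
    color.palette = grDevices::hcl.colors,
    xlab = "z (A)", ylab = expression(chi[2] * " (deg)"),
    main = if (what == "F") "free energy (kcal/mol)" else
      "replica error (kcal/mol)", ...)
  invisible(x)
}
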