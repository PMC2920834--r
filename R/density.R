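# 3D occupancy grids and chemical-potential maps relative to bulk.

#' Density grid specification
#'
#' Regular voxel grid covering the channel (walls on z, a few lateral standard
#' deviations in x/y). Voxel centers start at the lower corner plus half a
#' voxel.
#'
#' @param voxel voxel edge length (Angstrom).
#' @param xlim,ylim,zlim grid extents (Angstrom).
#' @return a `density_grid_spec`.
#' @export
density_grid_spec <- function(voxel = 0.5, xlim = c(-1.75, 1.75),
                              ylim = c(-1.75, 1.75), zlim = c(-18, 0)) {
  stopifnot(voxel > 0)
  dims <- c(max(1, round(diff(xlim) / voxel)),
            max(1, round(diff(ylim) / voxel)),
            max(1, round(diff(zlim) / voxel)))
  structure(list(voxel = voxel, lower = c(xlim[1], ylim[1], zlim[1]),
                 dims = dims,
                 origin = c(xlim[1], ylim[1], zlim[1]) + voxel / 2),
            class = "density_grid_spec")
}

#' Accumulate ion positions into a voxel occupancy grid
#'
#' Per-voxel visit counts over all frames of all supplied trajectories
#' (single-ion model: one count per frame). Frames outside the grid go to an
#' overflow bin and are warned about; total counts plus overflow always equal
#' the number of frames.
#'
#' @param trajs a `cv_trajectory` or list of them.
#' @param spec a `density_grid_spec`.
#' @param bulk_concentration reference bulk concentration (mol/L).
#' @param temperature temperature (K) used for the kBT scale of derived maps.
#' @return an object of class `density_grid`: counts grid
#'   (`volumetric_grid`), `frames`, `overflow`, `voxel_volume`, derived
#'   `density` (ions/A^3), `bulk_density` and `temperature`.
#' @export
accumulate_density <- function(trajs, spec = density_grid_spec(),
                               bulk_concentration = 0.150,
                               temperature = 300) {
  if (is.data.frame(trajs)) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1)
  counts <- array(0, dim = spec$dims)
  overflow <- 0
  total <- 0
  for (tr in trajs) {
    total <- total + nrow(tr)
    ix <- floor((tr$x - spec$lower[1]) / spec$voxel) + 1
    iy <- floor((tr$y - spec$lower[2]) / spec$voxel) + 1
    iz <- floor((tr$z - spec$lower[3]) / spec$voxel) + 1
    ok <- ix >= 1 & ix <= spec$dims[1] & iy >= 1 & iy <= spec$dims[2] &
      iz >= 1 & iz <= spec$dims[3]
    overflow <- overflow + sum(!ok)
    lin <- (ix[ok] - 1) + spec$dims[1] * (iy[ok] - 1) +
      spec$dims[1] * spec$dims[2] * (iz[ok] - 1) + 1
    tb <- tabulate(lin, nbins = prod(spec$dims))
    counts <- counts + array(tb, dim = spec$dims)
  }
  if (overflow > 0)
    warning(overflow, " frame(s) outside the density grid counted in the ",
            "overflow bin")
  voxvol <- spec$voxel^3
  structure(list(
    counts = volumetric_grid(spec$origin, spec$voxel, counts, kind = "counts"),
    frames = total, overflow = overflow, voxel_volume = voxvol,
    density = volumetric_grid(spec$origin, spec$voxel,
                              counts / (total * voxvol), kind = "density"),
    bulk_density = bulk_density_from_concentration(bulk_concentration),
    temperature = temperature), class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf(
    "Density grid: %s voxels (%.2f A), %d frames (%d overflow), bulk %.4g ions/A^3\n",
    paste(x$counts$dims, collapse = " x "), x$counts$spacing[1], x$frames,
    x$overflow, x$bulk_density))
  invisible(x)
}

#' Bulk number density from a molar concentration
#'
#' @param concentration concentration in mol/L; must be positive.
#' @return number density in ions/Angstrom^3 (150 mM gives 9.033e-5).
#' @export
bulk_density_from_concentration <- function(concentration) {
  stopifnot(concentration > 0)
  concentration * 6.02214076e23 / 1e27
}

#' Chemical-potential map relative to bulk
#'
#' Per-voxel `mu(r) = -ln(rho(r)/rho_bulk)` in kBT units, so regions enriched
#' over bulk are negative (a voxel at `exp(4)` times bulk density maps to
#' -4 kBT). Voxels never visited are unsampled: they get `+Inf`, are excluded
#' from isosurface masks, and are never silently treated as zero.
#'
#' @param d a `density_grid` with positive bulk density.
#' @return a `volumetric_grid` of kind `"chemical_potential"` (kBT units).
#' @export
chemical_potential_map <- function(d) {
  stopifnot(inherits(d, "density_grid"), d$bulk_density > 0)
  mu <- -log(d$density$values / d$bulk_density)
  mu[d$counts$values == 0] <- Inf
  volumetric_grid(d$counts$origin, d$counts$spacing, mu,
                  kind = "chemical_potential")
}

#' Threshold a chemical-potential map
#'
#' Mask of sampled voxels with `mu <= level`, its volume, and its 6-connected
#' components.
#'
#' @param mu a `volumetric_grid` of chemical potential (kBT).
#' @param level threshold in kBT (finite).
#' @return list with `mask` (logical array), `volume` (Angstrom^3),
#'   `n_components` and `component_sizes` (voxel counts, decreasing).
#' @export
threshold_region <- function(mu, level) {
  stopifnot(inherits(mu, "volumetric_grid"), is.finite(level))
  mask <- is.finite(mu$values) & mu$values <= level
  voxvol <- prod(mu$spacing)
  comp <- .connected_components(mask)
  sizes <- if (comp$n > 0) sort(tabulate(comp$labels[mask], comp$n),
                                decreasing = TRUE) else integer(0)
  list(mask = mask, volume = sum(mask) * voxvol, n_components = comp$n,
       component_sizes = sizes)
}

# 6-connected components of a logical 3D array (BFS)
.connected_components <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, dim = d)
  n <- 0L
  idx <- which(mask)
  if (!length(idx)) return(list(labels = labels, n = 0L))
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  key <- function(m) (m[, 1] - 1) + d[1] * (m[, 2] - 1) +
    d[1] * d[2] * (m[, 3] - 1) + 1
  for (start in idx) {
    if (labels[start] != 0L) next
    n <- n + 1L
    queue <- start
    labels[start] <- n
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ci <- arrayInd(cur, d)
      for (k in seq_len(6)) {
        nb <- ci + offs[k, , drop = FALSE]
        if (any(nb < 1) || any(nb > d)) next
        j <- key(nb)
        if (mask[j] && labels[j] == 0L) {
          labels[j] <- n
          queue <- c(queue, j)
        }
      }
    }
  }
  list(labels = labels, n = n)
}
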