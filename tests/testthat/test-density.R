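frames_at <- function(pts) {
  data.frame(time_ps = seq_len(nrow(pts)), x = pts[, 1], y = pts[, 2],
             z = pts[, 3], chi1_deg = -68, chi2_deg = 0)
}

test_that("a single frame lands in exactly its voxel", {
  spec <- density_grid_spec(voxel = 0.5)
  tr <- frames_at(cbind(0, 0.5, -15.25)) # a voxel center
  d <- accumulate_density(tr, spec)
  expect_equal(sum(d$counts$values), 1)
  idx <- which(d$counts$values == 1, arr.ind = TRUE)
  ctr <- d$counts$origin + (idx - 1) * 0.5
  expect_equal(as.numeric(ctr), c(0, 0.5, -15.25))
})

test_that("density accumulation is additive over replicas and conserves counts", {
  set.seed(14)
  pts1 <- cbind(rnorm(300, 0, 0.6), rnorm(300, 0, 0.6), runif(300, -17, -1))
  pts2 <- cbind(rnorm(200, 0, 0.6), rnorm(200, 0, 0.6), runif(200, -17, -1))
  spec <- density_grid_spec()
  d1 <- suppressWarnings(accumulate_density(frames_at(pts1), spec))
  d2 <- suppressWarnings(accumulate_density(frames_at(pts2), spec))
  d12 <- suppressWarnings(accumulate_density(list(frames_at(pts1),
                                                  frames_at(pts2)), spec))
  expect_equal(d12$counts$values, d1$counts$values + d2$counts$values)
  expect_equal(sum(d12$counts$values) + d12$overflow, 500)
  # out-of-grid frames go to the overflow bin with a warning
  far <- frames_at(cbind(10, 10, -5))
  expect_warning(dfar <- accumulate_density(far, spec), "overflow")
  expect_equal(dfar$overflow, 1)
  expect_equal(sum(dfar$counts$values), 0)
})

test_that("bulk density conversion matches hand unit arithmetic", {
  expect_equal(bulk_density_from_concentration(0.150), 9.033e-5,
               tolerance = 1e-4)
  expect_equal(bulk_density_from_concentration(1), 6.022e-4,
               tolerance = 1e-4)
  expect_error(bulk_density_from_concentration(0))
})

make_density <- function(counts, frames, voxel = 1,
                         bulk = bulk_density_from_concentration(0.150)) {
  org <- c(0, 0, 0) + voxel / 2
  structure(list(
    counts = volumetric_grid(org, voxel, counts, kind = "counts"),
    frames = frames, overflow = 0, voxel_volume = voxel^3,
    density = volumetric_grid(org, voxel, counts / (frames * voxel^3),
                              kind = "density"),
    bulk_density = bulk, temperature = 300), class = "density_grid")
}

test_that("chemical potential map algebra matches its definition", {
  bulk <- bulk_density_from_concentration(0.150)
  frames <- 1e6
  c_bulk <- bulk * frames          # voxel volume 1: rho = counts/frames
  counts <- array(c_bulk, c(3, 3, 3))
  d <- make_density(counts, frames)
  mu <- chemical_potential_map(d)
  expect_equal(as.numeric(mu$values), rep(0, 27), tolerance = 1e-12)

  counts[2, 2, 2] <- exp(4) * c_bulk
  counts[1, 1, 1] <- 0
  d <- make_density(counts, frames)
  mu <- chemical_potential_map(d)
  expect_equal(mu$values[2, 2, 2], -4, tolerance = 1e-12)
  expect_identical(mu$values[1, 1, 1], Inf) # unsampled, never silently 0
})

test_that("thresholding masks sampled voxels only and reports components", {
  bulk <- bulk_density_from_concentration(0.150)
  counts <- array(bulk * 1000, c(5, 5, 5))
  counts[1, 1, 1] <- 0                       # unsampled
  counts[2, 2, 2] <- exp(5) * bulk * 1000    # mu = -5
  counts[4, 4, 4] <- exp(5) * bulk * 1000
  d <- make_density(counts, 1000)
  mu <- chemical_potential_map(d)
  thr <- threshold_region(mu, -4)
  expect_equal(sum(thr$mask), 2)
  expect_false(thr$mask[1, 1, 1])
  expect_equal(thr$n_components, 2)
  expect_equal(thr$volume, 2)
  # level below the minimum: empty
  expect_equal(sum(threshold_region(mu, min(mu$values[is.finite(mu$values)]) -
                                      1)$mask), 0)
  # uniform at bulk: empty at -4
  du <- make_density(array(bulk * 1000, c(3, 3, 3)), 1000)
  expect_equal(sum(threshold_region(chemical_potential_map(du), -4)$mask), 0)
})

test_that("the mu map is translation-covariant with the grid", {
  set.seed(15)
  pts <- cbind(rnorm(400, 0, 0.5), rnorm(400, 0, 0.5), rnorm(400, -15, 0.6))
  spec1 <- density_grid_spec(voxel = 0.5, zlim = c(-18, 0))
  spec2 <- density_grid_spec(voxel = 0.5, zlim = c(-19, -1))
  d1 <- suppressWarnings(accumulate_density(frames_at(pts), spec1))
  shifted <- pts; shifted[, 3] <- shifted[, 3] - 1
  d2 <- suppressWarnings(accumulate_density(frames_at(shifted), spec2))
  m1 <- threshold_region(chemical_potential_map(d1), -4)$mask
  m2 <- threshold_region(chemical_potential_map(d2), -4)$mask
  expect_identical(m1, m2)
})

test_that("sampled density is Boltzmann-consistent with the true potential", {
  # cross-basin mu differences from an exact Boltzmann ensemble match the
  # potential difference in kBT (quadrature over each voxel as oracle), and
  # the -4 kBT isosurface contains the three site centers but not the saddle
  pot <- default_pot()
  d <- suppressWarnings(accumulate_density(boltzmann_sample(5e5)))
  mu <- chemical_potential_map(d)
  kT <- kBT(300)
  voxel_mu_pred <- function(zlo) {
    zg <- seq(zlo, zlo + 0.5, by = 0.005)
    chig <- seq(0, 359, by = 1)
    u <- potential_energy(pot, rep(zg, length(chig)),
                          rep(chig, each = length(zg)))
    -log(mean(rowSums(exp(-matrix(u, length(zg), length(chig)) / kT))))
  }
  zc <- d$counts$origin[3] + (seq_len(d$counts$dims[3]) - 1) * 0.5
  ixy <- ceiling(d$counts$dims[1] / 2)
  vox <- function(zt) which(abs(zc - zt) < 0.01)
  obs <- mu$values[ixy, ixy, vox(-15.25)] - mu$values[ixy, ixy, vox(-5.25)]
  pred <- voxel_mu_pred(-15.5) - voxel_mu_pred(-5.5)
  expect_lt(abs(obs - pred), 0.3)

  thr <- threshold_region(mu, -4)
  expect_true(thr$mask[ixy, ixy, vox(-5.25)])
  expect_true(thr$mask[ixy, ixy, vox(-7.25)])
  expect_true(thr$mask[ixy, ixy, vox(-15.25)])
  expect_false(thr$mask[ixy, ixy, vox(-12.25)]) # b->c saddle voxel
})

test_that("a site-c-restricted Langevin run is Boltzmann within the basin", {
  # within-basin mixing is fast, so the finite run itself must match the
  # Boltzmann law voxel-wise inside site c
  pot <- default_pot()
  tr <- unbiased_run(7)
  d <- suppressWarnings(accumulate_density(tr))
  mu <- chemical_potential_map(d)
  kT <- kBT(300)
  voxel_mu_pred <- function(zlo) {
    zg <- seq(zlo, zlo + 0.5, by = 0.005)
    chig <- seq(0, 359, by = 1)
    u <- potential_energy(pot, rep(zg, length(chig)),
                          rep(chig, each = length(zg)))
    -log(mean(rowSums(exp(-matrix(u, length(zg), length(chig)) / kT))))
  }
  zc <- d$counts$origin[3] + (seq_len(d$counts$dims[3]) - 1) * 0.5
  ixy <- ceiling(d$counts$dims[1] / 2)
  vox <- function(zt) which(abs(zc - zt) < 0.01)
  obs <- mu$values[ixy, ixy, vox(-14.25)] - mu$values[ixy, ixy, vox(-15.25)]
  pred <- voxel_mu_pred(-14.5) - voxel_mu_pred(-15.5)
  expect_lt(abs(obs - pred), 0.3)
  # lateral: harmonic confinement, one voxel off-axis at the c center
  obs_lat <- mu$values[ixy + 1, ixy, vox(-15.25)] -
    mu$values[ixy, ixy, vox(-15.25)]
  dx2 <- 0.5^2 # mean x^2 shift between adjacent 0.5 A voxel centers
  expect_lt(abs(obs_lat - pot$k_xy / 2 * dx2 / kT), 0.35)
})
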