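test_that("well-tempered deposit heights follow the closed form", {
  p <- wt_params(w0 = 0.12, gamma = 10, temperature = 300)
  st <- new_bias_state(p)
  st <- deposit(st, -7.5, 0)
  expect_equal(st$h[1], 0.12)   # first deposit anywhere: exactly w0
  st <- deposit(st, -7.5, 0)
  kbdT <- kBT(300) / 300 * (10 - 1) * 300
  expect_equal(st$h[2], 0.12 * exp(-0.12 / kbdT), tolerance = 1e-12)
  st <- deposit(st, -7.5, 0)
  expect_true(all(diff(st$h) < 0)) # heights non-increasing at a fixed point

  # gamma -> infinity: standard metadynamics, constant heights
  st2 <- new_bias_state(wt_params(gamma = 1e9))
  st2 <- deposit(st2, -7.5, 0); st2 <- deposit(st2, -7.5, 0)
  expect_equal(st2$h[2], st2$h[1], tolerance = 1e-9)
})

test_that("bias evaluation matches the closed form and is chi-periodic", {
  p <- wt_params(w0 = 0.5, sigma_z = 0.7, sigma_chi = 15)
  st <- new_bias_state(p)
  expect_equal(bias_value(st, -9, 50), 0)
  st <- deposit(st, -9, 50)
  expect_equal(bias_value(st, -9, 50), 0.5, tolerance = 1e-12)
  v <- bias_value(st, -9.7, 65)
  expect_equal(v, 0.5 * exp(-0.5 * (0.7 / 0.7)^2) * exp(-0.5 * (15 / 15)^2),
               tolerance = 1e-9)
  expect_equal(bias_value(st, -9.7, 65 + 360), v, tolerance = 1e-12)
  # wrap-around distance: chi = 50 - 340 = -290 == +70 on the circle
  expect_equal(bias_value(st, -9, 340),
               bias_value(st, -9, 120), tolerance = 1e-12)
})

test_that("bias gradient matches central differences on random states", {
  set.seed(17)
  p <- wt_params()
  st <- new_bias_state(p)
  for (k in 1:30) st <- deposit(st, runif(1, -16, -2), runif(1, 0, 360))
  z <- runif(20, -16, -2); chi <- runif(20, 0, 360)
  g <- bias_gradient(st, z, chi)
  h <- 1e-5
  gz <- (bias_value(st, z + h, chi) - bias_value(st, z - h, chi)) / (2 * h)
  gc <- (bias_value(st, z, chi + h) - bias_value(st, z, chi - h)) / (2 * h)
  expect_lt(max(abs(g$dz - gz) / pmax(abs(gz), 1e-3)), 1e-5)
  expect_lt(max(abs(g$dchi - gc) / pmax(abs(gc), 1e-3)), 1e-5)
})

test_that("fes_from_bias inverts and rescales the accumulated bias", {
  p <- wt_params(gamma = 10)
  st <- new_bias_state(p)
  grid <- fes_grid_spec()
  f0 <- fes_from_bias(st, grid)
  expect_true(all(f0$F == 0))    # empty bias: flat surface

  st <- deposit(st, -9, 100)
  f <- fes_from_bias(st, grid)
  # single Gaussian: F = (gamma/(gamma-1)) * (max V - V), a flipped Gaussian
  v <- matrix(bias_value(st, rep(grid$z, length(grid$chi)),
                         rep(grid$chi, each = length(grid$z))),
              length(grid$z), length(grid$chi))
  expect_equal(f$F, 10 / 9 * (max(v) - v), tolerance = 1e-9)
})

test_that("replica statistics align offsets and report zero error when exact", {
  pot <- default_pot()
  f1 <- true_fes(pot)
  f2 <- f1; f2$F <- f2$F + 3.7     # same surface, shifted reference
  st <- replica_statistics(list(f1, f2))
  expect_equal(max(abs(st$error)), 0, tolerance = 1e-10)
  expect_equal(st$F, f1$F - min(f1$F), tolerance = 1e-9)
  expect_equal(st$n_replicas, 2)
  f3 <- f1; f3$z <- f3$z + 0.1
  expect_error(replica_statistics(list(f1, f3)), "grids do not match")
})

test_that("find_basins refines minima to sub-cell precision", {
  grid <- fes_grid_spec()
  zm <- -9.03; cm <- 117   # off-node minimum
  f <- outer((grid$z - zm)^2, 0 * grid$chi + 1) +
    outer(0 * grid$z + 1, 0.002 * ang_diff(grid$chi, cm)^2)
  fes <- structure(list(z = grid$z, chi = grid$chi, F = f - min(f),
                        error = NULL), class = "fes_grid")
  b <- find_basins(fes, list(all = matrix(TRUE, length(grid$z),
                                          length(grid$chi))))
  expect_equal(b$z, zm, tolerance = 0.02)
  expect_lt(ang_diff(b$chi, cm), 1)
  expect_error(find_basins(fes, list(bad = matrix(FALSE, length(grid$z),
                                                  length(grid$chi)))),
               "empty mask")
})

test_that("minimax barrier is exact against an exhaustive path-closure oracle", {
  set.seed(19)
  for (k in 1:5) {
    f <- matrix(round(runif(64), 3), 8, 8)
    fes <- structure(list(z = 1:8, chi = seq(0, 315, by = 45), F = f,
                          error = NULL), class = "fes_grid")
    d <- minimax_closure(f)
    i1 <- which.min(f)
    i2 <- order(f)[2]
    ij1 <- arrayInd(i1, dim(f)); ij2 <- arrayInd(i2, dim(f))
    r <- minimax_barrier(fes, c(ij1[1], fes$chi[ij1[2]]),
                         c(ij2[1], fes$chi[ij2[2]]))
    expect_equal(r$level, d[i1, i2], tolerance = 1e-12)
    expect_equal(r$barrier, d[i1, i2] - f[i1], tolerance = 1e-12)
  }
})

test_that("minimax barrier handles flat grids, symmetry and disconnection", {
  fes <- structure(list(z = 1:6, chi = seq(0, 300, by = 60),
                        F = matrix(1, 6, 6), error = NULL),
                   class = "fes_grid")
  r <- minimax_barrier(fes, c(1, 0), c(6, 300))
  expect_equal(r$barrier, 0)

  # two wells with a known saddle level; symmetric saddle, offset barriers
  pot <- default_pot()
  ft <- true_fes(pot)
  masks <- default_basin_masks(ft, pot)
  fwd <- minimax_barrier(ft, masks$b, masks$c)
  bwd <- minimax_barrier(ft, masks$c, masks$b)
  expect_equal(fwd$level, bwd$level, tolerance = 1e-12)
  expect_equal(bwd$barrier - fwd$barrier, fwd$from_value - bwd$from_value,
               tolerance = 1e-12)

  # disconnected mask
  m <- matrix(TRUE, 6, 6); m[3:4, ] <- FALSE
  fes$F[2, 2] <- 0; fes$F[6, 6] <- 0.5
  expect_error(minimax_barrier(fes, c(1, 0), c(6, 300), mask = m),
               "disconnected")
})

test_that("metadynamics runs are seed-deterministic and cover both regimes", {
  pot <- default_pot()
  cfg <- generator_config(steps = 1e6, stride = 500, seed = 2)
  r1 <- run_wtmetad(pot, wt_params(), cfg)
  r2 <- run_wtmetad(pot, wt_params(), cfg)
  expect_identical(r1$bias$h, r2$bias$h)
  expect_identical(as.data.frame(r1$trajectory), as.data.frame(r2$trajectory))
  expect_gte(r1$coverage[["z_crossings"]], 3)
  expect_true(all(r1$coverage[c("z_above", "z_below", "chi_lo", "chi_hi")] > 0))
  # heights at revisited points never increase (well-tempered decay)
  dep <- r1$bias
  for (i in seq(50, length(dep$z), by = 50)) {
    close_prev <- which(abs(dep$z[1:(i - 1)] - dep$z[i]) < 0.1 &
                          ang_diff(dep$chi[1:(i - 1)], dep$chi[i]) < 2)
    if (length(close_prev))
      expect_true(all(dep$h[i] <= dep$h[close_prev] * 1.05))
  }
})

test_that("a single replica already recovers the c-region rotamer barrier", {
  pot <- default_pot()
  r <- run_wtmetad(pot, wt_params(),
                   generator_config(steps = 2e6, stride = 200, seed = 101))
  f <- fes_from_bias(r$bias)
  rb <- rotamer_barrier(f, default_basin_masks(f, pot)$c_region)
  expect_lt(abs(rb$barrier - 4.0), 0.8)
})
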