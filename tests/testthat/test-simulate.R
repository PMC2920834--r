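test_that("identical configs and seeds give bit-identical trajectories", {
  pot <- default_pot()
  cfg <- generator_config(steps = 5e4, seed = 42)
  t1 <- simulate_trajectory(pot, cfg)
  t2 <- simulate_trajectory(pot, cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- simulate_trajectory(pot, generator_config(steps = 5e4, seed = 43))
  expect_false(identical(t1$z, t3$z))
})

test_that("trajectory respects frame count, walls and angle ranges", {
  pot <- default_pot()
  cfg <- generator_config(steps = 12345, stride = 10, seed = 1)
  tr <- simulate_trajectory(pot, cfg)
  expect_equal(nrow(tr), floor(12345 / 10) + 1)
  expect_true(all(tr$z >= pot$z_min & tr$z <= pot$z_max))
  expect_true(all(tr$chi2_deg >= 0 & tr$chi2_deg < 360))
  expect_true(all(tr$chi1_deg > -180 & tr$chi1_deg <= 180))
  expect_equal(tr$time_ps[2] - tr$time_ps[1], cfg$dt * cfg$stride)
})

test_that("the T -> 0 limit descends the potential into a stationary point", {
  pot <- default_pot()
  tr <- simulate_trajectory(pot, generator_config(temperature = 0,
                                                  steps = 3e4, stride = 100,
                                                  seed = 1, z0 = -6.5))
  u <- potential_energy(pot, tr$z, tr$chi2_deg, tr$x, tr$y)
  expect_true(all(diff(u) <= 1e-9))
  g <- potential_gradient(pot, tail(tr$z, 1), tail(tr$chi2_deg, 1),
                          tail(tr$x, 1), tail(tr$y, 1))
  expect_lt(max(abs(g)), 1e-3)
  expect_equal(tail(tr$z, 1), -7.5, tolerance = 0.05)
})

test_that("single-basin sampling is Boltzmann-distributed in z", {
  # restrict to the site-c basin of a long run and compare the z histogram to
  # direct quadrature of exp(-U/kBT) (two-sample chi-square on 0.25 A bins)
  pot <- default_pot()
  tr <- short_run()
  zc <- tr$z[tr$z <= -13 & tr$z >= -16.6]
  breaks <- seq(-16.6, -13, by = 0.3)
  obs <- hist(zc, breaks = breaks, plot = FALSE)$counts
  zg <- seq(-16.6, -13, by = 0.002)
  chig <- seq(0, 359, by = 1)
  u <- potential_energy(pot, rep(zg, length(chig)),
                        rep(chig, each = length(zg)))
  w <- rowSums(exp(-(matrix(u, length(zg), length(chig)) - min(u)) / kBT(300)))
  pred <- vapply(seq_len(length(breaks) - 1), function(i)
    sum(w[zg >= breaks[i] & zg < breaks[i + 1]]), 0)
  pred <- pred / sum(pred)
  keep <- obs > 100
  # log-density differences equal -dU/kBT within statistical tolerance
  emp <- obs / sum(obs)
  expect_lt(max(abs(log(emp[keep] / pred[keep]))), 0.35)
})

test_that("unbiased frames below the switch have chi2 locked near 100 deg", {
  tr <- short_run()
  sel <- tr$z < -12.5
  expect_gt(sum(sel), 1000)
  expect_lt(ang_diff(circular_mean(tr$chi2_deg[sel]), 100), 12)
})

test_that("chi1 relaxes as an OU process about its mean", {
  tr <- short_run()
  expect_equal(mean(tr$chi1_deg), -68, tolerance = 0.5)
  expect_equal(sd(tr$chi1_deg), 5, tolerance = 0.5)
})

test_that("oversized time steps are rejected", {
  pot <- default_pot()
  expect_error(simulate_trajectory(pot, generator_config(dt = 2, steps = 100)),
               "dt")
})

test_that("simulate() S3 method wraps the generator", {
  pot <- default_pot()
  tr <- simulate(pot, seed = 9, cfg = generator_config(steps = 1e3))
  expect_s3_class(tr, "cv_trajectory")
  expect_equal(attr(tr, "seed"), 9)
  trs <- simulate(pot, nsim = 2, seed = 9, cfg = generator_config(steps = 1e3))
  expect_length(trs, 2)
  expect_identical(as.data.frame(trs[[1]]), as.data.frame(tr))
})
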