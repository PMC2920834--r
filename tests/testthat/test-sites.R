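test_that("site assignment matches the printed site positions", {
  expect_equal(assign_site(-5.0), "a")
  expect_equal(assign_site(-7.5), "b")
  expect_equal(assign_site(-15.0), "c")
  expect_equal(assign_site(-6.25), "b")   # boundary: half-open toward +z
  expect_equal(assign_site(-12.0), "c")
  expect_equal(assign_site(0.5), "none")
})

test_that("site assignment partitions the axis", {
  z <- seq(-18, 2, by = 0.01)
  lab <- assign_site(z)
  expect_true(all(lab %in% c("a", "b", "c", "none")))
  # labels change only at boundaries, and in the none/a/b/c order
  changes <- which(diff(match(lab, c("c", "b", "a", "none"))) != 0)
  expect_equal(length(changes), 3)
  expect_equal(sort(z[changes + 1] - 0.01 / 2),
               sort(c(-12, -6.25, 0)), tolerance = 0.02)
  expect_error(assign_site(NaN), "is.finite")
})

test_that("dwell episodes merge runs and count transitions", {
  ep <- dwell_episodes(rep("a", 10), 1:10)
  expect_equal(nrow(ep), 1)
  expect_equal(attr(ep, "transitions"), 0)
  expect_equal(ep$site, "a")

  ep <- dwell_episodes(c("a", "a", "c", "c"), c(0, 1, 2, 3))
  expect_equal(nrow(ep), 2)
  expect_equal(attr(ep, "transitions"), 1)
  expect_equal(ep$site, c("a", "c"))
  expect_true(all(ep$duration > 0))

  # constructed b<->c switching with known flip times
  times <- seq(0, 99)
  lab <- rep(c("b", "c", "b", "c"), each = 25)
  ep <- dwell_episodes(lab, times)
  expect_equal(ep$start, c(0, 25, 50, 75))
  expect_equal(ep$end, c(24, 49, 74, 99))
  expect_error(dwell_episodes(lab, times[-1]), "different lengths")
})

test_that("short episodes are absorbed into flanking episodes", {
  lab <- c(rep("a", 20), "b", rep("a", 20), rep("c", 30))
  times <- seq_along(lab)
  ep0 <- dwell_episodes(lab, times)
  expect_equal(nrow(ep0), 4)
  ep <- dwell_episodes(lab, times, min_duration = 5)
  expect_equal(ep$site, c("a", "c"))
  expect_equal(nrow(ep), 2)
  # episodes stay non-overlapping and time-ordered
  expect_true(all(diff(ep$start) > 0))
  expect_true(all(ep$end >= ep$start))
})

test_that("circular statistics wrap correctly", {
  expect_equal(circular_mean(c(350, 10)), 0, tolerance = 1e-10)
  expect_equal(circular_mean(rep(100, 5)), 100)
  expect_equal(circular_sd(rep(42, 10)), 0)
  expect_gt(circular_sd(c(0, 90, 180, 270)), 100)
})

test_that("rotamer state by site computes circular summaries", {
  df <- data.frame(z = c(-5, -5, -7.5, -15, -15),
                   chi2_deg = c(350, 10, 0, 90, 110))
  rs <- rotamer_state_by_site(df)
  expect_equal(rs$chi2_mean[rs$site == "a"], 0, tolerance = 1e-9)
  expect_equal(rs$chi2_sd[rs$site == "b"], 0)
  expect_equal(rs$chi2_mean[rs$site == "c"], 100, tolerance = 1e-9)
  df2 <- data.frame(z = c(-5, -5), chi2_deg = c(0, 0))
  expect_warning(rotamer_state_by_site(df2), "no frames in site")
})

test_that("site-c frames occupy the 100-degree rotamer basin more than a/b", {
  tr <- short_run()
  lab <- assign_site(tr$z)
  in100 <- ang_diff(tr$chi2_deg, 100) <= 50
  frac_c <- mean(in100[lab == "c"])
  frac_ab <- mean(in100[lab %in% c("a", "b")])
  expect_gt(frac_c, frac_ab)
  expect_gt(frac_c, 0.8)
  expect_lt(frac_ab, 0.2)
})
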