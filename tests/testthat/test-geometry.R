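test_that("dihedral reproduces planar reference configurations", {
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               0, tolerance = 1e-12)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)),
               180, tolerance = 1e-12)
})

test_that("dihedral recovers construction angles and rigid-motion invariance", {
  set.seed(3)
  p1 <- c(0, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1, 0, 0)
  for (k in 1:200) {
    theta <- runif(1, -179.9, 180)
    # rotate the trans reference end point about the p2->p3 axis by theta
    th <- theta * pi / 180
    # start from the cis point (1, 1, 0); rotation about x by -theta gives the
    # IUPAC-signed dihedral theta
    p4 <- c(1, cos(th), -sin(th))
    expect_equal(dihedral_angle(p1, p2, p3, p4), theta, tolerance = 1e-9)
    r <- random_rotation(); t0 <- rnorm(3, 0, 5)
    rot <- function(p) as.numeric(r %*% p + t0)
    expect_lt(ang_diff(dihedral_angle(rot(p1), rot(p2), rot(p3), rot(p4)),
                       theta), 1e-9)
  }
})

test_that("degenerate dihedral geometry is rejected", {
  expect_error(dihedral_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "coincide")
  expect_error(dihedral_angle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0), c(2, 0, 1)),
               "collinear")
})

test_that("place_trp_atoms round-trips chi1/chi2 through the dihedral operator", {
  a <- place_trp_atoms(0, 0)
  expect_equal(dihedral_angle(a["CA", ], a["CB", ], a["CG", ], a["CD1", ]), 0,
               tolerance = 1e-9)
  a <- place_trp_atoms(-68, 100)
  expect_equal(dihedral_angle(a["N", ], a["CA", ], a["CB", ], a["CG", ]), -68,
               tolerance = 1e-6)
  expect_equal(dihedral_angle(a["CA", ], a["CB", ], a["CG", ], a["CD1", ]),
               100, tolerance = 1e-6)
  # fixed internal geometry
  expect_equal(unname(sqrt(sum((a["CG", ] - a["CB", ])^2))), 1.5,
               tolerance = 1e-9)
  set.seed(21)
  worst <- 0
  for (k in 1:1000) {
    c1 <- runif(1, -180, 180); c2 <- runif(1, 0, 360)
    at <- place_trp_atoms(c1, c2)
    e1 <- ang_diff(dihedral_angle(at["N", ], at["CA", ], at["CB", ],
                                  at["CG", ]), c1)
    e2 <- ang_diff(dihedral_angle(at["CA", ], at["CB", ], at["CG", ],
                                  at["CD1", ]), c2)
    worst <- max(worst, e1, e2)
  }
  expect_lt(worst, 1e-6)
})

test_that("kabsch superposition is exact on rigid copies", {
  set.seed(5)
  x <- matrix(rnorm(30), 10, 3)
  res <- kabsch_rmsd(x, x)
  expect_equal(res$rmsd, 0, tolerance = 1e-12)
  r <- random_rotation(); t0 <- c(3, -2, 7)
  y <- x %*% t(r) + matrix(t0, 10, 3, byrow = TRUE)
  res <- kabsch_rmsd(x, y)
  expect_lt(res$rmsd, 1e-9)
  expect_equal(det(res$rotation), 1, tolerance = 1e-9)
  expect_equal(res$rotation, r, tolerance = 1e-9)
})

test_that("kabsch is optimal: no sampled rotation beats it", {
  set.seed(8)
  x <- matrix(rnorm(12), 4, 3)
  y <- x %*% t(random_rotation()) + matrix(rnorm(12, 0, 0.3), 4, 3)
  best <- kabsch_rmsd(x, y)$rmsd
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  for (k in 1:2000) {
    r <- random_rotation()
    expect_gte(sqrt(mean(rowSums((xc %*% t(r) - yc)^2))), best - 1e-10)
  }
})

test_that("kabsch rmsd under isotropic noise matches its expected scale", {
  set.seed(13)
  n <- 200; sigma <- 0.2
  x <- matrix(rnorm(3 * n), n, 3)
  y <- x + matrix(rnorm(3 * n, 0, sigma), n, 3)
  r <- kabsch_rmsd(x, y)$rmsd
  expect_gt(r, sqrt(3) * sigma * 0.85)
  expect_lt(r, sqrt(3) * sigma * 1.1)
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(kabsch_rmsd(line, line), "collinear")
  expect_error(kabsch_rmsd(matrix(0, 2, 3), matrix(0, 2, 3)), "3 points")
})
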