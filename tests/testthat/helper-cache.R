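# Shared lazily-computed fixtures.  Everything is generated in code; the
# expensive objects (default potential, long unbiased runs, the metadynamics
# replica panel) are computed once per test session and reused.

.tcache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.tcache[[name]])) .tcache[[name]] <- expr
  .tcache[[name]]
}

default_pot <- function() build_default_potential()

# long unbiased run (contact / rotamer-by-site and Boltzmann checks)
unbiased_run <- function(seed) {
  cached(paste0("run", seed),
         simulate_trajectory(default_pot(),
                             generator_config(steps = 5e6, seed = seed)))
}

# moderate run for distributional checks (shares the acceptance run)
short_run <- function() unbiased_run(7)

# i.i.d. samples from the exact Boltzmann law of the potential (inverse-CDF
# in z, conditional inverse-CDF in chi, Gaussian lateral modes): the oracle
# ensemble for cross-basin density-map checks, free of kinetic mixing bias
boltzmann_sample <- function(n, seed = 1, pot = default_pot(),
                             temperature = 300) {
  cached(paste0("boltz", n, "_", seed), {
    set.seed(seed)
    kT <- kBT(temperature)
    zg <- seq(pot$z_min, pot$z_max, by = 0.01)
    chig <- seq(0, 359.5, by = 0.5)
    u <- potential_energy(pot, rep(zg, length(chig)),
                          rep(chig, each = length(zg)))
    w <- exp(-(matrix(u, length(zg), length(chig)) - min(u)) / kT)
    wz <- rowSums(w)
    iz <- findInterval(runif(n), cumsum(wz) / sum(wz)) + 1
    z <- zg[iz]
    chi <- vapply(iz, function(i) {
      chig[findInterval(runif(1), cumsum(w[i, ]) / sum(w[i, ])) + 1]
    }, 0)
    sig <- sqrt(kT / pot$k_xy)
    data.frame(time_ps = seq_len(n), x = rnorm(n, 0, sig),
               y = rnorm(n, 0, sig), z = z, chi1_deg = -68, chi2_deg = chi)
  })
}

# the 25-replica metadynamics panel and its replica-averaged FES
metad_panel <- function() {
  cached("metad25", {
    pot <- default_pot()
    runs <- lapply(1:25, function(i) {
      r <- run_wtmetad(pot, wt_params(),
                       generator_config(steps = 2e6, stride = 200, seed = i))
      fes_from_bias(r$bias)
    })
    list(runs = runs, fes = replica_statistics(runs))
  })
}

# wrapped absolute angular difference in degrees
ang_diff <- function(a, b) abs((a - b + 180) %% 360 - 180)

# random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# independent minimax oracle: Floyd-Warshall closure over max-edge costs on
# the 8-connected chi-periodic grid graph
minimax_closure <- function(f) {
  nz <- nrow(f); nc <- ncol(f); n <- nz * nc
  d <- matrix(Inf, n, n)
  idx <- function(i, j) (j - 1) * nz + i
  for (i in seq_len(nz)) for (j in seq_len(nc)) {
    d[idx(i, j), idx(i, j)] <- f[i, j]
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di
      if (ii < 1 || ii > nz) next
      jj <- j + dj
      if (jj < 1) jj <- nc else if (jj > nc) jj <- 1
      d[idx(i, j), idx(ii, jj)] <- max(f[i, j], f[ii, jj])
    }
  }
  for (k in seq_len(n)) {
    dk <- pmax(matrix(d[, k], n, n), matrix(d[k, ], n, n, byrow = TRUE))
    d <- pmin(d, dk)
  }
  d
}
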