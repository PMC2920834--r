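# Config-driven orchestration of the three experiment designs at desk scale:
# one long unbiased run (md1-analog), many short unbiased replicas
# (md2-analog), and replica metadynamics (md3-analog), each followed by the
# standard analyses and a JSON report.

#' Preset experiment configurations
#'
#' @param kind `"md1-analog"` (one long unbiased run), `"md2-analog"` (many
#'   short unbiased replicas) or `"md3-analog"` (well-tempered metadynamics
#'   replicas).
#' @param seed base seed; replica i uses `seed + i - 1`.
#' @param ... overrides of the preset fields (`n_runs`, `steps`, `stride`,
#'   `wt` for metadynamics parameters, ...).
#' @return a named list config (YAML-serializable).
#' @export
experiment_config <- function(kind = c("md1-analog", "md2-analog",
                                       "md3-analog"), seed = 1, ...) {
  kind <- match.arg(kind)
  base <- switch(kind,
    "md1-analog" = list(kind = kind, n_runs = 1, steps = 5e6, stride = 100),
    "md2-analog" = list(kind = kind, n_runs = 100, steps = 5e5, stride = 100),
    "md3-analog" = list(kind = kind, n_runs = 25, steps = 2e6, stride = 200,
                        wt = unclass(wt_params())))
  base$seed <- seed
  base$version <- as.character(utils::packageVersion("iontoggle"))
  utils::modifyList(base, list(...))
}

#' Run an experiment preset end to end
#'
#' Generates the trajectories (or metadynamics replicas), runs the analyses
#' (site dwell summary, rotamer-by-site table, contact report, density /
#' chemical-potential threshold summary; FES basins and barriers with replica
#' errors for metadynamics), writes artifacts (TSV trajectories, .dx grids,
#' JSON report, YAML manifest) under `out_dir`, and returns the report.
#' Outputs are deterministic given the config (identical seeds give
#' byte-identical numeric reports). A failing unbiased replica is recorded in
#' the report and skipped rather than aborting the experiment.
#'
#' @param config a config from [experiment_config()] (or a YAML file path).
#' @param out_dir output directory (created if missing), or `NULL` to skip
#'   writing artifacts.
#' @param pot a `channel_potential`.
#' @return the report, a named list (invisibly the same list that is written
#'   as JSON), with the run manifest attached as `manifest`.
#' @export
run_experiment <- function(config, out_dir = NULL,
                           pot = build_default_potential()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is.list(config), !is.null(config$kind))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  seeds <- config$seed + seq_len(config$n_runs) - 1
  chash <- config_hash(config)
  is_metad <- identical(config$kind, "md3-analog")

  report <- list(kind = config$kind, seed = config$seed,
                 config_hash = chash, n_runs = config$n_runs,
                 failed_runs = integer(0))

  if (is_metad) {
    wt <- do.call(wt_params, config$wt[setdiff(names(config$wt), NULL)])
    runs <- vector("list", config$n_runs)
    for (i in seq_len(config$n_runs)) {
      cfg <- generator_config(steps = config$steps, stride = config$stride,
                              seed = seeds[i])
      r <- run_wtmetad(pot, wt, cfg)
      runs[[i]] <- fes_from_bias(r$bias)
    }
    fes <- replica_statistics(runs)
    s <- summary(fes, pot = pot)
    report$fes <- list(
      basins = s$basins,
      barrier_bc = s$barrier_bc, saddle_bc_z = s$saddle_bc_z,
      rotamer_barrier_ab = s$rotamer_barrier_ab,
      rotamer_barrier_c = s$rotamer_barrier_c,
      site_c_advantage = s$site_c_advantage,
      basin_error_median = s$basin_error_median,
      basin_error_max = s$basin_error_max)
    if (!is.null(out_dir)) {
      .write_fes_dx(fes, file.path(out_dir, "fes_mean.dx"),
                    file.path(out_dir, "fes_err.dx"))
    }
  } else {
    trajs <- list()
    for (i in seq_len(config$n_runs)) {
      cfg <- generator_config(steps = config$steps, stride = config$stride,
                              seed = seeds[i])
      tr <- tryCatch(simulate_trajectory(pot, cfg), error = function(e) e)
      if (inherits(tr, "error")) {
        warning("replica ", i, " failed: ", conditionMessage(tr))
        report$failed_runs <- c(report$failed_runs, i)
      } else trajs[[length(trajs) + 1]] <- tr
    }
    if (!length(trajs)) stop("all replicas failed")
    sites <- site_definition()
    all_lab <- unlist(lapply(trajs, function(tr) assign_site(tr$z, sites)))
    ep <- dwell_episodes(assign_site(trajs[[1]]$z, sites),
                         trajs[[1]]$time_ps)
    big <- do.call(rbind, lapply(trajs, as.data.frame))
    report$site_occupancy <- as.list(table(all_lab) / length(all_lab))
    report$dwell <- list(n_episodes = nrow(ep),
                         transitions = attr(ep, "transitions"),
                         mean_duration_ps = mean(ep$duration))
    report$rotamer_by_site <- rotamer_state_by_site(big, sites)
    anchors <- default_anchor_set(pot)
    report$contacts <- tryCatch(
      as.data.frame(contact_frequency(big, anchors, site = "c",
                                      sites = sites)),
      error = function(e) conditionMessage(e))
    dg <- suppressWarnings(accumulate_density(trajs))
    mu <- chemical_potential_map(dg)
    thr <- threshold_region(mu, -4)
    report$density <- list(frames = dg$frames, overflow = dg$overflow,
                           mu_min = min(mu$values),
                           level = -4, volume_A3 = thr$volume,
                           n_components = thr$n_components)
    if (!is.null(out_dir)) {
      write_cv_table(trajs[[1]], file.path(out_dir, "run001.tsv"))
      write_dx(dg$density, file.path(out_dir, "density.dx"))
      mu_w <- mu
      write_dx(mu_w, file.path(out_dir, "mu.dx"))
    }
  }

  manifest <- list(kind = config$kind, seeds = seeds, config_hash = chash,
                   version = as.character(utils::packageVersion("iontoggle")),
                   outputs = if (is.null(out_dir)) character(0)
                             else list.files(out_dir))
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_run_config(manifest, file.path(out_dir, "manifest.yaml"))
  }
  attr(report, "manifest") <- manifest
  invisible(report)
}

# FES grids are 2D; store them as single-layer volumetric grids (z, chi, 1)
.write_fes_dx <- function(fes, path_mean, path_err = NULL) {
  v <- array(fes$F, dim = c(dim(fes$F), 1))
  g <- volumetric_grid(c(fes$z[1], fes$chi[1], 0),
                       c(fes$z[2] - fes$z[1], fes$chi[2] - fes$chi[1], 1),
                       v, kind = "free_energy")
  write_dx(g, path_mean)
  if (!is.null(path_err) && !is.null(fes$error)) {
    ge <- volumetric_grid(g$origin, g$spacing,
                          array(fes$error, dim = dim(v)), kind = "fes_error")
    write_dx(ge, path_err)
  }
  invisible(path_mean)
}
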