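# Site segmentation, dwell episodes and rotamer-by-site statistics.

#' Binding-site definition on the channel axis
#'
#' Sites are half-open z intervals, open toward +z: with the default
#' boundaries, a = (-6.25, 0], b = (-12, -6.25], c = \[z_min, -12\]; z above
#' the upper boundary is labeled `"none"`. The default a/b boundary is the
#' constructed a-b saddle position and the b/c boundary the rotamer switch
#' position.
#'
#' @param boundaries strictly decreasing z positions separating none/a, a/b
#'   and b/c (Angstrom).
#' @param z_min lower end of the domain.
#' @param labels site labels, outermost first.
#' @return an object of class `site_definition`.
#' @export
site_definition <- function(boundaries = c(0, -6.25, -12), z_min = -18,
                            labels = c("a", "b", "c")) {
  stopifnot(length(boundaries) == length(labels),
            all(diff(boundaries) < 0), z_min < min(boundaries))
  structure(list(boundaries = boundaries, z_min = z_min, labels = labels),
            class = "site_definition")
}

#' Assign binding-site labels to z positions
#'
#' @param z numeric vector of z positions (Angstrom).
#' @param sites a `site_definition`.
#' @return character vector of labels (`"none"` above the first boundary).
#' @export
assign_site <- function(z, sites = site_definition()) {
  stopifnot(all(is.finite(z)))
  b <- sites$boundaries
  out <- rep("none", length(z))
  for (i in seq_along(b)) out[z <= b[i]] <- sites$labels[i]
  out
}

#' Dwell episodes from a per-frame site-label series
#'
#' Merges consecutive equal labels into episodes. Episodes shorter than
#' `min_duration` are absorbed into the preceding episode (into the following
#' one at the start of the series), repeatedly until none remain; the default
#' `min_duration = 0` reports the raw segmentation.
#'
#' @param labels per-frame site labels.
#' @param times per-frame times (ps), same length, strictly increasing.
#' @param min_duration minimum episode duration (ps).
#' @return data frame with columns `site`, `start`, `end`, `duration`
#'   (`end` is the time of the episode's last frame; for single-frame episodes
#'   a half-frame-interval duration is reported so durations are positive),
#'   with the number of transitions as attribute `"transitions"`.
#' @export
dwell_episodes <- function(labels, times, min_duration = 0) {
  if (length(labels) != length(times))
    stop("labels and times have different lengths (", length(labels),
         " vs ", length(times), ")")
  stopifnot(length(labels) >= 1, all(diff(times) > 0))
  r <- rle(as.character(labels))
  vals <- r$values
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  dt_med <- if (length(times) > 1) stats::median(diff(times)) else 1
  if (min_duration > 0) {
    repeat {
      if (length(vals) == 1) break
      dur <- times[ends] - times[starts] + dt_med
      short <- which(dur < min_duration)
      if (!length(short)) break
      i <- short[1]
      into <- if (i > 1) i - 1 else i + 1
      # absorb episode i into its flanking episode
      if (into < i) ends[into] <- ends[i] else starts[into] <- starts[i]
      vals <- vals[-i]; starts <- starts[-i]; ends <- ends[-i]
      # re-merge now-adjacent equal labels
      j <- 1
      while (j < length(vals)) {
        if (vals[j] == vals[j + 1]) {
          ends[j] <- ends[j + 1]
          vals <- vals[-(j + 1)]
          starts <- starts[-(j + 1)]; ends <- ends[-(j + 1)]
        } else j <- j + 1
      }
    }
  }
  r$values <- vals
  out <- data.frame(site = r$values, start = times[starts],
                    end = times[ends],
                    duration = times[ends] - times[starts] +
                      ifelse(ends == starts, dt_med / 2, 0),
                    stringsAsFactors = FALSE)
  attr(out, "transitions") <- max(0L, nrow(out) - 1L)
  out
}

#' Circular mean and standard deviation of angles
#'
#' @param theta angles in degrees.
#' @return `circular_mean`: mean direction in degrees in (-180, 180\];
#'   `circular_sd`: circular standard deviation `sqrt(-2 log Rbar)` in
#'   degrees.
#' @export
circular_mean <- function(theta) {
  r <- theta * pi / 180
  ang <- atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' @rdname circular_mean
#' @export
circular_sd <- function(theta) {
  r <- theta * pi / 180
  rbar <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  sqrt(pmax(0, -2 * log(rbar))) * 180 / pi
}

#' Rotamer state (circular chi2 statistics) by binding site
#'
#' Restricts the trajectory's chi2 series to the frames assigned to each site
#' and reports circular mean and circular standard deviation per site. Sites
#' with no frames are omitted with a warning.
#'
#' @param traj a `cv_trajectory` (or data frame with `z` and `chi2_deg`).
#' @param sites a `site_definition`.
#' @return data frame with columns `site`, `n_frames`, `chi2_mean`,
#'   `chi2_sd` (degrees; means reported in (-180, 180\]).
#' @export
rotamer_state_by_site <- function(traj, sites = site_definition()) {
  lab <- assign_site(traj$z, sites)
  all_sites <- c(sites$labels, "none")
  present <- intersect(all_sites, unique(lab))
  missing_sites <- setdiff(sites$labels, present)
  if (length(missing_sites))
    warning("no frames in site(s): ", paste(missing_sites, collapse = ", "))
  out <- do.call(rbind, lapply(present, function(s) {
    chi <- traj$chi2_deg[lab == s]
    data.frame(site = s, n_frames = length(chi),
               chi2_mean = circular_mean(chi), chi2_sd = circular_sd(chi),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
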