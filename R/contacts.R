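# Anchor contact frequencies, optionally conditioned on a binding site.

#' Contact frequency of each anchor within a cutoff
#'
#' For each anchor, the percentage of (optionally site-filtered) frames in
#' which the ion lies within the closed ball `|ion - anchor| <= cutoff`.
#'
#' @param traj a `cv_trajectory` (needs columns `x`, `y`, `z`).
#' @param anchors an `anchor_set` or an n x 3 matrix with rownames.
#' @param cutoff contact cutoff radius (Angstrom); defaults to the anchor
#'   set's cutoff.
#' @param site conditioning site label (e.g. `"c"`), or `NULL` for all frames.
#' @param sites a `site_definition` used for the conditioning.
#' @return a `contact_report`: data frame with columns `anchor`,
#'   `frames_considered`, `contact_frames`, `frequency` (percent), with
#'   `cutoff` and `site` attached as attributes.
#' @export
contact_frequency <- function(traj, anchors, cutoff = NULL, site = "c",
                              sites = site_definition()) {
  pts <- if (inherits(anchors, "anchor_set")) anchors$points else as.matrix(anchors)
  if (is.null(cutoff))
    cutoff <- if (inherits(anchors, "anchor_set")) anchors$cutoff else 2.5
  stopifnot(cutoff > 0, ncol(pts) == 3)
  keep <- if (is.null(site)) rep(TRUE, nrow(traj))
          else assign_site(traj$z, sites) == site
  if (!any(keep))
    stop("no frames assigned to site '", site, "'")
  xi <- traj$x[keep]; yi <- traj$y[keep]; zi <- traj$z[keep]
  n <- length(xi)
  hits <- vapply(seq_len(nrow(pts)), function(i) {
    sum((xi - pts[i, 1])^2 + (yi - pts[i, 2])^2 + (zi - pts[i, 3])^2
        <= cutoff^2)
  }, 0)
  out <- data.frame(anchor = rownames(pts), frames_considered = n,
                    contact_frames = hits, frequency = 100 * hits / n,
                    stringsAsFactors = FALSE)
  structure(out, cutoff = cutoff, site = if (is.null(site)) NA else site,
            class = c("contact_report", "data.frame"))
}

#' @export
print.contact_report <- function(x, ...) {
  site <- attr(x, "site")
  cat(sprintf("Contact frequencies (cutoff %.2f A%s, %d frames):\n",
              attr(x, "cutoff"),
              if (!is.na(site)) paste0(", site ", site) else "",
              x$frames_considered[1]))
  print(data.frame(anchor = x$anchor,
                   frequency = sprintf("%.1f%%", x$frequency)),
        row.names = FALSE)
  invisible(x)
}
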