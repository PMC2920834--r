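# Readers/writers for the formats every stage touches: TSV CV tables,
# multi-frame XYZ, OpenDX scalar grids and YAML run configs.  All writers are
# deterministic byte-for-byte given identical inputs (fixed float formatting,
# no locale-dependent output).

.cv_required_cols <- c("time_ps", "x", "y", "z", "chi1_deg", "chi2_deg")

.fmt_num <- function(x) sprintf("%.6f", x)

#' Write / read a collective-variable table
#'
#' Tab-separated table with columns `time_ps`, `x`, `y`, `z`, `chi1_deg`,
#' `chi2_deg` (unknown extra columns are preserved) and `# key: value`
#' provenance comment lines (seed, config hash) before the header. Numeric
#' values are written with 6 decimal places; a write/read round trip is
#' lossless at that precision and two writes of the same table are
#' byte-identical.
#'
#' @param traj a `cv_trajectory` (or plain data frame with the required
#'   columns).
#' @param path file path.
#' @return `write_cv_table` returns `path` invisibly; `read_cv_table` returns
#'   a `cv_trajectory` with provenance attributes.
#' @export
write_cv_table <- function(traj, path) {
  df <- as.data.frame(traj)
  miss <- setdiff(.cv_required_cols, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  meta <- c(list(format = "iontoggle-cv-v1"),
            if (!is.null(attr(traj, "seed")) && !is.na(attr(traj, "seed")))
              list(seed = format(attr(traj, "seed"), scientific = FALSE)),
            attr(traj, "meta"))
  hdr <- vapply(seq_along(meta), function(i)
    sprintf("# %s: %s", names(meta)[i], as.character(meta[[i]])), "")
  cols <- c(.cv_required_cols, setdiff(names(df), .cv_required_cols))
  body <- do.call(paste, c(lapply(df[cols], function(col)
    if (is.numeric(col)) .fmt_num(col) else as.character(col)), sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, paste(cols, collapse = "\t"), body), con, sep = "\n")
  invisible(path)
}

#' @rdname write_cv_table
#' @export
read_cv_table <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  n_meta <- if (any(!is_meta)) which(!is_meta)[1] - 1 else length(lines)
  meta <- list()
  for (l in lines[seq_len(n_meta)]) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[!is_meta]
  if (length(body) < 1) stop("no frames: file has no header or data rows")
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  miss <- setdiff(.cv_required_cols, cols)
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (length(body) < 2) stop("no frames: table contains a header but no rows")
  df <- read.table(text = body, header = TRUE, sep = "\t",
                   check.names = FALSE)
  bad <- which(diff(df$time_ps) <= 0)
  if (length(bad))
    stop("non-monotone time at data line ", bad[1] + 1, " (time ",
         df$time_ps[bad[1] + 1], " follows ", df$time_ps[bad[1]], ")")
  seed <- if (!is.null(meta$seed)) as.numeric(meta$seed) else NA
  meta$seed <- NULL; meta$format <- NULL
  new_cv_trajectory(df, seed = seed, meta = meta)
}

#' Write / read multi-frame XYZ
#'
#' Standard XYZ dialect: per frame an atom-count line, a comment line, then
#' `element x y z` rows (6 decimal places).
#'
#' @param frames a list of n_atoms x 3 coordinate matrices (or a single
#'   matrix).
#' @param labels character vector of atom labels, one per atom.
#' @param path file path.
#' @param comments optional per-frame comment lines.
#' @return `write_xyz` returns `path` invisibly; `read_xyz` returns
#'   `list(labels, frames, comments)`.
#' @export
write_xyz <- function(frames, labels, path, comments = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  n_at <- length(labels)
  if (is.null(comments)) comments <- sprintf("frame %d", seq_along(frames))
  out <- character(0)
  chunks <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    m <- frames[[f]]
    if (nrow(m) != n_at)
      stop("frame ", f, " has ", nrow(m), " atoms, expected ", n_at)
    chunks[[f]] <- c(as.character(n_at), comments[f],
                     sprintf("%s %.6f %.6f %.6f", labels,
                             m[, 1], m[, 2], m[, 3]))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(unlist(chunks), con, sep = "\n")
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); comments <- character(0); labels <- NULL
  i <- 1; f <- 0
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    f <- f + 1
    if (is.na(n) || n < 1)
      stop("bad atom-count line at frame ", f)
    if (i + 1 + n > length(lines))
      stop("count-line mismatch at frame ", f, ": expected ", n,
           " atom rows, file truncated")
    comments <- c(comments, lines[i + 1])
    rows <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "\\s+")
    if (any(lengths(rows) < 4))
      stop("count-line mismatch at frame ", f, ": malformed atom row")
    lab <- vapply(rows, `[`, "", 1)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("non-numeric coordinates at frame ", f)
    if (is.null(labels)) labels <- lab
    else if (!identical(labels, lab))
      stop("atom labels change at frame ", f)
    frames[[f]] <- unname(xyz)
    i <- i + 2 + n
  }
  if (f == 0) stop("no frames in XYZ file")
  list(labels = labels, frames = frames, comments = comments)
}

#' Volumetric grid container
#'
#' A regular 3D scalar grid: `origin` is the center of the first voxel,
#' `spacing` the voxel edge lengths, `values` an array indexed \[x, y, z\].
#'
#' @param origin length-3 origin (Angstrom, voxel center).
#' @param spacing length-3 (or scalar) voxel spacings (Angstrom).
#' @param values 3D numeric array.
#' @param kind value kind tag (e.g. `"counts"`, `"density"`, `"chemical_potential"`).
#' @return an object of class `volumetric_grid`.
#' @export
volumetric_grid <- function(origin, spacing, values, kind = "density") {
  spacing <- rep_len(as.numeric(spacing), 3)
  stopifnot(length(origin) == 3, all(spacing > 0), length(dim(values)) == 3)
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = dim(values), values = values, kind = kind),
            class = "volumetric_grid")
}

#' @export
print.volumetric_grid <- function(x, ...) {
  cat(sprintf("Volumetric grid [%s]: %d x %d x %d voxels, spacing %s A\n",
              x$kind, x$dims[1], x$dims[2], x$dims[3],
              paste(format(x$spacing), collapse = " x ")))
  fin <- x$values[is.finite(x$values)]
  if (length(fin))
    cat(sprintf("  finite value range [%.4g, %.4g]; %d unsampled voxel(s)\n",
                min(fin), max(fin), sum(!is.finite(x$values))))
  invisible(x)
}

# sentinel used on disk for unsampled (+Inf) voxels
.dx_inf <- 9.999e99

#' Write / read an OpenDX scalar grid
#'
#' OpenDX-style scalar grid files. Values are written x-fastest (the first
#' grid index varies fastest within the data block), three per line; the
#' reader expects the same ordering, so write/read round trips are exact to
#' the printed precision (better than 1e-6 relative). Non-finite (unsampled)
#' voxels are stored as the sentinel `9.999e99` and restored to `Inf` on read.
#'
#' @param grid a `volumetric_grid`.
#' @param path file path.
#' @return `write_dx` returns `path` invisibly; `read_dx` a `volumetric_grid`.
#' @export
write_dx <- function(grid, path) {
  stopifnot(inherits(grid, "volumetric_grid"))
  d <- grid$dims
  v <- as.vector(grid$values) # x fastest (R column-major)
  v[!is.finite(v)] <- .dx_inf
  n <- length(v)
  pad <- (3 - n %% 3) %% 3
  vm <- matrix(c(sprintf("%.8e", v), rep("", pad)), nrow = 3)
  data_lines <- trimws(apply(vm, 2, paste, collapse = " "))
  hdr <- c(
    sprintf("# OpenDX scalar grid (%s); ordering: x fastest", grid$kind),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.8e %.8e %.8e", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.8e 0 0", grid$spacing[1]),
    sprintf("delta 0 %.8e 0", grid$spacing[2]),
    sprintf("delta 0 0 %.8e", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            n))
  tail_ <- c("attribute \"dep\" string \"positions\"",
             sprintf("object \"%s\" class field", grid$kind),
             "component \"positions\" value 1",
             "component \"connections\" value 2",
             "component \"data\" value 3")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, data_lines, tail_), con, sep = "\n")
  invisible(path)
}

#' @rdname write_dx
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  g1 <- grep("gridpositions counts", lines, value = TRUE)[1]
  if (is.na(g1)) stop("not an OpenDX grid: no gridpositions object")
  d <- as.integer(strsplit(sub(".*counts\\s+", "", g1), "\\s+")[[1]])
  org <- as.numeric(strsplit(sub("^origin\\s+", "",
                                 grep("^origin", lines, value = TRUE)[1]),
                             "\\s+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  dl <- t(vapply(deltas[1:3], function(l)
    as.numeric(strsplit(sub("^delta\\s+", "", l), "\\s+")[[1]]), numeric(3)))
  spacing <- c(dl[1, 1], dl[2, 2], dl[3, 3])
  i3 <- grep("class array", lines)[1]
  n_items <- as.integer(sub(".*items\\s+(\\d+)\\s+data follows.*", "\\1",
                            lines[i3]))
  if (n_items != prod(d))
    stop("dimension/value-count mismatch: ", n_items, " items for grid ",
         paste(d, collapse = "x"))
  j <- i3 + 1
  vals <- numeric(0)
  while (j <= length(lines) && !grepl("^(attribute|object)", lines[j])) {
    vals <- c(vals, as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1]]))
    j <- j + 1
  }
  if (length(vals) != n_items)
    stop("dimension/value-count mismatch: read ", length(vals),
         " values, expected ", n_items)
  kind <- sub(".*object \"([^\"]+)\" class field.*", "\\1",
              grep("class field", lines, value = TRUE)[1])
  if (is.na(kind) || !nzchar(kind)) kind <- "density"
  vals[vals >= .dx_inf] <- Inf
  volumetric_grid(org, spacing, array(vals, dim = d), kind = kind)
}

#' Read / write a YAML run configuration
#'
#' @param path file path.
#' @param config a named list.
#' @return `read_run_config` returns the named list; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  writeLines(yaml::as.yaml(config), path)
  invisible(path)
}

#' Stable short hash of a configuration object
#'
#' Polynomial hash of the YAML rendering; used to fingerprint run configs in
#' provenance headers and manifests.
#'
#' @param x any YAML-serializable object.
#' @return an 8-hex-digit string.
#' @export
config_hash <- function(x) {
  b <- as.integer(charToRaw(yaml::as.yaml(x)))
  h <- 0
  for (v in b) h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", h)
}

#' Write a trajectory as a multi-frame XYZ of pseudo-atoms
#'
#' Writes the ion (`NA` sodium pseudo-atom), the four idealized Trp side-chain
#' atoms placed from each frame's chi1/chi2 (translated to sit near the switch
#' position), and the anchor points, one XYZ frame per trajectory frame.
#'
#' @param traj a `cv_trajectory`.
#' @param anchors an `anchor_set` (see [default_anchor_set()]).
#' @param path file path.
#' @param every write every `every`-th frame.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, anchors, path, every = 1) {
  idx <- seq(1, nrow(traj), by = every)
  trp_offset <- c(3.0, 0, -12.0)
  apos <- anchors$points
  labels <- c("NA", "CA", "CB", "CG", "CD1", rownames(apos))
  frames <- lapply(idx, function(i) {
    trp <- place_trp_atoms(traj$chi1_deg[i], traj$chi2_deg[i])[-1, , drop = FALSE]
    rbind(c(traj$x[i], traj$y[i], traj$z[i]),
          sweep(trp, 2, trp_offset, "+"),
          apos)
  })
  write_xyz(frames, labels, path,
            comments = sprintf("t= %.6f ps", traj$time_ps[idx]))
}
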