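# Dihedral, idealized side-chain placement, and Kabsch superposition.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.norm3 <- function(a) sqrt(sum(a * a))

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: the angle is positive for a clockwise rotation of
#' the far bond when viewed from the second atom toward the third; the cis
#' configuration is 0 degrees. The result is invariant under global rotation
#' and translation.
#'
#' @param p1,p2,p3,p4 numeric length-3 points (Angstrom).
#' @return angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (.norm3(b1) < 1e-12 || .norm3(b2) < 1e-12 || .norm3(b3) < 1e-12)
    stop("degenerate geometry: consecutive points coincide")
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (.norm3(n1) < 1e-10 * .norm3(b1) * .norm3(b2) ||
      .norm3(n2) < 1e-10 * .norm3(b2) * .norm3(b3))
    stop("degenerate geometry: three consecutive points are collinear")
  b2u <- b2 / .norm3(b2)
  m1 <- .cross3(n1, b2u)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# NeRF atom placement: position D with |CD| = bond, angle(B,C,D) = theta and
# dihedral(A,B,C,D) = phi (degrees, IUPAC convention matching dihedral_angle)
.place_atom <- function(a, b, c, bond, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- c - b; bc <- bc / .norm3(bc)
  ab <- b - a
  n <- .cross3(ab, bc); n <- n / .norm3(n)
  m <- .cross3(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), -bond * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Idealized tryptophan side-chain frame for given chi1/chi2
#'
#' Emits the five-atom frame N, CA, CB, CG, CD1 with fixed bond lengths
#' (1.5 Angstrom) and bond angles (110 degrees) such that
#' `dihedral_angle(N, CA, CB, CG)` returns `chi1` and
#' `dihedral_angle(CA, CB, CG, CD1)` returns `chi2` (round-trip error below
#' 1e-6 degrees).
#'
#' @param chi1,chi2 dihedral angles in degrees.
#' @return a 5 x 3 matrix with rownames N, CA, CB, CG, CD1.
#' @export
place_trp_atoms <- function(chi1, chi2) {
  stopifnot(is.finite(chi1), is.finite(chi2))
  bond <- 1.5; theta <- 110
  n <- c(0, 0, 0)
  ca <- c(bond, 0, 0)
  th <- theta * pi / 180
  cb <- ca + bond * c(-cos(th), sin(th), 0)
  cg <- .place_atom(n, ca, cb, bond, theta, chi1)
  cd1 <- .place_atom(ca, cb, cg, bond, theta, chi2)
  out <- rbind(N = n, CA = ca, CB = cb, CG = cg, CD1 = cd1)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Kabsch superposition and RMSD
#'
#' Least-squares optimal rigid superposition of point set `x` onto `y`
#' (optionally weighted), constrained to a proper rotation (det = +1).
#'
#' @param x,y n x 3 matrices of matched points, n >= 3 and not collinear.
#' @param weights optional non-negative per-point weights.
#' @return list with `rotation` (3 x 3), `translation` (length 3; the fitted
#'   map is `x %*% t(rotation) + translation`), and `rmsd` (Angstrom).
#' @export
kabsch_rmsd <- function(x, y, weights = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y)) || ncol(x) != 3)
    stop("x and y must be matched n x 3 matrices")
  n <- nrow(x)
  if (n < 3) stop("at least 3 points are required")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  mx <- colSums(x * w); my <- colSums(y * w)
  xc <- sweep(x, 2, mx); yc <- sweep(y, 2, my)
  sv_x <- svd(xc * sqrt(w))$d
  if (sv_x[2] < 1e-9 * max(sv_x[1], 1))
    stop("degenerate point set: points are (nearly) collinear")
  h <- t(xc * w) %*% yc
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fit <- xc %*% t(r)
  rmsd <- sqrt(sum(w * rowSums((fit - yc)^2)))
  list(rotation = r, translation = as.numeric(my - r %*% mx), rmsd = rmsd)
}
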