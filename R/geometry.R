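# Small 3D geometry kernel shared by the builders and the analyses.
# Internal length unit is the angstrom throughout.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

crossp <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: the cis (eclipsed) arrangement is 0 degrees and
#' the angle is measured in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric xyz vectors (angstrom).
#' @return angle in degrees.
#' @keywords internal
dihedral_points <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- crossp(b1, b2)
  n2 <- crossp(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop("collinear atoms: dihedral undefined")
  m1 <- crossp(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Rotation matrix for angle theta (radians) about unit axis u (Rodrigues).
rotation_matrix <- function(u, theta) {
  u <- unitv(u)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)),
    nrow = 3, byrow = TRUE)
}

# Rotate rows of an n x 3 matrix about an axis through `origin`.
rotate_about_axis <- function(xyz, origin, axis, theta) {
  R <- rotation_matrix(axis, theta)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, `+`)
}

# Random rotation matrix, uniform over SO(3) (via quaternion sampling).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

# Rotation taking unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  v <- crossp(a, b)
  c0 <- sum(a * b)
  if (vnorm(v) < 1e-12) {
    if (c0 > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rotation_matrix(unitv(crossp(a, p)), pi))
  }
  rotation_matrix(unitv(v), acos(max(-1, min(1, c0))))
}

# Place atom D given positions A, B, C, the bond length |C-D|, the angle
# B-C-D (deg) and the dihedral A-B-C-D (deg).  Natural-extension frame.
place_atom <- function(a, b, c3, bond, angle_deg, dihedral_deg) {
  th <- angle_deg * pi / 180
  ph <- dihedral_deg * pi / 180
  bc <- unitv(c3 - b)
  n <- unitv(crossp(b - a, bc))
  m <- crossp(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), -bond * sin(th) * sin(ph))
  c3 + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Optimal proper rotation + translation mapping rows of X onto rows of Y
# (Kabsch, base svd).  Returns list(R, t) with y ~ x %*% R + t.
kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  s <- svd(crossprod(x0, y0))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, t = cy - as.numeric(cx %*% R))
}

apply_rigid <- function(xyz, tr) sweep(xyz %*% tr$R, 2, tr$t, `+`)

# Minimum-image displacement components.  box entries of NA or Inf mean
# non-periodic in that direction.
min_image <- function(d, box_len) {
  if (is.na(box_len) || !is.finite(box_len)) return(d)
  d - box_len * round(d / box_len)
}

# All minimum-image distances between rows of A (n x 3) and rows of B
# (m x 3) under an orthorhombic box (angstrom, NA = open).  Returns n x m.
pair_distances <- function(a, b, box = c(NA, NA, NA)) {
  dx <- min_image(outer(a[, 1], b[, 1], `-`), box[1])
  dy <- min_image(outer(a[, 2], b[, 2], `-`), box[2])
  dz <- min_image(outer(a[, 3], b[, 3], `-`), box[3])
  sqrt(dx * dx + dy * dy + dz * dz)
}

wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y <= -180] <- y[y <= -180] + 360
  y
}
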