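# Low-level 3-D geometry used across modules. All angles in degrees,
# all distances in Angstrom. Vectors are length-3 numerics; coordinate
# sets are n x 3 matrices.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Signed dihedral p1-p2-p3-p4, IUPAC convention, degrees in (-180, 180].
dihedral_points <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -atan2(y, x) / DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

angle_points <- function(p1, p2, p3) {
  a <- unitv(p1 - p2)
  b <- unitv(p3 - p2)
  acos(max(-1, min(1, sum(a * b)))) / DEG
}

## NeRF atom placement: position d with |c-d| = bond, angle(b,c,d) = angle
## and dihedral(a,b,c,d) = dihedral.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  ang <- angle * DEG
  dih <- dihedral * DEG
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## Proper rotation by theta degrees about 'axis' (through the origin).
rotation_about_axis <- function(axis, theta) {
  u <- unitv(axis)
  t <- theta * DEG
  ct <- cos(t); st <- sin(t)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

## Axis/angle of a proper rotation matrix. Angle in [0, 180]; for angle 0
## the axis is arbitrary (returns +z).
axis_angle <- function(R) {
  tr <- sum(diag(R))
  ang <- acos(max(-1, min(1, (tr - 1) / 2))) / DEG
  if (ang < 1e-9) return(list(axis = c(0, 0, 1), angle = 0))
  if (ang > 180 - 1e-6) {
    # near-pi rotation: axis from the largest diagonal of (R + I)/2
    B <- (R + diag(3)) / 2
    i <- which.max(diag(B))
    ax <- unitv(B[, i])
    return(list(axis = ax, angle = ang))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  list(axis = unitv(ax), angle = ang)
}

## Kabsch least-squares rigid superposition of mobile onto target
## (paired rows). Returns the proper rotation R and translation t with
## fitted = mobile %*% t(R) + t, plus the post-fit RMSD.
kabsch <- function(mobile, target) {
  stopifnot(is.matrix(mobile), is.matrix(target))
  if (nrow(mobile) != nrow(target))
    stop("superposition requires equal-length paired coordinate sets")
  if (nrow(mobile) < 3)
    stop("superposition requires at least 3 points")
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  A <- sweep(mobile, 2, cm)
  B <- sweep(target, 2, ct)
  sv <- svd(crossprod(A, B))   # t(A) %*% B
  # degenerate (collinear) sets have rank < 2
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    stop("degenerate (collinear) coordinate set: superposition undefined")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- ct - as.vector(R %*% cm)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

apply_transform <- function(xyz, rotation, translation) {
  sweep(xyz %*% t(rotation), 2, translation, "+")
}
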