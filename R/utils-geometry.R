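## Small geometric helpers shared across modules. All coordinates are
## N x 3 matrices in Angstrom; angles are degrees unless noted.

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

## squared cross-distances between two coordinate sets (na x nb)
.cross_dist2 <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

## angle between two vectors, degrees in [0, 180]
.vec_angle <- function(u, v) {
  c <- sum(.unit(u) * .unit(v))
  .deg(acos(max(-1, min(1, c))))
}

## signed torsion of v1 -> v2 about axis, right-handed, (-180, 180]
.torsion_about <- function(v1, v2, axis) {
  ax <- .unit(axis)
  u <- v1 - sum(v1 * ax) * ax
  w <- v2 - sum(v2 * ax) * ax
  if (sqrt(sum(u^2)) < 1e-9 || sqrt(sum(w^2)) < 1e-9)
    stop("torsion undefined: vector parallel to axis")
  ang <- .deg(atan2(sum(ax * .cross3(u, w)), sum(u * w)))
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## rotation about a unit axis by an angle (degrees), Rodrigues form.
## All rotation matrices in this package act on row-vector coordinate
## matrices: X %*% .rot_about(axis, th) rotates the points of X by +th
## right-handed about the axis.
.rot_about <- function(axis, deg) {
  ax <- .unit(axis)
  th <- .rad(deg)
  K <- matrix(c(0, ax[3], -ax[2],
                -ax[3], 0, ax[1],
                ax[2], -ax[1], 0), 3, 3)
  Rc <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  t(Rc)
}

## minimal rotation taking unit vector 'from' onto unit vector 'to'
.rot_between <- function(from, to) {
  f <- .unit(from); t <- .unit(to)
  c <- sum(f * t)
  if (c > 1 - 1e-12) return(diag(3))
  if (c < -1 + 1e-12) {
    # pick any axis orthogonal to f
    ref <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- .unit(.cross3(f, ref))
    return(.rot_about(ax, 180))
  }
  ax <- .cross3(f, t)
  .rot_about(ax, .deg(atan2(sqrt(sum(ax^2)), c)))
}

## Kabsch: optimal proper rotation R and translation t such that
## mobile %*% R + t ~= target (least squares). Returns list(R, t, rmsd).
.kabsch <- function(mobile, target, weights = NULL) {
  stopifnot(nrow(mobile) == nrow(target), nrow(mobile) >= 3)
  if (is.null(weights)) weights <- rep(1, nrow(mobile))
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  ct <- colSums(target * w)
  M <- sweep(mobile, 2, cm)
  T <- sweep(target, 2, ct)
  H <- crossprod(M * w, T)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)  # mobile %*% R maps into target frame
  fit <- M %*% R
  rmsd <- sqrt(sum(w * rowSums((fit - T)^2)))
  list(R = R, t = as.vector(ct - cm %*% R), rmsd = rmsd)
}
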