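# Small geometry helpers: rotations, quaternions, Kabsch superposition.

# Rotation matrix from a unit quaternion (w, x, y, z).
quat_to_mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Rotation by angle about a (unit) axis, Rodrigues form.
axis_angle_mat <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Rotate points (n x 3) about a line through `origin` with direction `axis`.
rotate_about_axis <- function(xyz, origin, axis, angle) {
  R <- axis_angle_mat(axis, angle)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, "+")
}

# Random unit quaternion (uniform on SO(3)) from 4 normal deviates.
random_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

# Random rotation matrix, uniform on SO(3).
random_rotation <- function() quat_to_mat(random_quat())

#' Kabsch superposition
#'
#' Optimal rigid rotation + translation of `mobile` onto `target`
#' (least-squares over matched rows).
#'
#' @param mobile,target n x 3 coordinate matrices with matched rows.
#' @return list with `R` (3 x 3 rotation), `t` (translation), `rmsd`, and
#'   `transform(xyz)` applying the fit to arbitrary coordinates.
#' @export
kabsch <- function(mobile, target) {
  stopifnot(nrow(mobile) == nrow(target), ncol(mobile) == 3, ncol(target) == 3)
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  tr <- ct - as.vector(R %*% cm)
  fit <- sweep(mobile %*% t(R), 2, tr, "+")
  list(R = R, t = tr,
       rmsd = sqrt(mean(rowSums((fit - target)^2))),
       transform = function(xyz) sweep(xyz %*% t(R), 2, tr, "+"))
}

.vnorm <- function(v) sqrt(sum(v^2))
.unit <- function(v) v / .vnorm(v)
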