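# Rotation quaternions: construction from axis/angle, application via the
# sandwich product r q r^-1, and recovery of the rotation between two unit
# directions. A rotation by angle theta about unit axis u is encoded as
# r = cos(theta/2) + sin(theta/2) (ux i + uy j + uz k); r and -r encode the
# same rotation (double cover), so constructors canonicalize the sign of the
# real part to be non-negative.

.norm3 <- function(v) sqrt(sum(v^2))

#' Rotation quaternion from axis and angle
#'
#' @param axis Length-3 rotation axis (normalized internally; must be
#'   non-zero).
#' @param angle Rotation angle in radians.
#' @return A unit `quat` with non-negative real part (canonical
#'   representative of the double cover).
#' @examples
#' rotation_quat(c(1, 0, 0), pi)  # = i
#' @export
rotation_quat <- function(axis, angle) {
  stopifnot(is.numeric(axis), length(axis) == 3L, is.finite(angle))
  n <- .norm3(axis)
  if (n == 0) stop("rotation axis must be non-zero", call. = FALSE)
  u <- axis / n
  r <- quat(cos(angle / 2),
            sin(angle / 2) * u[1],
            sin(angle / 2) * u[2],
            sin(angle / 2) * u[3])
  canonical_rotation(r)
}

#' Canonicalize a rotation quaternion's sign
#'
#' Resolves the double cover by negating the quaternion when its real part is
#' negative, so serialized rotations are reproducible.
#'
#' @param r A unit `quat`.
#' @export
canonical_rotation <- function(r) {
  r <- .as_quat(r)
  if (length(r) != 1L) stop("expected a single quaternion", call. = FALSE)
  if (r$a < 0) r <- -r
  r
}

.check_unit_rotation <- function(r) {
  r <- .as_quat(r)
  if (length(r) != 1L) {
    stop("a rotation must be a single quaternion", call. = FALSE)
  }
  dev <- abs(qmod(r) - 1)
  if (dev > .quatst_tol$unit) {
    stop(sprintf(
      "rotation quaternion is not unit norm (|q| deviates by %.3g)", dev),
      call. = FALSE)
  }
  r
}

#' Rotation angle and axis of a rotation quaternion
#'
#' @param r A unit `quat`.
#' @return `rotation_angle`: the angle in `[0, pi]` (radians);
#'   `rotation_axis`: the unit axis (arbitrary for the identity rotation,
#'   where `c(1, 0, 0)` is returned).
#' @rdname rotation-accessors
#' @export
rotation_angle <- function(r) {
  r <- canonical_rotation(.check_unit_rotation(r))
  2 * acos(min(1, max(-1, r$a)))
}

#' @rdname rotation-accessors
#' @export
rotation_axis <- function(r) {
  r <- canonical_rotation(.check_unit_rotation(r))
  v <- c(r$b, r$c, r$d)
  n <- .norm3(v)
  if (n < .quatst_tol$assert) return(c(1, 0, 0))
  v / n
}

#' Apply a rotation to quaternion values
#'
#' Rotates the vector part of `q` by the rotation encoded in the unit
#' quaternion `r` via the sandwich product `r v r^-1`; the real part of `q`
#' is returned unchanged. For unit `r` the inverse equals the conjugate,
#' which is used for numerical stability. Works element-wise on quaternion
#' arrays.
#'
#' @param r A unit rotation `quat`.
#' @param q A `quat` (any shape).
#' @return `q` with its vector part rotated, same shape.
#' @export
qrotate <- function(r, q) {
  r <- .check_unit_rotation(r)
  q <- .as_quat(q)
  v <- quat(0 * q$a, q$b, q$c, q$d)
  rv <- qmul(qmul(r, v), qconj(r))
  quat(q$a, rv$b, rv$c, rv$d)
}

#' Rotation mapping one unit direction onto another
#'
#' Returns the minimal-angle rotation quaternion taking the unit 3-vector
#' `u1` to `u2`: angle `acos(u1 . u2)`, axis along `u1 x u2`. For
#' antiparallel inputs the axis is ambiguous; a deterministic axis
#' orthogonal to `u1` is chosen (the normalized cross product of `u1` with
#' the standard basis vector having the smallest absolute component in
#' `u1`, ties resolved toward the lowest index).
#'
#' @param u1,u2 Unit length-3 vectors (checked to tolerance).
#' @return A unit `quat` `r` with `qrotate(r, pure_quat(u1))` equal to
#'   `pure_quat(u2)`.
#' @export
rotation_between <- function(u1, u2) {
  stopifnot(length(u1) == 3L, length(u2) == 3L)
  for (u in list(u1, u2)) {
    if (abs(.norm3(u) - 1) > .quatst_tol$unit) {
      stop("rotation_between expects unit-length directions", call. = FALSE)
    }
  }
  d <- min(1, max(-1, sum(u1 * u2)))
  cr <- c(u1[2] * u2[3] - u1[3] * u2[2],
          u1[3] * u2[1] - u1[1] * u2[3],
          u1[1] * u2[2] - u1[2] * u2[1])
  ncr <- .norm3(cr)
  if (ncr < .quatst_tol$assert) {
    if (d > 0) return(quat(1, 0, 0, 0))   # identical directions
    # antiparallel: rotate by pi about a deterministic orthogonal axis
    e <- which.min(abs(u1))
    basis <- c(0, 0, 0); basis[e] <- 1
    axis <- c(u1[2] * basis[3] - u1[3] * basis[2],
              u1[3] * basis[1] - u1[1] * basis[3],
              u1[1] * basis[2] - u1[2] * basis[1])
    return(rotation_quat(axis, pi))
  }
  rotation_quat(cr, acos(d))
}

#' Angular distance between two rotations
#'
#' The angle (radians) of the relative rotation `r1 r2^-1`, computed as
#' `2 * acos(|<r1, r2>|)` so the double cover is respected.
#'
#' @param r1,r2 Unit rotation `quat`s.
#' @export
rotation_distance <- function(r1, r2) {
  r1 <- .check_unit_rotation(r1); r2 <- .check_unit_rotation(r2)
  dot <- abs(r1$a * r2$a + r1$b * r2$b + r1$c * r2$c + r1$d * r2$d)
  2 * acos(min(1, dot))
}
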