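# Hamilton quaternion arithmetic on scalars and element-wise on arrays.
#
# A quaternion q = a + b*i + c*j + d*k is stored as four parallel real
# coefficient planes sharing one shape (structure-of-arrays), so that the
# complex planes needed by the Cayley-Dickson Fourier transform can be formed
# without reshuffling memory.

# module-level tolerance configuration
.quatst_tol <- new.env(parent = emptyenv())
.quatst_tol$unit <- 1e-8    # unit-norm admission check for rotation quaternions
.quatst_tol$assert <- 1e-12 # internal consistency assertions

#' Get or set numerical tolerances
#'
#' `unit` is the admissible deviation from unit norm when a rotation
#' quaternion is required; `assert` is the tolerance used by internal
#' consistency checks.
#'
#' @param unit,assert New values; omit both to just query.
#' @return Invisibly, the current tolerance list.
#' @export
quatst_tolerances <- function(unit = NULL, assert = NULL) {
  if (!is.null(unit)) .quatst_tol$unit <- unit
  if (!is.null(assert)) .quatst_tol$assert <- assert
  invisible(list(unit = .quatst_tol$unit, assert = .quatst_tol$assert))
}

.qshape <- function(x) {
  if (is.null(dim(x))) length(x) else dim(x)
}

.shape_str <- function(s) paste(s, collapse = "x")

#' Construct a quaternion (array)
#'
#' Builds a quaternion or an element-wise quaternion array from four real
#' coefficient planes `a + b*i + c*j + d*k`. All planes must share one shape;
#' length-1 planes are recycled to the common shape.
#'
#' @param a Real (scalar) coefficient plane.
#' @param b,c,d Coefficient planes of the `i`, `j`, `k` imaginary basis.
#' @return An object of class `"quat"`: a list with numeric components
#'   `a`, `b`, `c`, `d` of identical shape.
#' @examples
#' quat(1, 2, 3, 4)
#' quat(matrix(0, 2, 2), b = 1)   # constant pure-i 2x2 array
#' @export
quat <- function(a = 0, b = 0, c = 0, d = 0) {
  parts <- list(a = a, b = b, c = c, d = d)
  for (nm in names(parts)) {
    if (!is.numeric(parts[[nm]])) {
      stop("quaternion plane '", nm, "' must be numeric", call. = FALSE)
    }
  }
  sizes <- vapply(parts, length, integer(1))
  ref <- parts[[which.max(sizes)]]
  shape <- .qshape(ref)
  for (nm in names(parts)) {
    p <- parts[[nm]]
    if (length(p) == 1L && !identical(.qshape(p), shape)) {
      p <- if (is.null(dim(ref))) rep(as.numeric(p), length(ref)) else
        array(as.numeric(p), dim = dim(ref))
    } else if (!identical(.qshape(p), shape)) {
      stop("quaternion planes have mismatched shapes: ", .shape_str(shape),
           " vs ", .shape_str(.qshape(p)), call. = FALSE)
    }
    parts[[nm]] <- p * 1.0
  }
  structure(parts, class = "quat")
}

#' @export
is.quat <- function(x) inherits(x, "quat")

.as_quat <- function(x) {
  if (is.quat(x)) return(x)
  if (is.numeric(x) && length(x) == 4L && is.null(dim(x))) {
    return(quat(x[1], x[2], x[3], x[4]))
  }
  stop("cannot interpret object of class '", paste(class(x), collapse = "/"),
       "' as a quaternion", call. = FALSE)
}

#' Pure (vector) quaternion from 3-vectors
#'
#' @param v A length-3 vector or an n x 3 matrix of vector parts.
#' @return A `quat` with zero real plane.
#' @export
pure_quat <- function(v) {
  if (is.null(dim(v))) {
    stopifnot(length(v) == 3L)
    quat(0, v[1], v[2], v[3])
  } else {
    stopifnot(ncol(v) == 3L)
    quat(rep(0, nrow(v)), v[, 1], v[, 2], v[, 3])
  }
}

#' Scalar and vector parts
#'
#' `scalar_part` returns the real coefficient plane; `vec_part` returns the
#' `i`, `j`, `k` coefficients as an n x 3 matrix (flattening any array shape
#' in column-major order).
#'
#' @param q A `quat`.
#' @rdname quat-parts
#' @export
scalar_part <- function(q) .as_quat(q)$a

#' @rdname quat-parts
#' @export
vec_part <- function(q) {
  q <- .as_quat(q)
  cbind(b = as.vector(q$b), c = as.vector(q$c), d = as.vector(q$d))
}

#' @export
dim.quat <- function(x) dim(x$a)

#' @export
length.quat <- function(x) length(x$a)

#' @export
`[.quat` <- function(x, ...) {
  quat(x$a[...], x$b[...], x$c[...], x$d[...])
}

#' @export
print.quat <- function(x, ...) {
  n <- length(x)
  shape <- .shape_str(.qshape(x$a))
  if (n == 1L) {
    cat(sprintf("quaternion: %.6g + %.6gi + %.6gj + %.6gk\n",
                x$a, x$b, x$c, x$d))
  } else {
    cat(sprintf("quaternion array [%s], %d elements\n", shape, n))
    cat(" |q| range:", paste(signif(range(qmod(x)), 6), collapse = " .. "),
        "\n")
  }
  invisible(x)
}

#' @export
`+.quat` <- function(e1, e2) {
  e1 <- .as_quat(e1); e2 <- .as_quat(e2)
  quat(e1$a + e2$a, e1$b + e2$b, e1$c + e2$c, e1$d + e2$d)
}

#' @export
`-.quat` <- function(e1, e2) {
  if (missing(e2)) {
    e1 <- .as_quat(e1)
    return(quat(-e1$a, -e1$b, -e1$c, -e1$d))
  }
  e1 <- .as_quat(e1); e2 <- .as_quat(e2)
  quat(e1$a - e2$a, e1$b - e2$b, e1$c - e2$c, e1$d - e2$d)
}

.broadcast_check <- function(q1, q2) {
  s1 <- .qshape(q1$a); s2 <- .qshape(q2$a)
  if (identical(s1, s2) || length(q1) == 1L || length(q2) == 1L) return()
  stop("quaternion shapes not broadcastable: ", .shape_str(s1), " vs ",
       .shape_str(s2), call. = FALSE)
}

#' Hamilton product
#'
#' Element-wise quaternion multiplication following Hamilton's basis rules
#' (`i^2 = j^2 = k^2 = ijk = -1`, `ij = k`, `ji = -k`, ...). The product is
#' non-commutative. Operands must share a shape, or one of them must be a
#' single quaternion, which is broadcast.
#'
#' @param q1,q2 `quat` objects (or length-4 numeric coefficient vectors).
#' @return The product `q1 q2` as a `quat`.
#' @examples
#' i <- quat(0, 1, 0, 0); j <- quat(0, 0, 1, 0)
#' qmul(i, j)  # = k
#' qmul(j, i)  # = -k
#' @export
qmul <- function(q1, q2) {
  q1 <- .as_quat(q1); q2 <- .as_quat(q2)
  .broadcast_check(q1, q2)
  a1 <- q1$a; b1 <- q1$b; c1 <- q1$c; d1 <- q1$d
  a2 <- q2$a; b2 <- q2$b; c2 <- q2$c; d2 <- q2$d
  quat(a1 * a2 - b1 * b2 - c1 * c2 - d1 * d2,
       a1 * b2 + b1 * a2 + c1 * d2 - d1 * c2,
       a1 * c2 - b1 * d2 + c1 * a2 + d1 * b2,
       a1 * d2 + b1 * c2 - c1 * b2 + d1 * a2)
}

#' Conjugate, norm, and inverse
#'
#' `qconj` negates the vector part; `qmod` is the Euclidean norm
#' `sqrt(a^2 + b^2 + c^2 + d^2)`; `qinv` is the multiplicative inverse
#' `conj(q) / |q|^2`, defined only for non-zero quaternions.
#'
#' @param q A `quat`.
#' @rdname quat-conj
#' @export
qconj <- function(q) {
  q <- .as_quat(q)
  quat(q$a, -q$b, -q$c, -q$d)
}

#' @rdname quat-conj
#' @export
qmod <- function(q) {
  q <- .as_quat(q)
  sqrt(q$a^2 + q$b^2 + q$c^2 + q$d^2)
}

#' @rdname quat-conj
#' @export
qinv <- function(q) {
  q <- .as_quat(q)
  n2 <- q$a^2 + q$b^2 + q$c^2 + q$d^2
  if (any(n2 == 0)) {
    stop("cannot invert the zero quaternion", call. = FALSE)
  }
  quat(q$a / n2, -q$b / n2, -q$c / n2, -q$d / n2)
}

# real-scalar multiplication
.qscale <- function(q, s) quat(q$a * s, q$b * s, q$c * s, q$d * s)
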