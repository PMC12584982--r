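# Two-dimensional quaternion-domain discrete Fourier transform via
# Cayley-Dickson decomposition.
#
# Writing q = a + bi + cj + dk = alpha + beta j with complex alpha = a + bi
# and beta = c + di, and noting that e^{-i t}(alpha + beta j) =
# (e^{-i t} alpha) + (e^{-i t} beta) j, the forward transform reduces to two
# standard complex 2D FFTs. The result is exactly the LEFT one-sided
# quaternion DFT with transform axis i:
#   F(u, v) = sum_{m,n} exp(-i 2 pi (u m / R + v n / C)) Q(m, n)
# with the exponential multiplying from the left. Forward is unnormalized;
# the inverse carries the 1/(R C) factor.

#' Cayley-Dickson decomposition
#'
#' Splits a quaternion array `q = a + bi + cj + dk` into the complex pair
#' `alpha = a + bi`, `beta = c + di` (so `q = alpha + beta j`), and back.
#'
#' @param q A `quat`.
#' @return `cayley_dickson`: list with complex arrays `alpha`, `beta`;
#'   `from_cayley_dickson`: the reassembled `quat`.
#' @rdname cayley-dickson
#' @export
cayley_dickson <- function(q) {
  q <- .as_quat(q)
  list(alpha = q$a + 1i * q$b, beta = q$c + 1i * q$d)
}

#' @param alpha,beta Complex arrays of one shape.
#' @rdname cayley-dickson
#' @export
from_cayley_dickson <- function(alpha, beta) {
  quat(Re(alpha), Im(alpha), Re(beta), Im(beta))
}

.grid_q <- function(x) {
  if (inherits(x, "quat_grid")) x$q else .as_quat(x)
}

.check_2d_finite <- function(q, what = "input") {
  if (is.null(dim(q$a)) || length(dim(q$a)) != 2L) {
    stop(what, " must be a 2D quaternion array", call. = FALSE)
  }
  if (any(!is.finite(q$a)) || any(!is.finite(q$b)) ||
      any(!is.finite(q$c)) || any(!is.finite(q$d))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  q
}

#' Forward 2D quaternion Fourier transform
#'
#' Computes the left one-sided quaternion-domain 2D DFT (axis `i`) of a
#' quaternion matrix via the Cayley-Dickson recipe: complex-FFT the `alpha`
#' and `beta` planes and reassemble `F = F_alpha + F_beta j`. The DC term
#' sits at index (1, 1) (standard FFT ordering); the forward transform is
#' unnormalized.
#'
#' @param q A 2D `quat` or a `quat_grid` (occupancy is ignored by the
#'   transform; fill the grid first if desired).
#' @return The spectrum as a 2D `quat` with attribute `domain =
#'   "frequency"`.
#' @seealso [iqfft2()]
#' @export
qfft2 <- function(q) {
  q <- .check_2d_finite(.grid_q(q))
  cd <- cayley_dickson(q)
  out <- from_cayley_dickson(stats::fft(cd$alpha), stats::fft(cd$beta))
  attr(out, "domain") <- "frequency"
  out
}

#' Inverse 2D quaternion Fourier transform
#'
#' Inverse of [qfft2()]; carries the `1/(R*C)` normalization so that
#' `iqfft2(qfft2(q))` recovers `q`.
#'
#' @param f A 2D `quat` spectrum.
#' @return A 2D `quat` in the spatial domain.
#' @export
iqfft2 <- function(f) {
  f <- .check_2d_finite(.grid_q(f), "spectrum")
  cd <- cayley_dickson(f)
  n <- length(cd$alpha)
  out <- from_cayley_dickson(stats::fft(cd$alpha, inverse = TRUE) / n,
                             stats::fft(cd$beta, inverse = TRUE) / n)
  attr(out, "domain") <- "spatial"
  out
}
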