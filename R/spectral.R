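# Spectral filtering, kernel and mask construction, FFT-based convolution
# with real masks, and biconvolution with quaternion-valued masks.
#
# All convolutions are circular (FFT-native). Real masks commute with
# quaternion values, so real-mask convolution is computed plane-wise with
# complex FFTs. Quaternion masks use the Cayley-Dickson identities for the
# left and right products:
#   (C1 + C2 j)(A + B j) = (C1 A - C2 conj(B)) + (C1 B + C2 conj(A)) j
#   (A + B j)(C1 + C2 j) = (A C1 - B conj(C2)) + (A C2 + B conj(C1)) j
# where each term becomes one complex FFT convolution.

#' Built-in real convolution kernels
#'
#' The 3 x 3 sharpening and edge-detection kernels
#' \deqn{K_{sharp} = \begin{pmatrix} 0 & -1 & 0 \\ -1 & 5 & -1 \\
#'   0 & -1 & 0 \end{pmatrix}, \quad
#'   K_{edge} = \begin{pmatrix} -1 & -1 & -1 \\ -1 & 8 & -1 \\
#'   -1 & -1 & -1 \end{pmatrix}}
#' returned as real-valued `quat` matrices (zero imaginary planes).
#'
#' @return A 3 x 3 `quat`.
#' @rdname builtin-kernels
#' @export
kernel_sharpen <- function() {
  quat(matrix(c(0, -1, 0,
                -1, 5, -1,
                0, -1, 0), 3, 3, byrow = TRUE))
}

#' @rdname builtin-kernels
#' @export
kernel_edge <- function() {
  quat(matrix(c(-1, -1, -1,
                -1, 8, -1,
                -1, -1, -1), 3, 3, byrow = TRUE))
}

#' Rotation-quaternion edge-detection kernel pair
#'
#' Builds the 3 x 3 left and right quaternion kernels
#' `KL = [r 0 r^-1]` (each row) and `KR = [r^-1 0 r]` (each row) from a unit
#' rotation quaternion `r`. Biconvolution with masks embedding this pair
#' performs edge detection in the subspace orthogonal to the rotation axis:
#' the output component orthogonal to the axis responds only to changes
#' orthogonal to the axis.
#'
#' @param r A unit rotation `quat`.
#' @return List with 3 x 3 `quat` components `KL` and `KR`.
#' @export
rotation_kernels <- function(r) {
  r <- .check_unit_rotation(r)
  ri <- qinv(r)
  z <- matrix(0, 3, 3)
  kl <- quat(z, z, z, z)
  kr <- quat(z, z, z, z)
  for (nm in c("a", "b", "c", "d")) {
    kl[[nm]][, 1] <- r[[nm]]
    kl[[nm]][, 3] <- ri[[nm]]
    kr[[nm]][, 1] <- ri[[nm]]
    kr[[nm]][, 3] <- r[[nm]]
  }
  list(KL = kl, KR = kr)
}

#' Embed a kernel into a grid-sized mask matrix
#'
#' Places a small `k1 x k2` kernel into an `rows x cols` mask, wrap-around
#' centred at the FFT origin so that FFT convolution with the mask equals
#' circular spatial convolution with the kernel centred on each cell (no
#' half-kernel shift).
#'
#' @param kernel A `quat` matrix (or plain numeric matrix, treated as
#'   real-valued).
#' @param rows,cols Mask dimensions; must be at least the kernel size.
#' @return An `rows x cols` `quat` mask.
#' @export
embed_kernel <- function(kernel, rows, cols) {
  if (is.matrix(kernel)) kernel <- quat(kernel)
  kernel <- .as_quat(kernel)
  kd <- dim(kernel$a)
  if (is.null(kd)) stop("kernel must be a matrix", call. = FALSE)
  if (kd[1] > rows || kd[2] > cols) {
    stop(sprintf("kernel (%dx%d) larger than grid (%dx%d)",
                 kd[1], kd[2], rows, cols), call. = FALSE)
  }
  ctr <- (kd + 1L) %/% 2L  # centre element (upper-left of centre for even)
  z <- matrix(0, rows, cols)
  mask <- quat(z, z, z, z)
  for (s in seq_len(kd[1])) {
    for (t in seq_len(kd[2])) {
      rr <- ((s - ctr[1]) %% rows) + 1L
      cc <- ((t - ctr[2]) %% cols) + 1L
      for (nm in c("a", "b", "c", "d")) {
        mask[[nm]][rr, cc] <- mask[[nm]][rr, cc] + kernel[[nm]][s, t]
      }
    }
  }
  mask
}

# complex circular convolution via FFT
.cconv2 <- function(f, g) {
  stats::fft(stats::fft(f) * stats::fft(g), inverse = TRUE) / length(f)
}

# left quaternion circular convolution (M * X), both full-size quats
.qconv_left <- function(m, x) {
  cm <- cayley_dickson(m); cx <- cayley_dickson(x)
  alpha <- .cconv2(cm$alpha, cx$alpha) - .cconv2(cm$beta, Conj(cx$beta))
  beta <- .cconv2(cm$alpha, cx$beta) + .cconv2(cm$beta, Conj(cx$alpha))
  from_cayley_dickson(alpha, beta)
}

# right quaternion circular convolution (X * M)
.qconv_right <- function(x, m) {
  cm <- cayley_dickson(m); cx <- cayley_dickson(x)
  alpha <- .cconv2(cx$alpha, cm$alpha) - .cconv2(cx$beta, Conj(cm$beta))
  beta <- .cconv2(cx$alpha, cm$beta) + .cconv2(cx$beta, Conj(cm$alpha))
  from_cayley_dickson(alpha, beta)
}

#' Spectral filtering of a quaternion matrix
#'
#' Transforms to the frequency domain with [qfft2()], zeroes the selected
#' radial frequency bands, and transforms back. Frequency cells are ranked
#' by the centred radial frequency
#' `rho(u, v) = sqrt((u'/R)^2 + (v'/C)^2)` (`u'`, `v'` signed centred
#' indices); `lowpass` removes the `n_components` distinct highest-`rho`
#' bands, `highpass` the `n_components` distinct lowest (the DC band
#' included). Banding keeps conjugate-symmetric cell pairs together.
#'
#' @param q A 2D `quat` or `quat_grid`.
#' @param mode `"lowpass"` or `"highpass"`.
#' @param n_components Number of distinct radial bands to remove (>= 0).
#' @return The filtered quaternion matrix (2D `quat`); if `q` was a
#'   `quat_grid`, a grid with the same occupancy and edges.
#' @export
spectral_filter <- function(q, mode = c("lowpass", "highpass"),
                            n_components) {
  mode <- match.arg(mode)
  stopifnot(n_components >= 0)
  was_grid <- inherits(q, "quat_grid")
  qq <- .check_2d_finite(.grid_q(q))
  R <- nrow(qq$a); C <- ncol(qq$a)
  u <- 0:(R - 1); u <- ifelse(u <= R %/% 2, u, u - R)
  v <- 0:(C - 1); v <- ifelse(v <= C %/% 2, v, v - C)
  rho <- outer((u / R)^2, (v / C)^2, `+`)
  band <- round(sqrt(rho), 10)
  levels <- sort(unique(as.vector(band)))
  if (n_components > length(levels)) {
    stop(sprintf("n_components = %d exceeds the %d available frequency bands",
                 n_components, length(levels)), call. = FALSE)
  }
  drop_levels <- if (mode == "lowpass") {
    utils::tail(levels, n_components)
  } else {
    utils::head(levels, n_components)
  }
  f <- qfft2(qq)
  kill <- band %in% drop_levels
  for (nm in c("a", "b", "c", "d")) f[[nm]][kill] <- 0
  out <- iqfft2(f)
  if (was_grid) {
    q$q <- out
    q
  } else out
}

#' Convolution with a real-valued kernel
#'
#' Circular convolution of a quaternion matrix with a real kernel, computed
#' by FFT (real masks commute with quaternion values, so plane-wise complex
#' FFT convolution is exact). With `vector_only = TRUE` (default, matching
#' the use of the model where the real plane is sequencing depth rather
#' than signal) the real plane passes through unchanged and only the
#' vector planes are convolved.
#'
#' @param q A 2D `quat` or `quat_grid`.
#' @param kernel Real kernel: plain numeric matrix or real-valued `quat`
#'   (e.g. [kernel_edge()]).
#' @param vector_only Convolve only the `i`, `j`, `k` planes?
#' @return Same container type as `q`.
#' @export
convolve_real <- function(q, kernel, vector_only = TRUE) {
  was_grid <- inherits(q, "quat_grid")
  qq <- .check_2d_finite(.grid_q(q))
  if (is.matrix(kernel)) kernel <- quat(kernel)
  kernel <- .as_quat(kernel)
  if (any(kernel$b != 0) || any(kernel$c != 0) || any(kernel$d != 0)) {
    stop("convolve_real expects a real-valued kernel; use biconvolve() ",
         "for quaternion kernels", call. = FALSE)
  }
  R <- nrow(qq$a); C <- ncol(qq$a)
  mask <- embed_kernel(kernel, R, C)
  fm <- stats::fft(mask$a)
  planes <- c(if (!vector_only) "a", "b", "c", "d")
  out <- qq
  for (nm in planes) {
    out[[nm]] <- Re(stats::fft(stats::fft(qq[[nm]]) * fm,
                               inverse = TRUE)) / (R * C)
  }
  if (was_grid) {
    q$q <- out
    q
  } else out
}

#' Biconvolution with left and right quaternion masks
#'
#' Computes the circular biconvolution `ML * X * MR` with quaternion
#' products taken in the stated left/right order, mirroring the sandwich
#' form `r q r^-1` of quaternion rotation. Each side is evaluated through
#' the Cayley-Dickson identities as four complex FFT convolutions, which is
#' exactly equal to the spatial double convolution.
#'
#' With `vector_only = TRUE` the real plane of `X` is excluded from the
#' convolution and passed through unchanged; scalar components generated by
#' the quaternion products of the vector planes are discarded (rotation
#' kernel pairs generate none).
#'
#' @param ml,mr Mask matrices (`quat`, same shape as `q`), e.g. built with
#'   [embed_kernel()] from [rotation_kernels()].
#' @param q A 2D `quat` or `quat_grid`.
#' @param vector_only Convolve only the vector planes?
#' @return Same container type as `q`.
#' @export
biconvolve <- function(ml, q, mr, vector_only = TRUE) {
  was_grid <- inherits(q, "quat_grid")
  qq <- .check_2d_finite(.grid_q(q))
  ml <- .check_2d_finite(.as_quat(ml), "left mask")
  mr <- .check_2d_finite(.as_quat(mr), "right mask")
  if (!identical(dim(ml$a), dim(qq$a)) || !identical(dim(mr$a), dim(qq$a))) {
    stop(sprintf(
      "mask shapes (%s, %s) must match the input shape (%s); embed kernels with embed_kernel()",
      .shape_str(dim(ml$a)), .shape_str(dim(mr$a)), .shape_str(dim(qq$a))),
      call. = FALSE)
  }
  xin <- if (vector_only) quat(0 * qq$a, qq$b, qq$c, qq$d) else qq
  out <- .qconv_right(.qconv_left(ml, xin), mr)
  if (vector_only) out$a <- qq$a
  if (was_grid) {
    q$q <- out
    q
  } else out
}

#' Read or write a quaternion kernel CSV
#'
#' Kernel files are CSVs with columns `row,col,a,b,c,d`, one line per
#' kernel cell.
#'
#' @param path CSV path.
#' @rdname kernel-io
#' @export
read_kernel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path)
  need <- c("row", "col", "a", "b", "c", "d")
  if (!all(need %in% names(tab))) {
    stop("kernel CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  R <- max(tab$row); C <- max(tab$col)
  mk <- function(v) {
    m <- matrix(0, R, C)
    m[cbind(tab$row, tab$col)] <- v
    m
  }
  quat(mk(tab$a), mk(tab$b), mk(tab$c), mk(tab$d))
}

#' @param kernel A `quat` matrix.
#' @rdname kernel-io
#' @export
write_kernel <- function(kernel, path) {
  kernel <- .as_quat(kernel)
  kd <- dim(kernel$a)
  df <- data.frame(row = rep(seq_len(kd[1]), times = kd[2]),
                   col = rep(seq_len(kd[2]), each = kd[1]),
                   a = as.vector(kernel$a), b = as.vector(kernel$b),
                   c = as.vector(kernel$c), d = as.vector(kernel$d))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
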