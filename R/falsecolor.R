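# False-colour rendering: the unit vector part of each quaternion maps to
# RGB through a sigmoid, the real part (sequencing depth) to opacity through
# a quantile-capped log rescale, so locations with no reads are fully
# transparent and the deepest-sequenced (least uncertain) locations fully
# opaque.

.sigmoid2 <- function(x) 1 / (1 + exp(-2 * x))

#' Map a quaternion grid to an RGBA image
#'
#' RGB channels are the sigmoid-squashed vector coefficients
#' `sigma(x) = 1 / (1 + exp(-2x))` (so a coefficient of 0 renders as 0.5
#' and the unit-length bound maps into (0.12, 0.88)). Opacity is derived
#' from the real part over non-empty cells: values are capped
#' (winsorized) at the `alpha_quantile` quantile, log-transformed as
#' `log(x - min(x) + 1)`, and linearly rescaled to `[0, 1]`; a real part
#' of 0 therefore renders fully transparent and cells at or above the
#' quantile cap fully opaque. Empty cells get neutral grey RGB (invisible
#' at alpha 0).
#'
#' @param grid A `quat_grid` (or 2D `quat`).
#' @param alpha_quantile Winsorization quantile for the opacity channel,
#'   in (0, 1]; default 0.9.
#' @return An `rows x cols x 4` numeric array (R, G, B, A) in `[0, 1]`,
#'   class `"rgba_image"`.
#' @export
to_rgba <- function(grid, alpha_quantile = 0.9) {
  stopifnot(alpha_quantile > 0, alpha_quantile <= 1)
  grid <- as_quat_grid(grid)
  q <- grid$q
  R <- nrow(q$a); C <- ncol(q$a)
  nonempty <- grid$occupancy != "empty"
  img <- array(0, c(R, C, 4))
  img[, , 1] <- .sigmoid2(q$b)
  img[, , 2] <- .sigmoid2(q$c)
  img[, , 3] <- .sigmoid2(q$d)
  alpha <- matrix(0, R, C)
  if (any(nonempty)) {
    vals <- q$a[nonempty]
    cap <- stats::quantile(vals, alpha_quantile, names = FALSE)
    capped <- pmin(vals, cap)
    y <- log(capped - min(capped) + 1)
    if (max(y) == min(y)) {
      warning("all real parts equal after capping: opacity set to 1",
              call. = FALSE)
      alpha[nonempty] <- 1
    } else {
      alpha[nonempty] <- (y - min(y)) / (max(y) - min(y))
    }
  }
  img[, , 4] <- alpha
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[!nonempty] <- 0.5
    img[, , ch] <- plane
  }
  structure(img, class = "rgba_image")
}

#' @export
print.rgba_image <- function(x, ...) {
  cat(sprintf("rgba_image: %d x %d, alpha range %.3f .. %.3f\n",
              dim(x)[1], dim(x)[2], min(x[, , 4]), max(x[, , 4])))
  invisible(x)
}

#' Write an RGBA image as 8-bit PNG
#'
#' Values are quantized to `round(255 * v)` by the PNG encoder.
#'
#' @param img An `rgba_image` (or plain `R x C x 4` array in `[0, 1]`).
#' @param path Output path.
#' @export
write_png <- function(img, path) {
  a <- unclass(img)
  stopifnot(is.array(a), length(dim(a)) == 3L, dim(a)[3] == 4L)
  if (min(a) < 0 || max(a) > 1) {
    stop("image values must lie in [0, 1]", call. = FALSE)
  }
  png::writePNG(a, target = path)
  invisible(path)
}

#' Write a difference-length map as grayscale PNG
#'
#' Linearly rescales the map to `[0, 1]` (a constant map renders black)
#' and writes an 8-bit grayscale PNG.
#'
#' @param map Non-negative numeric matrix, e.g. from
#'   [difference_length()].
#' @param path Output path.
#' @export
write_gray_png <- function(map, path) {
  m <- as.matrix(map)
  rng <- range(m)
  g <- if (diff(rng) == 0) m * 0 else (m - rng[1]) / diff(rng)
  png::writePNG(g, target = path)
  invisible(path)
}
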