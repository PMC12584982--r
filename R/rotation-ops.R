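# Grid-level rotation analyses: rotating vector parts, difference-length
# maps, association-axis probes, and estimation of a perturbation rotation
# from two sets of locations.

#' Rotate the vector parts of a quaternion grid
#'
#' Applies `r v r^-1` to the vector part of every cell; real parts and
#' occupancy are unchanged (empty cells hold the zero vector, which is
#' rotation-invariant).
#'
#' @param grid A `quat_grid` (or 2D `quat`).
#' @param r Unit rotation `quat`.
#' @return A `quat_grid` of the same shape.
#' @export
rotate_grid <- function(grid, r) {
  grid <- as_quat_grid(grid)
  grid$q <- qrotate(r, grid$q)
  grid
}

#' Difference-length map
#'
#' Per-cell Euclidean length of the vector part of `q - qrot` (real parts
#' ignored). Cells whose vector part is parallel to the rotation axis are
#' unchanged by the rotation and map to 0; a unit vector orthogonal to the
#' axis under a rotation by `theta` maps to the chord length
#' `2 |sin(theta/2)|`.
#'
#' @param q,qrot `quat_grid`s (or 2D `quat`s) of one shape, the original
#'   and rotated matrices.
#' @return A non-negative numeric matrix with attributes `occupancy` (from
#'   `q` when available) and `rotation` (from `qrot`'s metadata when
#'   available).
#' @export
difference_length <- function(q, qrot) {
  occ <- if (inherits(q, "quat_grid")) q$occupancy else NULL
  qq <- .grid_q(q); qr <- .grid_q(qrot)
  if (!identical(.qshape(qq$a), .qshape(qr$a))) {
    stop("shape mismatch: ", .shape_str(.qshape(qq$a)), " vs ",
         .shape_str(.qshape(qr$a)), call. = FALSE)
  }
  out <- sqrt((qq$b - qr$b)^2 + (qq$c - qr$c)^2 + (qq$d - qr$d)^2)
  if (!is.null(occ)) attr(out, "occupancy") <- occ
  out
}

#' Probe a grid for association with an axis
#'
#' Rotates the grid about `axis` by `angle` and returns the
#' difference-length map. Low values mark locations whose relative
#' expression profile aligns (or anti-aligns) with the axis: e.g. the axis
#' `i + j + k` probes for locations where all three vector features move
#' together.
#'
#' @param grid A `quat_grid` (or 2D `quat`).
#' @param axis Length-3 axis (need not be normalized).
#' @param angle Rotation angle in radians (default `pi`).
#' @return A difference-length matrix (see [difference_length()]), with
#'   the rotation stored in attribute `rotation`.
#' @export
association_probe <- function(grid, axis, angle = pi) {
  r <- rotation_quat(axis, angle)
  out <- difference_length(grid, rotate_grid(grid, r))
  attr(out, "rotation") <- r
  out
}

.directions_matrix <- function(x, what = "set") {
  v <- if (inherits(x, "location_quats")) vec_part(x$q)
  else if (is.quat(x)) vec_part(x)
  else as.matrix(x)
  if (ncol(v) != 3L) stop(what, " must provide 3D directions", call. = FALSE)
  len <- sqrt(rowSums(v^2))
  keep <- len > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-length direction(s) dropped from ", what,
            call. = FALSE)
  }
  v[keep, , drop = FALSE] / len[keep]
}

#' Estimate a perturbation rotation between two location sets
#'
#' Computes the average unit direction of each set's quaternion vector
#' parts (coefficient-wise chordal mean, renormalized), and returns the
#' rotation taking the first mean onto the second. To assess how well a
#' single rotation models the perturbation, rotation quaternions are also
#' computed between pairs of members (all pairs, or a seeded random subset
#' without replacement when there are more than `n_pairs`); their
#' variability is summarized as `dispersion = 1 - ||mean of sign-aligned
#' unit rotation quaternions||`, which is 0 when all pairwise rotations are
#' identical and grows toward 1 as they disagree.
#'
#' @param a,b The two sets: `location_quats`, `quat`s, or n x 3 matrices
#'   of vector parts (normalized internally; zero rows dropped).
#' @param n_pairs Maximum number of pairs used for the dispersion (default
#'   2000; capped at `nA * nB`).
#' @param seed Seed for the pair subsample.
#' @return A `rotation_estimate`: list with `r` (unit rotation `quat`),
#'   `dispersion` in `[0, 1]`, and `n_pairs`.
#' @export
estimate_perturbation_rotation <- function(a, b, n_pairs = 2000L,
                                           seed = NULL) {
  va <- .directions_matrix(a, "set A")
  vb <- .directions_matrix(b, "set B")
  if (!nrow(va) || !nrow(vb)) stop("both sets must be non-empty",
                                   call. = FALSE)
  stopifnot(n_pairs >= 1L)
  mean_dir <- function(v, lab) {
    m <- colMeans(v)
    if (.norm3(m) < 1e-8) {
      stop("directions in set ", lab, " cancel (mean vector length < 1e-8);",
           " inspect the subset for opposing profiles", call. = FALSE)
    }
    m / .norm3(m)
  }
  ma <- mean_dir(va, "A"); mb <- mean_dir(vb, "B")
  r <- rotation_between(ma, mb)

  total <- nrow(va) * nrow(vb)
  m <- min(as.integer(n_pairs), total)
  pair_idx <- if (m < total) {
    .with_seed(seed, sample.int(total, m))
  } else seq_len(total)
  ia <- ((pair_idx - 1L) %% nrow(va)) + 1L
  ib <- ((pair_idx - 1L) %/% nrow(va)) + 1L
  quats <- matrix(0, m, 4)
  for (t in seq_len(m)) {
    rp <- rotation_between(va[ia[t], ], vb[ib[t], ])
    quats[t, ] <- c(rp$a, rp$b, rp$c, rp$d)
  }
  # resolve the double cover toward the first sample before averaging
  ref <- quats[1, ]
  flip <- quats %*% ref < 0
  quats[flip, ] <- -quats[flip, , drop = FALSE]
  dispersion <- 1 - sqrt(sum(colMeans(quats)^2))
  structure(list(r = r, dispersion = dispersion, n_pairs = m),
            class = "rotation_estimate")
}

#' @export
print.rotation_estimate <- function(x, ...) {
  cat(sprintf(
    "rotation_estimate: angle %.3f rad about (%.3f, %.3f, %.3f); dispersion %.4f (%d pairs)\n",
    rotation_angle(x$r), rotation_axis(x$r)[1], rotation_axis(x$r)[2],
    rotation_axis(x$r)[3], x$dispersion, x$n_pairs))
  invisible(x)
}

#' Apply an estimated perturbation rotation to grid cells
#'
#' Rotates the vector parts of the masked cells by the estimated rotation,
#' predicting the perturbation's impact on those locations; unmasked cells
#' are returned bit-identical.
#'
#' @param grid A `quat_grid` (or 2D `quat`).
#' @param est A `rotation_estimate` (or unit rotation `quat`).
#' @param mask Logical matrix of the grid shape selecting cells; `NULL`
#'   (default) rotates every cell.
#' @return A `quat_grid`.
#' @export
apply_perturbation <- function(grid, est, mask = NULL) {
  grid <- as_quat_grid(grid)
  r <- if (inherits(est, "rotation_estimate")) est$r else .as_quat(est)
  if (is.null(mask)) return(rotate_grid(grid, r))
  stopifnot(is.logical(mask), identical(dim(mask), dim(grid$occupancy)))
  if (!any(mask)) {
    warning("empty mask: grid returned unchanged", call. = FALSE)
    return(grid)
  }
  rotated <- qrotate(r, grid$q)
  for (nm in c("b", "c", "d")) grid$q[[nm]][mask] <- rotated[[nm]][mask]
  grid
}
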