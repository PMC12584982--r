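# Independent oracles used across the suite. These deliberately avoid the
# package's own vectorized code paths: plain loops, matrix representations,
# and closed-form geometry.

qvec <- function(q) c(q$a, q$b, q$c, q$d)

rand_quat <- function(n = 1L) {
  quat(stats::rnorm(n), stats::rnorm(n), stats::rnorm(n), stats::rnorm(n))
}

rand_unit3 <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# 4x4 left-multiplication matrix representation of a quaternion: the
# Hamilton product q1 q2 equals L(q1) %*% coefficients(q2).
left_mult_matrix <- function(q) {
  a <- q$a; b <- q$b; c <- q$c; d <- q$d
  matrix(c(a, -b, -c, -d,
           b,  a, -d,  c,
           c,  d,  a, -b,
           d, -c,  b,  a), 4, 4, byrow = TRUE)
}

# Rodrigues 3x3 rotation matrix for angle about unit axis
rodrigues_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Brute-force left-sided quaternion 2D DFT with transform axis i:
# F(u,v) = sum_{m,n} exp(-i 2 pi (u m / R + v n / C)) Q(m,n),
# the exponential multiplying from the left. O((RC)^2) double sum.
brute_qdft2 <- function(q) {
  R <- nrow(q$a); C <- ncol(q$a)
  out <- quat(matrix(0, R, C), matrix(0, R, C), matrix(0, R, C),
              matrix(0, R, C))
  for (u in 0:(R - 1)) for (v in 0:(C - 1)) {
    acc <- quat(0, 0, 0, 0)
    for (m in 0:(R - 1)) for (n in 0:(C - 1)) {
      phi <- 2 * pi * (u * m / R + v * n / C)
      w <- quat(cos(phi), -sin(phi), 0, 0)  # exp(-i phi)
      acc <- acc + qmul(w, quat(q$a[m + 1, n + 1], q$b[m + 1, n + 1],
                                q$c[m + 1, n + 1], q$d[m + 1, n + 1]))
    }
    for (nm in c("a", "b", "c", "d")) out[[nm]][u + 1, v + 1] <- acc[[nm]]
  }
  out
}

# Spatial circular convolution oracles over a small kernel given as a
# quat with odd dimensions (centre at the middle element). side = "left"
# computes K * X, "right" computes X * K.
spatial_qconv <- function(kernel, x, side = c("left", "right")) {
  side <- match.arg(side)
  R <- nrow(x$a); C <- ncol(x$a)
  kd <- dim(kernel$a)
  off_r <- seq_len(kd[1]) - (kd[1] + 1L) %/% 2L
  off_c <- seq_len(kd[2]) - (kd[2] + 1L) %/% 2L
  out <- quat(matrix(0, R, C), matrix(0, R, C), matrix(0, R, C),
              matrix(0, R, C))
  for (m in 1:R) for (n in 1:C) {
    acc <- quat(0, 0, 0, 0)
    for (s in seq_len(kd[1])) for (t in seq_len(kd[2])) {
      kq <- quat(kernel$a[s, t], kernel$b[s, t], kernel$c[s, t],
                 kernel$d[s, t])
      mm <- ((m - 1L - off_r[s]) %% R) + 1L
      nn <- ((n - 1L - off_c[t]) %% C) + 1L
      xq <- quat(x$a[mm, nn], x$b[mm, nn], x$c[mm, nn], x$d[mm, nn])
      acc <- acc + if (side == "left") qmul(kq, xq) else qmul(xq, kq)
    }
    for (nm in c("a", "b", "c", "d")) out[[nm]][m, n] <- acc[[nm]]
  }
  out
}

spatial_biconv <- function(kl, x, kr) {
  spatial_qconv(kr, spatial_qconv(kl, x, "left"), "right")
}

max_abs_diff <- function(q1, q2) {
  max(abs(q1$a - q2$a), abs(q1$b - q2$b), abs(q1$c - q2$c),
      abs(q1$d - q2$d))
}

rel_diff <- function(q1, q2) {
  scale <- max(qmod(q1), 1e-12)
  max_abs_diff(q1, q2) / scale
}

# two-domain vertical-boundary quaternion field for selectivity fixtures
two_domain_field <- function(vA, vB, rows = 6, cols = 6) {
  b <- matrix(rep(ifelse(seq_len(cols) <= cols / 2, vA[1], vB[1]),
                  each = rows), rows, cols)
  cc <- matrix(rep(ifelse(seq_len(cols) <= cols / 2, vA[2], vB[2]),
                   each = rows), rows, cols)
  d <- matrix(rep(ifelse(seq_len(cols) <= cols / 2, vA[3], vB[3]),
                  each = rows), rows, cols)
  quat(matrix(0, rows, cols), b, cc, d)
}

# directions spread on the great circle orthogonal to the planted axis
# (the perturbation acts on states away from its invariant axis)
planted_sets <- function(axis, theta, n = 50, noise_deg = 0, seed = 7) {
  set.seed(seed)
  axis <- axis / sqrt(sum(axis^2))
  seed_v <- rnorm(3)
  u0 <- seed_v - sum(seed_v * axis) * axis
  u0 <- u0 / sqrt(sum(u0^2))
  spread <- runif(n, -pi / 3, pi / 3)
  a <- t(vapply(spread, function(s) {
    rodrigues_matrix(axis, s) %*% u0
  }, numeric(3)))
  rstar <- rotation_quat(axis, theta)
  b <- t(apply(a, 1, function(u) {
    w <- rodrigues_matrix(axis, theta) %*% u
    if (noise_deg > 0) {
      w <- rodrigues_matrix(rnorm(3), runif(1, 0, noise_deg * pi / 180)) %*% w
    }
    w / sqrt(sum(w^2))
  }))
  list(a = a, b = b, rstar = rstar)
}
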