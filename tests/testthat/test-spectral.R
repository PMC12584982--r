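test_that("built-in kernels match their printed definitions", {
  ks <- kernel_sharpen()
  ke <- kernel_edge()
  expect_equal(ks$a, matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3, 3,
                            byrow = TRUE))
  expect_equal(ke$a, matrix(c(-1, -1, -1, -1, 8, -1, -1, -1, -1), 3, 3,
                            byrow = TRUE))
  expect_equal(ks$a[2, 2], 5)
  expect_equal(ke$a[2, 2], 8)
  expect_true(all(ks$b == 0) && all(ke$b == 0))
  expect_equal(sum(ke$a), 0)  # edge kernel sums to zero
})

test_that("rotation kernel pair has the sandwich structure", {
  r <- rotation_quat(c(1, 0, 0), pi)  # r = i, pure unit, so r^-1 = -r
  ks <- rotation_kernels(r)
  for (row in 1:3) {
    expect_equal(qvec(ks$KL[row, 1]), c(0, 1, 0, 0))
    expect_equal(qvec(ks$KL[row, 3]), c(0, -1, 0, 0))
    expect_equal(qvec(ks$KR[row, 1]), c(0, -1, 0, 0))
    expect_equal(qvec(ks$KR[row, 3]), c(0, 1, 0, 0))
    expect_equal(qvec(ks$KL[row, 2]), c(0, 0, 0, 0))  # centre column zero
    expect_equal(qvec(ks$KR[row, 2]), c(0, 0, 0, 0))
  }
  # r^-1 column agrees with the quaternion inverse
  rq <- rotation_quat(c(1, 2, -1), 0.7)
  ks2 <- rotation_kernels(rq)
  expect_equal(qvec(ks2$KL[1, 3]), qvec(qinv(rq)), tolerance = 1e-12)
  ident <- rotation_kernels(quat(1, 0, 0, 0))
  expect_equal(qvec(ident$KL[2, 1]), c(1, 0, 0, 0))
  expect_error(rotation_kernels(quat(1, 1, 0, 0)), "unit norm")
})

test_that("embed_kernel centres the kernel at the FFT origin", {
  one <- embed_kernel(quat(matrix(1, 1, 1)), 4, 4)
  expect_equal(one$a[1, 1], 1)
  expect_equal(sum(one$a != 0), 1L)
  k <- quat(matrix(1:9, 3, 3))
  m <- embed_kernel(k, 8, 8)
  nz <- which(m$a != 0, arr.ind = TRUE)
  expect_setequal(nz[, 1], c(1, 2, 8))  # rows -1, 0, 1 mod 8
  expect_setequal(nz[, 2], c(1, 2, 8))
  expect_equal(sum(m$a), sum(k$a))
  expect_equal(m$a[1, 1], k$a[2, 2])  # centre entry lands at the origin
  expect_error(embed_kernel(k, 2, 8), "larger than grid")
})

test_that("convolve_real with a delta kernel is the identity", {
  set.seed(81)
  q <- quat(matrix(rnorm(30), 5, 6), matrix(rnorm(30), 5, 6),
            matrix(rnorm(30), 5, 6), matrix(rnorm(30), 5, 6))
  delta <- quat(matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3))
  expect_lt(rel_diff(convolve_real(q, delta, vector_only = FALSE), q),
            1e-12)
})

test_that("the edge kernel annihilates constant fields", {
  q <- quat(matrix(2, 6, 6), matrix(0.3, 6, 6), matrix(-0.1, 6, 6),
            matrix(0.9, 6, 6))
  out <- convolve_real(q, kernel_edge())
  expect_lt(max(abs(out$b), abs(out$c), abs(out$d)), 1e-12)
  expect_equal(out$a, q$a)  # vector_only passes the real plane through
})

test_that("FFT real-mask convolution matches the spatial oracle", {
  set.seed(83)
  for (rep in 1:5) {
    R <- sample(5:8, 1); C <- sample(5:8, 1)
    q <- quat(matrix(rnorm(R * C), R, C), matrix(rnorm(R * C), R, C),
              matrix(rnorm(R * C), R, C), matrix(rnorm(R * C), R, C))
    got <- convolve_real(q, kernel_edge(), vector_only = FALSE)
    want <- spatial_qconv(kernel_edge(), q, "left")
    expect_lt(rel_diff(got, want), 1e-9)
  }
})

test_that("biconvolution with delta masks is the identity", {
  set.seed(87)
  q <- quat(matrix(rnorm(25), 5, 5), matrix(rnorm(25), 5, 5),
            matrix(rnorm(25), 5, 5), matrix(rnorm(25), 5, 5))
  delta <- embed_kernel(quat(matrix(1, 1, 1)), 5, 5)
  expect_lt(rel_diff(biconvolve(delta, q, delta, vector_only = FALSE), q),
            1e-12)
})

test_that("FFT biconvolution matches the spatial triple-loop oracle", {
  set.seed(89)
  for (rep in 1:6) {
    R <- sample(5:8, 1); C <- sample(5:8, 1)
    q <- quat(matrix(rnorm(R * C), R, C), matrix(rnorm(R * C), R, C),
              matrix(rnorm(R * C), R, C), matrix(rnorm(R * C), R, C))
    kl <- quat(matrix(rnorm(9), 3, 3), matrix(rnorm(9), 3, 3),
               matrix(rnorm(9), 3, 3), matrix(rnorm(9), 3, 3))
    kr <- quat(matrix(rnorm(9), 3, 3), matrix(rnorm(9), 3, 3),
               matrix(rnorm(9), 3, 3), matrix(rnorm(9), 3, 3))
    got <- biconvolve(embed_kernel(kl, R, C), q, embed_kernel(kr, R, C),
                      vector_only = FALSE)
    want <- spatial_biconv(kl, q, kr)
    expect_lt(rel_diff(got, want), 1e-9)
  }
})

test_that("rotation-kernel biconvolution is axis-selective", {
  r <- rotation_quat(c(1, 0, 0), pi)
  ks <- rotation_kernels(r)
  ml <- embed_kernel(ks$KL, 6, 6)
  mr <- embed_kernel(ks$KR, 6, 6)
  off_axis_mag <- function(out) max(sqrt(out$c^2 + out$d^2))
  # constant field aligned with the axis: output vector planes uniform (zero)
  const <- two_domain_field(c(1, 0, 0), c(1, 0, 0))
  out_const <- biconvolve(ml, const, mr)
  expect_lt(max(abs(out_const$b), abs(out_const$c), abs(out_const$d)),
            1e-9)
  # boundary differing only along the rotation axis: no off-axis response
  par_field <- two_domain_field(c(1, 0.3, 0.5), c(2, 0.3, 0.5))
  out_par <- biconvolve(ml, par_field, mr)
  expect_lt(off_axis_mag(out_par), 1e-9)
  # matches the spatial oracle too
  expect_lt(rel_diff(out_par, spatial_biconv(ks$KL,
                                             quat(0 * par_field$a,
                                                  par_field$b, par_field$c,
                                                  par_field$d), ks$KR)),
            1e-9)
  # boundary differing orthogonally to the axis fires off-axis
  perp_field <- two_domain_field(c(1, 0.3, 0.5), c(1, 0.9, 0.5))
  out_perp <- biconvolve(ml, perp_field, mr)
  expect_gt(off_axis_mag(out_perp), 0.1)
  # and generates no response along the axis
  expect_lt(max(abs(out_perp$b)), 1e-9)
})

test_that("spectral_filter removes the selected radial bands", {
  set.seed(97)
  q <- quat(matrix(rnorm(48), 6, 8), matrix(rnorm(48), 6, 8),
            matrix(rnorm(48), 6, 8), matrix(rnorm(48), 6, 8))
  expect_lt(rel_diff(spectral_filter(q, "lowpass", 0), q), 1e-10)
  # a constant matrix has only DC: any highpass removes everything...
  const <- quat(matrix(1, 5, 5), matrix(0.2, 5, 5), matrix(0.4, 5, 5),
                matrix(-0.3, 5, 5))
  hp <- spectral_filter(const, "highpass", 1)
  expect_lt(max(qmod(hp)), 1e-12)
  # ...while lowpass leaves it untouched
  lp <- spectral_filter(const, "lowpass", 3)
  expect_lt(rel_diff(lp, const), 1e-10)
  # filtering is a projection: applying it twice changes nothing
  f1 <- spectral_filter(q, "lowpass", 4)
  expect_lt(rel_diff(spectral_filter(f1, "lowpass", 4), f1), 1e-10)
  expect_error(spectral_filter(q, "lowpass", 1000), "exceeds")
})

test_that("kernel CSV files round-trip", {
  r <- rotation_quat(c(0, 1, 1), 2 * pi / 3)
  k <- rotation_kernels(r)$KL
  path <- withr::local_tempfile(fileext = ".csv")
  write_kernel(k, path)
  k2 <- read_kernel(path)
  expect_equal(k2$a, k$a)
  expect_equal(k2$d, k$d)
})
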