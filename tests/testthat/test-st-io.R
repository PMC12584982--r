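write_mtx_fixture <- function(dir, m, genes, barcodes) {
  dir.create(dir, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(paste(genes, genes, "Gene Expression", sep = "\t"),
             file.path(dir, "features.tsv"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  dir
}

test_that("dense CSV counts round-trip through read_counts", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("location,gA,gB", "s1,3,0", "s2,1,5", "s3,0,2"), path)
  x <- read_counts(path, format = "csv")
  expect_equal(dim(x), c(3L, 2L))
  expect_equal(x$gene_ids, c("gA", "gB"))
  expect_equal(unname(x$counts["s2", ]), c(1, 5))
  # write_counts is the inverse
  out <- withr::local_tempfile(fileext = ".csv")
  write_counts(x, out)
  expect_equal(read_counts(out)$counts, x$counts)
})

test_that("10x-style MTX triplets are transposed to locations x genes", {
  m <- matrix(c(0, 2, 1,
                4, 0, 0), nrow = 2, byrow = TRUE)  # genes x barcodes
  dir <- write_mtx_fixture(withr::local_tempdir(), m,
                           c("gene1", "gene2"), c("bc1", "bc2", "bc3"))
  x <- read_counts(dir, format = "mtx")
  expect_equal(dim(x), c(3L, 2L))  # barcodes are locations
  expect_equal(unname(x$counts["bc1", ]), c(0, 4))
  # all-zero location retained
  expect_equal(unname(x$counts["bc2", ]), c(2, 0))
})

test_that("MTX dimension mismatches are reported", {
  m <- matrix(1, 2, 3)
  dir <- write_mtx_fixture(withr::local_tempdir(), m,
                           c("gene1", "gene2"), c("bc1", "bc2"))
  expect_error(read_counts(dir, format = "mtx"),
               "barcodes.tsv has 2 entries but matrix has 3 columns")
})

test_that("count validation rejects negatives and non-integers", {
  expect_error(st_counts(matrix(-1, 2, 2)), "non-negative")
  expect_error(st_counts(matrix(0.5, 2, 2)), "integer-valued")
  expect_error(st_counts(matrix(0, 2, 2), location_ids = c("a", "a")),
               "duplicate")
})

test_that("coordinates realign to count order and report mismatches", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("location,x,y", "s3,3,0", "s1,1,2", "s2,2,1"), path)
  xy <- read_coords(path, location_ids = c("s1", "s2", "s3"))
  expect_equal(rownames(xy), c("s1", "s2", "s3"))
  expect_equal(unname(xy[, "x"]), c(1, 2, 3))
  expect_error(read_coords(path, location_ids = c("s1", "s2", "s4")),
               "s4")
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("location,x,y", "s1,0,0", "s1,1,1"), dup)
  expect_error(read_coords(dup), "duplicate")
})

test_that("array_row/array_col coordinates use the image convention", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("location,array_row,array_col", "s1,1,5", "s2,3,2"), path)
  xy <- read_coords(path)
  expect_equal(unname(xy["s1", ]), c(5, -1))  # larger row -> smaller y
  expect_gt(xy["s1", "y"], xy["s2", "y"])
})

test_that("binning places corner locations in corner cells", {
  q <- quat(1:4, c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))
  coords <- cbind(x = c(0, 1, 0, 1), y = c(1, 1, 0, 0))
  g <- build_grid(q, coords, rows = 2, cols = 2, fill = FALSE)
  expect_equal(g$occupancy, matrix("observed", 2, 2))
  expect_equal(g$q$a, matrix(c(1, 3, 2, 4), 2, 2))  # y=1 -> row 1
})

test_that("colliding locations are averaged with renormalized vector part", {
  # two locations in one cell with orthogonal unit vectors
  q <- quat(c(2, 4, 1, 1), c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 1))
  coords <- cbind(x = c(0, 0.01, 5, 5), y = c(5, 5, 5, 0))
  g <- build_grid(q, coords, rows = 2, cols = 2, fill = FALSE)
  cell <- qvec(g$q[1, 1])
  expect_equal(cell[1], 3)               # mean of real parts
  s <- 1 / sqrt(2)
  expect_equal(cell[2:4], c(s, s, 0))    # mean vector renormalized
})

test_that("fill-in averages the 8-neighbourhood and renormalizes", {
  # 3x3 grid, centre unobserved, 8 observed neighbours with known values
  set.seed(61)
  v <- matrix(rnorm(24), 8, 3)
  v <- v / sqrt(rowSums(v^2))
  q <- quat(1:8, v[, 1], v[, 2], v[, 3])
  xy <- expand.grid(x = 0:2, y = 2:0)
  xy <- xy[-5, ]  # drop the centre
  g <- build_grid(q, as.matrix(xy), rows = 3, cols = 3, fill = TRUE)
  expect_equal(g$occupancy[2, 2], "filled")
  expect_equal(sum(g$occupancy == "filled"), 1L)
  mv <- colMeans(v)
  want <- mv / sqrt(sum(mv^2))
  expect_equal(qvec(g$q[2, 2]), c(mean(1:8), want), tolerance = 1e-12)
  # observed cells untouched by fill
  nofill <- build_grid(q, as.matrix(xy), rows = 3, cols = 3, fill = FALSE)
  obs <- g$occupancy == "observed"
  expect_equal(g$q$a[obs], nofill$q$a[obs])
})

test_that("holes unreachable on the first pass fill on a later pass", {
  # 5x1-wide interior: ring of observed cells around a 3x3 hole block;
  # the centre of the block has no non-empty neighbour on pass 1
  n <- 5
  xy <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
  ring <- xy$x %in% c(0, n - 1) | xy$y %in% c(0, n - 1)
  xy <- xy[ring, ]
  q <- quat(rep(1, nrow(xy)), rep(1, nrow(xy)), 0, 0)
  g <- build_grid(q, as.matrix(xy), rows = n, cols = n, fill = TRUE)
  expect_equal(g$occupancy[3, 3], "filled")  # needs two passes
  expect_true(all(g$occupancy != "empty"))
})

test_that("cells outside the convex hull stay empty", {
  # L-shaped tissue: the far corner is outside the hull of observed cells
  xy <- rbind(cbind(x = 0:4, y = 0), cbind(x = 0, y = 0:4))
  xy <- unique(xy)
  q <- quat(rep(1, nrow(xy)), 1, 0, 0)
  g <- build_grid(q, xy, rows = 5, cols = 5, fill = TRUE)
  expect_equal(g$occupancy[1, 5], "empty")  # top-right corner
  expect_equal(unname(qvec(g$q[1, 5])), c(0, 0, 0, 0))
})

test_that("build_grid is deterministic and validates inputs", {
  set.seed(91)
  q <- rand_quat(20)
  coords <- cbind(runif(20), runif(20))
  g1 <- build_grid(q, coords, 4, 5)
  g2 <- build_grid(q, coords, 4, 5)
  expect_identical(g1$q, g2$q)
  expect_identical(g1$occupancy, g2$occupancy)
  expect_error(build_grid(q, cbind(rep(1, 20), rep(2, 20)), 4, 4),
               "degenerate")
  expect_error(build_grid(q, coords, 1, 4), ">= 2")
})

test_that("grid containers round-trip bit-faithfully", {
  set.seed(77)
  q <- quat(matrix(rnorm(35), 5, 7), matrix(rnorm(35), 5, 7),
            matrix(rnorm(35), 5, 7), matrix(rnorm(35), 5, 7))
  coords <- cbind(runif(35), runif(35))
  # a realistic grid with all three occupancy states
  g <- build_grid(rand_quat(12), cbind(c(runif(11), 0.5), runif(12)), 5, 7)
  path <- withr::local_tempfile(fileext = ".txt")
  write_grid(g, path)
  g2 <- read_grid(path)
  expect_identical(g2$q$a, g$q$a)
  expect_identical(g2$q$b, g$q$b)
  expect_identical(g2$q$c, g$q$c)
  expect_identical(g2$q$d, g$q$d)
  expect_identical(g2$occupancy, g$occupancy)
  expect_equal(g2$row_edges, g$row_edges)
  # zero grid and bare quat matrices also round-trip
  z <- quat(matrix(0, 3, 3))
  write_grid(z, path)
  expect_identical(read_grid(path)$q$a, matrix(0, 3, 3))
  # corrupted container is rejected
  lines <- readLines(path)
  writeLines(lines[-8], path)
  expect_error(read_grid(path), "expected 9 cells")
})
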