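# Synthetic spatial transcriptomics data: a three-population worked example
# with fixed relative-abundance profiles scaled by varying library size, and
# spatially structured grids with contiguous expression domains for
# exercising the spectral and convolution operations.

.fig1_profiles <- function() {
  list(c(0.5, 0.2, 0.1, 0.1, 0.1),
       c(0.1, 0.1, 0.1, 0.2, 0.5),
       c(0.1, 0.3, 0.3, 0.2, 0.1))
}

#' Three-population worked example counts
#'
#' Generates the noise-free 30-location x 5-gene count matrix used as the
#' package's worked example for the SVD model: three populations of ten
#' locations with fixed relative-abundance profiles `{0.5, 0.2, 0.1, 0.1,
#' 0.1}`, `{0.1, 0.1, 0.1, 0.2, 0.5}`, and `{0.1, 0.3, 0.3, 0.2, 0.1}`,
#' library size within each population scaling linearly over a 1-to-10
#' range (ten equally spaced multiples of `base_depth`; the default 100
#' keeps every count integral). Counts are `round(size * profile)`, so
#' rows within a population are exact scalar multiples of each other and
#' the SVD projection places each population along a single line through
#' the origin.
#'
#' @param base_depth Library size of the shallowest location in each
#'   population (default 100).
#' @return An [st_counts] with a `population` attribute (1, 2, 3 per
#'   location).
#' @export
simulate_fig1 <- function(base_depth = 100) {
  profiles <- .fig1_profiles()
  sizes <- base_depth * (1:10)
  counts <- do.call(rbind, lapply(profiles, function(p) {
    t(vapply(sizes, function(s) round(s * p), numeric(5)))
  }))
  out <- st_counts(counts,
                   gene_ids = paste0("gene", 1:5),
                   location_ids = sprintf("loc%02d", 1:30))
  attr(out, "population") <- rep(1:3, each = 10)
  out
}

#' Domain map helpers
#'
#' Integer matrices assigning each cell of an `rows x cols` raster to an
#' expression domain (values index into a profile list):
#' `domain_map_halfplanes` splits the raster into two vertical (or
#' horizontal) half-planes, `domain_map_quadrants` into four quadrants,
#' and `domain_map_disk` into a central disk (domain 2) in a background
#' square (domain 1).
#'
#' @param rows,cols Raster dimensions.
#' @param direction For half-planes: `"vertical"` (left/right, default) or
#'   `"horizontal"` (top/bottom).
#' @param radius Disk radius in cells (default a third of the smaller
#'   dimension).
#' @return An `rows x cols` integer matrix.
#' @rdname domain-maps
#' @export
domain_map_halfplanes <- function(rows, cols,
                                  direction = c("vertical", "horizontal")) {
  direction <- match.arg(direction)
  if (direction == "vertical") {
    matrix(rep(ifelse(seq_len(cols) <= cols / 2, 1L, 2L), each = rows),
           rows, cols)
  } else {
    matrix(ifelse(seq_len(rows) <= rows / 2, 1L, 2L), rows, cols)
  }
}

#' @rdname domain-maps
#' @export
domain_map_quadrants <- function(rows, cols) {
  top <- seq_len(rows) <= rows / 2
  left <- seq_len(cols) <= cols / 2
  m <- matrix(4L, rows, cols)
  m[top, left] <- 1L
  m[top, !left] <- 2L
  m[!top, left] <- 3L
  m
}

#' @rdname domain-maps
#' @export
domain_map_disk <- function(rows, cols, radius = min(rows, cols) / 3) {
  ctr <- c((rows + 1) / 2, (cols + 1) / 2)
  d2 <- outer((seq_len(rows) - ctr[1])^2, (seq_len(cols) - ctr[2])^2, `+`)
  m <- matrix(1L, rows, cols)
  m[d2 <= radius^2] <- 2L
  m
}

#' Simulate spatially structured ST counts
#'
#' One location per cell of an `rows x cols` raster; each cell draws its
#' relative-abundance profile from `profiles` according to `domain_map` and
#' its library size uniformly from `depth_range`. With
#' `noise = "multinomial"` (default) counts are multinomial draws
#' `(size = depth, prob = profile)`; with `noise = "none"` counts are
#' `round(depth * profile)`. Fully seeded and reproducible.
#'
#' Coordinates are cell centres with `x = col` and `y = rows - row + 1`,
#' so [build_grid()] with the same `rows`/`cols` reproduces the layout.
#'
#' @param rows,cols Raster dimensions.
#' @param domain_map Integer matrix indexing `profiles`; default vertical
#'   half-planes.
#' @param profiles List of relative-abundance vectors (non-negative,
#'   each summing to 1); default: the three worked-example profiles.
#' @param depth_range Length-2 positive range of library sizes; default
#'   `c(100, 1000)` (the 1-to-10 relative depth span of the worked
#'   example).
#' @param noise `"multinomial"` or `"none"`.
#' @param seed Seed for depths and multinomial sampling.
#' @return An [st_counts] with coordinates and a `domain` attribute (the
#'   per-location domain index, in location order).
#' @export
simulate_domains <- function(rows, cols,
                             domain_map = domain_map_halfplanes(rows, cols),
                             profiles = .fig1_profiles(),
                             depth_range = c(100, 1000),
                             noise = c("multinomial", "none"),
                             seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(all(depth_range > 0), length(depth_range) == 2L)
  for (p in profiles) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop("each profile must be non-negative and sum to 1", call. = FALSE)
    }
  }
  domain_map <- matrix(as.integer(domain_map), rows, cols)
  if (any(domain_map < 1L) || any(domain_map > length(profiles))) {
    stop("domain_map values must index into profiles (1..",
         length(profiles), ")", call. = FALSE)
  }
  p_genes <- length(profiles[[1]])
  n <- rows * cols
  .with_seed(seed, {
    depths <- round(stats::runif(n, depth_range[1], depth_range[2]))
    counts <- matrix(0, n, p_genes)
    ridx <- rep(seq_len(rows), times = cols)
    cidx <- rep(seq_len(cols), each = rows)
    for (t in seq_len(n)) {
      prof <- profiles[[domain_map[ridx[t], cidx[t]]]]
      counts[t, ] <- if (noise == "multinomial") {
        stats::rmultinom(1, depths[t], prof)[, 1]
      } else {
        round(depths[t] * prof)
      }
    }
    coords <- cbind(x = cidx, y = rows - ridx + 1)
    out <- st_counts(counts,
                     gene_ids = paste0("gene", seq_len(p_genes)),
                     location_ids = sprintf("loc_r%03d_c%03d", ridx, cidx),
                     coords = coords)
    attr(out, "domain") <- domain_map[cbind(ridx, cidx)]
    out
  })
}
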