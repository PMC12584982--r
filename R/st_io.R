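# Reading spatial transcriptomics counts and coordinates, rasterizing
# per-location quaternions into a 2D quaternion grid, and a plain-text grid
# container with a bit-faithful round trip.

#' Spatial transcriptomics count container
#'
#' An n x p non-negative integer matrix of UMI counts (locations x genes)
#' with gene and location identifiers and optional per-location coordinates.
#'
#' @param counts Numeric matrix, locations in rows, genes in columns;
#'   entries must be non-negative integers.
#' @param gene_ids Character vector of length `ncol(counts)`.
#' @param location_ids Character vector of length `nrow(counts)`, unique.
#' @param coords Optional n x 2 matrix/data.frame of (x, y) coordinates.
#' @return An object of class `"st_counts"`.
#' @export
st_counts <- function(counts, gene_ids = colnames(counts),
                      location_ids = rownames(counts), coords = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts))) {
    stop("counts contain non-finite values", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts != round(counts))) {
    stop("counts must be integer-valued", call. = FALSE)
  }
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  if (is.null(location_ids)) {
    location_ids <- paste0("loc", seq_len(nrow(counts)))
  }
  gene_ids <- as.character(gene_ids)
  location_ids <- as.character(location_ids)
  stopifnot(length(gene_ids) == ncol(counts),
            length(location_ids) == nrow(counts))
  if (anyDuplicated(location_ids)) {
    stop("duplicate location ids: ",
         paste(unique(location_ids[duplicated(location_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
    stopifnot(ncol(coords) == 2L, nrow(coords) == nrow(counts))
    dimnames(coords) <- list(location_ids, c("x", "y"))
  }
  dimnames(counts) <- list(location_ids, gene_ids)
  structure(list(counts = counts, gene_ids = gene_ids,
                 location_ids = location_ids, coords = coords),
            class = "st_counts")
}

#' @export
print.st_counts <- function(x, ...) {
  cat(sprintf("st_counts: %d locations x %d genes%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$coords)) "" else " (with coordinates)"))
  invisible(x)
}

#' @export
dim.st_counts <- function(x) dim(x$counts)

.read_tsv_col <- function(path, col = 1L) {
  tab <- utils::read.table(.maybe_gz(path), sep = "\t", header = FALSE,
                           quote = "", comment.char = "",
                           colClasses = "character")
  tab[[col]]
}

.maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

#' Read a count matrix
#'
#' Reads spatial transcriptomics counts either from a 10x-style Matrix
#' Market triplet directory (`matrix.mtx[.gz]` stored genes x barcodes plus
#' `features.tsv[.gz]` and `barcodes.tsv[.gz]`; transposed on read) or from
#' a dense CSV with a header row of gene ids and location ids in the first
#' column. Orientation is normalized to locations x genes.
#'
#' @param path Directory (mtx) or file (csv).
#' @param format One of `"auto"`, `"mtx"`, `"csv"`.
#' @return An [st_counts] object.
#' @export
read_counts <- function(path, format = c("auto", "mtx", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx" else "csv"
  }
  if (format == "mtx") {
    if (!dir.exists(path)) {
      stop("mtx format expects a directory: ", path, call. = FALSE)
    }
    find1 <- function(base) {
      for (cand in file.path(path, c(base, paste0(base, ".gz")))) {
        if (file.exists(cand)) return(cand)
      }
      stop("missing ", base, "[.gz] in ", path, call. = FALSE)
    }
    m <- Matrix::readMM(.maybe_gz(find1("matrix.mtx")))
    genes <- .read_tsv_col(find1("features.tsv"), 1L)
    barcodes <- .read_tsv_col(find1("barcodes.tsv"), 1L)
    if (length(genes) != nrow(m)) {
      stop(sprintf("features.tsv has %d entries but matrix has %d rows",
                   length(genes), nrow(m)), call. = FALSE)
    }
    if (length(barcodes) != ncol(m)) {
      stop(sprintf("barcodes.tsv has %d entries but matrix has %d columns",
                   length(barcodes), ncol(m)), call. = FALSE)
    }
    x <- t(as.matrix(m))  # barcodes (locations) x genes
    return(st_counts(x, gene_ids = genes, location_ids = barcodes))
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(tab[[1]])
  x <- as.matrix(tab[, -1, drop = FALSE])
  st_counts(x, gene_ids = colnames(x), location_ids = ids)
}

#' Write counts as dense CSV
#'
#' Inverse of the CSV dialect of [read_counts]: gene ids as header, location
#' ids in the first column.
#'
#' @param x An [st_counts].
#' @param path Output CSV path.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "st_counts"))
  df <- data.frame(location = x$location_ids, x$counts,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-location coordinates
#'
#' Reads a CSV with columns `(location id, x, y)` or
#' `(location id, array_row, array_col)`. When `location_ids` is supplied
#' the coordinates are realigned to that order and mismatches are reported.
#' Array rows/cols are converted so that increasing `array_row` maps to
#' decreasing `y` (image convention).
#'
#' @param path CSV path.
#' @param location_ids Optional id vector (e.g. from [read_counts]) to
#'   align against.
#' @return An n x 2 numeric matrix with columns `x`, `y` and location ids
#'   as row names.
#' @export
read_coords <- function(path, location_ids = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (ncol(tab) < 3L) {
    stop("coordinate file needs (id, x, y) or (id, array_row, array_col)",
         call. = FALSE)
  }
  nm <- tolower(names(tab))
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate location ids in coordinates: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (all(c("array_row", "array_col") %in% nm)) {
    xy <- cbind(x = as.numeric(tab[[which(nm == "array_col")]]),
                y = -as.numeric(tab[[which(nm == "array_row")]]))
  } else if (all(c("x", "y") %in% nm)) {
    xy <- cbind(x = as.numeric(tab[[which(nm == "x")[1]]]),
                y = as.numeric(tab[[which(nm == "y")[1]]]))
  } else {
    xy <- cbind(x = as.numeric(tab[[2]]), y = as.numeric(tab[[3]]))
  }
  rownames(xy) <- ids
  if (!is.null(location_ids)) {
    location_ids <- as.character(location_ids)
    missing_xy <- setdiff(location_ids, ids)
    extra_xy <- setdiff(ids, location_ids)
    if (length(missing_xy)) {
      stop(sprintf(
        "%d location id(s) have no coordinates (e.g. %s); %d coordinate id(s) unmatched",
        length(missing_xy),
        paste(utils::head(missing_xy, 5), collapse = ", "),
        length(extra_xy)), call. = FALSE)
    }
    xy <- xy[location_ids, , drop = FALSE]
  }
  xy
}

#' Write coordinates CSV
#' @param coords Matrix with columns x, y and ids as row names.
#' @param path Output path.
#' @export
write_coords <- function(coords, path) {
  df <- data.frame(location = rownames(coords), x = coords[, 1],
                   y = coords[, 2])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.renorm_vec <- function(a, b, c, d) {
  l <- sqrt(b^2 + c^2 + d^2)
  if (l > 0) { b <- b / l; c <- c / l; d <- d / l }
  c(a, b, c, d)
}

#' Rasterize per-location quaternions into a quaternion grid
#'
#' Bins each location into one cell of an `rows x cols` raster using uniform
#' half-open bins over the coordinate extent (last bin closed); `y` maps to
#' rows with descending `y` giving increasing row index (image convention),
#' `x` to columns. Locations colliding in one cell are averaged
#' coefficient-wise and the vector part renormalized to unit length. Cells
#' receiving no location start as exact zeros; when `fill = TRUE`, empty
#' cells interior to the convex hull of observed cells are replaced by the
#' coefficient-wise mean of their non-empty 8-neighbours (vector part
#' renormalized), iterating until no reachable interior hole remains (at
#' most `max_passes` passes). Exterior cells stay empty, preserving the
#' tissue boundary.
#'
#' @param q A `quat` of length n (one quaternion per location).
#' @param coords n x 2 matrix of (x, y) coordinates.
#' @param rows,cols Raster dimensions (each >= 2).
#' @param fill Fill interior holes? Default `TRUE`.
#' @param max_passes Maximum fill iterations (default 10).
#' @return An object of class `"quat_grid"`: list with `q` (a `quat` of
#'   `rows x cols` matrices), `occupancy` (character matrix:
#'   `"observed"`, `"filled"`, `"empty"`), `row_edges`, `col_edges` (bin
#'   edges in tissue coordinates; row edges in descending y), and `type`
#'   (`"spatial"`).
#' @export
build_grid <- function(q, coords, rows, cols, fill = TRUE, max_passes = 10L) {
  q <- .as_quat(q)
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L, nrow(coords) == length(q))
  if (any(!is.finite(coords))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (rows < 2L || cols < 2L) stop("rows and cols must be >= 2",
                                   call. = FALSE)
  rx <- range(coords[, 1]); ry <- range(coords[, 2])
  if (diff(rx) == 0 || diff(ry) == 0) {
    stop("degenerate coordinate extent: all x or all y identical",
         call. = FALSE)
  }
  xe <- seq(rx[1], rx[2], length.out = cols + 1L)
  ye <- seq(ry[1], ry[2], length.out = rows + 1L)
  ic <- findInterval(coords[, 1], xe, rightmost.closed = TRUE)
  iy <- findInterval(coords[, 2], ye, rightmost.closed = TRUE)
  ir <- rows + 1L - iy  # descending y -> increasing row

  zero <- matrix(0, rows, cols)
  planes <- list(a = zero, b = zero, c = zero, d = zero)
  counts <- matrix(0L, rows, cols)
  idx <- cbind(ir, ic)
  for (nm in names(planes)) {
    acc <- matrix(0, rows, cols)
    val <- as.vector(q[[nm]])
    for (t in seq_len(nrow(idx))) {
      acc[idx[t, 1], idx[t, 2]] <- acc[idx[t, 1], idx[t, 2]] + val[t]
    }
    planes[[nm]] <- acc
  }
  for (t in seq_len(nrow(idx))) {
    counts[idx[t, 1], idx[t, 2]] <- counts[idx[t, 1], idx[t, 2]] + 1L
  }
  occ <- matrix("empty", rows, cols)
  hit <- counts > 0L
  occ[hit] <- "observed"
  for (nm in names(planes)) planes[[nm]][hit] <- planes[[nm]][hit] / counts[hit]
  # collisions: renormalize averaged vector part back to unit length
  coll <- which(counts > 1L, arr.ind = TRUE)
  for (t in seq_len(nrow(coll))) {
    rr <- coll[t, 1]; cc <- coll[t, 2]
    v <- .renorm_vec(planes$a[rr, cc], planes$b[rr, cc],
                     planes$c[rr, cc], planes$d[rr, cc])
    planes$a[rr, cc] <- v[1]; planes$b[rr, cc] <- v[2]
    planes$c[rr, cc] <- v[3]; planes$d[rr, cc] <- v[4]
  }

  grid <- structure(list(
    q = quat(planes$a, planes$b, planes$c, planes$d),
    occupancy = occ,
    row_edges = rev(ye),  # descending y, edge k bounds row k from above
    col_edges = xe,
    type = "spatial"), class = "quat_grid")
  if (fill) grid <- .fill_grid(grid, max_passes) else grid
}

# interior = inside the convex hull of observed cell centres
.interior_mask <- function(occ) {
  obs <- which(occ == "observed", arr.ind = TRUE)
  mask <- matrix(FALSE, nrow(occ), ncol(occ))
  if (nrow(obs) < 3L) return(mask)
  hull <- grDevices::chull(obs[, 2], obs[, 1])
  if (length(hull) < 3L) return(mask)
  hx <- obs[hull, 2]; hy <- obs[hull, 1]
  all_cells <- which(occ == "empty", arr.ind = TRUE)
  if (!nrow(all_cells)) return(mask)
  inside <- pracma::inpolygon(all_cells[, 2], all_cells[, 1], hx, hy,
                              boundary = TRUE)
  mask[all_cells[inside, , drop = FALSE]] <- TRUE
  mask
}

.fill_grid <- function(grid, max_passes = 10L) {
  occ <- grid$occupancy
  interior <- .interior_mask(occ)
  if (!any(interior)) return(grid)
  a <- grid$q$a; b <- grid$q$b; c_ <- grid$q$c; d <- grid$q$d
  R <- nrow(occ); C <- ncol(occ)
  for (pass in seq_len(max_passes)) {
    holes <- which(interior & occ == "empty", arr.ind = TRUE)
    if (!nrow(holes)) break
    nonempty <- occ != "empty"
    updates <- NULL
    for (t in seq_len(nrow(holes))) {
      rr <- holes[t, 1]; cc <- holes[t, 2]
      nr <- max(1L, rr - 1L):min(R, rr + 1L)
      nc <- max(1L, cc - 1L):min(C, cc + 1L)
      nb <- nonempty[nr, nc, drop = FALSE]
      nb[match(rr, nr), match(cc, nc)] <- FALSE
      if (!any(nb)) next
      v <- .renorm_vec(mean(a[nr, nc][nb]), mean(b[nr, nc][nb]),
                       mean(c_[nr, nc][nb]), mean(d[nr, nc][nb]))
      updates <- rbind(updates, c(rr, cc, v))
    }
    if (is.null(updates)) break
    for (t in seq_len(nrow(updates))) {
      rr <- updates[t, 1]; cc <- updates[t, 2]
      a[rr, cc] <- updates[t, 3]; b[rr, cc] <- updates[t, 4]
      c_[rr, cc] <- updates[t, 5]; d[rr, cc] <- updates[t, 6]
      occ[rr, cc] <- "filled"
    }
  }
  grid$q <- quat(a, b, c_, d)
  grid$occupancy <- occ
  grid
}

#' @export
print.quat_grid <- function(x, ...) {
  tab <- table(factor(x$occupancy, levels = c("observed", "filled", "empty")))
  cat(sprintf("quat_grid [%d x %d, %s]: %d observed, %d filled, %d empty\n",
              nrow(x$occupancy), ncol(x$occupancy), x$type,
              tab["observed"], tab["filled"], tab["empty"]))
  invisible(x)
}

#' @export
dim.quat_grid <- function(x) dim(x$occupancy)

.fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read a quaternion grid container
#'
#' Plain-text, self-describing container: header lines (`#key value`)
#' carrying dimensions, content type and bin edges, followed by one CSV row
#' per cell with the four coefficient planes (printed with 17 significant
#' digits, which round-trips IEEE doubles bit-faithfully) and the occupancy
#' flag. `write_grid` also accepts a bare 2D `quat` (occupancy recorded as
#' observed everywhere).
#'
#' @param grid A `quat_grid` (or 2D `quat`).
#' @param path File path.
#' @param type Content marker, `"spatial"` or `"spectrum"`; defaults to the
#'   grid's own type.
#' @return `read_grid` returns the `quat_grid`; `write_grid` returns `path`
#'   invisibly.
#' @rdname grid-io
#' @export
write_grid <- function(grid, path, type = NULL) {
  grid <- as_quat_grid(grid)
  if (is.null(type)) type <- grid$type
  R <- nrow(grid$occupancy); C <- ncol(grid$occupancy)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#quatst-grid v1",
               paste("#rows", R), paste("#cols", C),
               paste("#type", type),
               paste("#row_edges", paste(.fmt17(grid$row_edges),
                                         collapse = " ")),
               paste("#col_edges", paste(.fmt17(grid$col_edges),
                                         collapse = " ")),
               "row,col,a,b,c,d,occupancy"), con)
  ridx <- rep(seq_len(R), times = C)
  cidx <- rep(seq_len(C), each = R)
  writeLines(paste(ridx, cidx,
                   .fmt17(as.vector(grid$q$a)), .fmt17(as.vector(grid$q$b)),
                   .fmt17(as.vector(grid$q$c)), .fmt17(as.vector(grid$q$d)),
                   as.vector(grid$occupancy), sep = ","), con)
  invisible(path)
}

#' @rdname grid-io
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "#quatst-grid v1") {
    stop("not a quatst grid container: ", path, call. = FALSE)
  }
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    ln <- grep(paste0("^#", key, " "), hdr, value = TRUE)
    if (!length(ln)) stop("grid container missing header '", key, "'",
                          call. = FALSE)
    sub(paste0("^#", key, " "), "", ln[1])
  }
  R <- as.integer(getv("rows")); C <- as.integer(getv("cols"))
  type <- getv("type")
  row_edges <- as.numeric(strsplit(getv("row_edges"), " ")[[1]])
  col_edges <- as.numeric(strsplit(getv("col_edges"), " ")[[1]])
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.csv(text = body, colClasses = c(
    "integer", "integer", "numeric", "numeric", "numeric", "numeric",
    "character"))
  if (nrow(tab) != R * C) {
    stop(sprintf("grid container corrupt: expected %d cells, found %d",
                 R * C, nrow(tab)), call. = FALSE)
  }
  if (any(!is.finite(as.matrix(tab[, 3:6])))) {
    stop("grid container has non-finite coefficient values", call. = FALSE)
  }
  mk <- function(v) {
    m <- matrix(NA_real_, R, C)
    m[cbind(tab$row, tab$col)] <- v
    m
  }
  occ <- matrix(NA_character_, R, C)
  occ[cbind(tab$row, tab$col)] <- tab$occupancy
  if (anyNA(occ)) stop("grid container is missing cells", call. = FALSE)
  structure(list(q = quat(mk(tab$a), mk(tab$b), mk(tab$c), mk(tab$d)),
                 occupancy = occ, row_edges = row_edges,
                 col_edges = col_edges, type = type),
            class = "quat_grid")
}

#' Coerce to a quaternion grid
#'
#' Wraps a bare 2D `quat` as a `quat_grid` with all cells observed and
#' index-based edges; `quat_grid` inputs pass through.
#'
#' @param x A `quat_grid` or 2D `quat`.
#' @export
as_quat_grid <- function(x) {
  if (inherits(x, "quat_grid")) return(x)
  x <- .as_quat(x)
  if (is.null(dim(x)) || length(dim(x)) != 2L) {
    stop("expected a 2D quaternion array", call. = FALSE)
  }
  R <- nrow(x$a); C <- ncol(x$a)
  structure(list(q = x,
                 occupancy = matrix("observed", R, C),
                 row_edges = seq(R, 0), col_edges = seq(0, C),
                 type = "spatial"), class = "quat_grid")
}
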