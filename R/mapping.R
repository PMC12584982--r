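# Mapping ST count data to per-location quaternions.
#
# The SVD model projects the unnormalized count matrix onto its first four
# singular vectors: the absolute projection on the first singular vector
# (which tracks library size for count data) becomes the real part, and the
# projection on singular vectors 2-4, normalized to unit length, becomes the
# vector part. The gene model instead uses three genes (optionally
# reduced-rank reconstructed), and the gene-set model assembles quaternions
# from caller-provided per-location scores.

.counts_matrix <- function(x) {
  if (inherits(x, "st_counts")) x$counts else {
    x <- as.matrix(x); storage.mode(x) <- "double"; x
  }
}

# deterministic SVD sign convention: the largest-|.| element of each right
# singular vector is made positive (ties: lowest index, which.max default)
.fix_svd_signs <- function(s) {
  for (k in seq_along(s$d)) {
    piv <- which.max(abs(s$v[, k]))
    if (s$v[piv, k] < 0) {
      s$v[, k] <- -s$v[, k]
      s$u[, k] <- -s$u[, k]
    }
  }
  s
}

# Seeded Halko-style randomized SVD of the top k factors (Gaussian sketch,
# two power iterations, QR re-orthonormalization).
.randomized_svd <- function(x, k, seed = NULL, oversample = 10L,
                            power_iter = 2L) {
  .with_seed(seed, {
    l <- min(ncol(x), k + oversample)
    omega <- matrix(stats::rnorm(ncol(x) * l), ncol(x), l)
    y <- x %*% omega
    q <- qr.Q(qr(y))
    for (it in seq_len(power_iter)) {
      q <- qr.Q(qr(crossprod(x, q)))
      q <- qr.Q(qr(x %*% q))
    }
    b <- crossprod(q, x)
    s <- svd(b, nu = k, nv = k)
    list(u = q %*% s$u, d = s$d[seq_len(k)], v = s$v)
  })
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

.location_quats <- function(q, lengths, location_ids, model) {
  structure(list(q = q, lengths = lengths, location_ids = location_ids,
                 model = model), class = "location_quats")
}

#' @export
print.location_quats <- function(x, ...) {
  cat(sprintf("location_quats (%s model): %d locations\n", x$model,
              length(x$q)))
  invisible(x)
}

#' @export
length.location_quats <- function(x) length(x$q)

#' SVD quaternion model
#'
#' Projects the unnormalized count matrix onto its first four singular
#' vectors (`P = U4 D4`) and maps each location `i` to the quaternion
#' `(|p_i1|, p_i2 / l_i, p_i3 / l_i, p_i4 / l_i)` with
#' `l_i = sqrt(p_i2^2 + p_i3^2 + p_i4^2)`. For unnormalized counts the real
#' part tracks library size and the unit vector part the reduced-rank
#' relative expression profile. A deterministic sign convention (largest
#' absolute loading of each right singular vector made positive) makes
#' repeated runs bit-identical.
#'
#' @param x An [st_counts] or a locations x genes count matrix (needs at
#'   least 4 rows, 4 columns, numerical rank >= 4).
#' @param randomized Use a seeded randomized SVD of the top four factors
#'   (for large matrices) instead of the exact `svd()`.
#' @param seed Seed for the randomized path.
#' @return A `location_quats` object: `q` (length-n `quat`), `lengths`
#'   (the `l_i`), `location_ids`, `model`.
#' @export
svd_model <- function(x, randomized = FALSE, seed = NULL) {
  ids <- if (inherits(x, "st_counts")) x$location_ids else rownames(x)
  x <- .counts_matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 4L || p < 4L) {
    stop("svd_model needs at least 4 locations and 4 genes", call. = FALSE)
  }
  if (all(x == 0)) stop("count matrix is all zero", call. = FALSE)
  s <- if (randomized) .randomized_svd(x, 4L, seed = seed) else {
    sv <- svd(x, nu = 4L, nv = 4L)
    list(u = sv$u, d = sv$d[1:4], v = sv$v)
  }
  rank_tol <- max(n, p) * .Machine$double.eps * s$d[1]
  if (s$d[2] <= rank_tol) {
    stop("count matrix has rank < 2: locations carry no direction ",
         "information - consider gene_model()", call. = FALSE)
  }
  if (s$d[4] <= rank_tol) {
    message("note: count matrix has rank < 4; quaternion vector parts are ",
            "confined to a lower-dimensional subspace (consider ",
            "gene_model() for full 3D directions)")
  }
  s <- .fix_svd_signs(s)
  P <- s$u %*% diag(s$d[1:4])
  qa <- abs(P[, 1])
  l <- sqrt(P[, 2]^2 + P[, 3]^2 + P[, 4]^2)
  zero_loc <- rowSums(x) == 0
  if (any(zero_loc)) {
    warning(sum(zero_loc), " all-zero location(s) mapped to the zero ",
            "quaternion", call. = FALSE)
    qa[zero_loc] <- 0
    l[zero_loc] <- 0
  }
  safe_l <- ifelse(l > 0, l, 1)
  qb <- ifelse(l > 0, P[, 2] / safe_l, 0)
  qc <- ifelse(l > 0, P[, 3] / safe_l, 0)
  qd <- ifelse(l > 0, P[, 4] / safe_l, 0)
  .location_quats(quat(qa, qb, qc, qd), l, ids, "svd")
}

.match_genes <- function(genes, gene_ids) {
  idx <- match(genes, gene_ids)
  if (anyNA(idx)) {
    missing <- genes[is.na(idx)]
    near <- unique(unlist(lapply(missing, function(g) {
      utils::head(agrep(g, gene_ids, value = TRUE, max.distance = 0.3), 3)
    })))
    stop("unknown gene id(s): ", paste(missing, collapse = ", "),
         if (length(near)) paste0("; did you mean: ",
                                  paste(near, collapse = ", "), "?") else "",
         call. = FALSE)
  }
  idx
}

#' Three-gene quaternion model
#'
#' Maps each location to a quaternion whose vector part is the (optionally
#' reduced-rank reconstructed) expression of three chosen genes, normalized
#' to unit length, and whose real part is the location's total library size
#' (or the summed counts of the three genes).
#'
#' @param x An [st_counts] or count matrix with gene ids as column names.
#' @param genes Character vector of exactly 3 gene ids.
#' @param recon_rank Truncation rank for the SVD reconstruction
#'   `X_hat = U_r D_r V_r'`; `0` (default) uses the expression values
#'   directly, `min(n, p)` is the identity reconstruction.
#' @param real_part `"library"` (total UMI count of the location, default)
#'   or `"genes"` (summed raw counts of the three genes).
#' @param normalize Library-size normalize counts (to the median library
#'   size) before reconstruction. Default `FALSE`, matching the use of
#'   unnormalized counts in the SVD model.
#' @return A `location_quats` object.
#' @export
gene_model <- function(x, genes, recon_rank = 0L,
                       real_part = c("library", "genes"),
                       normalize = FALSE) {
  real_part <- match.arg(real_part)
  ids <- if (inherits(x, "st_counts")) x$location_ids else rownames(x)
  gene_ids <- if (inherits(x, "st_counts")) x$gene_ids else colnames(x)
  x <- .counts_matrix(x)
  if (length(genes) != 3L) stop("gene_model needs exactly 3 genes",
                                call. = FALSE)
  gi <- .match_genes(genes, gene_ids)
  libsize <- rowSums(x)
  xw <- x
  if (normalize) {
    med <- stats::median(libsize[libsize > 0])
    nz <- libsize > 0
    xw[nz, ] <- xw[nz, , drop = FALSE] / libsize[nz] * med
  }
  if (recon_rank > min(dim(x))) {
    stop("recon_rank exceeds min(n, p) = ", min(dim(x)), call. = FALSE)
  }
  expr <- if (recon_rank >= 1L) {
    s <- svd(xw, nu = recon_rank, nv = recon_rank)
    r <- seq_len(recon_rank)
    (s$u %*% (s$d[r] * t(s$v)))[, gi, drop = FALSE]
  } else {
    xw[, gi, drop = FALSE]
  }
  l <- sqrt(rowSums(expr^2))
  if (any(l == 0)) {
    warning(sum(l == 0), " location(s) with zero expression of the chosen ",
            "genes mapped to a zero vector part", call. = FALSE)
  }
  safe_l <- ifelse(l > 0, l, 1)
  v <- expr / safe_l
  v[l == 0, ] <- 0
  qa <- unname(if (real_part == "library") libsize else
    rowSums(x[, gi, drop = FALSE]))
  .location_quats(quat(qa, v[, 1], v[, 2], v[, 3]), l, ids, "gene")
}

#' Gene-set quaternion model
#'
#' Assembles quaternions from caller-provided per-location scores of three
#' gene sets (e.g. set-scoring or cell-type deconvolution output): the
#' vector part is the row-normalized score triple (signs preserved), the
#' real part the supplied sequencing depth. Scoring itself is out of scope;
#' this operation only performs the quaternion assembly.
#'
#' @param scores n x 3 numeric matrix of set scores (may be negative).
#' @param depth Length-n non-negative depths for the real part.
#' @return A `location_quats` object.
#' @export
geneset_model <- function(scores, depth) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 3L, length(depth) == nrow(scores))
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (any(depth < 0)) stop("depth must be non-negative", call. = FALSE)
  l <- sqrt(rowSums(scores^2))
  if (any(l == 0)) {
    warning(sum(l == 0), " all-zero score row(s) mapped to a zero vector ",
            "part", call. = FALSE)
  }
  safe_l <- ifelse(l > 0, l, 1)
  v <- scores / safe_l
  v[l == 0, ] <- 0
  .location_quats(quat(as.numeric(depth), v[, 1], v[, 2], v[, 3]), l,
                  rownames(scores), "geneset")
}
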