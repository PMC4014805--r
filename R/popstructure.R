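# Kinship-based classical multidimensional scaling (population structure view).

#' Convert a kinship matrix to squared Euclidean distances
#'
#' `D2[i,j] = K[i,i] + K[j,j] - 2 K[i,j]`. The diagonal is exactly zero;
#' negative entries (possible with a noisy, non-Euclidean kinship estimate)
#' are clipped to zero with a warning.
#'
#' @param kinship symmetric kinship matrix.
#' @return Symmetric matrix of squared distances.
#' @export
kinship_to_sq_distance <- function(kinship) {
  if (!is.matrix(kinship) || nrow(kinship) != ncol(kinship)) {
    stop("kinship must be a square matrix")
  }
  dk <- diag(kinship)
  d2 <- outer(dk, dk, `+`) - 2 * kinship
  diag(d2) <- 0
  if (any(d2 < 0)) {
    warning("clipping ", sum(d2 < 0), " negative squared distances to 0")
    d2[d2 < 0] <- 0
  }
  dimnames(d2) <- dimnames(kinship)
  d2
}

#' Classical (Torgerson) multidimensional scaling of a squared-distance matrix
#'
#' Double-centers the squared distances, eigen-decomposes, and returns the
#' top-`k` coordinates scaled by the square root of their eigenvalues
#' (delegating to [stats::cmdscale()]). Negative eigenvalues are dropped from
#' the coordinates and excluded from the explained-variance denominator. For
#' reproducibility each coordinate column is sign-fixed so that its
#' largest-magnitude entry is positive. If fewer than `k` positive eigenvalues
#' exist, the coordinates are padded with zero columns with a warning.
#'
#' @param sq_distance symmetric matrix of squared distances
#'   (see [kinship_to_sq_distance()]).
#' @param k number of dimensions to return (`k <= n - 1`).
#' @return An object of class `kinship_mds` with elements `coordinates`
#'   (`n x k`), `eigenvalues` (descending) and `explained_fraction`
#'   (per returned dimension).
#' @export
classical_mds <- function(sq_distance, k = 2) {
  if (!is.matrix(sq_distance) || nrow(sq_distance) != ncol(sq_distance)) {
    stop("sq_distance must be a square matrix")
  }
  n <- nrow(sq_distance)
  if (k < 1 || k > n - 1) stop("k must satisfy 1 <= k <= n - 1")
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(sqrt(sq_distance)), k = k, eig = TRUE)
  )
  eig <- fit$eig                         # descending from cmdscale
  # treat eigenvalues that are numerically zero relative to the leading one
  # as non-positive (degenerate directions)
  tol <- max(abs(eig), .Machine$double.eps) * 1e-8
  pos <- eig[eig > tol]
  coords <- fit$points
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1L)
  got <- ncol(coords)
  if (got > length(pos)) {
    coords[, (length(pos) + 1L):got] <- 0
    got <- length(pos)
  }
  if (got < k) {
    warning("only ", got, " positive eigenvalue(s); padding coordinates ",
            "with zero columns")
    if (ncol(coords) < k) coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
  }
  # deterministic sign: largest-magnitude entry of each column positive
  for (j in seq_len(ncol(coords))) {
    col <- coords[, j]
    if (any(col != 0)) {
      lead <- which.max(abs(col))
      if (col[lead] < 0) coords[, j] <- -col
    }
  }
  denom <- sum(pos)
  expl <- if (denom > 0) {
    ifelse(eig[seq_len(k)] > tol, eig[seq_len(k)], 0) / denom
  } else rep(0, k)
  rownames(coords) <- rownames(sq_distance)
  colnames(coords) <- paste0("dim", seq_len(k))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 explained_fraction = expl),
            class = "kinship_mds")
}

#' @export
print.kinship_mds <- function(x, ...) {
  cat("classical MDS:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "dimensions\n")
  cat("  explained fraction:",
      paste(sprintf("%.1f%%", 100 * x$explained_fraction), collapse = ", "),
      "\n")
  invisible(x)
}

#' Scatter plot of the first two MDS dimensions
#'
#' @param x a `kinship_mds` object.
#' @param populations optional factor/character vector colouring the samples.
#' @param ... passed to [graphics::plot()].
#' @export
plot.kinship_mds <- function(x, populations = NULL, ...) {
  co <- x$coordinates
  if (ncol(co) < 2L) stop("need at least 2 dimensions to plot")
  col <- 1L
  if (!is.null(populations)) {
    populations <- as.factor(populations)
    col <- as.integer(populations)
  }
  graphics::plot(co[, 1], co[, 2], col = col, pch = 19,
                 xlab = sprintf("dim 1 (%.1f%%)", 100 * x$explained_fraction[1]),
                 ylab = sprintf("dim 2 (%.1f%%)", 100 * x$explained_fraction[2]),
                 ...)
  if (!is.null(populations)) {
    graphics::legend("topright", legend = levels(populations),
                     col = seq_along(levels(populations)), pch = 19)
  }
  invisible(x)
}

#' Write MDS coordinates as a tab-separated table
#'
#' @param mds a `kinship_mds` object.
#' @param populations population label per sample.
#' @param path output path.
#' @export
write_mds_coordinates <- function(mds, populations, path) {
  df <- data.frame(sample_id = rownames(mds$coordinates),
                   population = populations,
                   mds$coordinates,
                   stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
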