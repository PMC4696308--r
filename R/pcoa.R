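#' Principal coordinates analysis of a genetic distance matrix
#'
#' Metric multidimensional scaling: the element-wise squared distance
#' matrix is Gower-centered (`B = -1/2 J D^2 J`) and eigendecomposed;
#' coordinates are eigenvectors scaled by the square root of their
#' (positive) eigenvalues, ordered by eigenvalue. Negative eigenvalues
#' (non-Euclidean distances) are excluded with a warning. The decomposition
#' is delegated to [stats::cmdscale()], which implements exactly this
#' centering.
#'
#' @param d Symmetric distance matrix with zero diagonal (e.g. from
#'   [pairwise_distances()]).
#' @param n_axes Number of axes to return (truncated, with a warning, to
#'   the number of positive eigenvalues).
#' @return Object of class `pcoa_result`: `coordinates` (individuals x
#'   axes), `eigenvalues` (all, by decreasing value), and
#'   `pct_explained` (percent of the positive-eigenvalue total per
#'   returned axis).
#' @export
pcoa <- function(d, n_axes = 2L) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  n <- nrow(d)
  fit <- suppressWarnings(cmdscale(stats::as.dist(d), k = min(n_axes, n - 1L),
                                   eig = TRUE))
  eig <- fit$eig
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  if (any(eig < -sqrt(.Machine$double.eps) * max(abs(eig), 1)))
    warning("negative eigenvalues excluded (non-Euclidean distances)")
  k <- min(n_axes, n_pos)
  if (k < n_axes)
    warning("requested ", n_axes, " axes but only ", n_pos,
            " positive eigenvalues; truncated")
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(k))
  pct <- 100 * eig[seq_len(k)] / sum(eig[eig > 0])
  structure(list(coordinates = coords, eigenvalues = eig,
                 pct_explained = pct),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "points,", ncol(x$coordinates),
      "axes\n")
  cat("Percent explained:",
      paste(sprintf("%.1f%%", x$pct_explained), collapse = ", "), "\n")
  invisible(x)
}
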