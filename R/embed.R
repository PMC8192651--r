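#' PCA of a genotype matrix
#'
#' Standard biallelic-genotype PCA: each site's dosages are centred by twice
#' the ALT frequency and (by default) scaled by the binomial standard
#' deviation sqrt(2 p (1 - p)); missing dosages become 0 after centring;
#' monomorphic sites are skipped. Scores are the left singular vectors
#' scaled by their singular values, i.e. the eigenvectors of the sample
#' covariance scaled to the component variances. Each component's sign is
#' fixed by making its largest-magnitude site loading positive.
#'
#' @param G a `genotype_matrix`
#' @param n_comp number of components to return
#' @param scale divide by sqrt(2p(1-p)) (default `TRUE`); `FALSE` gives the
#'   unscaled (covariance) PCA dual to classical scaling of Euclidean
#'   genotype distances
#' @return object of class `embedding`: list with `scores` (n x n_comp),
#'   `eigenvalues` (component variances, non-increasing), `method = "pca"`
#' @export
snp_pca <- function(G, n_comp = 10, scale = TRUE) {
  X <- G$dosage
  storage.mode(X) <- "double"
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < 2) stop("need at least 2 polymorphic sites")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  X <- sweep(X, 2, 2 * p)
  if (scale) X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  X[is.na(X)] <- 0
  n <- nrow(X)
  if (n_comp > min(dim(X))) {
    stop("n_comp exceeds min(n samples, n polymorphic sites)")
  }
  sv <- svd(X, nu = n_comp, nv = n_comp)
  # sign convention: largest-|loading| positive per component
  for (j in seq_len(n_comp)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) {
      sv$v[, j] <- -v
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(n_comp)], n_comp)
  rownames(scores) <- G$sample_ids
  structure(list(scores = scores,
                 eigenvalues = sv$d[seq_len(n_comp)]^2 / (n - 1),
                 method = "pca"),
            class = "embedding")
}

#' Principal coordinates (classical multidimensional scaling)
#'
#' Classical scaling of a distance matrix: double-centre -D^2/2 and embed on
#' the top non-negative eigenpairs (delegated to [stats::cmdscale()]).
#' Negative eigenvalues — the signature of a non-Euclidean distance — are
#' dropped with a warning.
#'
#' @param D symmetric distance matrix (or `dist`) with zero diagonal
#' @param n_comp number of coordinates requested
#' @return object of class `embedding`: `scores`, non-negative
#'   `eigenvalues` (non-increasing), `method = "pco"`
#' @export
pco <- function(D, n_comp = 2) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  n <- nrow(D)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(D), k = min(n_comp, n - 1), eig = TRUE)
  )
  eig <- fit$eig
  if (any(eig < -1e-8 * max(abs(eig), 1))) {
    warning("negative eigenvalues dropped (non-Euclidean distances)")
  }
  pos <- which(eig > 1e-12 * max(abs(eig), 1))
  d <- min(n_comp, length(pos))
  scores <- if (d > 0) fit$points[, seq_len(d), drop = FALSE] else
    matrix(0, n, 0)
  if (d < n_comp && length(pos) == 0) {
    # degenerate all-zero distances: return zero coordinates as requested
    scores <- matrix(0, n, n_comp)
    d <- n_comp
  }
  rownames(scores) <- rownames(D)
  structure(list(scores = scores,
                 eigenvalues = if (length(pos) > 0)
                   sort(eig[pos], decreasing = TRUE)[seq_len(d)] else
                     rep(0, d),
                 method = "pco"),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding (%s): %d samples x %d components\n",
              x$method, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}
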