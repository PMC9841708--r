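#' Principal components analysis of a genotype matrix
#'
#' Mean-imputes missing dosages, centres sites (optionally standardizes),
#' and eigendecomposes the sample covariance. For typical SNP data with many
#' more sites than samples the decomposition is done on the samples-side
#' cross-product, which has the same non-zero spectrum. The explained
#' variance of component k is \eqn{100 \lambda_k / \sum_j \lambda_j}, the
#' percentage of the total (post-centering) variance.
#'
#' @param gm A `genotype_matrix` (may contain missing cells; they are
#'   mean-imputed).
#' @param n_components Number of components to return; at most
#'   `min(n_samples, n_sites)`.
#' @param scale Logical: standardize sites before decomposition (correlation
#'   PCA)? Default `FALSE` (covariance PCA on centred dosages).
#' @return A `pca_result`: list with `scores` (samples x components),
#'   `explained_variance_pct` (length `n_components`, non-increasing),
#'   `loadings` (sites x components) and `eigenvalues`.
#' @export
run_pca <- function(gm, n_components = 2, scale = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- nrow(gm$values)
  if (n < 2) stop("PCA requires at least 2 samples")
  x <- center_sites(mean_impute(gm), scale = scale)
  m <- ncol(x)
  if (n_components < 1 || n_components > min(n, m)) {
    stop(sprintf("n_components must be in [1, %d]", min(n, m)))
  }
  cp <- tcrossprod(x) / (n - 1)          # n x n, spectrum = covariance spectrum
  eg <- eigen(cp, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  total_var <- sum(lam)
  k <- seq_len(n_components)
  lam_k <- lam[k]
  u <- eg$vectors[, k, drop = FALSE]
  scores <- u %*% diag(sqrt(lam_k * (n - 1)), n_components)
  # loadings: V = X' U D^{-1}; zero-eigenvalue components get zero loadings
  d <- sqrt(lam_k * (n - 1))
  inv_d <- ifelse(d > .Machine$double.eps^0.5 * max(d, 1), 1 / d, 0)
  loadings <- crossprod(x, u) %*% diag(inv_d, n_components)
  rownames(scores) <- gm$sample_ids
  colnames(scores) <- paste0("PC", k)
  colnames(loadings) <- paste0("PC", k)
  structure(list(
    scores = scores,
    explained_variance_pct = if (total_var > 0) 100 * lam_k / total_var
                             else rep(0, n_components),
    loadings = loadings,
    eigenvalues = lam_k
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d components\n", nrow(x$scores),
              ncol(x$scores)))
  cat("explained variance (%):",
      paste(sprintf("%.2f", x$explained_variance_pct), collapse = " "), "\n")
  invisible(x)
}
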