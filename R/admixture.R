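#' Estimate individual-specific allele frequencies by latent-subspace projection
#'
#' The likelihood-free admixture model treats each dosage as
#' \eqn{x_{ij} \sim Binomial(2, f_{ij})} with a rank-K frequency matrix
#' \eqn{F = P Q'}. The K-dimensional latent subspace spanned by the rows of
#' Q is estimated from the top-K eigenvectors of the samples' second-moment
#' matrix of `dosage / 2`; with `adjust = TRUE` (default) the binomial
#' sampling variance is removed from its diagonal first (the matrix
#' \eqn{(1/m) W'W - diag(d)} with \eqn{d_j = (1/m)\sum_i w_{ij}(1-w_{ij})},
#' which is unbiased for \eqn{(1/m) F'F}). Rows of `dosage / 2` are then
#' projected onto that subspace and clipped to \eqn{[\epsilon, 1-\epsilon]}.
#'
#' @param gm A complete `genotype_matrix` (mean-impute upstream if needed).
#' @param K Number of latent populations, `1 <= K <= n_samples`.
#' @param adjust Logical: subtract the binomial-sampling diagonal before the
#'   eigendecomposition? Turn off for noise-free dosages (e.g. exact `2 P Q'`
#'   inputs).
#' @param eps Clipping margin keeping frequencies inside (0, 1).
#' @return Numeric matrix `n_sites x n_samples` of estimated frequencies.
#' @export
estimate_individual_frequencies <- function(gm, K, adjust = TRUE,
                                            eps = 1e-6) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (any(gm$mask)) {
    stop("estimate_individual_frequencies requires a complete matrix; impute first")
  }
  n <- nrow(gm$values)
  if (K < 1 || K > n) stop(sprintf("K must be in [1, %d]", n))
  w <- t(gm$values) / 2            # m x n, entries in [0, 1]
  m <- nrow(w)
  if (K == n) {
    fhat <- w
  } else {
    g <- crossprod(w) / m          # n x n second-moment matrix
    if (adjust) g <- g - diag(colSums(w * (1 - w)) / m, n)
    v <- eigen(g, symmetric = TRUE)$vectors[, seq_len(K), drop = FALSE]
    fhat <- w %*% v %*% t(v)
  }
  fhat <- pmin(pmax(fhat, eps), 1 - eps)
  dimnames(fhat) <- list(gm$site_ids, gm$sample_ids)
  fhat
}

#' Factor an individual-frequency matrix into admixture components
#'
#' Constrained alternating least squares: given current Q, P is the
#' least-squares solution clipped entrywise to \[0, 1\]; given current P,
#' each row of Q is the least-squares solution Euclidean-projected onto the
#' probability simplex. Q is initialized from seeded Dirichlet(1, ..., 1)
#' draws with `n_restarts` restarts, keeping the fit with the lowest
#' reconstruction error. An iteration that would increase the objective is
#' rejected and iteration stops there, so the recorded objective sequence is
#' non-increasing by construction.
#'
#' @param fhat Numeric matrix `n_sites x n_samples` with entries in \[0, 1\].
#' @param K Number of clusters.
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Maximum ALS iterations per restart.
#' @param seed Integer seed for the Dirichlet initializations.
#' @param n_restarts Number of random restarts.
#' @return An `admixture_fit`: list with `K`, `Q` (samples x K, rows on the
#'   simplex), `P` (sites x K, entries in \[0, 1\]), `n_iterations`,
#'   `final_objective` (Frobenius reconstruction error), `objective_trace`
#'   and `converged`.
#' @export
factorize <- function(fhat, K, tol = 1e-6, max_iter = 500, seed = 1,
                      n_restarts = 5) {
  stopifnot(is.matrix(fhat), K >= 1, tol > 0, max_iter >= 1)
  if (min(fhat) < -1e-9 || max(fhat) > 1 + 1e-9) {
    stop("fhat entries must lie in [0, 1]")
  }
  n <- ncol(fhat)
  m <- nrow(fhat)
  if (K == 1) {
    q <- matrix(1, n, 1)
    p <- matrix(rowMeans(fhat), m, 1)
    obj <- sum((fhat - p %*% t(q))^2)
    return(new_admixture_fit(K, q, p, 0L, obj, obj, TRUE, fhat))
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      fit <- als_once(fhat, K, tol, max_iter)
      if (is.null(best) || fit$final_objective < best$final_objective) {
        best <- fit
      }
    }
  })
  new_admixture_fit(K, best$Q, best$P, best$n_iterations,
                    best$final_objective, best$objective_trace,
                    best$converged, fhat)
}

new_admixture_fit <- function(K, Q, P, n_iter, obj, trace, converged, fhat) {
  rownames(Q) <- colnames(fhat)
  rownames(P) <- rownames(fhat)
  structure(list(K = K, Q = Q, P = P, n_iterations = n_iter,
                 final_objective = obj, objective_trace = trace,
                 converged = converged),
            class = "admixture_fit")
}

# one seeded-restart ALS run (RNG state managed by the caller)
als_once <- function(fhat, K, tol, max_iter) {
  n <- ncol(fhat)
  q <- rdirichlet(n, rep(1, K))
  p <- update_p(fhat, q)
  obj <- sum((fhat - p %*% t(q))^2)
  trace <- obj
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(max_iter)) {
    p_new <- update_p(fhat, q)
    q_new <- update_q(fhat, p_new)
    obj_new <- sum((fhat - p_new %*% t(q_new))^2)
    if (obj_new > obj + 1e-12) {
      # projected ALS offers no monotonicity guarantee; reject and stop
      converged <- TRUE
      break
    }
    iter <- it
    p <- p_new; q <- q_new
    trace <- c(trace, obj_new)
    if (obj > 0 && (obj - obj_new) / max(obj, .Machine$double.eps) < tol) {
      obj <- obj_new
      converged <- TRUE
      break
    }
    obj <- obj_new
  }
  list(Q = q, P = p, n_iterations = iter, final_objective = obj,
       objective_trace = trace, converged = converged)
}

inv_or_pinv <- function(a) {
  tryCatch(solve(a), error = function(e) MASS::ginv(a))
}

update_p <- function(fhat, q) {
  p <- fhat %*% q %*% inv_or_pinv(crossprod(q))
  pmin(pmax(p, 0), 1)
}

update_q <- function(fhat, p) {
  q <- crossprod(fhat, p) %*% inv_or_pinv(crossprod(p))
  t(apply(q, 1, project_simplex))
}

#' Fit admixture models over a range of K
#'
#' Mean-imputes the genotype matrix if needed, estimates individual-specific
#' allele frequencies at each K, and factorizes them into membership (Q) and
#' cluster-frequency (P) matrices. When the input had missing data the sweep
#' records that imputation occurred and makes no "best K" claim: the
#' latent-subspace machinery only supports K estimation on complete data, so
#' per-K objectives are reported for inspection only.
#'
#' @param gm A `genotype_matrix`.
#' @param K_min,K_max Range of cluster numbers to fit.
#' @param seed Integer seed (each K uses a seed derived from it).
#' @param adjust Passed to [estimate_individual_frequencies()].
#' @param tol,max_iter,n_restarts Passed to [factorize()].
#' @return An `admixture_sweep`: list with `fits` (one `admixture_fit` per K,
#'   named `K<k>`), `objectives`, `K_values` and `had_missing`.
#' @export
fit_admixture <- function(gm, K_min = 1, K_max = 8, seed = 1, adjust = TRUE,
                          tol = 1e-6, max_iter = 500, n_restarts = 5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- nrow(gm$values)
  if (!(K_min >= 1 && K_min <= K_max && K_max <= n)) {
    stop(sprintf("K range must satisfy 1 <= K_min <= K_max <= %d", n))
  }
  had_missing <- any(gm$mask)
  if (had_missing) gm <- mean_impute(gm)
  ks <- seq.int(K_min, K_max)
  fits <- lapply(ks, function(k) {
    fhat <- estimate_individual_frequencies(gm, k, adjust = adjust)
    factorize(fhat, k, tol = tol, max_iter = max_iter,
              seed = seed + k, n_restarts = n_restarts)
  })
  names(fits) <- paste0("K", ks)
  structure(list(fits = fits,
                 objectives = vapply(fits, `[[`, numeric(1),
                                     "final_objective"),
                 K_values = ks, had_missing = had_missing),
            class = "admixture_sweep")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: K = %d, %d samples, objective %.4g (%s)\n",
              x$K, nrow(x$Q), x$final_objective,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' @export
print.admixture_sweep <- function(x, ...) {
  cat(sprintf("admixture_sweep: K = %d..%d%s\n", min(x$K_values),
              max(x$K_values),
              if (x$had_missing) " (input had missing data; imputed)" else ""))
  print(round(x$objectives, 4))
  invisible(x)
}
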