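# shared numerical helpers

#' Euclidean projection of a vector onto the probability simplex
#'
#' Sort-based algorithm (Held et al. / Duchi et al.): deterministic,
#' O(K log K).
#'
#' @param v Numeric vector.
#' @return Numeric vector on the simplex (non-negative, sums to 1).
#' @export
project_simplex <- function(v) {
  k <- length(v)
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_len(k) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

# Dirichlet draws via gamma; rows on the simplex
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  # guard fully-degenerate draws (all-zero row possible for tiny alpha)
  zero <- rowSums(x) == 0
  if (any(zero)) x[zero, ] <- 1 / k
  x / rowSums(x)
}

# run code with a temporary RNG state seeded at `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' IUPAC ambiguity code for a set of bases
#'
#' @param bases Character vector of bases from {A, C, G, T}.
#' @return Single character: the base itself if unique, else the IUPAC code.
#' @export
iupac_code <- function(bases) {
  key <- paste(sort(unique(toupper(bases))), collapse = "")
  if (!nzchar(key)) return("N")
  map <- Biostrings::IUPAC_CODE_MAP
  hit <- names(map)[match(key, map)]
  if (is.na(hit)) stop(sprintf("no IUPAC code for base set '%s'", key))
  hit
}

#' Align an estimated membership matrix to a reference by column permutation
#'
#' Searches all column permutations (K is small) for the one minimizing the
#' mean absolute difference to `Q_ref`; used to score label-switching-free
#' recovery of admixture proportions.
#'
#' @param Q_est,Q_ref Numeric matrices, samples x K.
#' @return List with `Q` (permuted `Q_est`), `perm`, and `mae`.
#' @export
align_memberships <- function(Q_est, Q_ref) {
  stopifnot(ncol(Q_est) == ncol(Q_ref), nrow(Q_est) == nrow(Q_ref))
  k <- ncol(Q_est)
  perms <- permutations_of(k)
  best <- NULL
  best_mae <- Inf
  for (p in perms) {
    mae <- mean(abs(Q_est[, p, drop = FALSE] - Q_ref))
    if (mae < best_mae) {
      best_mae <- mae
      best <- p
    }
  }
  list(Q = Q_est[, best, drop = FALSE], perm = best, mae = best_mae)
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in permutations_of(k - 1L)) {
      rest <- seq_len(k)[-i]
      out[[length(out) + 1]] <- c(i, rest[p])
    }
  }
  out
}

# mean silhouette width of a 1-D split into two groups, without depending on
# a clustering package at run time (tests cross-check against
# cluster::silhouette)
silhouette_1d <- function(x, labels) {
  labs <- unique(labels)
  stopifnot(length(labs) == 2)
  s <- vapply(seq_along(x), function(i) {
    own <- x[labels == labels[i]]
    oth <- x[labels != labels[i]]
    a <- if (length(own) > 1) sum(abs(x[i] - own)) / (length(own) - 1) else 0
    b <- mean(abs(x[i] - oth))
    if (length(own) == 1) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
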