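#' Build an alternate-allele dosage matrix
#'
#' Converts a biallelic [variant_dataset] into a numeric samples x sites
#' matrix of alternate-allele dosages (0, 1, 2) with an explicit missingness
#' mask. Multi-allelic records are an error: they must be excluded upstream.
#'
#' @param ds A [variant_dataset] with only biallelic records.
#' @return A `genotype_matrix`: list with `values` (numeric matrix, `NA` at
#'   masked cells), `mask` (logical matrix, `TRUE` = missing), `sample_ids`
#'   and `site_ids` (`contig:pos`).
#' @export
build_dosage_matrix <- function(ds) {
  stopifnot(inherits(ds, "variant_dataset"))
  multi <- which(lengths(ds$alt) > 1)
  if (length(multi) > 0) {
    stop(sprintf("record %d (%s:%d) is multi-allelic; dosage matrix requires biallelic records",
                 multi[1], ds$contig[multi[1]], ds$pos[multi[1]]))
  }
  vals <- t(ds$gt1 + ds$gt2)  # samples x sites
  mask <- is.na(vals)
  storage.mode(vals) <- "double"
  dimnames(vals) <- NULL
  structure(list(values = vals, mask = mask,
                 sample_ids = ds$samples,
                 site_ids = if (n_records(ds)) paste0(ds$contig, ":", ds$pos)
                            else character(0)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  invisible(x)
}

#' Mean-impute missing dosages
#'
#' Replaces every masked cell by the unmasked mean dosage of its site and
#' clears the mask. Imputation preserves each site's mean exactly. A site
#' with no unmasked call has no defined mean and is an error (such sites
#' cannot survive the site-completeness filter).
#'
#' @param gm A `genotype_matrix`.
#' @return A complete `genotype_matrix` (all-`FALSE` mask).
#' @export
mean_impute <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  vals <- gm$values
  if (ncol(vals) > 0) {
    n_obs <- colSums(!gm$mask)
    if (any(n_obs == 0)) {
      stop(sprintf("site %s has no non-missing call; cannot impute",
                   gm$site_ids[which(n_obs == 0)[1]]))
    }
    mu <- colMeans(vals, na.rm = TRUE)
    idx <- which(gm$mask, arr.ind = TRUE)
    if (nrow(idx) > 0) vals[idx] <- mu[idx[, 2]]
  }
  structure(list(values = vals,
                 mask = matrix(FALSE, nrow(vals), ncol(vals)),
                 sample_ids = gm$sample_ids, site_ids = gm$site_ids),
            class = "genotype_matrix")
}

#' Centre (and optionally standardize) site columns
#'
#' Subtracts each site's mean dosage; with `scale = TRUE` also divides by the
#' site standard deviation, dropping zero-variance columns (they carry no
#' ordination signal) with a message reporting the count.
#'
#' @param gm A complete `genotype_matrix` (no masked cells).
#' @param scale Logical: divide columns by their standard deviation?
#' @return A plain numeric matrix (samples x sites) with attribute
#'   `dropped_sites` naming any zero-variance sites removed under scaling.
#' @export
center_sites <- function(gm, scale = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (any(gm$mask)) stop("center_sites requires a complete matrix; impute first")
  x <- scale(gm$values, center = TRUE, scale = FALSE)
  dropped <- character(0)
  if (scale && ncol(x) > 0) {
    sds <- apply(gm$values, 2, stats::sd)
    zero <- sds < .Machine$double.eps^0.5
    if (any(zero)) {
      dropped <- gm$site_ids[zero]
      message(sprintf("center_sites: dropped %d zero-variance site(s)",
                      sum(zero)))
    }
    x <- sweep(x[, !zero, drop = FALSE], 2, sds[!zero], "/")
    colnames(x) <- NULL
  }
  attr(x, "scaled:center") <- NULL
  attr(x, "dropped_sites") <- dropped
  rownames(x) <- gm$sample_ids
  x
}
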