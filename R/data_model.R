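#' Construct a variant dataset
#'
#' The in-memory representation of a set of unphased, diploid-coded SNP calls
#' across samples, as produced by a RAD/GBS assembler. Genotypes are stored as
#' two integer matrices (`n_records x n_samples`) holding the unordered allele
#' pair of each call sorted so that `gt1 <= gt2`; a missing call is `NA` in
#' both. Allele index 0 is the reference allele, index `k` the k-th alternate.
#'
#' @param samples Character vector of unique sample identifiers (column order
#'   of the genotype matrices).
#' @param contig Character vector, one contig/locus identifier per record.
#' @param pos Integer vector of 1-based positions within each contig.
#' @param ref Character vector of reference alleles (single nucleotides).
#' @param alt List of character vectors, the ordered alternate alleles of each
#'   record (at least one per record).
#' @param gt1,gt2 Integer matrices of allele indices, `n_records x n_samples`,
#'   with `gt1 <= gt2` and `NA` for missing calls.
#' @return An object of class `variant_dataset`.
#' @export
variant_dataset <- function(samples, contig, pos, ref, alt, gt1, gt2) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) {
    stop("sample identifiers must be unique")
  }
  contig <- as.character(contig)
  pos <- as.integer(pos)
  n_rec <- length(contig)
  if (length(pos) != n_rec || length(ref) != n_rec || length(alt) != n_rec) {
    stop("record fields (contig, pos, ref, alt) must have equal length")
  }
  if (n_rec > 0 && any(pos < 1L)) {
    stop("positions must be >= 1")
  }
  gt1 <- as.matrix(gt1); storage.mode(gt1) <- "integer"
  gt2 <- as.matrix(gt2); storage.mode(gt2) <- "integer"
  if (!identical(dim(gt1), c(n_rec, length(samples))) ||
      !identical(dim(gt2), c(n_rec, length(samples)))) {
    stop(sprintf("genotype matrices must be %d x %d", n_rec, length(samples)))
  }
  if (any(is.na(gt1) != is.na(gt2))) {
    stop("gt1 and gt2 must be missing at the same cells")
  }
  if (any(gt1 > gt2, na.rm = TRUE)) {
    stop("calls must be stored sorted (gt1 <= gt2)")
  }
  if (n_rec > 0) {
    n_alleles <- 1L + lengths(alt)
    bad <- which(apply_max_row(gt2) >= n_alleles)
    if (length(bad) > 0) {
      stop(sprintf("record %d: allele index exceeds allele count", bad[1]))
    }
  }
  structure(
    list(samples = samples, contig = contig, pos = pos,
         ref = as.character(ref), alt = alt, gt1 = gt1, gt2 = gt2),
    class = "variant_dataset"
  )
}

# row maxima ignoring NA; -1 for all-NA rows (0 records -> integer(0))
apply_max_row <- function(m) {
  if (nrow(m) == 0) return(integer(0))
  out <- suppressWarnings(apply(m, 1, max, na.rm = TRUE))
  out[!is.finite(out)] <- -1L
  as.integer(out)
}

#' Number of records / samples in a variant dataset
#' @param ds A `variant_dataset`.
#' @return Integer count.
#' @export
n_records <- function(ds) length(ds$contig)

#' @rdname n_records
#' @export
n_samples <- function(ds) length(ds$samples)

#' Subset a variant dataset by sample index
#' @param ds A `variant_dataset`.
#' @param idx Integer or logical index over samples (resp. records).
#' @return A `variant_dataset`.
#' @export
subset_samples <- function(ds, idx) {
  variant_dataset(ds$samples[idx], ds$contig, ds$pos, ds$ref, ds$alt,
                  ds$gt1[, idx, drop = FALSE], ds$gt2[, idx, drop = FALSE])
}

#' @rdname subset_samples
#' @export
subset_records <- function(ds, idx) {
  variant_dataset(ds$samples, ds$contig[idx], ds$pos[idx], ds$ref[idx],
                  ds$alt[idx], ds$gt1[idx, , drop = FALSE],
                  ds$gt2[idx, , drop = FALSE])
}

#' @export
print.variant_dataset <- function(x, ...) {
  cat(sprintf("variant_dataset: %d records x %d samples (%d contigs)\n",
              n_records(x), n_samples(x), length(unique(x$contig))))
  invisible(x)
}

#' Test two datasets for field-by-field equality
#' @param a,b `variant_dataset` objects.
#' @return Logical scalar.
#' @export
datasets_identical <- function(a, b) {
  identical(a$samples, b$samples) && identical(a$contig, b$contig) &&
    identical(a$pos, b$pos) && identical(a$ref, b$ref) &&
    identical(unname(a$alt), unname(b$alt)) &&
    identical(unname(a$gt1), unname(b$gt1)) &&
    identical(unname(a$gt2), unname(b$gt2))
}

#' Per-record fraction of missing calls
#' @param ds A `variant_dataset`.
#' @return Numeric vector, one value per record.
#' @export
site_missingness <- function(ds) {
  if (n_samples(ds) == 0) return(rep(NA_real_, n_records(ds)))
  rowMeans(is.na(ds$gt1))
}

#' Per-sample fraction of missing calls
#' @param ds A `variant_dataset`.
#' @return Numeric vector, one value per sample, named.
#' @export
individual_missingness <- function(ds) {
  if (n_records(ds) == 0) {
    stop("individual missingness is undefined on a dataset with 0 records")
  }
  stats::setNames(colMeans(is.na(ds$gt1)), ds$samples)
}

#' Per-record allele counts over non-missing calls
#'
#' Tallies allele indices (0 = ref) across both alleles of every non-missing
#' call of one record.
#'
#' @param ds A `variant_dataset`.
#' @param i Record index.
#' @return Integer vector of counts, one per allele (ref first).
#' @export
allele_counts <- function(ds, i) {
  n_all <- 1L + length(ds$alt[[i]])
  tabulate(c(ds$gt1[i, ], ds$gt2[i, ]) + 1L, nbins = n_all)
}
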