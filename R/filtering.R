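#' Filter cascade configuration
#'
#' Bundles the thresholds of the ordered filtering cascade. Defaults are the
#' multi-species profile used throughout the package: individuals with more
#' than 40% missing calls are dropped, sites typed in fewer than 80% of the
#' remaining individuals are dropped, sites with minor allele frequency below
#' 1% are dropped, and each contig is thinned to its single most central SNP.
#'
#' @param max_individual_missing Fraction in \[0, 1\]: an individual is
#'   removed when its missing fraction is strictly greater than this.
#' @param min_site_presence Fraction in \[0, 1\]: a site is kept when its
#'   non-missing call fraction is at least this.
#' @param maf Fraction in \[0, 0.5\]: a site is kept when its minor allele
#'   frequency (over non-missing calls) is at least this.
#' @param thin_to_center Logical: keep only the SNP closest to each locus
#'   centre?
#' @param min_allele_count Optional integer: if supplied, the MAF stage
#'   instead keeps sites whose minor allele is observed at least this many
#'   times (the "minimum allele frequency of 2 alleles" convention).
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_individual_missing = 0.40,
                          min_site_presence = 0.80,
                          maf = 0.01,
                          thin_to_center = TRUE,
                          min_allele_count = NULL) {
  stopifnot(max_individual_missing >= 0, max_individual_missing <= 1,
            min_site_presence >= 0, min_site_presence <= 1,
            maf >= 0, maf <= 0.5)
  if (!is.null(min_allele_count)) {
    stopifnot(min_allele_count >= 1)
  }
  structure(list(max_individual_missing = max_individual_missing,
                 min_site_presence = min_site_presence,
                 maf = maf,
                 thin_to_center = isTRUE(thin_to_center),
                 min_allele_count = min_allele_count),
            class = "filter_config")
}

#' Remove individuals with excess missing data
#'
#' Drops every sample whose fraction of missing calls over the current
#' records is strictly greater than `max_missing`; records are untouched.
#'
#' @param ds A [variant_dataset].
#' @param max_missing Fraction in \[0, 1\].
#' @return The filtered [variant_dataset].
#' @export
filter_individual_missingness <- function(ds, max_missing) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  frac <- individual_missingness(ds)  # errors on 0 records
  subset_samples(ds, which(frac <= max_missing))
}

#' Remove sites typed in too few individuals
#'
#' Keeps a record iff its non-missing call fraction over the current sample
#' set is at least `min_presence` (boundary inclusive, matching the
#' "maximum 20% missing per locus" convention).
#'
#' @param ds A [variant_dataset].
#' @param min_presence Fraction in \[0, 1\].
#' @return The filtered [variant_dataset].
#' @export
filter_site_completeness <- function(ds, min_presence) {
  stopifnot(min_presence >= 0, min_presence <= 1)
  if (n_records(ds) == 0) return(ds)
  present <- 1 - site_missingness(ds)
  subset_records(ds, which(present >= min_presence))
}

#' Per-record minor allele frequency and count
#'
#' MAF is the second-largest allele frequency among non-missing calls (for a
#' biallelic site, `min(f, 1 - f)`); records with no non-missing calls get
#' `NA`.
#'
#' @param ds A [variant_dataset].
#' @return Data frame with columns `maf` and `mac` (minor allele count).
#' @export
site_maf <- function(ds) {
  n_rec <- n_records(ds)
  maf <- numeric(n_rec)
  mac <- integer(n_rec)
  for (i in seq_len(n_rec)) {
    cnt <- allele_counts(ds, i)
    tot <- sum(cnt)
    if (tot == 0) {
      maf[i] <- NA_real_
      mac[i] <- NA_integer_
    } else {
      srt <- sort(cnt, decreasing = TRUE)
      mac[i] <- if (length(srt) >= 2) srt[2] else 0L
      maf[i] <- mac[i] / tot
    }
  }
  data.frame(maf = maf, mac = mac)
}

#' Remove sites by minor allele frequency
#'
#' Keeps a record iff its minor allele frequency (computed over non-missing
#' calls, two alleles per call) is at least `maf` — a site exactly at the
#' threshold is kept. Monomorphic sites have MAF 0 and are dropped for any
#' `maf > 0`. Records with zero non-missing calls are always dropped. If
#' `min_allele_count` is given, the criterion is instead a minimum count of
#' the minor allele.
#'
#' @param ds A [variant_dataset].
#' @param maf Fraction in \[0, 0.5\].
#' @param min_allele_count Optional integer minimum minor-allele count.
#' @return The filtered [variant_dataset].
#' @export
filter_maf <- function(ds, maf, min_allele_count = NULL) {
  stopifnot(maf >= 0, maf <= 0.5)
  if (n_records(ds) == 0) return(ds)
  tab <- site_maf(ds)
  if (is.null(min_allele_count)) {
    keep <- !is.na(tab$maf) & tab$maf >= maf
  } else {
    keep <- !is.na(tab$mac) & tab$mac >= min_allele_count
  }
  subset_records(ds, which(keep))
}

#' Thin each contig to its single most central SNP
#'
#' For every contig, keeps exactly the record minimizing the distance
#' `|pos - centre|`. The centre is `(alignment_length + 1) / 2` when the
#' contig's locus alignment is available in `loci`, otherwise the midpoint of
#' the observed SNP positions, `(min(pos) + max(pos)) / 2`. Ties are broken
#' toward the lower position (deterministic).
#'
#' @param ds A [variant_dataset].
#' @param loci Optional `loci_collection` giving alignment lengths.
#' @return The thinned [variant_dataset], one record per contig.
#' @export
thin_to_center_snp <- function(ds, loci = NULL) {
  if (n_records(ds) == 0) return(ds)
  keep <- vapply(split(seq_len(n_records(ds)), ds$contig), function(idx) {
    ctg <- ds$contig[idx[1]]
    centre <- if (!is.null(loci) && ctg %in% names(loci)) {
      (nchar(loci[[ctg]]$seqs[[1]]) + 1) / 2
    } else {
      (min(ds$pos[idx]) + max(ds$pos[idx])) / 2
    }
    d <- abs(ds$pos[idx] - centre)
    cand <- idx[d == min(d)]
    cand[which.min(ds$pos[cand])]
  }, integer(1))
  subset_records(ds, sort(unname(keep)))
}

#' Apply the ordered filtering cascade
#'
#' Runs individual-missingness, site-completeness, MAF and (optionally)
#' centre-SNP thinning, in exactly that order, and returns the filtered
#' dataset together with a per-stage accounting report. The order matters:
#' removing high-missingness individuals first changes which sites pass the
#' completeness threshold.
#'
#' @param ds A [variant_dataset].
#' @param cfg A [filter_config].
#' @param loci Optional `loci_collection` for centre definition in thinning.
#' @return List with elements `dataset` (the filtered [variant_dataset]) and
#'   `report` (data frame: stage, samples in/out, sites in/out).
#' @export
apply_cascade <- function(ds, cfg, loci = NULL) {
  stopifnot(inherits(cfg, "filter_config"))
  stages <- list()
  step <- function(name, fn, d) {
    out <- fn(d)
    stages[[length(stages) + 1]] <<- data.frame(
      stage = name,
      n_samples_in = n_samples(d), n_samples_out = n_samples(out),
      n_sites_in = n_records(d), n_sites_out = n_records(out))
    out
  }
  out <- step("individual_missingness",
              function(d) filter_individual_missingness(
                d, cfg$max_individual_missing), ds)
  out <- step("site_completeness",
              function(d) filter_site_completeness(
                d, cfg$min_site_presence), out)
  out <- step("maf",
              function(d) filter_maf(d, cfg$maf, cfg$min_allele_count), out)
  if (cfg$thin_to_center) {
    out <- step("thin_center", function(d) thin_to_center_snp(d, loci), out)
  }
  report <- do.call(rbind, stages)
  class(report) <- c("filter_report", class(report))
  list(dataset = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter cascade report:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
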