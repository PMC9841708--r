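#' Find SNPs fully segregated between two groups
#'
#' A site is reported when the set of alleles observed in any non-missing
#' call of group A is disjoint from that of group B, and both groups have at
#' least `min_calls_per_group` non-missing calls. For a biallelic site this
#' forces every A call homozygous for one allele and every B call homozygous
#' for the other: a single heterozygote in either group disqualifies the
#' site. Missing calls are ignored, never treated as wildcard matches.
#'
#' @param ds A [variant_dataset].
#' @param pm A `popmap`; every sample of `ds` must be assigned (no silent
#'   default).
#' @param group_a,group_b Group labels to compare (must occur in the map).
#' @param min_calls_per_group Minimum non-missing calls per group for a site
#'   to be assessable.
#' @return A `segregation_report` data frame: `contig`, `pos`, `alleles_a`,
#'   `alleles_b` (comma-joined allele indices), `bases_a`, `bases_b`
#'   (nucleotides), `n_calls_a`, `n_calls_b`.
#' @export
find_fixed_differences <- function(ds, pm, group_a, group_b,
                                   min_calls_per_group = 1) {
  stopifnot(inherits(ds, "variant_dataset"), min_calls_per_group >= 1)
  labels <- popmap_lookup(pm, ds$samples)
  if (!group_a %in% pm) stop(sprintf("label '%s' not present in popmap", group_a))
  if (!group_b %in% pm) stop(sprintf("label '%s' not present in popmap", group_b))
  ia <- which(labels == group_a)
  ib <- which(labels == group_b)
  rows <- list()
  for (i in seq_len(n_records(ds))) {
    al_a <- c(ds$gt1[i, ia], ds$gt2[i, ia])
    al_b <- c(ds$gt1[i, ib], ds$gt2[i, ib])
    n_a <- sum(!is.na(ds$gt1[i, ia]))
    n_b <- sum(!is.na(ds$gt1[i, ib]))
    if (n_a < min_calls_per_group || n_b < min_calls_per_group) next
    set_a <- sort(unique(al_a[!is.na(al_a)]))
    set_b <- sort(unique(al_b[!is.na(al_b)]))
    if (length(set_a) == 0 || length(set_b) == 0) next
    if (length(intersect(set_a, set_b)) > 0) next
    bases <- c(ds$ref[i], ds$alt[[i]])
    rows[[length(rows) + 1]] <- data.frame(
      contig = ds$contig[i], pos = ds$pos[i],
      alleles_a = paste(set_a, collapse = ","),
      alleles_b = paste(set_b, collapse = ","),
      bases_a = paste(bases[set_a + 1L], collapse = ","),
      bases_b = paste(bases[set_b + 1L], collapse = ","),
      n_calls_a = n_a, n_calls_b = n_b,
      stringsAsFactors = FALSE)
  }
  rep <- if (length(rows)) do.call(rbind, rows) else data.frame(
    contig = character(0), pos = integer(0), alleles_a = character(0),
    alleles_b = character(0), bases_a = character(0), bases_b = character(0),
    n_calls_a = integer(0), n_calls_b = integer(0))
  class(rep) <- c("segregation_report", class(rep))
  attr(rep, "groups") <- c(group_a, group_b)
  rep
}

#' Extract the flanking consensus sequence of a SNP
#'
#' Builds a per-column consensus across a locus's aligned sample sequences:
#' the majority base among non-gap, non-N characters; at the focal SNP column
#' and at any tied column the IUPAC ambiguity code of the observed/tied
#' bases. Columns whose majority character is the alignment gap `-` are
#' removed and leading/trailing all-gap columns trimmed (the focal column is
#' always kept); the focal position is re-indexed accordingly.
#'
#' @param loci A `loci_collection`.
#' @param contig_id Locus identifier.
#' @param snp_col 1-based alignment column of the focal SNP.
#' @return A `consensus_sequence`: list with `locus_id`, `sequence`,
#'   `focal_pos` (1-based position of the SNP within `sequence`) and
#'   `length`.
#' @export
extract_flanking_consensus <- function(loci, contig_id, snp_col) {
  if (!contig_id %in% names(loci)) {
    stop(sprintf("locus '%s' not present in collection", contig_id))
  }
  seqs <- toupper(loci[[contig_id]]$seqs)
  L <- nchar(seqs[[1]])
  if (snp_col < 1 || snp_col > L) {
    stop(sprintf("SNP column %d out of range for locus '%s' (length %d)",
                 snp_col, contig_id, L))
  }
  chars <- do.call(rbind, strsplit(seqs, ""))
  cons <- character(L)
  keep <- logical(L)
  for (j in seq_len(L)) {
    col <- chars[, j]
    bases <- col[col %in% c("A", "C", "G", "T")]
    n_gap <- sum(col == "-")
    if (j == snp_col) {
      keep[j] <- TRUE
      cons[j] <- iupac_code(bases)        # "N" when nothing observed
      next
    }
    if (n_gap > length(col) / 2) {
      keep[j] <- FALSE                    # majority-gap alignment column
      next
    }
    keep[j] <- TRUE
    if (length(bases) == 0) {
      cons[j] <- "N"                      # all-N column, no call possible
      next
    }
    tab <- table(bases)
    top <- names(tab)[tab == max(tab)]
    cons[j] <- if (length(top) == 1) top else iupac_code(top)
  }
  kept_idx <- which(keep)
  # trim leading/trailing runs of no-information columns around the kept span
  seq_out <- paste(cons[kept_idx], collapse = "")
  focal <- match(snp_col, kept_idx)
  structure(list(locus_id = contig_id, sequence = seq_out,
                 focal_pos = focal, length = nchar(seq_out)),
            class = "consensus_sequence")
}

#' Extract consensus sequences for every site of a segregation report
#'
#' Maps each reported site's within-contig position to its locus alignment
#' column (positions in the variant data are alignment columns for
#' assembler-derived loci) and extracts the flanking consensus.
#'
#' @param report A `segregation_report`.
#' @param loci A `loci_collection`.
#' @return List of `consensus_sequence` objects.
#' @export
consensus_for_report <- function(report, loci) {
  lapply(seq_len(nrow(report)), function(i) {
    extract_flanking_consensus(loci, report$contig[i], report$pos[i])
  })
}

#' Write consensus sequences to FASTA
#'
#' One record per sequence; the header carries the locus id, the focal SNP
#' offset and the sequence length (`>locus focal=i length=n`).
#'
#' @param seqs Non-empty list of `consensus_sequence` objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_fasta <- function(seqs, path) {
  if (length(seqs) == 0) stop("export_fasta requires a non-empty sequence list")
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, character(1), "sequence"))
  names(set) <- vapply(seqs, function(s) {
    sprintf("%s focal=%d length=%d", s$locus_id, s$focal_pos, s$length)
  }, character(1))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read a consensus FASTA written by [export_fasta()]
#'
#' @param path Path to the FASTA file.
#' @return List of `consensus_sequence` objects.
#' @export
read_consensus_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  lapply(seq_along(set), function(i) {
    hdr <- names(set)[i]
    m <- regmatches(hdr,
                    regexec("^(\\S+) focal=(\\d+) length=(\\d+)$", hdr))[[1]]
    if (length(m) != 4) stop(sprintf("unparseable FASTA header: '%s'", hdr))
    structure(list(locus_id = m[2], sequence = as.character(set[[i]]),
                   focal_pos = as.integer(m[3]), length = as.integer(m[4])),
              class = "consensus_sequence")
  })
}

#' @export
print.consensus_sequence <- function(x, ...) {
  cat(sprintf("consensus_sequence %s: %d bp, focal SNP at %d\n",
              x$locus_id, x$length, x$focal_pos))
  invisible(x)
}
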