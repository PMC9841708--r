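#' Read a VCF file into a variant dataset
#'
#' Minimal VCF 4.x reader for GT-only population data. All sample columns are
#' parsed; `./.`, `.|.` and `.` (and any call with a `.` allele) become
#' missing. Phased separators are accepted but phase is discarded: calls are
#' stored as unordered pairs, so `0|1` and `1/0` parse identically. Genotype
#' arity other than 2 is rejected: the package works on diploid-coded calls
#' (the coding RAD assemblers emit even for polyploid samples) and refuses to
#' silently collapse true polyploid genotypes.
#'
#' @param path Path to a VCF 4.x file with a GT FORMAT field.
#' @return A [variant_dataset].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop(sprintf("VCF file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0 || !startsWith(lines[1], "##fileformat=VCF")) {
    stop("malformed VCF header at line 1: missing ##fileformat declaration")
  }
  hdr_idx <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_idx) != 1) {
    stop("malformed VCF header: expected exactly one #CHROM line")
  }
  meta_bad <- which(!startsWith(lines[seq_len(hdr_idx - 1)], "##"))
  if (length(meta_bad) > 0) {
    stop(sprintf("malformed VCF header at line %d: expected '##' meta line",
                 meta_bad[1]))
  }
  hdr <- strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]]
  fixed_cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                  "INFO", "FORMAT")
  if (length(hdr) < 10 || !identical(hdr[1:9], fixed_cols)) {
    stop(sprintf("malformed VCF header at line %d: bad column line", hdr_idx))
  }
  samples <- hdr[-(1:9)]
  body <- lines[-seq_len(hdr_idx)]
  n_rec <- length(body)
  n_smp <- length(samples)
  if (n_rec == 0) {
    return(variant_dataset(samples, character(0), integer(0), character(0),
                           list(), matrix(NA_integer_, 0, n_smp),
                           matrix(NA_integer_, 0, n_smp)))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  lens <- lengths(fields)
  bad <- which(lens != 9L + n_smp)
  if (length(bad) > 0) {
    stop(sprintf(
      "record %d: expected %d sample columns, found %d",
      bad[1], n_smp, max(0L, lens[bad[1]] - 9L)))
  }
  tab <- matrix(unlist(fields), nrow = n_rec, byrow = TRUE)
  contig <- tab[, 1]
  pos <- as.integer(tab[, 2])
  ref <- tab[, 4]
  alt <- strsplit(tab[, 5], ",", fixed = TRUE)
  alt <- lapply(alt, function(a) a[a != "."])
  fmt <- strsplit(tab[, 9], ":", fixed = TRUE)
  gt_pos <- vapply(fmt, function(f) match("GT", f), integer(1))
  if (anyNA(gt_pos)) {
    stop(sprintf("record %d: FORMAT has no GT field", which(is.na(gt_pos))[1]))
  }
  calls <- tab[, -(1:9), drop = FALSE]
  # pull the GT subfield out of each call
  for (i in seq_len(n_rec)) {
    if (gt_pos[i] != 1L || any(grepl(":", calls[i, ], fixed = TRUE))) {
      calls[i, ] <- vapply(strsplit(calls[i, ], ":", fixed = TRUE),
                           `[`, character(1), gt_pos[i])
    }
  }
  calls <- gsub("|", "/", calls, fixed = TRUE)
  is_miss <- calls == "." | grepl(".", calls, fixed = TRUE)
  nonmiss <- calls[!is_miss]
  if (length(nonmiss) > 0) {
    n_sep <- nchar(nonmiss) - nchar(gsub("/", "", nonmiss, fixed = TRUE))
    if (any(n_sep != 1L)) {
      bad_call <- nonmiss[n_sep != 1L][1]
      stop(sprintf(
        paste0("genotype '%s' does not have arity 2; only diploid-coded ",
               "calls are supported (polyploid GT fields are rejected, ",
               "not collapsed)"), bad_call))
    }
  }
  a1 <- suppressWarnings(as.integer(sub("/.*$", "", calls)))
  a2 <- suppressWarnings(as.integer(sub("^.*/", "", calls)))
  a1[is_miss] <- NA_integer_
  a2[is_miss] <- NA_integer_
  if (any(is.na(a1) != is_miss) || any(is.na(a2) != is_miss)) {
    stop("malformed genotype call: non-integer allele index")
  }
  gt1 <- matrix(pmin(a1, a2), n_rec, n_smp)
  gt2 <- matrix(pmax(a1, a2), n_rec, n_smp)
  variant_dataset(samples, contig, pos, ref, alt, gt1, gt2)
}

#' Write a variant dataset as minimal VCF 4.2
#'
#' Emits a GT-only VCF (CHROM, POS, REF, ALT plus genotype columns); missing
#' calls are written as `./.`. Output is canonical, so
#' write -> read -> write is byte-stable.
#'
#' @param ds A [variant_dataset].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(ds, path) {
  stopifnot(inherits(ds, "variant_dataset"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=gbspop",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ds$samples), collapse = "\t")
  )
  if (n_records(ds) > 0) {
    gt <- matrix(paste0(ds$gt1, "/", ds$gt2), nrow(ds$gt1), ncol(ds$gt1))
    gt[is.na(ds$gt1)] <- "./."
    alt_str <- vapply(ds$alt, function(a) {
      if (length(a) == 0) "." else paste(a, collapse = ",")
    }, character(1))
    left <- paste(ds$contig, ds$pos, ".", ds$ref, alt_str, ".", ".", ".",
                  "GT", sep = "\t")
    body <- paste(left, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    # 0-sample edge: apply() collapses to character(0) rows
    if (n_samples(ds) == 0) body <- left
    writeLines(c(hdr, body), path)
  } else {
    writeLines(hdr, path)
  }
  invisible(path)
}

#' Read a population map
#'
#' Two-column whitespace-delimited text assigning each sample to a group
#' (species or site) label. Lines starting with `#` are comments. A sample
#' listed twice with the same label is accepted once; conflicting labels are
#' an error.
#'
#' @param path Path to the popmap file.
#' @return A named character vector (names = samples, values = labels) of
#'   class `popmap`.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) stop(sprintf("popmap file not found: %s", path))
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty population map")
  parts <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    stop(sprintf("popmap line %d: expected two columns", bad[1]))
  }
  smp <- vapply(parts, `[`, character(1), 1)
  lab <- vapply(parts, `[`, character(1), 2)
  for (s in unique(smp[duplicated(smp)])) {
    if (length(unique(lab[smp == s])) > 1) {
      stop(sprintf("sample '%s' assigned conflicting labels", s))
    }
  }
  keep <- !duplicated(smp)
  structure(stats::setNames(lab[keep], smp[keep]), class = "popmap")
}

#' Write a population map
#' @param pm Named character vector (sample -> label).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_popmap <- function(pm, path) {
  writeLines(paste(names(pm), unname(pm), sep = "\t"), path)
  invisible(path)
}

#' Look up group labels for samples, erroring on unassigned samples
#' @param pm A `popmap`.
#' @param samples Character vector of sample ids.
#' @return Character vector of labels.
#' @export
popmap_lookup <- function(pm, samples) {
  miss <- setdiff(samples, names(pm))
  if (length(miss) > 0) {
    stop(sprintf("sample(s) not assigned in population map: %s",
                 paste(miss, collapse = ", ")))
  }
  unname(pm[samples])
}

#' Read an ipyrad-style .loci file
#'
#' Parses the block dialect: each locus is a run of `sample<ws>sequence`
#' lines terminated by a `//` line whose trailing annotation marks variable
#' columns with `*` or `-` flags and carries the locus identifier between
#' pipes (`|id|`). All sequences of a block must be aligned (equal length,
#' same start column).
#'
#' @param path Path to the .loci file.
#' @return A `loci_collection`: named list of loci, each a list with `seqs`
#'   (named character vector of aligned sequences) and `snp_cols` (integer
#'   vector of 1-based variable column positions).
#' @export
read_loci <- function(path) {
  if (!file.exists(path)) stop(sprintf(".loci file not found: %s", path))
  lines <- readLines(path)
  loci <- list()
  block_names <- character(0)
  block_seqs <- character(0)
  seq_off <- NA_integer_
  n_block <- 0L
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, "//")) {
      n_block <- n_block + 1L
      if (length(block_seqs) == 0) {
        stop(sprintf("locus block %d: terminator before any sequence line",
                     n_block))
      }
      L <- nchar(block_seqs[1])
      marker <- substr(ln, seq_off + 1L, seq_off + L)
      marker <- formatC(marker, width = -L)  # pad if line ends early
      chars <- strsplit(marker, "")[[1]]
      snp_cols <- which(chars %in% c("*", "-"))
      m <- regmatches(ln, regexec("\\|([^|]+)\\|", ln))[[1]]
      id <- if (length(m) == 2) m[2] else as.character(n_block)
      loci[[id]] <- list(seqs = stats::setNames(block_seqs, block_names),
                         snp_cols = as.integer(snp_cols))
      block_names <- character(0)
      block_seqs <- character(0)
      seq_off <- NA_integer_
    } else {
      m <- regmatches(ln, regexec("^(\\S+)([ \t]+)(\\S+)[ \t]*$", ln))[[1]]
      if (length(m) != 4) {
        stop(sprintf("malformed .loci sequence line: '%s'", ln))
      }
      off <- nchar(m[2]) + nchar(m[3])
      if (is.na(seq_off)) {
        seq_off <- off
      } else if (off != seq_off || nchar(m[4]) != nchar(block_seqs[1])) {
        stop(sprintf("locus block %d ('%s'): ragged alignment lengths",
                     n_block + 1L, m[2]))
      }
      block_names <- c(block_names, m[2])
      block_seqs <- c(block_seqs, m[4])
    }
  }
  if (length(block_seqs) > 0) {
    stop("unterminated final locus block (missing // line)")
  }
  structure(loci, class = "loci_collection")
}

#' Write a loci collection in the ipyrad-style .loci dialect
#'
#' Names are padded to a file-wide fixed width so that the `//` terminator's
#' `*` flags align with sequence columns; output is canonical, so
#' write -> read -> write is byte-stable.
#'
#' @param loci A `loci_collection`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_loci <- function(loci, path) {
  all_names <- unlist(lapply(loci, function(l) names(l$seqs)), use.names = FALSE)
  w <- max(2L, if (length(all_names)) max(nchar(all_names)) else 0L) + 4L
  out <- character(0)
  for (id in names(loci)) {
    l <- loci[[id]]
    L <- if (length(l$seqs)) nchar(l$seqs[[1]]) else 0L
    out <- c(out, paste0(formatC(names(l$seqs), width = -w), l$seqs))
    flags <- rep(" ", L)
    flags[l$snp_cols] <- "*"
    out <- c(out, paste0(formatC("//", width = -w),
                         paste(flags, collapse = ""), "|", id, "|"))
  }
  writeLines(out, path)
  invisible(path)
}

#' @export
print.loci_collection <- function(x, ...) {
  cat(sprintf("loci_collection: %d loci\n", length(x)))
  invisible(x)
}
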