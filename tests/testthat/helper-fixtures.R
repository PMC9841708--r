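# fixtures and independent brute-force oracles shared across test files

# build a variant_dataset from a character matrix of calls ("0/0", "0/1",
# "./.", ...), records in rows
make_ds <- function(calls, contig = NULL, pos = NULL, ref = NULL,
                    alt = NULL, samples = NULL) {
  calls <- as.matrix(calls)
  n_rec <- nrow(calls)
  n_smp <- ncol(calls)
  if (is.null(samples)) samples <- paste0("s", seq_len(n_smp))
  if (is.null(contig)) contig <- sprintf("c%d", seq_len(n_rec))
  if (is.null(pos)) pos <- rep(1L, n_rec)
  if (is.null(ref)) ref <- rep("A", n_rec)
  if (is.null(alt)) alt <- rep(list("G"), n_rec)
  gt1 <- matrix(NA_integer_, n_rec, n_smp)
  gt2 <- matrix(NA_integer_, n_rec, n_smp)
  for (i in seq_len(n_rec)) for (j in seq_len(n_smp)) {
    g <- calls[i, j]
    if (!grepl("\\.", g)) {
      ab <- sort(as.integer(strsplit(g, "[/|]")[[1]]))
      gt1[i, j] <- ab[1]
      gt2[i, j] <- ab[2]
    }
  }
  variant_dataset(samples, contig, pos, ref, alt, gt1, gt2)
}

# random biallelic dataset with missingness; test-side generator, independent
# of the package's synthetic_data module
random_ds <- function(seed, n_smp = 20, n_rec = 50, miss = 0.2) {
  set.seed(seed)
  n_contig <- max(1L, n_rec %/% 3L)
  contig <- sort(sample(sprintf("c%03d", seq_len(n_contig)), n_rec,
                        replace = TRUE))
  pos <- integer(n_rec)
  for (ct in unique(contig)) {
    idx <- which(contig == ct)
    pos[idx] <- sort(sample.int(80L, length(idx)))
  }
  calls <- matrix(sample(c("0/0", "0/1", "1/1"), n_rec * n_smp,
                         replace = TRUE, prob = c(0.6, 0.25, 0.15)),
                  n_rec, n_smp)
  calls[matrix(runif(n_rec * n_smp) < miss, n_rec, n_smp)] <- "./."
  make_ds(calls, contig = contig, pos = pos)
}

# ---- brute-force filter oracles (loop-based, no shared code paths) ----

oracle_keep_samples <- function(ds, max_missing) {
  keep <- integer(0)
  for (j in seq_along(ds$samples)) {
    n_miss <- 0L
    for (i in seq_len(n_records(ds))) {
      if (is.na(ds$gt1[i, j])) n_miss <- n_miss + 1L
    }
    if (n_miss / n_records(ds) <= max_missing) keep <- c(keep, j)
  }
  keep
}

oracle_keep_sites_presence <- function(ds, min_presence) {
  keep <- integer(0)
  for (i in seq_len(n_records(ds))) {
    n_call <- 0L
    for (j in seq_along(ds$samples)) {
      if (!is.na(ds$gt1[i, j])) n_call <- n_call + 1L
    }
    if (n_call / length(ds$samples) >= min_presence) keep <- c(keep, i)
  }
  keep
}

oracle_keep_sites_maf <- function(ds, maf) {
  keep <- integer(0)
  for (i in seq_len(n_records(ds))) {
    tally <- rep(0L, 1L + length(ds$alt[[i]]))
    for (j in seq_along(ds$samples)) {
      if (!is.na(ds$gt1[i, j])) {
        tally[ds$gt1[i, j] + 1L] <- tally[ds$gt1[i, j] + 1L] + 1L
        tally[ds$gt2[i, j] + 1L] <- tally[ds$gt2[i, j] + 1L] + 1L
      }
    }
    if (sum(tally) == 0) next
    srt <- sort(tally, decreasing = TRUE)
    minor <- if (length(srt) > 1) srt[2] else 0L
    if (minor / sum(tally) >= maf) keep <- c(keep, i)
  }
  keep
}

oracle_thin_keep <- function(ds, loci = NULL) {
  keep <- integer(0)
  for (ct in unique(ds$contig)) {
    idx <- which(ds$contig == ct)
    centre <- if (!is.null(loci) && ct %in% names(loci)) {
      (nchar(loci[[ct]]$seqs[[1]]) + 1) / 2
    } else {
      (min(ds$pos[idx]) + max(ds$pos[idx])) / 2
    }
    best <- idx[1]
    for (i in idx) {
      if (abs(ds$pos[i] - centre) < abs(ds$pos[best] - centre) ||
          (abs(ds$pos[i] - centre) == abs(ds$pos[best] - centre) &&
           ds$pos[i] < ds$pos[best])) {
        best <- i
      }
    }
    keep <- c(keep, best)
  }
  sort(keep)
}

# independent per-column consensus tally (character-by-character)
oracle_consensus <- function(seqs, focal) {
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  out <- character(0)
  focal_out <- NA_integer_
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    obs <- col[col %in% c("A", "C", "G", "T")]
    if (sum(col == "-") > length(col) / 2 && j != focal) next
    if (j == focal) {
      out <- c(out, iupac_code(obs))
      focal_out <- length(out)
    } else if (length(obs) == 0) {
      out <- c(out, "N")
    } else {
      tb <- table(obs)
      winners <- names(tb)[tb == max(tb)]
      out <- c(out, if (length(winners) == 1) winners else iupac_code(winners))
    }
  }
  list(sequence = paste(out, collapse = ""), focal_pos = focal_out)
}

# align two score matrices up to per-component sign
flip_align <- function(a, b) {
  for (k in seq_len(ncol(a))) {
    if (sum(abs(a[, k] - b[, k])) > sum(abs(a[, k] + b[, k]))) {
      b[, k] <- -b[, k]
    }
  }
  b
}
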