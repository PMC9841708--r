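popmap_of <- function(samples, labels) {
  structure(stats::setNames(labels, samples), class = "popmap")
}

test_that("a canonical fixed difference is reported; a heterozygote disqualifies", {
  calls <- rbind(c("0/0", "0/0", "./.", "1/1", "1/1"),
                 c("0/0", "0/1", "0/0", "1/1", "1/1"))
  ds <- make_ds(calls, contig = c("c1", "c2"), pos = c(3L, 4L))
  pm <- popmap_of(ds$samples, c("A", "A", "A", "B", "B"))
  rep <- find_fixed_differences(ds, pm, "A", "B")
  expect_equal(nrow(rep), 1)
  expect_equal(rep$contig, "c1")
  expect_equal(rep$alleles_a, "0")
  expect_equal(rep$alleles_b, "1")
  expect_equal(rep$n_calls_a, 2L)
  expect_equal(rep$n_calls_b, 2L)

  # swapping the groups yields the same site set
  rep_sw <- find_fixed_differences(ds, pm, "B", "A")
  expect_equal(rep_sw$contig, rep$contig)

  # min_calls_per_group: requiring 3 calls in A excludes the c1 site
  expect_equal(nrow(find_fixed_differences(ds, pm, "A", "B",
                                           min_calls_per_group = 3)), 0)

  expect_error(find_fixed_differences(ds, pm, "A", "Z"), "Z")
  pm_short <- popmap_of(ds$samples[-1], c("A", "A", "B", "B"))
  expect_error(find_fixed_differences(ds, pm_short, "A", "B"), "s1")
})

test_that("masking a disqualifying heterozygote can only grow the report", {
  for (seed in 1:5) {
    ds <- random_ds(seed + 400, n_smp = 12, n_rec = 40, miss = 0.1)
    pm <- popmap_of(ds$samples, rep(c("A", "B"), each = 6))
    base <- find_fixed_differences(ds, pm, "A", "B")
    base_sites <- paste0(base$contig, ":", base$pos)
    # find a record disqualified by exactly one A-side heterozygote
    for (i in seq_len(n_records(ds))) {
      het_a <- which(ds$gt1[i, 1:6] == 0 & ds$gt2[i, 1:6] == 1)
      if (length(het_a) != 1) next
      ds2 <- ds
      ds2$gt1[i, het_a] <- NA_integer_
      ds2$gt2[i, het_a] <- NA_integer_
      out <- find_fixed_differences(ds2, pm, "A", "B")
      expect_true(all(base_sites %in% paste0(out$contig, ":", out$pos)))
      break
    }
  }
})

test_that("planted fixed differences are recovered exactly on synthetic data", {
  sim <- simulate_dataset(sim_config(n_populations = 2,
                                     samples_per_population = 15,
                                     n_loci = 500, snps_per_locus = 1:2,
                                     n_planted_fixed_differences = 8,
                                     seed = 88))
  rep <- find_fixed_differences(sim$dataset, sim$popmap, "pop1", "pop2")
  found <- paste0(rep$contig, ":", rep$pos)
  expect_setequal(found, sim$truth$planted_sites)
})

test_that("consensus handles identical sequences, majority and tie columns", {
  loci <- structure(list(L1 = list(
    seqs = c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"),
    snp_cols = 4L)), class = "loci_collection")
  cs <- extract_flanking_consensus(loci, "L1", 4L)
  expect_equal(cs$sequence, "ACGTACGT")
  expect_equal(cs$focal_pos, 4L)
  expect_equal(cs$length, 8L)

  loci2 <- structure(list(L2 = list(
    seqs = c(a = "AAGG", b = "AANC", c = "GATC"),
    snp_cols = c(1L, 4L))), class = "loci_collection")
  cs2 <- extract_flanking_consensus(loci2, "L2", 1L)
  # col1 focal {A,A,G} -> R; col2 majority A; col3 tie {G,T} (one N) -> K;
  # col4 {G,C,C} -> C
  expect_equal(cs2$sequence, "RAKC")
  expect_equal(cs2$focal_pos, 1L)

  expect_error(extract_flanking_consensus(loci2, "nope", 1L), "nope")
  expect_error(extract_flanking_consensus(loci2, "L2", 9L), "out of range")
})

test_that("majority-gap columns are removed and the focal position re-indexed", {
  loci <- structure(list(L3 = list(
    seqs = c(a = "--ACGT--", b = "--ACCT--", c = "-TACCTG-"),
    snp_cols = 5L)), class = "loci_collection")
  cs <- extract_flanking_consensus(loci, "L3", 5L)
  # cols 1,2,7,8 are majority-gap -> dropped; kept cols 3..6 = ACC T/G...
  expect_equal(cs$focal_pos, 3L)
  expect_equal(substr(cs$sequence, 1, 2), "AC")
  expect_equal(cs$length, 4L)
})

test_that("consensus matches an independent per-column tally oracle", {
  sim <- simulate_dataset(sim_config(n_populations = 2,
                                     samples_per_population = 10,
                                     n_loci = 20, locus_length = 60,
                                     seed = 17))
  for (id in names(sim$loci)[1:10]) {
    for (col in sim$loci[[id]]$snp_cols) {
      cs <- extract_flanking_consensus(sim$loci, id, col)
      orc <- oracle_consensus(sim$loci[[id]]$seqs, col)
      expect_equal(cs$sequence, orc$sequence)
      expect_equal(cs$focal_pos, orc$focal_pos)
    }
  }
})

test_that("FASTA export round-trips headers, sequences and lengths", {
  loci <- structure(list(
    L1 = list(seqs = c(a = "ACGTACGT", b = "ACGTACGT"), snp_cols = 4L),
    L2 = list(seqs = c(a = "TTTTAA", b = "TTGTAA"), snp_cols = 3L)),
    class = "loci_collection")
  seqs <- list(extract_flanking_consensus(loci, "L1", 4L),
               extract_flanking_consensus(loci, "L2", 3L))
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  export_fasta(seqs, f1)
  back <- read_consensus_fasta(f1)
  expect_length(back, 2)
  for (i in 1:2) {
    expect_equal(back[[i]]$locus_id, seqs[[i]]$locus_id)
    expect_equal(back[[i]]$focal_pos, seqs[[i]]$focal_pos)
    expect_equal(back[[i]]$sequence, seqs[[i]]$sequence)
    expect_equal(back[[i]]$length, nchar(back[[i]]$sequence))
  }
  export_fasta(back, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(export_fasta(list(), f1), "non-empty")
})
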