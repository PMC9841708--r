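test_that("individual-missingness filter drops strictly-above-threshold samples", {
  # 10 records; per-sample missing fractions 0.0, 0.1, 0.5, 1.0
  calls <- matrix("0/1", 10, 4)
  calls[1, 2] <- "./."
  calls[1:5, 3] <- "./."
  calls[, 4] <- "./."
  ds <- make_ds(calls)
  out <- filter_individual_missingness(ds, 0.40)
  expect_equal(out$samples, c("s1", "s2"))
  expect_equal(n_records(out), 10)  # records untouched

  # boundary: exactly at the threshold is kept (strictly-greater drops)
  out <- filter_individual_missingness(ds, 0.50)
  expect_equal(out$samples, c("s1", "s2", "s3"))

  expect_equal(filter_individual_missingness(ds, 1.0)$samples, ds$samples)
  complete <- make_ds(matrix("0/0", 3, 3))
  expect_true(datasets_identical(
    filter_individual_missingness(complete, 0.0), complete))

  empty <- make_ds(matrix(character(0), 0, 3))
  expect_error(filter_individual_missingness(empty, 0.4), "0 records")
})

test_that("site-completeness filter keeps boundary-inclusive 80% presence", {
  calls <- matrix("0/1", 3, 10)
  calls[2, 1:2] <- "./."   # 8/10 present -> kept at 0.8
  calls[3, 1:3] <- "./."   # 7/10 present -> dropped at 0.8
  ds <- make_ds(calls)
  out <- filter_site_completeness(ds, 0.8)
  expect_equal(out$contig, c("c1", "c2"))
  expect_true(datasets_identical(filter_site_completeness(ds, 0), ds))
})

test_that("MAF filter keeps the 1-in-100-alleles boundary case and drops monomorphic sites", {
  calls <- matrix("0/0", 1, 50)
  calls[1, 1] <- "0/1"     # MAF = 1/100 = 0.01, boundary inclusive
  ds <- make_ds(calls)
  expect_equal(n_records(filter_maf(ds, 0.01)), 1)

  mono <- make_ds(matrix("0/0", 1, 50))
  expect_equal(n_records(filter_maf(mono, 0.01)), 0)

  # minimum-allele-count mode: 1 copy of the minor allele fails mac >= 2
  expect_equal(n_records(filter_maf(ds, 0, min_allele_count = 2)), 0)
  calls[1, 2] <- "0/1"
  expect_equal(n_records(filter_maf(make_ds(calls), 0,
                                    min_allele_count = 2)), 1)

  # a record with zero non-missing calls can never be kept
  allmiss <- make_ds(matrix("./.", 1, 5))
  expect_equal(n_records(filter_maf(allmiss, 0)), 0)
})

test_that("each filter matches its brute-force oracle on random datasets", {
  for (seed in 1:10) {
    ds <- random_ds(seed, n_smp = 20, n_rec = 50)
    expect_equal(
      filter_individual_missingness(ds, 0.25)$samples,
      ds$samples[oracle_keep_samples(ds, 0.25)])
    expect_true(datasets_identical(
      filter_site_completeness(ds, 0.8),
      subset_records(ds, oracle_keep_sites_presence(ds, 0.8))))
    expect_true(datasets_identical(
      filter_maf(ds, 0.05),
      subset_records(ds, oracle_keep_sites_maf(ds, 0.05))))
    expect_true(datasets_identical(
      thin_to_center_snp(ds),
      subset_records(ds, oracle_thin_keep(ds))))
  }
})

test_that("centre-SNP thinning picks the most central SNP with a low-position tie-break", {
  ds <- make_ds(matrix("0/1", 3, 2), contig = rep("c1", 3),
                pos = c(10L, 45L, 80L))
  loci <- structure(list(c1 = list(seqs = c(a = strrep("A", 100)),
                                   snp_cols = c(10L, 45L, 80L))),
                    class = "loci_collection")
  out <- thin_to_center_snp(ds, loci)     # centre (100+1)/2 = 50.5
  expect_equal(out$pos, 45L)

  # without loci: centre = (10+80)/2 = 45 -> same pick
  expect_equal(thin_to_center_snp(ds)$pos, 45L)

  single <- make_ds(matrix("0/1", 1, 2), contig = "c9", pos = 7L)
  expect_true(datasets_identical(thin_to_center_snp(single), single))

  # tie: pos 40 and 60 both 10 from centre 50 -> keep lower
  tie <- make_ds(matrix("0/1", 2, 2), contig = rep("c1", 2),
                 pos = c(40L, 60L))
  expect_equal(thin_to_center_snp(tie)$pos, 40L)
})

test_that("every filter is idempotent", {
  ds <- random_ds(77, n_smp = 15, n_rec = 40)
  f1 <- filter_individual_missingness(ds, 0.3)
  expect_true(datasets_identical(filter_individual_missingness(f1, 0.3), f1))
  f2 <- filter_site_completeness(ds, 0.8)
  expect_true(datasets_identical(filter_site_completeness(f2, 0.8), f2))
  f3 <- filter_maf(ds, 0.05)
  expect_true(datasets_identical(filter_maf(f3, 0.05), f3))
  f4 <- thin_to_center_snp(ds)
  expect_true(datasets_identical(thin_to_center_snp(f4), f4))
})

test_that("the cascade equals manual stage composition and reports stagewise counts", {
  ds <- random_ds(5, n_smp = 30, n_rec = 60)
  cfg <- filter_config(0.40, 0.80, 0.01, thin_to_center = TRUE)
  res <- apply_cascade(ds, cfg)
  manual <- thin_to_center_snp(
    filter_maf(
      filter_site_completeness(
        filter_individual_missingness(ds, 0.40), 0.80), 0.01))
  expect_true(datasets_identical(res$dataset, manual))

  # report chains: stage k input == stage k-1 output; non-increasing
  rep <- res$report
  expect_equal(rep$n_samples_in[-1], rep$n_samples_out[-nrow(rep)])
  expect_equal(rep$n_sites_in[-1], rep$n_sites_out[-nrow(rep)])
  expect_true(all(rep$n_samples_out <= rep$n_samples_in))
  expect_true(all(rep$n_sites_out <= rep$n_sites_in))
  expect_true(n_samples(res$dataset) <= n_samples(ds))
  expect_true(n_records(res$dataset) <= n_records(ds))

  # all-permissive config is the identity
  res0 <- apply_cascade(ds, filter_config(1.0, 0.0, 0.0,
                                          thin_to_center = FALSE))
  expect_true(datasets_identical(res0$dataset, ds))
  expect_equal(res0$report$n_sites_in, res0$report$n_sites_out)
})

test_that("stage order is observable: individual-then-site differs from site-then-individual", {
  # sample s5 is 60% missing overall; record r2 misses s4 but has s5.
  # individual-first: s5 dropped -> r2 presence 3/4 < 0.8 -> r2 dropped.
  # site-first: r2 presence 4/5 >= 0.8 -> r2 kept, then s5 dropped.
  calls <- matrix("0/1", 5, 5)
  calls[c(1, 3, 4), 5] <- "./."
  calls[2, 4] <- "./."
  ds <- make_ds(calls)
  canonical <- filter_site_completeness(
    filter_individual_missingness(ds, 0.40), 0.80)
  reversed <- filter_individual_missingness(
    filter_site_completeness(ds, 0.80), 0.40)
  expect_false(identical(canonical$contig, reversed$contig))
  expect_false("c2" %in% canonical$contig)
  expect_true("c2" %in% reversed$contig)

  cfg <- filter_config(0.40, 0.80, 0, thin_to_center = FALSE)
  expect_equal(apply_cascade(ds, cfg)$dataset$contig, canonical$contig)
})
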