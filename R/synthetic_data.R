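#' Configuration for the synthetic GBS dataset generator
#'
#' Describes an admixed set of populations under the Balding-Nichols / PSD
#' model, organized into contigs ("loci") carrying one to several linked
#' SNPs, with missing-completely-at-random genotype dropout and optionally a
#' set of planted diagnostic SNPs fully segregated between two designated
#' groups. Defaults emulate a post-assembly reduced-representation product at
#' desk scale: a few populations of a few dozen samples, thousands of short
#' contigs, moderate drift and missingness.
#'
#' @param n_populations Number of latent populations K.
#' @param samples_per_population Scalar or length-K vector of group sizes.
#' @param n_loci Number of contigs.
#' @param snps_per_locus Integer vector of candidate SNP counts per locus
#'   (sampled uniformly); a scalar fixes the count.
#' @param locus_length Alignment length of each contig in bp.
#' @param divergence Balding-Nichols drift parameter F in (0, 1); scalar or
#'   length-K vector (per-population divergence from the shared ancestral
#'   frequency).
#' @param admixture_alpha Dirichlet concentration for individual membership
#'   vectors; `0` means unadmixed one-hot memberships.
#' @param missing_rate_individual,missing_rate_site MCAR dropout rates in
#'   \[0, 1); each cell is masked with probability
#'   `1 - (1 - rate_ind) * (1 - rate_site)`.
#' @param n_planted_fixed_differences Number of sites planted as fixed
#'   differences (group A homozygous reference, group B homozygous
#'   alternate, no missingness at those sites) between the first two
#'   population labels.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_populations = 3,
                       samples_per_population = 20,
                       n_loci = 2000,
                       snps_per_locus = 1:3,
                       locus_length = 100,
                       divergence = 0.2,
                       admixture_alpha = 0,
                       missing_rate_individual = 0.05,
                       missing_rate_site = 0.05,
                       n_planted_fixed_differences = 0,
                       seed = 1) {
  K <- as.integer(n_populations)
  sizes <- rep_len(as.integer(samples_per_population), K)
  Fk <- rep_len(divergence, K)
  stopifnot(K >= 1, all(sizes >= 1), n_loci >= 1, locus_length >= 1,
            all(snps_per_locus >= 1), all(snps_per_locus <= locus_length),
            all(Fk > 0), all(Fk < 1), admixture_alpha >= 0,
            missing_rate_individual >= 0, missing_rate_individual < 1,
            missing_rate_site >= 0, missing_rate_site < 1,
            n_planted_fixed_differences >= 0,
            n_planted_fixed_differences <= n_loci)
  structure(list(n_populations = K, samples_per_population = sizes,
                 n_loci = as.integer(n_loci),
                 snps_per_locus = as.integer(snps_per_locus),
                 locus_length = as.integer(locus_length),
                 divergence = Fk, admixture_alpha = admixture_alpha,
                 missing_rate_individual = missing_rate_individual,
                 missing_rate_site = missing_rate_site,
                 n_planted_fixed_differences =
                   as.integer(n_planted_fixed_differences),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a GBS-style SNP dataset with ground truth
#'
#' Generates, from a single seed: ancestral allele frequencies
#' `p ~ Uniform(0.05, 0.95)` per locus; population frequencies
#' `p_k ~ Beta(p (1-F_k)/F_k, (1-p)(1-F_k)/F_k)` (Balding-Nichols), shared
#' with small jitter across a locus's linked SNPs; individual memberships
#' `q ~ Dirichlet(alpha)` (or one-hot blocks when `alpha = 0`); and dosages
#' `x ~ Binomial(2, q'p)`. Planted fixed differences between the first two
#' population labels are written over the first SNP of randomly chosen loci
#' (group A fixed `0/0`, group B fixed `1/1`) and exempted from missingness.
#' Any *accidental* fixed difference between the designated groups at a
#' non-planted site is broken (first group-A call set heterozygous) so the
#' returned truth lists exactly the fully segregated sites.
#'
#' @param cfg A [sim_config].
#' @return List with `dataset` ([variant_dataset]), `popmap` (`popmap`),
#'   `loci` (`loci_collection` of per-sample alignments consistent with the
#'   calls), and `truth` (list: `Q`, `P`, `planted_sites`, `labels`,
#'   `config`).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, simulate_dataset_impl(cfg))
}

simulate_dataset_impl <- function(cfg) {
  K <- cfg$n_populations
  sizes <- cfg$samples_per_population
  n <- sum(sizes)
  pops <- paste0("pop", seq_len(K))
  samples <- sprintf("s%03d", seq_len(n))

  if (cfg$admixture_alpha > 0) {
    Q <- rdirichlet(n, rep(cfg$admixture_alpha, K))
    labels <- pops[max.col(Q, ties.method = "first")]
  } else {
    Q <- matrix(0, n, K)
    labels <- rep(pops, sizes)
    Q[cbind(seq_len(n), match(labels, pops))] <- 1
  }
  colnames(Q) <- pops
  rownames(Q) <- samples

  group_a <- pops[1]
  group_b <- pops[min(2, K)]
  if (cfg$n_planted_fixed_differences > 0) {
    if (K < 2) stop("planting fixed differences requires >= 2 populations")
    if (!any(labels == group_a) || !any(labels == group_b)) {
      stop("a designated group has size 0; cannot plant fixed differences")
    }
  }

  bases <- c("A", "C", "G", "T")
  jitter_sd <- 0.02
  contigs <- sprintf("locus_%05d", seq_len(cfg$n_loci))
  snp_count <- if (length(cfg$snps_per_locus) == 1) {
    rep(cfg$snps_per_locus, cfg$n_loci)
  } else {
    sample(cfg$snps_per_locus, cfg$n_loci, replace = TRUE)
  }
  m <- sum(snp_count)

  contig <- character(m); pos <- integer(m)
  ref <- character(m); alt_b <- character(m)
  dosage <- matrix(0L, m, n)              # sites x samples
  P <- matrix(0, m, K, dimnames = list(NULL, pops))
  background <- character(cfg$n_loci)
  snp_cols_by_locus <- vector("list", cfg$n_loci)

  s <- 0L
  for (l in seq_len(cfg$n_loci)) {
    bg <- sample(bases, cfg$locus_length, replace = TRUE)
    background[l] <- paste(bg, collapse = "")
    p_anc <- stats::runif(1, 0.05, 0.95)
    p_base <- stats::rbeta(K, p_anc * (1 - cfg$divergence) / cfg$divergence,
                           (1 - p_anc) * (1 - cfg$divergence) / cfg$divergence)
    cols <- sort(sample.int(cfg$locus_length, snp_count[l]))
    snp_cols_by_locus[[l]] <- cols
    for (j in seq_along(cols)) {
      s <- s + 1L
      pk <- pmin(pmax(p_base + stats::rnorm(K, 0, jitter_sd), 0.01), 0.99)
      f <- as.vector(Q %*% pk)            # per-individual alt frequency
      dosage[s, ] <- stats::rbinom(n, 2L, f)
      P[s, ] <- pk
      contig[s] <- contigs[l]
      pos[s] <- cols[j]
      ref[s] <- bg[cols[j]]
      alt_b[s] <- sample(setdiff(bases, bg[cols[j]]), 1)
    }
  }

  ia <- which(labels == group_a)
  ib <- which(labels == group_b)

  # plant diagnostic fixed differences on the first SNP of chosen loci
  planted_idx <- integer(0)
  if (cfg$n_planted_fixed_differences > 0) {
    first_snp_of <- c(1L, utils::head(cumsum(snp_count), -1) + 1L)
    planted_loci <- sample.int(cfg$n_loci, cfg$n_planted_fixed_differences)
    planted_idx <- first_snp_of[planted_loci]
    for (s in planted_idx) {
      dosage[s, ia] <- 0L
      dosage[s, ib] <- 2L
      P[s, 1] <- 0
      P[s, min(2, K)] <- 1
    }
  }

  # MCAR missingness, exempting planted sites
  miss_rate <- 1 - (1 - cfg$missing_rate_individual) *
    (1 - cfg$missing_rate_site)
  if (miss_rate > 0) {
    mask <- matrix(stats::runif(m * n) < miss_rate, m, n)
    mask[planted_idx, ] <- FALSE
    dosage[mask] <- NA_integer_
  }

  # break accidental fixed differences between the designated groups so the
  # planted list is the complete ground truth
  if (K >= 2 && length(ia) > 0 && length(ib) > 0) {
    for (s in setdiff(seq_len(m), planted_idx)) {
      da <- dosage[s, ia]; db <- dosage[s, ib]
      da <- da[!is.na(da)]; db <- db[!is.na(db)]
      if (length(da) == 0 || length(db) == 0) next
      set_a <- unique(c(if (any(da < 2)) 0L, if (any(da > 0)) 1L))
      set_b <- unique(c(if (any(db < 2)) 0L, if (any(db > 0)) 1L))
      if (length(intersect(set_a, set_b)) == 0) {
        first_a <- ia[which(!is.na(dosage[s, ia]))[1]]
        dosage[s, first_a] <- 1L
      }
    }
  }

  gt1 <- matrix(NA_integer_, m, n)
  gt2 <- matrix(NA_integer_, m, n)
  obs <- !is.na(dosage)
  gt1[obs] <- ifelse(dosage[obs] == 2L, 1L, 0L)
  gt2[obs] <- ifelse(dosage[obs] == 0L, 0L, 1L)
  ds <- variant_dataset(samples, contig, pos, ref,
                        as.list(alt_b), gt1, gt2)

  loci <- vector("list", cfg$n_loci)
  names(loci) <- contigs
  site_of <- split(seq_len(m), contig)
  for (l in seq_len(cfg$n_loci)) {
    bg <- strsplit(background[l], "")[[1]]
    seq_mat <- matrix(rep(bg, each = n), n, cfg$locus_length)
    for (s in site_of[[contigs[l]]]) {
      col <- pos[s]
      chr <- rep("N", n)                  # het or missing -> N
      chr[!is.na(dosage[s, ]) & dosage[s, ] == 0L] <- ref[s]
      chr[!is.na(dosage[s, ]) & dosage[s, ] == 2L] <- alt_b[s]
      seq_mat[, col] <- chr
    }
    loci[[l]] <- list(
      seqs = stats::setNames(apply(seq_mat, 1, paste, collapse = ""), samples),
      snp_cols = snp_cols_by_locus[[l]])
  }
  class(loci) <- "loci_collection"

  pm <- structure(stats::setNames(labels, samples), class = "popmap")
  truth <- list(Q = Q, P = P,
                planted_sites = if (length(planted_idx))
                  paste0(contig[planted_idx], ":", pos[planted_idx])
                  else character(0),
                labels = labels,
                group_a = group_a, group_b = group_b,
                config = cfg)
  list(dataset = ds, popmap = pm, loci = loci, truth = truth)
}

#' Summarize a simulation's ground truth
#'
#' @param truth The `truth` element returned by [simulate_dataset()].
#' @return Character vector of report lines (also printed invisibly usable
#'   via `cat`).
#' @export
summarize_truth <- function(truth) {
  K <- ncol(truth$Q)
  sizes <- table(factor(truth$labels, levels = colnames(truth$Q)))
  div <- mean_pairwise_divergence(truth$P)
  c(sprintf("populations: %d", K),
    sprintf("sizes: %s",
            paste(sprintf("%s=%d", names(sizes), as.integer(sizes)),
                  collapse = ", ")),
    sprintf("sites: %d", nrow(truth$P)),
    sprintf("planted fixed differences: %d (%s)",
            length(truth$planted_sites),
            if (length(truth$planted_sites))
              paste(truth$planted_sites, collapse = ", ") else "none"),
    sprintf("mean pairwise allele-frequency divergence: %.4f", div))
}

#' Mean pairwise absolute allele-frequency divergence between populations
#' @param P Sites x populations frequency matrix.
#' @return Numeric scalar (mean over population pairs and sites).
#' @export
mean_pairwise_divergence <- function(P) {
  K <- ncol(P)
  if (K < 2) return(0)
  pairs <- utils::combn(K, 2)
  mean(apply(pairs, 2, function(pr) mean(abs(P[, pr[1]] - P[, pr[2]]))))
}
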