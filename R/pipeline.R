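#' Pipeline configuration
#'
#' Bundles the thresholds, K range and seed for [run_pipeline()]. Two named
#' profiles encode the two study designs the defaults target: `"species"`
#' (multi-species panel; individuals up to 40% missing kept) and `"lvu_lma"`
#' (two-species panel; stricter 10% individual-missingness cap). Both share
#' the 80% site-presence and 1% MAF thresholds and centre-SNP thinning.
#'
#' @param profile `"species"` or `"lvu_lma"`, or `NULL` when all thresholds
#'   are given explicitly.
#' @param max_individual_missing,min_site_presence,maf,thin_to_center
#'   Overrides for the profile thresholds (see [filter_config()]).
#' @param K_min,K_max Admixture sweep range (default 1..8).
#' @param group_a,group_b Labels for the segregation stage; `NULL` disables
#'   segregation/consensus only if the popmap is also absent.
#' @param min_calls_per_group Segregation minimum calls per group.
#' @param seed Integer seed for the admixture initializations.
#' @param n_components Number of principal components to report.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(profile = c("species", "lvu_lma"),
                            max_individual_missing = NULL,
                            min_site_presence = 0.80,
                            maf = 0.01,
                            thin_to_center = TRUE,
                            K_min = 1, K_max = 8,
                            group_a = NULL, group_b = NULL,
                            min_calls_per_group = 1,
                            seed = 1,
                            n_components = 2) {
  profile <- match.arg(profile)
  if (is.null(max_individual_missing)) {
    max_individual_missing <- switch(profile, species = 0.40, lvu_lma = 0.10)
  }
  structure(list(
    profile = profile,
    filter = filter_config(max_individual_missing, min_site_presence, maf,
                           thin_to_center),
    K_min = K_min, K_max = K_max,
    group_a = group_a, group_b = group_b,
    min_calls_per_group = min_calls_per_group,
    seed = as.integer(seed), n_components = n_components),
    class = "pipeline_config")
}

#' Run the full post-assembly analysis pipeline
#'
#' Chains the stages in their canonical order: filtering cascade -> dosage
#' matrix -> PCA -> admixture sweep -> fixed-difference segregation ->
#' flanking-consensus extraction. Every artifact is written in a standard
#' text format readable by this package's own readers, and a JSON manifest
#' records an MD5 checksum per artifact, so identical inputs and seed yield
#' identical manifests. Any stage error aborts with the stage name.
#'
#' @param vcf_path Input VCF.
#' @param out_dir Output directory (created if absent).
#' @param cfg A [pipeline_config].
#' @param popmap_path Optional popmap path (required by the segregation
#'   stage).
#' @param loci_path Optional .loci path (locus centres for thinning and the
#'   consensus stage).
#' @return List with `status` (0 on success), `manifest` (named MD5 vector),
#'   `manifest_path`, `report`, `pca`, `sweep`, `segregation`, and the
#'   filtered `dataset`.
#' @export
run_pipeline <- function(vcf_path, out_dir, cfg = pipeline_config(),
                         popmap_path = NULL, loci_path = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s [artifacts so far: %s]", name,
                   conditionMessage(e),
                   if (length(artifacts)) paste(basename(artifacts),
                                                collapse = ", ")
                   else "none"), call. = FALSE)
    })
  }

  ds <- stage("input", read_vcf(vcf_path))
  pm <- if (!is.null(popmap_path)) stage("input", read_popmap(popmap_path))
        else NULL
  loci <- if (!is.null(loci_path)) stage("input", read_loci(loci_path))
          else NULL

  filt <- stage("filter", apply_cascade(ds, cfg$filter, loci))
  fds <- filt$dataset
  p_vcf <- file.path(out_dir, "filtered.vcf")
  write_vcf(fds, p_vcf)
  p_rep <- file.path(out_dir, "filter_report.tsv")
  utils::write.table(filt$report, p_rep, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  artifacts <- c(artifacts, p_vcf, p_rep)

  gm <- stage("matrix", build_dosage_matrix(fds))

  pca <- stage("pca", run_pca(gm, n_components = cfg$n_components))
  p_scores <- file.path(out_dir, "pca_scores.tsv")
  utils::write.table(data.frame(sample = rownames(pca$scores),
                                round(pca$scores, 8)),
                     p_scores, sep = "\t", quote = FALSE, row.names = FALSE)
  p_var <- file.path(out_dir, "pca_variance.tsv")
  utils::write.table(data.frame(component = seq_along(
                                  pca$explained_variance_pct),
                                explained_pct = round(
                                  pca$explained_variance_pct, 8)),
                     p_var, sep = "\t", quote = FALSE, row.names = FALSE)
  artifacts <- c(artifacts, p_scores, p_var)

  sweep <- stage("admixture",
                 fit_admixture(gm, cfg$K_min, cfg$K_max, seed = cfg$seed))
  for (k in sweep$K_values) {
    fit <- sweep$fits[[paste0("K", k)]]
    p_q <- file.path(out_dir, sprintf("admixture_Q_K%d.tsv", k))
    utils::write.table(data.frame(sample = rownames(fit$Q),
                                  round(fit$Q, 8)),
                       p_q, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, p_q)
  }

  seg <- stage("segregation", {
    if (is.null(pm)) {
      stop("precondition: a population map with both group labels is required")
    }
    ga <- if (is.null(cfg$group_a)) sort(unique(unclass(pm)))[1] else cfg$group_a
    gb <- if (is.null(cfg$group_b)) sort(unique(unclass(pm)))[2] else cfg$group_b
    find_fixed_differences(fds, pm, ga, gb,
                           min_calls_per_group = cfg$min_calls_per_group)
  })
  p_seg <- file.path(out_dir, "segregated_sites.tsv")
  utils::write.table(seg, p_seg, sep = "\t", quote = FALSE, row.names = FALSE)
  artifacts <- c(artifacts, p_seg)

  if (nrow(seg) > 0) {
    cons <- stage("consensus", {
      if (is.null(loci)) {
        stop("precondition: a .loci collection is required to extract flanking consensus")
      }
      consensus_for_report(seg, loci)
    })
    p_fa <- file.path(out_dir, "segregated_consensus.fasta")
    export_fasta(cons, p_fa)
    artifacts <- c(artifacts, p_fa)
  }

  manifest <- tools::md5sum(artifacts)
  names(manifest) <- basename(artifacts)
  p_man <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(as.list(manifest), p_man, auto_unbox = TRUE,
                       pretty = TRUE)
  list(status = 0L, manifest = manifest, manifest_path = p_man,
       report = filt$report, pca = pca, sweep = sweep, segregation = seg,
       dataset = fds)
}
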