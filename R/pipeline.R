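#' Simulate a cohort and write it to disk
#'
#' Materialises a simulated trio cohort as the package's interchange files:
#' a phased trio VCF, phenotype and truth TSVs, the true-weight table, and a
#' JSON manifest recording the seed and configuration. Re-running with the
#' same configuration and seed reproduces the files byte-for-byte.
#'
#' @param config A [sim_config()] (a seed is required for a reproducible
#'   manifest).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the written `paths` and the in-memory
#'   `cohort`.
#' @export
pipeline_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create '%s'", out_dir))
  cohort <- simulate_trios(config)
  paths <- list(
    vcf = file.path(out_dir, "trios.vcf"),
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    weights = file.path(out_dir, "weights.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_trio_vcf(cohort, paths$vcf)
  readr::write_tsv(cohort$phenotypes, paths$phenotypes)
  readr::write_tsv(cohort$truth, paths$truth)
  write_weights_tsv(
    dplyr::mutate(cohort$snp_meta[, c("id", "chrom", "pos", "ea", "oa",
                                      "weight")], eaf = cohort$snp_meta$freq),
    paths$weights
  )
  cfg <- config[setdiff(names(config), "pleiotropy")]
  jsonlite::write_json(
    list(tool = "ntmr", step = "simulate", seed = config$seed, config = cfg,
         n_trios = config$n_trios, n_snps = config$n_snps,
         files = lapply(paths, basename)),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE, null = "null"
  )
  invisible(list(paths = paths, cohort = cohort))
}

#' Run the full estimation workflow on cohort files
#'
#' Reads a trio VCF (or the dosage matrices of a cohort directory written by
#' [pipeline_simulate()]), resolves maternal non-transmitted dosages,
#' harmonises and scores the instrument weights, and fits the full
#' estimator suite per outcome: MV models one-three, TSLS with the
#' non-transmitted-allele score, first-stage diagnostics, and the MV-vs-MR
#' bootstrap z-test. Writes one tidy results TSV plus a human-readable
#' report logging the sample size at every filtering step.
#'
#' @param cohort_dir Directory holding `trios.vcf` and `phenotypes.tsv`.
#' @param weights_file Weight table TSV (defaults to the cohort's own
#'   `weights.tsv`).
#' @param outcomes Outcome columns (default: all `y_*` columns).
#' @param policy Ambiguity policy for [resolve_cohort()].
#' @param use_father Use paternal genotypes to resolve ambiguous duos
#'   (when present in the VCF).
#' @param n_boot,seed Bootstrap settings for [mv_mr_difference_test()].
#' @param out_dir Where to write `results.tsv` and `report.txt` (default:
#'   `cohort_dir`).
#' @return Invisibly, a list with the tidy `results` tibble, the `report`
#'   lines, and the instrument `scores`.
#' @export
pipeline_estimate <- function(cohort_dir, weights_file = NULL,
                              outcomes = NULL,
                              policy = c("expected", "drop"),
                              use_father = TRUE,
                              n_boot = 1000, seed = 1,
                              out_dir = cohort_dir) {
  policy <- match.arg(policy)
  vcf_path <- file.path(cohort_dir, "trios.vcf")
  ph_path <- file.path(cohort_dir, "phenotypes.tsv")
  for (p in c(vcf_path, ph_path)) {
    if (!file.exists(p)) abort(sprintf("input not found: %s", p))
  }
  geno <- read_trio_vcf(vcf_path)
  pheno <- readr::read_tsv(ph_path, show_col_types = FALSE)
  if (!"family_id" %in% names(pheno)) abort("phenotypes.tsv needs a family_id column")
  weights_file <- weights_file %||% file.path(cohort_dir, "weights.tsv")
  weights <- read_weights_tsv(weights_file)

  report <- c(
    sprintf("ntmr estimation report (%s)", format(Sys.time(), "%Y-%m-%d")),
    sprintf("families in VCF: %d", nrow(geno$mother_g)),
    sprintf("phenotype rows: %d", nrow(pheno)),
    sprintf("SNPs in VCF: %d; SNPs in weight table: %d",
            nrow(geno$snp_meta), nrow(weights))
  )

  fam <- intersect(rownames(geno$mother_g), pheno$family_id)
  if (!length(fam)) abort("no overlapping family ids between VCF and phenotypes")
  pheno <- pheno[match(fam, pheno$family_id), , drop = FALSE]
  report <- c(report, sprintf("families with genotypes + phenotypes: %d", length(fam)))

  res <- resolve_cohort(
    geno$mother_g[fam, , drop = FALSE], geno$child_g[fam, , drop = FALSE],
    if (use_father && !is.null(geno$father_g)) geno$father_g[fam, , drop = FALSE],
    policy = policy
  )
  report <- c(report,
    sprintf("duo resolution: %.2f%% ambiguous, %.3f%% Mendelian errors, %d SNP(s) excluded",
            100 * mean(res$qc$ambiguous), 100 * mean(res$qc$mendel_error),
            length(res$excluded)))

  hw <- harmonize(weights, geno$snp_meta[geno$snp_meta$id %in% colnames(res$nontransmitted), ])
  report <- c(report, sprintf("harmonised SNPs: %d (dropped %d)",
                              nrow(hw), nrow(attr(hw, "dropped"))))
  nt <- score(res$nontransmitted, hw)
  pheno$nt_score <- std(nt$score)

  outcomes <- outcomes %||% grep("^y_", names(pheno), value = TRUE)
  if (!length(outcomes)) abort("no outcome columns found")
  results <- purrr::map_dfr(outcomes, function(oc) {
    mv <- dplyr::bind_rows(
      mv_regress(pheno, oc, "one"), mv_regress(pheno, oc, "two"),
      mv_regress(pheno, oc, "three")
    )
    mr <- tsls(pheno, oc, "nt_score")
    dt <- mv_mr_difference_test(pheno, oc, "nt_score",
                                n_boot = n_boot, seed = seed)
    report <<- c(report,
      sprintf("%s: complete-case N (MV) = %d, N (MR) = %d, first-stage F = %.1f, P_dif = %.3g",
              oc, mv$n[1], mr$n, mr$first_stage_f, dt$p))
    out <- dplyr::bind_rows(mv, mr)
    out$p_difference <- dt$p
    out
  })
  results$stratum <- results$stratum %||% NA_character_

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(results, file.path(out_dir, "results.tsv"))
  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(list(results = results, report = report, scores = nt))
}
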