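#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. May be
#' built directly or loaded from a YAML file with [read_pipeline_config()].
#'
#' @param vcf,annotations,codes,code_map,kinship Paths to the input files;
#'   `kinship` may be `NULL` (no relatedness pruning).
#' @param pcs Optional path to a precomputed principal-component table;
#'   when given, [compute_pcs()] is bypassed (as for biobank-supplied PCs).
#' @param out_dir Output directory.
#' @param analysis_mode `"pathogenic"` (ultra-rare gnomAD-absent qualifying
#'   variants, the primary scan), `"pathogenic-subsidiary"` (gnomAD AF <
#'   `gnomad_af_threshold`), or `"synonymous-calibration"` (common
#'   synonymous negative-control scan).
#' @param avd_age_cutoff Age cutoff for the inferred-BAV rule.
#' @param max_cohort_carrier_freq,min_cadd,gnomad_af_threshold Qualifying
#'   variant thresholds (see [qv_criteria()]).
#' @param sd_threshold,n_pcs Ancestry filter parameters (see
#'   [ancestry_filter()]).
#' @param ci_method Confidence-interval method for the scan.
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, annotations, codes, code_map,
                            kinship = NULL, pcs = NULL, out_dir = "rvburden-out",
                            analysis_mode = c("pathogenic", "pathogenic-subsidiary",
                                              "synonymous-calibration"),
                            avd_age_cutoff = 65,
                            max_cohort_carrier_freq = 0.01,
                            min_cadd = 20, gnomad_af_threshold = 1e-4,
                            sd_threshold = 4, n_pcs = 4,
                            ci_method = c("wald", "conditional"), seed = 1L) {
  analysis_mode <- match.arg(analysis_mode)
  ci_method <- match.arg(ci_method)
  required <- c(vcf = vcf, annotations = annotations, codes = codes,
                code_map = code_map)
  missing_in <- required[!file.exists(required)]
  if (length(missing_in))
    stop("input file(s) not found: ",
         paste(names(missing_in), missing_in, sep = " = ", collapse = ", "))
  structure(list(vcf = vcf, annotations = annotations, codes = codes,
                 code_map = code_map, kinship = kinship, pcs = pcs,
                 out_dir = out_dir, analysis_mode = analysis_mode,
                 avd_age_cutoff = avd_age_cutoff,
                 max_cohort_carrier_freq = max_cohort_carrier_freq,
                 min_cadd = min_cadd, gnomad_af_threshold = gnomad_af_threshold,
                 sd_threshold = sd_threshold, n_pcs = n_pcs,
                 ci_method = ci_method, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(unclass(config)), collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the burden-analysis pipeline end to end
#'
#' Executes the stage order of the analysis: phenotype classification ->
#' genotype QC -> qualifying-variant selection -> cohort QC (relatedness
#' pruning and ancestry filtering) -> gene-level burden scan. Carrier
#' frequencies for the rarity filter use the full pre-cohort-QC sample
#' denominator. Writes the results table, QQ coordinates, and a JSON run
#' manifest with per-stage counts, the configuration hash, seed and
#' versions. Identical configuration gives identical outputs.
#'
#' @param config A [pipeline_config()] or path to a YAML file.
#' @return The run manifest (a list), invisibly; outputs are written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  counts <- list()

  message("stage phenotype: classifying samples")
  vcf <- run_stage("load-vcf", read_vcf(config$vcf))
  assignments <- run_stage("phenotype", {
    map <- read_code_map(config$code_map)
    codes <- read_phenotype_codes(config$codes)
    classify_samples(vcf$samples, codes, map, config$avd_age_cutoff)
  })
  design <- run_stage("phenotype", build_cohorts(assignments))
  counts$samples_in <- length(vcf$samples)
  counts$cases <- length(design$case_ids)
  counts$controls <- length(design$control_ids)
  counts$unknown <- length(design$unknown_ids)
  counts$excluded <- length(design$excluded_ids)

  message("stage genotype-qc: downgrading sub-threshold calls")
  geno <- run_stage("genotype-qc", apply_genotype_qc(vcf$geno, vcf$variants))
  counts$variants_in <- nrow(vcf$variants)

  message("stage qv-selection: mode ", config$analysis_mode)
  qvset <- run_stage("qv-selection", {
    ann <- read_annotations(config$annotations)
    switch(config$analysis_mode,
      "pathogenic" = select_qualifying_variants(
        vcf$variants, ann, geno, vcf$samples,
        qv_criteria(max_cohort_carrier_freq = config$max_cohort_carrier_freq,
                    gnomad_mode = "absent", min_cadd = config$min_cadd)),
      "pathogenic-subsidiary" = select_qualifying_variants(
        vcf$variants, ann, geno, vcf$samples,
        qv_criteria(max_cohort_carrier_freq = config$max_cohort_carrier_freq,
                    gnomad_mode = "below_threshold",
                    gnomad_af_threshold = config$gnomad_af_threshold,
                    min_cadd = config$min_cadd)),
      "synonymous-calibration" = select_synonymous_common(
        vcf$variants, ann, geno, vcf$samples))
  })
  counts$qualifying_variants <- nrow(qvset$variants)
  counts$qv_genes <- length(qvset$genes)

  message("stage cohort-qc: relatedness and ancestry")
  design <- run_stage("cohort-qc", {
    retained <- design_universe(design)
    if (!is.null(config$kinship)) {
      kin <- read_kinship(config$kinship)
      retained <- prune_related(kin, design)
    }
    counts$removed_related <- counts$samples_in - length(retained)
    pcs <- if (!is.null(config$pcs)) read_pcs(config$pcs) else NULL
    if (is.null(pcs)) {
      message("  no PC table supplied; skipping ancestry filter")
      counts$removed_ancestry <- 0L
      restrict_design(design, retained)
    } else {
      kept <- ancestry_filter(pcs[intersect(rownames(pcs), retained), , drop = FALSE],
                              config$sd_threshold, config$n_pcs)
      counts$removed_ancestry <- length(retained) - length(kept)
      restrict_design(design, kept)
    }
  })
  counts$analyzed_cases <- length(design$case_ids)
  counts$analyzed_controls <- length(design$control_ids)

  message("stage scan: gene-level burden test")
  scan <- run_stage("scan",
    burden_scan(qvset, design,
                ci_method = if (config$ci_method == "conditional")
                  "conditional" else "wald"))
  counts$genes_tested <- scan$m_tests

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- write_scan(scan, config$out_dir)
  manifest <- list(
    config_hash = config_hash(config), seed = config$seed,
    analysis_mode = config$analysis_mode, counts = counts,
    lambda_gc = scan$lambda_gc,
    versions = list(r = R.version.string,
                    rvburden = as.character(packageVersion("rvburden"))),
    outputs = as.list(files))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$scan <- scan
  invisible(manifest)
}
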