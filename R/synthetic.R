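#' Synthetic cohort simulation configuration
#'
#' Defines a seeded synthetic case/control exome cohort: gene-stratified
#' rare variants with annotations, per-sample diagnostic codes drawn from
#' the packaged toy code map, kinship pairs, principal components, and an
#' optional "spiked" risk gene whose carrier rate is elevated in cases.
#' Defaults emulate the structure of a biobank exome study of predominantly
#' mild congenital heart disease: a heavily imbalanced cohort (case
#' fraction 0.75%), ultra-rare qualifying variants with a baseline carrier
#' rate of 0.2% per gene, an inferred-BAV diagnostic-code rate of 0.4%, and
#' a common-synonymous calibration stratum.
#'
#' @param n_samples Number of samples (>= 2).
#' @param case_fraction Fraction of samples given CHD diagnostic codes
#'   (cases are an exact count, `round(n_samples * case_fraction)`).
#' @param genes Named integer vector: gene label -> number of variants.
#' @param baseline_carrier_rate Per-gene probability that a sample carries
#'   >= 1 rare qualifying variant.
#' @param spiked_gene `NULL`, or `list(gene =, case_rate =, control_rate =)`
#'   giving one gene an elevated carrier rate in cases (requires
#'   `case_rate >= control_rate`).
#' @param qc_fail_fraction Probability a carrier genotype is emitted with
#'   GQ or DP exactly one unit below its QC threshold (so filter boundary
#'   behaviour is exercised).
#' @param synonymous_common_fraction Fraction of each gene's variants
#'   emitted as synonymous with gnomAD AF > 0.01 (the calibration stratum).
#' @param synonymous_carrier_rate Per-variant carrier rate of the common
#'   synonymous variants.
#' @param missingness_rate Uniform per-genotype missingness rate (a
#'   simplification; real exome missingness is structured).
#' @param related_pairs Number of deliberately emitted kinship pairs
#'   (coefficient 0.25).
#' @param ancestry_outliers Number of samples emitted with PC1 displaced by
#'   10 standard deviations from the main cloud.
#' @param bav_code_rate Probability a non-CHD sample receives an
#'   aortic-valve-disease code before age 65 (inferred-BAV route to case
#'   status); default 0.4%, the inferred-BAV prevalence the pipeline is
#'   designed around.
#' @param late_avd_rate Probability a remaining sample receives an AVD code
#'   at age >= 65 (classified unknown downstream).
#' @param n_pcs Number of principal components emitted.
#' @param seed Integer seed; identical configuration and seed give a
#'   byte-identical bundle.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 5000,
                       case_fraction = 0.0075,
                       genes = setNames(rep(3L, 20), sprintf("G%04d", 1:20)),
                       baseline_carrier_rate = 0.002,
                       spiked_gene = NULL,
                       qc_fail_fraction = 0.01,
                       synonymous_common_fraction = 1 / 3,
                       synonymous_carrier_rate = 0.05,
                       missingness_rate = 0.001,
                       related_pairs = 0L,
                       ancestry_outliers = 0L,
                       bav_code_rate = 0.004,
                       late_avd_rate = 0.002,
                       n_pcs = 4L,
                       seed = 1L) {
  chk_prob <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stop("invalid ", name, ": must be a probability in [0, 1]")
  }
  if (!is.numeric(n_samples) || n_samples < 2 || n_samples != round(n_samples))
    stop("invalid n_samples: must be an integer >= 2")
  chk_prob(case_fraction, "case_fraction")
  chk_prob(baseline_carrier_rate, "baseline_carrier_rate")
  chk_prob(qc_fail_fraction, "qc_fail_fraction")
  chk_prob(synonymous_common_fraction, "synonymous_common_fraction")
  chk_prob(synonymous_carrier_rate, "synonymous_carrier_rate")
  chk_prob(missingness_rate, "missingness_rate")
  chk_prob(bav_code_rate, "bav_code_rate")
  chk_prob(late_avd_rate, "late_avd_rate")
  if (is.null(names(genes)) || any(!nzchar(names(genes))) || anyDuplicated(names(genes)))
    stop("invalid genes: must be a uniquely named vector of variant counts")
  if (any(genes < 1)) stop("invalid genes: every gene needs >= 1 variant")
  if (!is.null(spiked_gene)) {
    if (!all(c("gene", "case_rate", "control_rate") %in% names(spiked_gene)))
      stop("invalid spiked_gene: needs gene, case_rate, control_rate")
    chk_prob(spiked_gene$case_rate, "spiked_gene$case_rate")
    chk_prob(spiked_gene$control_rate, "spiked_gene$control_rate")
    if (spiked_gene$case_rate < spiked_gene$control_rate)
      stop("invalid spiked_gene: case_rate must be >= control_rate")
    if (!spiked_gene$gene %in% names(genes))
      stop("invalid spiked_gene: gene not in the gene list")
  }
  if (related_pairs < 0 || related_pairs != round(related_pairs))
    stop("invalid related_pairs: must be a non-negative integer")
  if (2 * related_pairs > n_samples)
    stop("invalid related_pairs: not enough samples for disjoint pairs")
  if (ancestry_outliers < 0 || ancestry_outliers > n_samples)
    stop("invalid ancestry_outliers: must be in [0, n_samples]")
  if (n_pcs < 1) stop("invalid n_pcs: must be >= 1")
  if (!is.numeric(seed) || seed != round(seed)) stop("invalid seed: must be an integer")
  structure(list(
    n_samples = as.integer(n_samples), case_fraction = case_fraction,
    genes = setNames(as.integer(genes), names(genes)),
    baseline_carrier_rate = baseline_carrier_rate,
    spiked_gene = spiked_gene, qc_fail_fraction = qc_fail_fraction,
    synonymous_common_fraction = synonymous_common_fraction,
    synonymous_carrier_rate = synonymous_carrier_rate,
    missingness_rate = missingness_rate,
    related_pairs = as.integer(related_pairs),
    ancestry_outliers = as.integer(ancestry_outliers),
    bav_code_rate = bav_code_rate, late_avd_rate = late_avd_rate,
    n_pcs = as.integer(n_pcs), seed = as.integer(seed)),
    class = "sim_config")
}

## Toy code-map codes used by the generator (kept in sync with
## inst/extdata/toy_code_map.tsv).
toy_chd_codes <- c("CHD001", "CHD002", "CHD003")
toy_avd_codes <- c("AVD001", "AVD002", "AVD003")
toy_neutral_codes <- c("NEU001", "NEU002")

#' Generate a synthetic cohort bundle
#'
#' Draws a complete cohort under a [sim_config()]: per-sample case/control
#' structure via diagnostic codes, gene-stratified sparse genotypes with
#' QC-boundary failures and uniform missingness, annotations (rare
#' qualifying-grade variants plus a common synonymous stratum), kinship
#' pairs, principal components with optional displaced outliers, and a
#' truth record of intended carrier and phenotype status. The random
#' stream is split per component (phenotypes, genotypes, PCs, kinship) so
#' enlarging one component does not perturb the draws of another.
#'
#' @param config A [sim_config()].
#' @return An object of class `cohort_bundle`: a list with elements
#'   `samples`, `variants`, `geno`, `annotations`, `phenotype_codes`,
#'   `kinship`, `pcs`, `truth`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  samples <- sprintf("S%06d", seq_len(n))
  set.seed(config$seed)
  comp_seed <- sample.int(.Machine$integer.max - 1, 4)

  ## --- phenotype component -------------------------------------------------
  set.seed(comp_seed[1])
  n_chd <- round(n * config$case_fraction)
  chd_idx <- sort(sample.int(n, n_chd))
  rest <- setdiff(seq_len(n), chd_idx)
  bav_idx <- rest[runif(length(rest)) < config$bav_code_rate]
  rest2 <- setdiff(rest, bav_idx)
  late_idx <- rest2[runif(length(rest2)) < config$late_avd_rate]
  ctrl_idx <- setdiff(rest2, late_idx)
  neutral_idx <- ctrl_idx[runif(length(ctrl_idx)) < 0.3]
  codes <- data.frame(
    sample_id = samples[c(chd_idx, bav_idx, late_idx, neutral_idx)],
    code = c(sample(toy_chd_codes, n_chd, replace = TRUE),
             sample(toy_avd_codes, length(bav_idx), replace = TRUE),
             sample(toy_avd_codes, length(late_idx), replace = TRUE),
             sample(toy_neutral_codes, length(neutral_idx), replace = TRUE)),
    source = "hospital-episode",
    age_at_event = as.numeric(c(sample(1:64, n_chd, replace = TRUE),
                                sample(40:64, length(bav_idx), replace = TRUE),
                                sample(65:85, length(late_idx), replace = TRUE),
                                sample(40:80, length(neutral_idx), replace = TRUE))))
  codes <- codes[order(match(codes$sample_id, samples)), ]
  rownames(codes) <- NULL
  is_case <- logical(n)
  is_case[c(chd_idx, bav_idx)] <- TRUE
  case_ids <- samples[is_case]
  noncase_ids <- samples[!is_case & !(seq_len(n) %in% late_idx)]
  unknown_ids <- samples[late_idx]

  ## --- genotype + annotation component -------------------------------------
  set.seed(comp_seed[2])
  gene_names <- names(config$genes)
  n_var <- sum(config$genes)
  gene_of <- rep(gene_names, config$genes)
  within <- sequence(config$genes)
  gi <- rep(seq_along(gene_names), config$genes)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_var, replace = TRUE)
  alt_base <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  is_indel <- runif(n_var) < 0.1
  alt <- ifelse(is_indel, paste0(ref, sample(bases, n_var, replace = TRUE)), alt_base)
  variants <- data.frame(
    chrom = paste0("chr", 1 + (gi - 1) %% 22),
    pos = as.integer(gi * 100000L + within * 100L),
    variant_id = sprintf("V%06d", seq_len(n_var)),
    ref = ref, alt = alt,
    vtype = ifelse(is_indel, "indel", "snp"), row.names = NULL)

  n_syn_per_gene <- round(config$synonymous_common_fraction * config$genes)
  is_syn <- within > (config$genes[gi] - n_syn_per_gene[gi])
  impact <- ifelse(is_syn, "LOW",
                   sample(c("HIGH", "MODERATE"), n_var, replace = TRUE,
                          prob = c(0.3, 0.7)))
  annotations <- data.frame(
    variant_id = variants$variant_id, gene = gene_of, impact = impact,
    consequence = ifelse(is_syn, "synonymous_variant",
                         ifelse(impact == "HIGH", "stop_gained", "missense_variant")),
    gnomad_af = ifelse(is_syn, round(runif(n_var, 0.011, 0.2), 6), NA),
    cadd_phred = round(ifelse(is_syn, runif(n_var, 0, 10), runif(n_var, 20, 40)), 1),
    row.names = NULL)

  draw_carriers <- function(pool, rate) {
    k <- rbinom(1, length(pool), rate)
    if (k) sample(pool, k) else character(0)
  }
  vid_l <- list(); sid_l <- list(); set_l <- list(); gene_l <- list()
  for (g in seq_along(gene_names)) {
    gname <- gene_names[g]
    vids <- variants$variant_id[gene_of == gname]
    syn <- is_syn[gene_of == gname]
    rare_vids <- vids[!syn]
    if (length(rare_vids)) {
      if (!is.null(config$spiked_gene) && gname == config$spiked_gene$gene) {
        carr <- c(draw_carriers(case_ids, config$spiked_gene$case_rate),
                  draw_carriers(c(noncase_ids, unknown_ids),
                                config$spiked_gene$control_rate))
      } else {
        carr <- draw_carriers(samples, config$baseline_carrier_rate)
      }
      if (length(carr)) {
        vid_l[[length(vid_l) + 1L]] <- sample(rare_vids, length(carr), replace = TRUE)
        sid_l[[length(sid_l) + 1L]] <- carr
        set_l[[length(set_l) + 1L]] <- rep("rare", length(carr))
        gene_l[[length(gene_l) + 1L]] <- rep(gname, length(carr))
      }
    }
    for (sv in vids[syn]) {
      carr <- draw_carriers(samples, config$synonymous_carrier_rate)
      if (length(carr)) {
        vid_l[[length(vid_l) + 1L]] <- rep(sv, length(carr))
        sid_l[[length(sid_l) + 1L]] <- carr
        set_l[[length(set_l) + 1L]] <- rep("synonymous", length(carr))
        gene_l[[length(gene_l) + 1L]] <- rep(gname, length(carr))
      }
    }
  }
  carrier_vid <- unlist(vid_l); carrier_sid <- unlist(sid_l)
  n_carr <- length(carrier_vid)
  truth_carriers <- data.frame(
    gene = unlist(gene_l) %||% character(0),
    variant_id = carrier_vid %||% character(0),
    sample_id = carrier_sid %||% character(0),
    set = unlist(set_l) %||% character(0), row.names = NULL)

  if (n_carr) {
    gt <- ifelse(runif(n_carr) < 0.02, "hom-alt", "het")
    vt <- variants$vtype[match(carrier_vid, variants$variant_id)]
    thr <- ifelse(vt == "indel", 10L, 7L)
    gq <- sample(20:99, n_carr, replace = TRUE)
    dp <- thr + sample(0:50, n_carr, replace = TRUE)
    fail <- runif(n_carr) < config$qc_fail_fraction
    fail_on_gq <- runif(n_carr) < 0.5
    gq[fail & fail_on_gq] <- 19L
    dp[fail & !fail_on_gq] <- thr[fail & !fail_on_gq] - 1L
    geno <- data.frame(variant_id = carrier_vid, sample_id = carrier_sid,
                       gt = gt, gq = as.integer(gq), dp = as.integer(dp),
                       row.names = NULL)
  } else {
    geno <- empty_geno()
  }
  if (config$missingness_rate > 0) {
    miss_vid <- list(); miss_sid <- list()
    for (i in seq_len(n_var)) {
      k <- rbinom(1, n, config$missingness_rate)
      if (k) {
        miss_vid[[length(miss_vid) + 1L]] <- rep(variants$variant_id[i], k)
        miss_sid[[length(miss_sid) + 1L]] <- sample(samples, k)
      }
    }
    if (length(miss_vid)) {
      miss <- data.frame(variant_id = unlist(miss_vid), sample_id = unlist(miss_sid),
                         gt = "missing", gq = NA_integer_, dp = NA_integer_,
                         row.names = NULL)
      miss <- miss[!paste(miss$variant_id, miss$sample_id) %in%
                     paste(geno$variant_id, geno$sample_id), ]
      geno <- rbind(geno, miss)
    }
  }
  geno <- canonical_geno_order(geno, variants$variant_id, samples)

  ## --- principal component component ---------------------------------------
  set.seed(comp_seed[3])
  pcs <- matrix(round(rnorm(n * config$n_pcs), 6), nrow = n,
                dimnames = list(samples, paste0("PC", seq_len(config$n_pcs))))
  outlier_ids <- character(0)
  if (config$ancestry_outliers > 0) {
    out_idx <- sample.int(n, config$ancestry_outliers)
    pcs[out_idx, 1] <- pcs[out_idx, 1] + 10
    outlier_ids <- samples[sort(out_idx)]
  }

  ## --- kinship component ----------------------------------------------------
  set.seed(comp_seed[4])
  kinship <- data.frame(sample_id_1 = character(0), sample_id_2 = character(0),
                        kinship = numeric(0))
  if (config$related_pairs > 0) {
    picks <- samples[sample.int(n, 2 * config$related_pairs)]
    kinship <- data.frame(
      sample_id_1 = picks[seq(1, length(picks), 2)],
      sample_id_2 = picks[seq(2, length(picks), 2)],
      kinship = 0.25, row.names = NULL)
  }

  structure(list(
    samples = samples, variants = variants, geno = geno,
    annotations = annotations, phenotype_codes = codes, kinship = kinship,
    pcs = pcs,
    truth = list(is_case = setNames(is_case, samples),
                 carriers = truth_carriers,
                 spiked_gene = config$spiked_gene,
                 bav_ids = samples[bav_idx],
                 unknown_ids = unknown_ids,
                 ancestry_outlier_ids = outlier_ids),
    config = config), class = "cohort_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("synthetic cohort bundle: ", length(x$samples), " samples, ",
      nrow(x$variants), " variants (", sum(x$truth$is_case), " intended cases)\n",
      sep = "")
  invisible(x)
}
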