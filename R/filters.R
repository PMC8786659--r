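impact_levels <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' Classify a variant as SNP or indel
#'
#' A variant is a SNP iff both alleles are single bases; anything else
#' (insertions, deletions, multi-base substitutions) is classed `indel` and
#' takes the stricter read-depth threshold during genotype QC.
#'
#' @param ref,alt Allele strings (vectorized).
#' @return Character vector, `"snp"` or `"indel"`.
#' @export
classify_variant_type <- function(ref, alt) {
  if (any(!nzchar(ref)) || any(!nzchar(alt))) stop("empty allele string")
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snp", "indel")
}

#' Per-genotype quality control predicate
#'
#' A called genotype passes QC iff genotype quality GQ >= 20 and read depth
#' DP >= 10 for indels or DP >= 7 for SNPs. Missing GQ or DP fails (the
#' call cannot be certified).
#'
#' @param gq,dp Integer vectors of genotype quality and read depth.
#' @param vtype Character vector, `"snp"` or `"indel"` per entry.
#' @param min_gq Genotype-quality threshold (default 20).
#' @param min_dp_snp,min_dp_indel Depth thresholds (defaults 7 and 10).
#' @return Logical vector.
#' @export
genotype_passes_qc <- function(gq, dp, vtype, min_gq = 20,
                               min_dp_snp = 7, min_dp_indel = 10) {
  thr <- ifelse(vtype == "indel", min_dp_indel, min_dp_snp)
  !is.na(gq) & !is.na(dp) & gq >= min_gq & dp >= thr
}

#' Downgrade QC-failing genotype calls to missing
#'
#' Non-reference calls failing [genotype_passes_qc()] are set to `missing`
#' rather than dropped, preserving the genotype table's shape; missing
#' counts as non-carrier downstream. Idempotent.
#'
#' @param geno Sparse genotype table: data frame with columns `variant_id`,
#'   `sample_id`, `gt` (`"het"`, `"hom-alt"`, `"missing"`), `gq`, `dp`.
#' @param variants Variant table with columns `variant_id`, `ref`, `alt`.
#' @return `geno` with failing calls downgraded.
#' @export
apply_genotype_qc <- function(geno, variants) {
  if (!nrow(geno)) return(geno)
  vtype <- classify_variant_type(variants$ref, variants$alt)
  vt <- vtype[match(geno$variant_id, variants$variant_id)]
  called <- geno$gt %in% c("het", "hom-alt")
  fail <- called & !genotype_passes_qc(geno$gq, geno$dp, vt)
  geno$gt[fail] <- "missing"
  geno
}

#' Cohort carrier frequency per variant
#'
#' Fraction of samples carrying at least one alternate allele (het or
#' hom-alt) at each variant; missing genotypes count as non-carriers.
#' The denominator is the full sample universe of the input VCF, before any
#' cohort assignment or relatedness pruning.
#'
#' @param geno Sparse genotype table (see [apply_genotype_qc()]), already
#'   QC-downgraded.
#' @param variant_ids Character vector of variants to report.
#' @param n_samples Total number of samples in the cohort.
#' @return Named numeric vector of carrier frequencies over `variant_ids`.
#' @export
cohort_carrier_frequency <- function(geno, variant_ids, n_samples) {
  if (n_samples <= 0) stop("n_samples must be positive")
  carriers <- geno[geno$gt %in% c("het", "hom-alt"), ]
  counts <- table(factor(carriers$variant_id, levels = variant_ids))
  setNames(as.numeric(counts) / n_samples, variant_ids)
}

#' Qualifying-variant selection criteria
#'
#' Defaults reproduce the primary ultra-rare potentially-pathogenic filter:
#' carrier frequency below 1% of all samples, HIGH or MODERATE predicted
#' impact, absent from gnomAD, and CADD PHRED >= 20. The subsidiary mode
#' relaxes gnomAD absence to `gnomad_af < gnomad_af_threshold`.
#'
#' @param max_cohort_carrier_freq Strict upper bound on carrier frequency.
#' @param impacts Allowed VEP impact categories.
#' @param gnomad_mode `"absent"` (never observed in gnomAD) or
#'   `"below_threshold"`.
#' @param gnomad_af_threshold Strict upper bound on gnomAD allele frequency,
#'   used only in `below_threshold` mode (default 1e-4).
#' @param min_cadd Minimum CADD PHRED score (inclusive); variants with no
#'   CADD score are excluded.
#' @return An object of class `qv_criteria`.
#' @export
qv_criteria <- function(max_cohort_carrier_freq = 0.01,
                        impacts = c("HIGH", "MODERATE"),
                        gnomad_mode = c("absent", "below_threshold"),
                        gnomad_af_threshold = 1e-4,
                        min_cadd = 20) {
  gnomad_mode <- match.arg(gnomad_mode)
  if (max_cohort_carrier_freq < 0) stop("max_cohort_carrier_freq must be non-negative")
  if (gnomad_af_threshold < 0) stop("gnomad_af_threshold must be non-negative")
  if (min_cadd < 0) stop("min_cadd must be non-negative")
  if (!length(impacts) || !all(impacts %in% impact_levels))
    stop("impacts must be a non-empty subset of ", paste(impact_levels, collapse = "/"))
  structure(list(max_cohort_carrier_freq = max_cohort_carrier_freq,
                 impacts = impacts, gnomad_mode = gnomad_mode,
                 gnomad_af_threshold = gnomad_af_threshold,
                 min_cadd = min_cadd),
            class = "qv_criteria")
}

#' Collapse multi-transcript annotations to one canonical row per variant
#'
#' With multiple annotation rows per variant (transcripts), the
#' highest-impact row wins; ties are broken by first occurrence.
#'
#' @param annotations Annotation data frame (columns `variant_id`, `gene`,
#'   `impact`, `consequence`, `gnomad_af`, `cadd_phred`).
#' @return One row per variant.
#' @export
canonical_annotations <- function(annotations) {
  rank <- match(annotations$impact, impact_levels)
  ord <- order(annotations$variant_id, rank, seq_len(nrow(annotations)))
  ann <- annotations[ord, ]
  ann[!duplicated(ann$variant_id), , drop = FALSE]
}

qv_set_from_pass <- function(variants, ann, geno, pass_ids, mode, criteria) {
  carriers <- geno[geno$gt %in% c("het", "hom-alt") &
                     geno$variant_id %in% pass_ids, c("variant_id", "sample_id", "gt")]
  carriers$gene <- ann$gene[match(carriers$variant_id, ann$variant_id)]
  carriers <- carriers[order(carriers$gene, carriers$variant_id, carriers$sample_id),
                       c("gene", "variant_id", "sample_id", "gt")]
  rownames(carriers) <- NULL
  surviving <- unique(carriers[, c("gene", "variant_id")])
  rownames(surviving) <- NULL
  structure(list(carriers = carriers, variants = surviving,
                 genes = unique(surviving$gene), mode = mode, criteria = criteria),
            class = "qv_set")
}

#' @export
print.qv_set <- function(x, ...) {
  cat("qualifying-variant set (", x$mode, " mode): ",
      nrow(x$variants), " variants in ", length(x$genes), " genes, ",
      nrow(x$carriers), " carrier genotypes\n", sep = "")
  invisible(x)
}

#' Select ultra-rare potentially pathogenic qualifying variants
#'
#' Applies, in order: per-genotype QC downgrade; cohort carrier frequency
#' strictly below `max_cohort_carrier_freq`; canonical impact in `impacts`;
#' the gnomAD condition (`absent`: no gnomAD record at all; or
#' `below_threshold`: absent or AF strictly below the threshold); and CADD
#' PHRED >= `min_cadd` (no score excludes). Variants with no annotation row
#' are excluded with a warning. Variants left with no passing carrier
#' genotype are dropped: they cannot contribute to any gene burden.
#'
#' @param variants Variant table (`variant_id`, `ref`, `alt`, ...).
#' @param annotations Annotation table (possibly multi-transcript).
#' @param geno Sparse genotype table.
#' @param samples Character vector: the full sample universe (the carrier
#'   frequency denominator).
#' @param criteria A [qv_criteria()] object.
#' @return An object of class `qv_set` with elements `carriers` (data frame
#'   `gene`, `variant_id`, `sample_id`, `gt` of passing carrier genotypes),
#'   `variants`, `genes`, `mode`, `criteria`.
#' @export
select_qualifying_variants <- function(variants, annotations, geno, samples,
                                       criteria = qv_criteria()) {
  stopifnot(inherits(criteria, "qv_criteria"))
  geno <- apply_genotype_qc(geno, variants)
  ann <- canonical_annotations(annotations)
  unannotated <- setdiff(variants$variant_id, ann$variant_id)
  if (length(unannotated))
    warning(length(unannotated), " variant(s) without annotation excluded: ",
            paste(utils::head(unannotated, 5), collapse = ", "),
            if (length(unannotated) > 5) ", ...")
  ann <- ann[ann$variant_id %in% variants$variant_id, ]
  freq <- cohort_carrier_frequency(geno, ann$variant_id, length(samples))

  gnomad_ok <- if (criteria$gnomad_mode == "absent") is.na(ann$gnomad_af)
    else is.na(ann$gnomad_af) | ann$gnomad_af < criteria$gnomad_af_threshold
  pass <- freq[ann$variant_id] < criteria$max_cohort_carrier_freq &
    ann$impact %in% criteria$impacts &
    gnomad_ok &
    !is.na(ann$cadd_phred) & ann$cadd_phred >= criteria$min_cadd
  qv_set_from_pass(variants, ann, geno, ann$variant_id[pass],
                   "pathogenic", criteria)
}

#' Select the common-synonymous calibration variant set
#'
#' Synonymous variants with gnomAD allele frequency strictly above 0.01.
#' Scanning this set should show no case/control difference in a sound
#' analysis; it serves as a negative-control calibration of the burden scan
#' (QQ plot close to the identity, genomic inflation near 1).
#'
#' @inheritParams select_qualifying_variants
#' @param min_gnomad_af Strict lower bound on gnomAD AF (default 0.01).
#' @return A `qv_set` (mode `"synonymous"`).
#' @export
select_synonymous_common <- function(variants, annotations, geno, samples,
                                     min_gnomad_af = 0.01) {
  geno <- apply_genotype_qc(geno, variants)
  ann <- canonical_annotations(annotations)
  ann <- ann[ann$variant_id %in% variants$variant_id, ]
  pass <- grepl("synonymous", ann$consequence, fixed = TRUE) &
    !is.na(ann$gnomad_af) & ann$gnomad_af > min_gnomad_af
  qv_set_from_pass(variants, ann, geno, ann$variant_id[pass],
                   "synonymous", list(min_gnomad_af = min_gnomad_af))
}
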