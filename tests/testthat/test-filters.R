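test_that("variant type classification follows allele lengths", {
  expect_equal(classify_variant_type("A", "T"), "snp")
  expect_equal(classify_variant_type("A", "AT"), "indel")
  expect_equal(classify_variant_type("AC", "G"), "indel")
  # multi-base substitutions take the stricter (indel) depth threshold
  expect_equal(classify_variant_type("AC", "GT"), "indel")
  expect_error(classify_variant_type("", "T"), "empty")
  expect_error(classify_variant_type("A", "A"), "differ")
})

test_that("genotype QC thresholds are inclusive at the stated boundaries", {
  expect_true(genotype_passes_qc(20, 7, "snp"))
  expect_false(genotype_passes_qc(19, 30, "snp"))
  expect_false(genotype_passes_qc(99, 9, "indel"))
  expect_true(genotype_passes_qc(20, 10, "indel"))
  expect_false(genotype_passes_qc(NA, 30, "snp"))
})

test_that("QC downgrade preserves shape, is idempotent", {
  variants <- data.frame(variant_id = c("V1", "V2"), ref = c("A", "A"),
                         alt = c("T", "AT"))
  geno <- data.frame(variant_id = c("V1", "V1", "V2"),
                     sample_id = c("S1", "S2", "S3"),
                     gt = c("het", "hom-alt", "het"),
                     gq = c(19L, 50L, 50L), dp = c(30L, 30L, 9L))
  once <- apply_genotype_qc(geno, variants)
  expect_equal(once$gt, c("missing", "hom-alt", "missing"))
  expect_equal(nrow(once), 3)
  expect_identical(apply_genotype_qc(once, variants), once)
})

test_that("carrier frequency counts samples after QC downgrade", {
  variants <- data.frame(variant_id = "V1", ref = "A", alt = "T")
  # 2 het + 1 hom-alt + 1 QC-failed het of 400 samples -> 3/400
  geno <- data.frame(variant_id = "V1", sample_id = sprintf("S%d", 1:4),
                     gt = c("het", "het", "hom-alt", "het"),
                     gq = c(50L, 50L, 50L, 19L), dp = 30L)
  geno <- apply_genotype_qc(geno, variants)
  expect_equal(unname(cohort_carrier_frequency(geno, "V1", 400)), 3 / 400)
  expect_equal(unname(cohort_carrier_frequency(empty_geno_df(), "V1", 10)), 0)
  expect_error(cohort_carrier_frequency(geno, "V1", 0), "positive")
})

test_that("packaged 60-variant fixture matches the hand-audited manifest", {
  vcf <- read_vcf(file.path(filter_fixture_dir, "toy.vcf"))
  ann <- read_annotations(file.path(filter_fixture_dir, "toy_annotations.tsv"))
  expected <- read.delim(file.path(filter_fixture_dir, "toy_expected.tsv"))
  expect_equal(nrow(vcf$variants), 60)

  expect_warning(
    path <- select_qualifying_variants(vcf$variants, ann, vcf$geno, vcf$samples),
    "without annotation")
  expect_setequal(path$variants$variant_id,
                  expected$variant_id[expected$pathogenic])

  subs <- suppressWarnings(select_qualifying_variants(
    vcf$variants, ann, vcf$geno, vcf$samples,
    qv_criteria(gnomad_mode = "below_threshold")))
  expect_setequal(subs$variants$variant_id,
                  expected$variant_id[expected$subsidiary])

  syn <- select_synonymous_common(vcf$variants, ann, vcf$geno, vcf$samples)
  expect_setequal(syn$variants$variant_id,
                  expected$variant_id[expected$synonymous])
  # rare-pathogenic and common-synonymous sets can never share a variant
  expect_length(intersect(path$variants$variant_id,
                          syn$variants$variant_id), 0)
})

test_that("tightening any single criterion never grows the QV set", {
  vcf <- read_vcf(file.path(filter_fixture_dir, "toy.vcf"))
  ann <- read_annotations(file.path(filter_fixture_dir, "toy_annotations.tsv"))
  base_crit <- qv_criteria(gnomad_mode = "below_threshold",
                           gnomad_af_threshold = 1e-3)
  base <- suppressWarnings(select_qualifying_variants(
    vcf$variants, ann, vcf$geno, vcf$samples, base_crit))
  tighter <- list(
    qv_criteria(max_cohort_carrier_freq = 0.005, gnomad_mode = "below_threshold",
                gnomad_af_threshold = 1e-3),
    qv_criteria(impacts = "HIGH", gnomad_mode = "below_threshold",
                gnomad_af_threshold = 1e-3),
    qv_criteria(gnomad_mode = "below_threshold", gnomad_af_threshold = 1e-5),
    qv_criteria(gnomad_mode = "absent"),
    qv_criteria(min_cadd = 30, gnomad_mode = "below_threshold",
                gnomad_af_threshold = 1e-3))
  for (crit in tighter) {
    qs <- suppressWarnings(select_qualifying_variants(
      vcf$variants, ann, vcf$geno, vcf$samples, crit))
    expect_true(all(qs$variants$variant_id %in% base$variants$variant_id))
  }
})

test_that("synonymous selection applies the strict frequency bound", {
  variants <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                         variant_id = c("V1", "V2", "V3"),
                         ref = "A", alt = "T", vtype = "snp")
  ann <- data.frame(variant_id = c("V1", "V2", "V3"), gene = "G1",
                    impact = "LOW",
                    consequence = c("synonymous_variant", "synonymous_variant",
                                    "missense_variant"),
                    gnomad_af = c(0.02, 0.01, 0.5), cadd_phred = 1)
  geno <- data.frame(variant_id = c("V1", "V2", "V3"), sample_id = "S1",
                     gt = "het", gq = 50L, dp = 30L)
  syn <- select_synonymous_common(variants, ann, geno, sprintf("S%d", 1:10))
  expect_equal(syn$variants$variant_id, "V1")
})

test_that("criteria validation names the offending field", {
  expect_error(qv_criteria(max_cohort_carrier_freq = -1), "max_cohort_carrier_freq")
  expect_error(qv_criteria(impacts = character(0)), "impacts")
  expect_error(qv_criteria(impacts = "EXTREME"), "impacts")
})
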