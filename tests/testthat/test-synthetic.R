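test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_samples = 100, case_fraction = 0.1, seed = 7,
                    genes = c(G1 = 3L, G2 = 2L), related_pairs = 2L,
                    ancestry_outliers = 1L)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  # a different seed perturbs the bundle
  cfg2 <- sim_config(n_samples = 100, case_fraction = 0.1, seed = 8,
                     genes = c(G1 = 3L, G2 = 2L))
  expect_false(identical(generate_cohort(cfg)$geno, generate_cohort(cfg2)$geno))
})

test_that("degenerate carrier rate yields zero rare carriers", {
  cfg <- sim_config(n_samples = 50, case_fraction = 0.1,
                    genes = c(G1 = 2L, G2 = 2L), baseline_carrier_rate = 0,
                    synonymous_common_fraction = 0, missingness_rate = 0,
                    seed = 3)
  b <- generate_cohort(cfg)
  expect_equal(nrow(b$truth$carriers), 0)
  expect_equal(sum(b$geno$gt %in% c("het", "hom-alt")), 0)
})

test_that("spiked-gene carrier counts are binomially calibrated", {
  cfg <- sim_config(n_samples = 20000, case_fraction = 0.1,
                    genes = setNames(rep(2L, 5), paste0("G", 1:5)),
                    synonymous_common_fraction = 0,
                    spiked_gene = list(gene = "G1", case_rate = 0.02,
                                       control_rate = 0.0025),
                    bav_code_rate = 0, late_avd_rate = 0, seed = 1)
  b <- generate_cohort(cfg)
  cases <- names(b$truth$is_case)[b$truth$is_case]
  spiked <- b$truth$carriers[b$truth$carriers$gene == "G1", ]
  case_carriers <- sum(unique(spiked$sample_id) %in% cases)
  # Binomial(2000, 0.02): mean 40, sd ~6.26
  expect_lt(abs(case_carriers - 40), 3 * sqrt(2000 * 0.02 * 0.98))
  ctrl_carriers <- sum(!unique(spiked$sample_id) %in% cases)
  expect_lt(abs(ctrl_carriers - 45), 3 * sqrt(18000 * 0.0025 * 0.9975))
})

test_that("mean realized carrier rate matches the configured rate over seeds", {
  rates <- vapply(1:100, function(s) {
    cfg <- sim_config(n_samples = 400, case_fraction = 0.1, genes = c(G1 = 2L),
                      baseline_carrier_rate = 0.01,
                      synonymous_common_fraction = 0, missingness_rate = 0,
                      seed = s)
    b <- generate_cohort(cfg)
    length(unique(b$truth$carriers$sample_id)) / 400
  }, 0)
  se <- sqrt(0.01 * 0.99 / (400 * 100))
  expect_lt(abs(mean(rates) - 0.01), 3 * se)
})

test_that("config validation names the offending field", {
  expect_error(sim_config(n_samples = 1), "n_samples")
  expect_error(sim_config(case_fraction = 1.2), "case_fraction")
  expect_error(sim_config(genes = c(3L, 2L)), "genes")
  expect_error(sim_config(spiked_gene = list(gene = "G0001", case_rate = 0.001,
                                             control_rate = 0.01)),
               "case_rate must be >= control_rate")
  expect_error(sim_config(spiked_gene = list(gene = "NOPE", case_rate = 0.01,
                                             control_rate = 0.001)),
               "spiked_gene")
  expect_error(sim_config(n_samples = 10, related_pairs = 6), "related_pairs")
})

test_that("bundle write/read round-trips exactly", {
  cfg <- sim_config(n_samples = 150, case_fraction = 0.2, seed = 12,
                    genes = c(GA = 3L, GB = 3L), baseline_carrier_rate = 0.05,
                    related_pairs = 2L, ancestry_outliers = 1L,
                    qc_fail_fraction = 0.2)
  b <- generate_cohort(cfg)
  d <- withr::local_tempdir()
  manifest <- write_bundle(b, d)
  expect_true(all(file.exists(manifest)))
  rb <- read_bundle(d)
  expect_equal(rb[names(b)], b[names(b)])
  # writing twice gives identical bytes (manifest hashes)
  d2 <- withr::local_tempdir()
  write_bundle(b, d2)
  expect_identical(unname(tools::md5sum(manifest)),
                   unname(tools::md5sum(file.path(d2, basename(manifest)))))
})

test_that("a zero-variant bundle writes a valid header-only VCF", {
  cfg <- sim_config(n_samples = 20, case_fraction = 0.1, genes = c(G1 = 1L),
                    baseline_carrier_rate = 0, synonymous_common_fraction = 0,
                    missingness_rate = 0, seed = 2)
  b <- generate_cohort(cfg)
  b$variants <- b$variants[0, ]
  b$geno <- b$geno[0, ]
  b$annotations <- b$annotations[0, ]
  d <- withr::local_tempdir()
  write_bundle(b, d)
  lines <- readLines(file.path(d, "cohort.vcf"))
  expect_true(all(startsWith(lines, "#")))
  expect_match(lines[1], "fileformat=VCFv4.2")
  expect_match(lines[length(lines)], "^#CHROM")
})

test_that("multi-allelic records are refused by the writer", {
  cfg <- sim_config(n_samples = 20, case_fraction = 0.1, genes = c(G1 = 1L),
                    seed = 2)
  b <- generate_cohort(cfg)
  b$variants$alt[1] <- "T,G"
  expect_error(write_bundle(b, withr::local_tempdir()), "bi-allelic")
})

test_that("the VCF reader splits multi-allelic records into bi-allelic ones", {
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="GQ">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    paste(c("chr1", "500", "rs1", "A", "T,G", ".", "PASS", ".", "GT:GQ:DP",
            "0/1:50:30", "1/2:60:25", "2/2:70:20"), collapse = "\t"))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines, path)
  v <- read_vcf(path)
  expect_equal(nrow(v$variants), 2)
  expect_setequal(v$variants$variant_id, c("chr1:500:A:T", "chr1:500:A:G"))
  gt_t <- v$geno[v$geno$variant_id == "chr1:500:A:T", ]
  expect_equal(gt_t$gt[gt_t$sample_id == "S1"], "het")
  expect_equal(gt_t$gt[gt_t$sample_id == "S2"], "het")
  gt_g <- v$geno[v$geno$variant_id == "chr1:500:A:G", ]
  expect_equal(gt_g$gt[gt_g$sample_id == "S2"], "het")
  expect_equal(gt_g$gt[gt_g$sample_id == "S3"], "hom-alt")
})
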