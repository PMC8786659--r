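avd_at <- function(age) data.frame(code = "AVD001", source = "hospital-episode",
                                   age_at_event = age)

test_that("inferred-BAV age rule is strict at the cutoff", {
  r64 <- classify_sample(avd_at(64), toy_map)
  expect_equal(r64$status, "case")
  expect_true(r64$inferred_bav)
  r65 <- classify_sample(avd_at(65), toy_map)
  expect_equal(r65$status, "unknown")
  expect_false(r65$inferred_bav)
  # CHD codes dominate regardless of age
  chd <- classify_sample(data.frame(code = "CHD001", source = "hospital-episode",
                                    age_at_event = 80), toy_map)
  expect_equal(chd$status, "case")
  expect_false(chd$inferred_bav)
})

test_that("classification edge cases follow the rule order", {
  none <- classify_sample(data.frame(code = character(0), source = character(0),
                                     age_at_event = numeric(0)), toy_map)
  expect_equal(none$status, "control")
  # earliest AVD age decides; missing age alone gives unknown
  two <- classify_sample(data.frame(code = c("AVD001", "AVD002"),
                                    source = "hospital-episode",
                                    age_at_event = c(70, 40)), toy_map)
  expect_equal(two$status, "case"); expect_true(two$inferred_bav)
  noage <- classify_sample(data.frame(code = "AVD001", source = "primary-care",
                                      age_at_event = NA_real_), toy_map)
  expect_equal(noage$status, "unknown")
  # exclusion only applies without CHD/AVD codes
  exc <- classify_sample(data.frame(code = "EXC001", source = "hospital-episode",
                                    age_at_event = 50), toy_map)
  expect_equal(exc$status, "excluded")
  # unmapped codes are neutral, reported via message
  expect_message(
    unk <- classify_sample(data.frame(code = "XXX", source = "primary-care",
                                      age_at_event = 50), toy_map),
    "neutral")
  expect_equal(unk$status, "control")
  expect_error(classify_sample(avd_at(64), toy_map, avd_age_cutoff = 0), "positive")
  expect_error(classify_sample(avd_at(150), toy_map), "\\[0, 120\\]")
})

test_that("packaged 20-sample fixture reproduces the hand classification", {
  codes <- read_phenotype_codes(
    system.file("extdata", "toy_phenotypes.tsv", package = "rvburden"))
  universe <- sprintf("P%02d", 1:20)
  assignments <- suppressMessages(classify_samples(universe, codes, toy_map))
  design <- build_cohorts(assignments)
  expect_setequal(design$case_ids,
                  c("P01", "P02", "P03", "P08", "P10", "P12", "P15", "P16"))
  expect_setequal(design$control_ids,
                  c("P06", "P11", "P14", "P18", "P19", "P20"))
  expect_setequal(design$unknown_ids, c("P04", "P05", "P09", "P13", "P17"))
  expect_setequal(design$excluded_ids, "P07")
  bav <- assignments$sample_id[assignments$inferred_bav]
  expect_setequal(bav, c("P02", "P03", "P12", "P15"))
  # partition completeness
  expect_setequal(unlist(design), universe)
  # condition labels accumulate from matched codes
  expect_true(grepl("aortic valve replacement",
                    assignments$condition_labels[assignments$sample_id == "P12"]))
})

test_that("cohort partition rejects duplicates and refuses an empty scan", {
  a <- data.frame(sample_id = c("A", "A"), status = "case",
                  inferred_bav = FALSE, condition_labels = "")
  expect_error(build_cohorts(a), "duplicate")
  all_unknown <- data.frame(sample_id = c("A", "B"), status = "unknown",
                            inferred_bav = FALSE, condition_labels = "")
  d <- build_cohorts(all_unknown)
  expect_length(d$case_ids, 0)
  qv <- qvset_from_carriers(data.frame(gene = "G1", variant_id = "V1",
                                       sample_id = "A", gt = "het"))
  expect_error(burden_scan(qv, d), "nothing to test")
})

test_that("raising the AVD age cutoff never loses cases (monotonicity)", {
  set.seed(5)
  codes <- data.frame(
    sample_id = sprintf("S%02d", 1:40),
    code = sample(c("AVD001", "AVD002", "CHD001", "NEU001"), 40, replace = TRUE),
    source = "hospital-episode",
    age_at_event = sample(30:90, 40, replace = TRUE))
  n_cases_at <- vapply(c(55, 65, 75), function(cut) {
    a <- classify_samples(sprintf("S%02d", 1:40), codes, toy_map, cut)
    sum(a$status == "case")
  }, 0)
  expect_false(is.unsorted(n_cases_at))
  # adding a CHD code never demotes a case
  base <- classify_sample(avd_at(40), toy_map)
  more <- classify_sample(rbind(avd_at(40),
                                data.frame(code = "CHD002", source = "primary-care",
                                           age_at_event = 12)), toy_map)
  expect_equal(base$status, "case")
  expect_equal(more$status, "case")
})

test_that("subtype prevalence counts labels over classified samples", {
  a <- data.frame(
    sample_id = sprintf("S%d", 1:5),
    status = c("case", "case", "control", "unknown", "excluded"),
    inferred_bav = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    condition_labels = c("aortic stenosis", "atrial septal defect", "", "", ""))
  d <- build_cohorts(a)
  expect_equal(subtype_prevalence(d, a, "inferred_bav"), 1 / 4)
  expect_equal(subtype_prevalence(d, a, "aortic stenosis"), 1 / 4)
  expect_equal(subtype_prevalence(d, a, "tetralogy of Fallot"), 0)
  empty <- build_cohorts(a[a$status == "excluded", ])
  expect_error(subtype_prevalence(empty, a, "inferred_bav"), "denominator")
})

test_that("generated BAV-code prevalence tracks the configured rate", {
  cfg <- sim_config(n_samples = 20000, case_fraction = 0.01,
                    genes = c(G1 = 2L), bav_code_rate = 0.004, seed = 21)
  b <- generate_cohort(cfg)
  assignments <- classify_samples(b$samples, b$phenotype_codes, toy_map)
  design <- build_cohorts(assignments)
  prev <- subtype_prevalence(design, assignments, "inferred_bav")
  # eligible pool excludes the 1% CHD-coded cases
  expected <- 0.004 * 0.99
  se <- sqrt(expected * (1 - expected) / 20000)
  expect_lt(abs(prev - expected), 3 * se)
  expect_setequal(assignments$sample_id[assignments$inferred_bav], b$truth$bav_ids)
})
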