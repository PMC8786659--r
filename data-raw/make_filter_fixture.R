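# Builds the packaged 60-variant filter fixture (inst/extdata/toy_filter/).
# Every variant's fate under each filter is fixed by the design table below;
# the expected manifest is written from these design labels, independently of
# the package's filtering code.

devtools::load_all(".", quiet = TRUE)

n_samples <- 101L
samples <- sprintf("F%03d", seq_len(n_samples))
genes <- sprintf("FG%02d", 1:6)

v <- function(id, gene, ref, alt, impact, consequence, gnomad, cadd,
              carriers, gq = 50L, dp = 20L,
              path = FALSE, subs = FALSE, syn = FALSE, annotated = TRUE,
              extra_low_row = FALSE) {
  data.frame(variant_id = id, gene = gene, ref = ref, alt = alt,
             impact = impact, consequence = consequence,
             gnomad_af = gnomad, cadd_phred = cadd, carriers = carriers,
             gq = gq, dp = dp, path = path, subs = subs, syn = syn,
             annotated = annotated, extra_low_row = extra_low_row)
}

rows <- list()
# A: all four pathogenic criteria met, single carrier (freq 1/101 < 1%)
for (i in 1:5)
  rows[[length(rows) + 1]] <- v(sprintf("V%02d", i), genes[(i - 1) %% 6 + 1],
    "A", "T", c("HIGH", "MODERATE")[i %% 2 + 1], "missense_variant",
    NA, 25 + i, 1, path = TRUE, subs = TRUE)
# A-MNP: multi-base substitution takes the indel depth threshold and passes it
rows[[length(rows) + 1]] <- v("V06", genes[6], "AG", "CT", "MODERATE",
  "missense_variant", NA, 26, 1, gq = 30L, dp = 10L, path = TRUE, subs = TRUE)
# A-multi-transcript: canonical (highest-impact) row qualifies; extra LOW row
rows[[length(rows) + 1]] <- v("V07", genes[1], "G", "C", "MODERATE",
  "missense_variant", NA, 31, 1, path = TRUE, subs = TRUE, extra_low_row = TRUE)
# B: CADD below 20 or absent
for (i in 8:10)
  rows[[length(rows) + 1]] <- v(sprintf("V%02d", i), genes[(i - 1) %% 6 + 1],
    "C", "G", "HIGH", "stop_gained", NA, 19.9, 1)
for (i in 11:13)
  rows[[length(rows) + 1]] <- v(sprintf("V%02d", i), genes[(i - 1) %% 6 + 1],
    "C", "T", "HIGH", "stop_gained", NA, NA, 1)
# C: impact below MODERATE
for (i in 14:19)
  rows[[length(rows) + 1]] <- v(sprintf("V%02d", i), genes[(i - 1) %% 6 + 1],
    "T", "A", c("LOW", "MODIFIER")[i %% 2 + 1], "splice_region_variant",
    NA, 25, 1)
# D: observed in gnomAD below 1e-4 (subsidiary mode only)
for (i in 20:25)
  rows[[length(rows) + 1]] <- v(sprintf("V%02d", i), genes[(i - 1) %% 6 + 1],
    "G", "A", "MODERATE", "missense_variant", 5e-5, 28, 1, subs = TRUE)
# E: observed in gnomAD at/above 1e-4
for (i in 26:28)
  rows[[length(rows) + 1]] <- v(sprintf("V%02d", i), genes[(i - 1) %% 6 + 1],
    "G", "T", "MODERATE", "missense_variant", 5e-4, 28, 1)
# M: no annotation row at all
rows[[length(rows) + 1]] <- v("V29", genes[5], "A", "G", "MODERATE",
  "missense_variant", NA, 30, 1, annotated = FALSE)
# F: carrier frequency 2/101 (>= 1%)
for (i in 30:35)
  rows[[length(rows) + 1]] <- v(sprintf("V%02d", i), genes[(i - 1) %% 6 + 1],
    "A", "C", "HIGH", "stop_gained", NA, 30, 2)
# G: the only carrier genotype fails QC (GQ 19, or SNP depth 6)
for (i in 36:38)
  rows[[length(rows) + 1]] <- v(sprintf("V%02d", i), genes[(i - 1) %% 6 + 1],
    "T", "G", "HIGH", "stop_gained", NA, 30, 1, gq = 19L)
for (i in 39:41)
  rows[[length(rows) + 1]] <- v(sprintf("V%02d", i), genes[(i - 1) %% 6 + 1],
    "T", "C", "HIGH", "stop_gained", NA, 30, 1, dp = 6L)
# H: common synonymous (gnomAD AF > 0.01), the calibration stratum
for (i in 42:49)
  rows[[length(rows) + 1]] <- v(sprintf("V%02d", i), genes[(i - 1) %% 6 + 1],
    "C", "A", "LOW", "synonymous_variant", 0.02 + (i - 42) / 50, 3, 3,
    syn = TRUE)
# I: synonymous at exactly AF 0.01 (strict bound excludes)
for (i in 50:53)
  rows[[length(rows) + 1]] <- v(sprintf("V%02d", i), genes[(i - 1) %% 6 + 1],
    "C", "G", "LOW", "synonymous_variant", 0.01, 2, 3)
# J: common missense (wrong class for both variant sets)
for (i in 54:57)
  rows[[length(rows) + 1]] <- v(sprintf("V%02d", i), genes[(i - 1) %% 6 + 1],
    "A", "G", "MODERATE", "missense_variant", 0.5, 15, 5)
# K: QC boundary passes - SNP at GQ 20 / DP 7, indel at GQ 20 / DP 10
rows[[length(rows) + 1]] <- v("V58", genes[3], "A", "T", "HIGH", "stop_gained",
  NA, 22, 1, gq = 20L, dp = 7L, path = TRUE, subs = TRUE)
rows[[length(rows) + 1]] <- v("V59", genes[4], "A", "AT", "HIGH",
  "frameshift_variant", NA, 33, 1, gq = 20L, dp = 10L, path = TRUE, subs = TRUE)
# L: MNP whose carrier has DP 9 - below the indel threshold it inherits
rows[[length(rows) + 1]] <- v("V60", genes[5], "TG", "CA", "HIGH",
  "stop_gained", NA, 30, 1, gq = 50L, dp = 9L)

design <- do.call(rbind, rows)
stopifnot(nrow(design) == 60, !anyDuplicated(design$variant_id))

variants <- data.frame(
  chrom = paste0("chr", match(design$gene, genes)),
  pos = 1000L + seq_len(nrow(design)) * 50L,
  variant_id = design$variant_id, ref = design$ref, alt = design$alt)

geno <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
  k <- design$carriers[i]
  data.frame(variant_id = design$variant_id[i],
             sample_id = samples[((i - 1) + (seq_len(k) - 1) * 40) %% 101 + 1],
             gt = "het", gq = design$gq[i], dp = design$dp[i])
}))

ann <- design[design$annotated,
              c("variant_id", "gene", "impact", "consequence",
                "gnomad_af", "cadd_phred")]
extra <- design[design$extra_low_row, ]
if (nrow(extra))
  ann <- rbind(ann, data.frame(
    variant_id = extra$variant_id, gene = extra$gene, impact = "LOW",
    consequence = "non_coding_transcript_variant", gnomad_af = NA,
    cadd_phred = extra$cadd_phred))

dir.create("inst/extdata/toy_filter", showWarnings = FALSE, recursive = TRUE)
write_vcf(variants, geno, samples, "inst/extdata/toy_filter/toy.vcf")
write_annotations(ann, "inst/extdata/toy_filter/toy_annotations.tsv")
write.table(
  data.frame(variant_id = design$variant_id, gene = design$gene,
             pathogenic = design$path, subsidiary = design$subs,
             synonymous = design$syn),
  "inst/extdata/toy_filter/toy_expected.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)
cat("fixture written:", nrow(design), "variants,", length(samples), "samples\n")
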