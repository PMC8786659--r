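#' Read a multi-sample VCF into the sparse genotype representation
#'
#' Parses a VCF 4.2 file (plain text or gzipped) with per-genotype
#' `GT:GQ:DP` fields. Multi-allelic records are split into bi-allelic
#' records, one per alternate allele; for a split record a sample's call is
#' classified by its copy number of that alternate allele. Bi-allelic
#' records keep their VCF ID as `variant_id` (falling back to
#' `chrom:pos:ref:alt` when the ID is missing); split records are always
#' keyed `chrom:pos:ref:alt`.
#'
#' Only non-reference entries are materialized: the sparse genotype table
#' holds het, hom-alt and explicitly missing (`./.`) calls; absent
#' (variant, sample) combinations are homozygous reference.
#'
#' @param path Path to the VCF file.
#' @return A list with `variants` (data frame: `chrom`, `pos`, `variant_id`,
#'   `ref`, `alt`, `vtype`), `geno` (sparse genotype data frame:
#'   `variant_id`, `sample_id`, `gt`, `gq`, `dp`), and `samples`.
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fixed <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (!nrow(fixed))
    return(list(variants = data.frame(chrom = character(0), pos = integer(0),
                                      variant_id = character(0), ref = character(0),
                                      alt = character(0), vtype = character(0)),
                geno = empty_geno(), samples = samples))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gq <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))

  var_rows <- list(); geno_rows <- list()
  for (i in seq_len(nrow(fixed))) {
    alts <- strsplit(fixed$ALT[i], ",", fixed = TRUE)[[1]]
    multi <- length(alts) > 1L
    alleles <- strsplit(gsub("|", "/", gt[i, ], fixed = TRUE), "/", fixed = TRUE)
    for (j in seq_along(alts)) {
      vid <- if (!multi && !is.na(fixed$ID[i]) && fixed$ID[i] != ".") fixed$ID[i]
             else paste(fixed$CHROM[i], fixed$POS[i], fixed$REF[i], alts[j], sep = ":")
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        chrom = fixed$CHROM[i], pos = as.integer(fixed$POS[i]), variant_id = vid,
        ref = fixed$REF[i], alt = alts[j],
        vtype = classify_variant_type(fixed$REF[i], alts[j]))
      copies <- vapply(alleles, function(al) sum(al == as.character(j)), 0L)
      miss <- is.na(gt[i, ]) | vapply(alleles, function(al) any(al == "."), NA)
      keep <- which(miss | copies > 0L)
      if (length(keep))
        geno_rows[[length(geno_rows) + 1L]] <- data.frame(
          variant_id = vid, sample_id = samples[keep],
          gt = ifelse(miss[keep], "missing",
                      ifelse(copies[keep] >= 2L, "hom-alt", "het")),
          gq = as.integer(gq[i, keep]), dp = as.integer(dp[i, keep]),
          row.names = NULL)
    }
  }
  variants <- do.call(rbind, var_rows)
  rownames(variants) <- NULL
  geno <- if (length(geno_rows)) do.call(rbind, geno_rows) else empty_geno()
  geno <- canonical_geno_order(geno, variants$variant_id, samples)
  list(variants = variants, geno = geno, samples = samples)
}

empty_geno <- function() {
  data.frame(variant_id = character(0), sample_id = character(0),
             gt = character(0), gq = integer(0), dp = integer(0))
}

canonical_geno_order <- function(geno, variant_ids, samples) {
  geno <- geno[order(match(geno$variant_id, variant_ids),
                     match(geno$sample_id, samples)), , drop = FALSE]
  rownames(geno) <- NULL
  geno
}

#' Write a sparse genotype set as a VCF 4.2 file
#'
#' Emits bi-allelic records with `GT:GQ:DP` FORMAT. Hom-ref calls (absent
#' from the sparse table) are written as `0/0:99:30`; explicitly missing
#' calls as `./.:.:.`.
#'
#' @param variants Variant table (`chrom`, `pos`, `variant_id`, `ref`, `alt`).
#' @param geno Sparse genotype table.
#' @param samples Character vector of all sample ids (VCF column order).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, geno, samples, path) {
  if (any(grepl(",", variants$alt, fixed = TRUE)))
    stop("multi-allelic records are not emitted; split into bi-allelic records")
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (!nrow(variants)) return(invisible(path))
  geno_by_var <- split(geno, factor(geno$variant_id, levels = variants$variant_id))
  sample_index <- seq_along(samples)
  names(sample_index) <- samples
  lines <- vapply(seq_len(nrow(variants)), function(i) {
    cells <- rep("0/0:99:30", length(samples))
    g <- geno_by_var[[variants$variant_id[i]]]
    if (!is.null(g) && nrow(g)) {
      gt_code <- c(het = "0/1", `hom-alt` = "1/1", missing = "./.")[g$gt]
      fmt <- function(x) ifelse(is.na(x), ".", as.character(x))
      cells[sample_index[g$sample_id]] <- paste(gt_code, fmt(g$gq), fmt(g$dp), sep = ":")
    }
    paste(c(variants$chrom[i], variants$pos[i], variants$variant_id[i],
            variants$ref[i], variants$alt[i], ".", "PASS", ".", "GT:GQ:DP", cells),
          collapse = "\t")
  }, "")
  writeLines(lines, con)
  invisible(path)
}

#' Read a per-variant annotation table
#'
#' Tab-delimited with header `variant_id, gene, impact, consequence,
#' gnomad_af, cadd_phred`. An empty `gnomad_af` field means the variant was
#' never observed in gnomAD — distinct from an observed frequency of 0.
#'
#' @param path Path to the annotation file.
#' @return Data frame with `gnomad_af` and `cadd_phred` numeric (`NA` =
#'   absent).
#' @export
read_annotations <- function(path) {
  ann <- read.delim(path, colClasses = c(
    variant_id = "character", gene = "character", impact = "character",
    consequence = "character", gnomad_af = "character", cadd_phred = "character"))
  ann$gnomad_af <- suppressWarnings(as.numeric(ann$gnomad_af))
  ann$cadd_phred <- suppressWarnings(as.numeric(ann$cadd_phred))
  bad <- setdiff(unique(ann$impact), impact_levels)
  if (length(bad)) stop("unknown impact categories: ", paste(bad, collapse = ", "))
  ann
}

#' Write an annotation table
#' @param annotations Annotation data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  out <- annotations
  out$gnomad_af <- ifelse(is.na(out$gnomad_af), "", as.character(out$gnomad_af))
  out$cadd_phred <- ifelse(is.na(out$cadd_phred), "", as.character(out$cadd_phred))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample diagnostic code table
#'
#' Tab-delimited with header `sample_id, code, source, age_at_event`
#' (age may be empty).
#' @param path Path to the code table.
#' @return Data frame.
#' @export
read_phenotype_codes <- function(path) {
  codes <- read.delim(path, colClasses = c(
    sample_id = "character", code = "character", source = "character",
    age_at_event = "character"))
  codes$age_at_event <- suppressWarnings(as.numeric(codes$age_at_event))
  codes
}

#' Read a kinship pair table
#'
#' Tab-delimited with header `sample_id_1, sample_id_2, kinship`. Any listed
#' pair is treated as related by the pruning step regardless of coefficient.
#' @param path Path to the kinship file.
#' @return Data frame.
#' @export
read_kinship <- function(path) {
  kin <- read.delim(path, colClasses = c(
    sample_id_1 = "character", sample_id_2 = "character", kinship = "numeric"))
  if (any(kin$sample_id_1 == kin$sample_id_2)) stop("self-pair in kinship table")
  if (any(kin$kinship < 0 | kin$kinship > 0.5))
    stop("kinship coefficients must lie in [0, 0.5]")
  kin
}

#' Read a principal-component coordinate table
#'
#' Tab-delimited with header `sample_id, pc1..pck`.
#' @param path Path to the PC table.
#' @return Numeric matrix with sample ids as row names.
#' @export
read_pcs <- function(path) {
  tab <- read.delim(path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$sample_id
  colnames(m) <- toupper(colnames(m))
  if (any(!is.finite(m))) stop("non-finite principal component coordinates")
  m
}
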