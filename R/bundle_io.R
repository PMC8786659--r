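#' Write a cohort bundle to a directory
#'
#' Emits the bundle as plain-text files: a VCF 4.2 with `GT:GQ:DP` FORMAT
#' fields, tab-delimited annotation / phenotype-code / kinship / PC tables,
#' and JSON records of the generating configuration and the truth record.
#' [read_bundle()] on the directory reproduces the bundle exactly.
#'
#' @param bundle A `cohort_bundle`.
#' @param directory Output directory (created if needed).
#' @return Named character vector of written file paths (the manifest),
#'   invisibly.
#' @export
write_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(directory, "cohort.vcf"),
    annotations = file.path(directory, "annotations.tsv"),
    phenotype_codes = file.path(directory, "phenotype_codes.tsv"),
    kinship = file.path(directory, "kinship.tsv"),
    pcs = file.path(directory, "pcs.tsv"),
    config = file.path(directory, "config.json"),
    truth = file.path(directory, "truth.json"))
  write_vcf(bundle$variants, bundle$geno, bundle$samples, paths["vcf"])
  write_annotations(bundle$annotations, paths["annotations"])
  codes <- bundle$phenotype_codes
  codes$age_at_event <- ifelse(is.na(codes$age_at_event), "",
                               as.character(codes$age_at_event))
  write.table(codes, paths["phenotype_codes"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(bundle$kinship, paths["kinship"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  pcs_tab <- data.frame(sample_id = rownames(bundle$pcs), bundle$pcs,
                        row.names = NULL, check.names = FALSE)
  names(pcs_tab) <- c("sample_id", tolower(colnames(bundle$pcs)))
  write.table(pcs_tab, paths["pcs"], sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(bundle$config)
  cfg$genes <- as.list(cfg$genes)   # keep gene names through JSON
  jsonlite::write_json(cfg, paths["config"],
                       auto_unbox = TRUE, digits = NA, null = "null")
  truth <- bundle$truth
  truth$is_case <- list(sample_id = names(truth$is_case),
                        is_case = unname(truth$is_case))
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

as_chr <- function(x) as.character(unlist(x))

#' Read a cohort bundle back from a directory
#'
#' Inverse of [write_bundle()]; restores the sparse genotype representation
#' (hom-ref calls implicit), the truth record and the configuration.
#'
#' @param directory Directory written by [write_bundle()].
#' @return A `cohort_bundle`.
#' @export
read_bundle <- function(directory) {
  vcf <- read_vcf(file.path(directory, "cohort.vcf"))
  cfg_raw <- jsonlite::read_json(file.path(directory, "config.json"),
                                 simplifyVector = TRUE)
  cfg_raw$genes <- unlist(cfg_raw$genes)
  if (!is.null(cfg_raw$spiked_gene)) cfg_raw$spiked_gene <- as.list(cfg_raw$spiked_gene)
  config <- do.call(sim_config, cfg_raw)
  truth_raw <- jsonlite::read_json(file.path(directory, "truth.json"),
                                   simplifyVector = TRUE)
  carriers <- truth_raw$carriers
  if (!is.data.frame(carriers) || !nrow(carriers))
    carriers <- data.frame(gene = character(0), variant_id = character(0),
                           sample_id = character(0), set = character(0))
  truth <- list(
    is_case = setNames(as.logical(unlist(truth_raw$is_case$is_case)),
                       as_chr(truth_raw$is_case$sample_id)),
    carriers = carriers,
    spiked_gene = if (is.null(truth_raw$spiked_gene)) NULL
                  else as.list(truth_raw$spiked_gene),
    bav_ids = as_chr(truth_raw$bav_ids),
    unknown_ids = as_chr(truth_raw$unknown_ids),
    ancestry_outlier_ids = as_chr(truth_raw$ancestry_outlier_ids))
  structure(list(
    samples = vcf$samples, variants = vcf$variants, geno = vcf$geno,
    annotations = read_annotations(file.path(directory, "annotations.tsv")),
    phenotype_codes = read_phenotype_codes(file.path(directory, "phenotype_codes.tsv")),
    kinship = read_kinship(file.path(directory, "kinship.tsv")),
    pcs = read_pcs(file.path(directory, "pcs.tsv")),
    truth = truth, config = config), class = "cohort_bundle")
}
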