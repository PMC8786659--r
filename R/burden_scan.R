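#' Collapse qualifying variants to gene-level carrier sets
#'
#' A sample is a carrier of a gene iff it has at least one het or hom-alt
#' QC-passing genotype at any qualifying variant of that gene; a sample
#' with several qualifying variants in one gene counts once. Samples with
#' unknown or excluded status are ignored.
#'
#' @param qvset A `qv_set` from [select_qualifying_variants()] or
#'   [select_synonymous_common()].
#' @param design A `cohort_design`.
#' @return Named list (per gene) of lists with `case_carriers` and
#'   `control_carriers` character vectors.
#' @export
collapse_to_gene <- function(qvset, design) {
  carriers <- qvset$carriers
  universe <- design_universe(design)
  stray <- setdiff(unique(carriers$sample_id), universe)
  if (length(stray))
    stop("carrier sample(s) absent from the cohort design universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  lapply(split(carriers$sample_id, carriers$gene), function(ids) {
    ids <- unique(ids)
    list(case_carriers = intersect(ids, design$case_ids),
         control_carriers = intersect(ids, design$control_ids))
  })
}

#' Carrier contingency table for one gene
#'
#' @param gene_carriers One element of [collapse_to_gene()]'s result.
#' @param design A `cohort_design` with non-empty case and control sets.
#' @return A [contingency_table()].
#' @export
contingency <- function(gene_carriers, design) {
  n_cases <- length(design$case_ids)
  n_controls <- length(design$control_ids)
  if (!n_cases || !n_controls) stop("empty case or control cohort")
  a <- length(gene_carriers$case_carriers)
  c_ <- length(gene_carriers$control_carriers)
  contingency_table(a, n_cases - a, c_, n_controls - c_)
}

## Display rounding: half away from zero, as tabulated prevalences/ORs are.
round_half_away <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Gene-level collapsing burden scan
#'
#' The package's central fit: for every gene with at least one qualifying
#' variant carrier among analyzed samples, compares carrier counts between
#' cases and controls with a two-sided Fisher exact test
#' ([fisher_two_sided()]), reports the odds ratio with either a Wald
#' ([odds_ratio_wald()]) or conditional-exact ([odds_ratio_conditional()])
#' 95% confidence interval, applies Bonferroni correction over the genes
#' tested, and computes QQ-plot coordinates and the genomic inflation
#' factor lambda for calibration.
#'
#' @param qvset A `qv_set`.
#' @param design A `cohort_design` (post cohort-QC).
#' @param ci_method `"wald"` (closed form; default) or `"conditional"`
#'   (exact conditional interval, the convention matching classical exact
#'   2x2 inference).
#' @param conf_level Confidence level for the odds-ratio interval.
#' @return An object of class `burden_scan`: a list with
#'   \describe{
#'     \item{results}{data frame, one row per gene, ordered by ascending p
#'       (ties: descending OR, then gene label): `gene`, `case_carriers`,
#'       `n_cases`, `control_carriers`, `n_controls`, `case_prev_pct`,
#'       `control_prev_pct`, `or`, `ci_low`, `ci_high`, `ci_method`, `p`,
#'       `p_bonferroni`. Prevalences and ORs are also kept at full
#'       precision in `or_exact`, `case_prev`, `control_prev`.}
#'     \item{m_tests}{number of genes tested (the Bonferroni family).}
#'     \item{lambda_gc}{genomic inflation factor of the scan.}
#'     \item{qq}{data frame of expected/observed -log10 p pairs.}
#'   }
#' @examples
#' \dontrun{
#' scan <- burden_scan(qvset, design, ci_method = "conditional")
#' summary(scan)
#' plot(scan)   # QQ plot
#' }
#' @export
burden_scan <- function(qvset, design, ci_method = c("wald", "conditional"),
                        conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  if (!nrow(qvset$carriers)) stop("nothing to test: empty qualifying-variant set")
  by_gene <- collapse_to_gene(qvset, design)
  n_cases <- length(design$case_ids)
  n_controls <- length(design$control_ids)
  by_gene <- Filter(function(g) length(g$case_carriers) + length(g$control_carriers) > 0,
                    by_gene)
  if (!length(by_gene)) stop("nothing to test: no carriers among analyzed samples")

  rows <- lapply(names(by_gene), function(g) {
    tab <- contingency(by_gene[[g]], design)
    or <- odds_ratio_wald(tab, conf_level)
    ci <- if (ci_method == "conditional")
      odds_ratio_conditional(tab, conf_level) else or
    data.frame(
      gene = g,
      case_carriers = unname(tab["a"]), n_cases = n_cases,
      control_carriers = unname(tab["c"]), n_controls = n_controls,
      case_prev = 100 * tab["a"] / n_cases,
      control_prev = 100 * tab["c"] / n_controls,
      or_exact = or$or,
      or_point = if (ci_method == "conditional") ci$or else or$or,
      ci_low = ci$ci_low, ci_high = ci$ci_high,
      p = fisher_two_sided(tab), row.names = NULL)
  })
  res <- do.call(rbind, rows)
  res$p_bonferroni <- bonferroni_adjust(res$p)
  res <- res[order(res$p, -res$or_exact, res$gene), ]
  rownames(res) <- NULL
  res$case_prev_pct <- round_half_away(res$case_prev, 2)
  res$control_prev_pct <- round_half_away(res$control_prev, 2)
  res$or <- round_half_away(res$or_point, 2)
  res$ci_method <- ci_method
  res <- res[, c("gene", "case_carriers", "n_cases", "control_carriers",
                 "n_controls", "case_prev_pct", "control_prev_pct", "or",
                 "ci_low", "ci_high", "ci_method", "p", "p_bonferroni",
                 "case_prev", "control_prev", "or_exact", "or_point")]
  structure(list(results = res, m_tests = nrow(res),
                 lambda_gc = lambda_gc(res$p), qq = qq_points(res$p),
                 mode = qvset$mode, ci_method = ci_method,
                 n_cases = n_cases, n_controls = n_controls),
            class = "burden_scan")
}

#' @export
print.burden_scan <- function(x, n = 10, ...) {
  cat("gene-level collapsing burden scan (", x$mode, " mode)\n", sep = "")
  cat("  ", x$n_cases, " cases vs ", x$n_controls, " controls; ",
      x$m_tests, " genes tested; lambda = ", format(x$lambda_gc, nsmall = 3),
      "\n\n", sep = "")
  top <- utils::head(x$results[, c("gene", "case_carriers", "control_carriers",
                                   "case_prev_pct", "control_prev_pct", "or",
                                   "ci_low", "ci_high", "p", "p_bonferroni")], n)
  top$ci_low <- signif(top$ci_low, 3); top$ci_high <- signif(top$ci_high, 3)
  top$p <- signif(top$p, 3); top$p_bonferroni <- signif(top$p_bonferroni, 3)
  print(top, row.names = FALSE)
  if (x$m_tests > n) cat("  ... ", x$m_tests - n, " more genes\n", sep = "")
  invisible(x)
}

#' @export
summary.burden_scan <- function(object, alpha = 0.05, ...) {
  sig <- object$results[object$results$p_bonferroni < alpha, "gene"]
  cat("burden scan summary\n")
  cat("  genes tested:          ", object$m_tests, "\n")
  cat("  cases / controls:      ", object$n_cases, "/", object$n_controls, "\n")
  cat("  genomic inflation:     ", format(object$lambda_gc, nsmall = 3), "\n")
  cat("  Bonferroni-significant:", if (length(sig)) paste(sig, collapse = ", ")
      else "none", "\n")
  invisible(object)
}

#' QQ plot of a burden scan
#'
#' Observed against expected -log10 p-values with the identity line; under
#' a calibrated null the points track the diagonal.
#'
#' @param x A `burden_scan`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.burden_scan <- function(x, ...) {
  plot(x$qq$expected, x$qq$observed,
       xlab = expression(Expected ~ -log[10](p)),
       ylab = expression(Observed ~ -log[10](p)),
       main = sprintf("QQ plot (%s mode), lambda = %.3f", x$mode, x$lambda_gc),
       pch = 20, ...)
  abline(0, 1, col = "grey50")
  invisible(x)
}

#' @export
as.data.frame.burden_scan <- function(x, ...) x$results

#' Write burden scan outputs
#'
#' Writes the results table (display columns) and the QQ coordinates as
#' tab-delimited files.
#'
#' @param scan A `burden_scan`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_scan <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  results_path <- file.path(dir, "burden_results.tsv")
  out <- scan$results[, c("gene", "case_carriers", "n_cases", "control_carriers",
                          "n_controls", "case_prev_pct", "control_prev_pct",
                          "or", "ci_low", "ci_high", "ci_method", "p",
                          "p_bonferroni")]
  write.table(out, results_path, sep = "\t", quote = FALSE, row.names = FALSE)
  qq_path <- file.path(dir, "qq_points.tsv")
  write.table(scan$qq, qq_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(results = results_path, qq = qq_path))
}
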