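#' Read a diagnostic code map
#'
#' The code map assigns each diagnostic code to one of four categories that
#' drive case/control classification:
#' \describe{
#'   \item{chd}{structural congenital heart disease codes; any such code
#'     makes the sample a case.}
#'   \item{avd}{aortic valve disease codes (stenosis, insufficiency,
#'     replacement); manifestation before the age cutoff is read as inferred
#'     bicuspid aortic valve (BAV), a mild CHD.}
#'   \item{exclusion}{codes that remove the sample from both cohorts.}
#'   \item{neutral}{codes with no bearing on cohort membership.}
#' }
#'
#' @param path Path to a tab-delimited file with columns
#'   `code`, `category`, `condition_label`.
#' @return A data frame with those three columns.
#' @export
read_code_map <- function(path) {
  map <- read.delim(path, colClasses = "character")
  required <- c("code", "category", "condition_label")
  if (!all(required %in% names(map)))
    stop("code map must have columns: ", paste(required, collapse = ", "))
  bad <- setdiff(unique(map$category), c("chd", "avd", "exclusion", "neutral"))
  if (length(bad))
    stop("unknown code-map categories: ", paste(bad, collapse = ", "))
  if (anyDuplicated(map$code))
    stop("each code must map to exactly one category")
  map
}

#' Path to the packaged toy code map
#' @return File path of the example code map shipped with the package.
#' @export
toy_code_map_path <- function() {
  system.file("extdata", "toy_code_map.tsv", package = "rvburden", mustWork = TRUE)
}

## Classification for one sample's codes; map columns pre-extracted.
classify_one <- function(categories, labels, ages) {
  labels <- sort(unique(labels[categories != ""]))
  if (any(categories == "chd"))
    return(list(status = "case", inferred_bav = FALSE, labels = labels))
  avd <- categories == "avd"
  if (any(avd)) {
    age <- suppressWarnings(min(ages[avd], na.rm = TRUE))
    if (is.finite(age) && age < attr(categories, "cutoff"))
      return(list(status = "case", inferred_bav = TRUE, labels = labels))
    return(list(status = "unknown", inferred_bav = FALSE, labels = labels))
  }
  if (any(categories == "exclusion"))
    return(list(status = "excluded", inferred_bav = FALSE, labels = labels))
  list(status = "control", inferred_bav = FALSE, labels = labels)
}

#' Classify one sample from its diagnostic codes
#'
#' Applies the case/control rule: any CHD-category code makes the sample a
#' case; otherwise an aortic-valve-disease (AVD) code with earliest recorded
#' age below `avd_age_cutoff` makes it a case with inferred BAV; AVD at or
#' above the cutoff (or with no recorded age) yields unknown status, since
#' late aortic valve disease is usually degenerative disease of a normal
#' tricuspid valve; otherwise an exclusion code excludes the sample; with no
#' qualifying codes the sample is a control. Codes absent from the map are
#' neutral (real code dictionaries are never exhaustive) and reported once
#' via a message.
#'
#' @param codes Data frame with columns `code`, `source`, `age_at_event`
#'   (years; may be `NA`). Zero rows means no diagnostic history.
#' @param code_map A code map as returned by [read_code_map()].
#' @param avd_age_cutoff Age (years) below which AVD is read as inferred
#'   BAV. Default 65.
#' @return A list with `status` (one of `"case"`, `"control"`, `"unknown"`,
#'   `"excluded"`), `inferred_bav` (logical), and `condition_labels`
#'   (character vector of labels from all mapped codes).
#' @examples
#' map <- read_code_map(toy_code_map_path())
#' classify_sample(data.frame(code = "AVD001", source = "hospital-episode",
#'                            age_at_event = 58), map)
#' @export
classify_sample <- function(codes, code_map, avd_age_cutoff = 65) {
  if (avd_age_cutoff <= 0) stop("avd_age_cutoff must be positive")
  if (nrow(codes)) {
    ages <- codes$age_at_event
    if (any(!is.na(ages) & (ages < 0 | ages > 120)))
      stop("age_at_event must lie in [0, 120]")
    idx <- match(codes$code, code_map$code)
    unknown_codes <- unique(codes$code[is.na(idx)])
    if (length(unknown_codes))
      message("codes absent from map treated as neutral: ",
              paste(unknown_codes, collapse = ", "))
    categories <- ifelse(is.na(idx), "", code_map$category[idx])
    labels <- ifelse(is.na(idx), "", code_map$condition_label[idx])
  } else {
    categories <- character(0); labels <- character(0); ages <- numeric(0)
  }
  attr(categories, "cutoff") <- avd_age_cutoff
  r <- classify_one(categories, labels, ages)
  list(status = r$status, inferred_bav = r$inferred_bav,
       condition_labels = r$labels)
}

#' Classify every sample in a cohort
#'
#' Vectorized wrapper over [classify_sample()]: samples with no rows in the
#' code table are controls.
#'
#' @param sample_ids Character vector: the full sample universe.
#' @param codes Data frame with columns `sample_id`, `code`, `source`,
#'   `age_at_event` (long format, one row per code event).
#' @param code_map A code map as returned by [read_code_map()].
#' @inheritParams classify_sample
#' @return A data frame with one row per sample: `sample_id`, `status`,
#'   `inferred_bav`, `condition_labels` (`;`-joined).
#' @export
classify_samples <- function(sample_ids, codes, code_map, avd_age_cutoff = 65) {
  if (avd_age_cutoff <= 0) stop("avd_age_cutoff must be positive")
  if (anyDuplicated(sample_ids)) stop("duplicate sample_id in universe")
  if (nrow(codes) && !all(codes$sample_id %in% sample_ids))
    stop("codes refer to samples outside the declared universe")
  idx <- match(codes$code, code_map$code)
  unknown_codes <- unique(codes$code[is.na(idx)])
  if (length(unknown_codes))
    message("codes absent from map treated as neutral: ",
            paste(unknown_codes, collapse = ", "))
  categories <- ifelse(is.na(idx), "", code_map$category[idx])
  labels <- ifelse(is.na(idx), "", code_map$condition_label[idx])
  by_sample <- split(seq_len(nrow(codes)), factor(codes$sample_id, levels = sample_ids))
  out <- lapply(by_sample, function(i) {
    cat_i <- categories[i]
    attr(cat_i, "cutoff") <- avd_age_cutoff
    classify_one(cat_i, labels[i], codes$age_at_event[i])
  })
  data.frame(
    sample_id = sample_ids,
    status = vapply(out, `[[`, "", "status"),
    inferred_bav = vapply(out, `[[`, NA, "inferred_bav"),
    condition_labels = vapply(out, function(r) paste(r$labels, collapse = ";"), ""),
    row.names = NULL
  )
}

#' Partition classified samples into analysis cohorts
#'
#' @param assignments Data frame as returned by [classify_samples()].
#' @return An object of class `cohort_design`: a list with character-vector
#'   elements `case_ids`, `control_ids`, `unknown_ids`, `excluded_ids`
#'   (pairwise disjoint; union is the sample universe).
#' @export
build_cohorts <- function(assignments) {
  if (anyDuplicated(assignments$sample_id))
    stop("duplicate sample_id in assignments")
  pick <- function(s) assignments$sample_id[assignments$status == s]
  design <- structure(list(case_ids = pick("case"),
                           control_ids = pick("control"),
                           unknown_ids = pick("unknown"),
                           excluded_ids = pick("excluded")),
                      class = "cohort_design")
  design
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("cohort design:",
      length(x$case_ids), "cases,",
      length(x$control_ids), "controls,",
      length(x$unknown_ids), "unknown,",
      length(x$excluded_ids), "excluded\n")
  invisible(x)
}

design_universe <- function(design)
  c(design$case_ids, design$control_ids, design$unknown_ids, design$excluded_ids)

#' Prevalence of a phenotype subtype
#'
#' Fraction of classified samples (cases + controls + unknown; excluded
#' samples are outside the denominator) carrying a given condition label,
#' or flagged as inferred BAV when `label = "inferred_bav"`.
#'
#' @param design A [build_cohorts()] result.
#' @param assignments The matching [classify_samples()] data frame.
#' @param label A condition label, or `"inferred_bav"`.
#' @return The prevalence as a fraction.
#' @export
subtype_prevalence <- function(design, assignments, label) {
  denom_ids <- c(design$case_ids, design$control_ids, design$unknown_ids)
  if (!length(denom_ids)) stop("no classified samples: empty denominator")
  rows <- assignments[assignments$sample_id %in% denom_ids, ]
  hit <- if (identical(label, "inferred_bav")) rows$inferred_bav
         else vapply(strsplit(rows$condition_labels, ";", fixed = TRUE),
                     function(l) label %in% l, NA)
  sum(hit) / length(denom_ids)
}
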