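#' Greedy pruning of related samples
#'
#' Removes samples until no listed kinship pair has both members retained.
#' Removal is greedy by descending number of remaining relatives; ties
#' prefer removing controls over cases (preserving the scarce case cohort),
#' then the lexicographically greater sample id. Deterministic. The output
#' is verified pair-free before returning.
#'
#' @param pairs Data frame with columns `sample_id_1`, `sample_id_2` (and
#'   optionally `kinship`); every listed pair counts as related.
#' @param design A `cohort_design`; pair members must belong to its sample
#'   universe.
#' @return Character vector of retained sample ids (the universe minus the
#'   removed samples).
#' @export
prune_related <- function(pairs, design) {
  universe <- design_universe(design)
  if (!nrow(pairs)) return(universe)
  if (any(pairs$sample_id_1 == pairs$sample_id_2))
    stop("self-pair in kinship list")
  members <- c(pairs$sample_id_1, pairs$sample_id_2)
  if (!all(members %in% universe))
    stop("kinship pair member(s) outside the sample universe: ",
         paste(unique(setdiff(members, universe)), collapse = ", "))
  is_case <- members %in% design$case_ids
  edges <- cbind(pairs$sample_id_1, pairs$sample_id_2)
  removed <- character(0)
  repeat {
    live <- !(edges[, 1] %in% removed) & !(edges[, 2] %in% removed)
    if (!any(live)) break
    deg <- table(c(edges[live, 1], edges[live, 2]))
    cand <- names(deg)[deg == max(deg)]
    cand_case <- cand %in% design$case_ids
    if (any(!cand_case)) cand <- cand[!cand_case]   # prefer removing non-cases
    removed <- c(removed, max(cand))                 # then greater id
  }
  retained <- setdiff(universe, removed)
  stopifnot(!any(pairs$sample_id_1 %in% retained & pairs$sample_id_2 %in% retained))
  retained
}

#' Principal components of a genotype dosage matrix
#'
#' Standard genotype PCA: missing dosages are mean-imputed per variant,
#' variant columns are standardized to mean 0 / unit variance
#' (zero-variance columns dropped), and the leading `k` principal
#' components are extracted. Columns are orthogonal and ordered by
#' decreasing explained variance.
#'
#' @param dosage Numeric matrix, samples x variants, dosages in `{0, 1, 2}`
#'   with `NA` for missing; row names are sample ids.
#' @param k Number of components.
#' @return Numeric matrix, samples x `k`, columns `PC1..PCk`.
#' @export
compute_pcs <- function(dosage, k) {
  if (nrow(dosage) < k + 1) stop("need at least k+1 samples for k components")
  if (ncol(dosage) < k) stop("need at least k variants for k components")
  for (j in seq_len(ncol(dosage))) {
    m <- mean(dosage[, j], na.rm = TRUE)
    dosage[is.na(dosage[, j]), j] <- if (is.nan(m)) 0 else m
  }
  sds <- apply(dosage, 2, sd)
  keep <- sds > 0
  if (!any(keep)) stop("no variance: all variant columns are constant")
  z <- scale(dosage[, keep, drop = FALSE])
  pc <- prcomp(z, center = FALSE, scale. = FALSE, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(dosage)
  scores
}

#' Remove ancestry outliers on leading principal components
#'
#' Two-pass rule: a sample is an outlier if its coordinate on any of the
#' first `n_pcs` components lies more than `sd_threshold` standard
#' deviations from that component's mean over the current sample set.
#' After removing first-pass outliers the mean and SD are recomputed once
#' on the retained samples and the rule applied a second time, then the
#' procedure stops (it is idempotent thereafter).
#'
#' @param pcs Numeric matrix of PC coordinates, sample ids as row names.
#' @param sd_threshold Outlier threshold in standard deviations (default 4).
#' @param n_pcs Number of leading components checked (default 4, capped at
#'   the number of columns).
#' @return Character vector of retained sample ids.
#' @export
ancestry_filter <- function(pcs, sd_threshold = 4, n_pcs = 4) {
  if (!nrow(pcs)) stop("empty PC matrix")
  if (sd_threshold <= 0) stop("sd_threshold must be positive")
  n_pcs <- min(n_pcs, ncol(pcs))
  retained <- rownames(pcs)
  for (pass in 1:2) {
    m <- pcs[retained, seq_len(n_pcs), drop = FALSE]
    mu <- colMeans(m)
    sds <- apply(m, 2, sd)
    sds[sds == 0] <- Inf     # a constant component flags no one
    out <- rowSums(abs(sweep(sweep(m, 2, mu), 2, sds, "/")) > sd_threshold) > 0
    retained <- retained[!out]
    if (!length(retained)) stop("ancestry filter removed every sample")
  }
  retained
}

#' Restrict a cohort design to a retained sample set
#'
#' Samples outside `retained` are moved from the case/control/unknown sets
#' to the excluded set: the design universe stays complete, so downstream
#' bookkeeping (samples in = retained + removed) always reconciles.
#'
#' @param design A `cohort_design`.
#' @param retained Character vector of sample ids to keep.
#' @return A new `cohort_design`.
#' @export
restrict_design <- function(design, retained) {
  removed <- setdiff(design_universe(design), retained)
  structure(list(case_ids = intersect(design$case_ids, retained),
                 control_ids = intersect(design$control_ids, retained),
                 unknown_ids = intersect(design$unknown_ids, retained),
                 excluded_ids = union(design$excluded_ids, removed)),
            class = "cohort_design")
}
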