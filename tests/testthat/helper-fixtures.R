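# Shared helpers: tiny in-code fixtures and independent oracles.

toy_map <- read_code_map(toy_code_map_path())

# Independent two-sided Fisher p by direct enumeration of the
# hypergeometric support with plain (non-log) probabilities.
enum_fisher_p <- function(a, b, c, d, rel_tol = 1e-7) {
  n1 <- a + b; n2 <- c + d; m1 <- a + c; N <- n1 + n2
  lo <- max(0, m1 - n2); hi <- min(m1, n1)
  k <- lo:hi
  pk <- choose(m1, k) * choose(N - m1, n1 - k) / choose(N, n1)
  sum(pk[pk <= pk[a - lo + 1] * (1 + rel_tol)])
}

# Minimum vertex cover by brute force (oracle for greedy kinship pruning).
brute_min_cover <- function(edges, nodes) {
  best <- nodes
  for (size in 0:length(nodes)) {
    combs <- utils::combn(nodes, size, simplify = FALSE)
    for (rm in combs) {
      keep1 <- !(edges[, 1] %in% rm); keep2 <- !(edges[, 2] %in% rm)
      if (!any(keep1 & keep2)) return(rm)
    }
  }
  best
}

# A small deterministic design for burden tests.
tiny_design <- function(n_cases = 3, n_controls = 7) {
  structure(list(
    case_ids = sprintf("case%02d", seq_len(n_cases)),
    control_ids = sprintf("ctrl%02d", seq_len(n_controls)),
    unknown_ids = character(0), excluded_ids = character(0)),
    class = "cohort_design")
}

# A qv_set built directly from a carriers data frame.
qvset_from_carriers <- function(carriers, mode = "pathogenic") {
  surviving <- unique(carriers[, c("gene", "variant_id")])
  structure(list(carriers = carriers, variants = surviving,
                 genes = unique(surviving$gene), mode = mode,
                 criteria = NULL), class = "qv_set")
}

design_universe_ids <- function(design) {
  c(design$case_ids, design$control_ids, design$unknown_ids, design$excluded_ids)
}

empty_geno_df <- function() {
  data.frame(variant_id = character(0), sample_id = character(0),
             gt = character(0), gq = integer(0), dp = integer(0))
}

filter_fixture_dir <- system.file("extdata", "toy_filter", package = "rvburden")
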