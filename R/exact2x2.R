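#' Gene-level 2x2 carrier table
#'
#' Construct the 2x2 contingency table for a collapsing burden test: carrier
#' and non-carrier counts of a gene's qualifying variants among cases and
#' controls.
#'
#' @param a Case carriers.
#' @param b Case non-carriers.
#' @param c Control carriers.
#' @param d Control non-carriers.
#' @return An object of class `contingency_table`: a named integer vector
#'   with elements `a`, `b`, `c`, `d`.
#' @examples
#' contingency_table(10, 1344, 174, 179136)
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("contingency table cells must be non-negative integers")
  structure(as.integer(round(cells)), names = c("a", "b", "c", "d"),
            class = "contingency_table")
}

as_table_cells <- function(table) {
  if (inherits(table, "contingency_table")) return(unclass(table))
  if (is.matrix(table) && all(dim(table) == 2))
    return(c(a = table[1, 1], b = table[1, 2], c = table[2, 1], d = table[2, 2]))
  if (length(table) == 4) return(setNames(as.numeric(table), c("a", "b", "c", "d")))
  stop("expected a contingency_table, a 2x2 matrix, or a length-4 vector (a,b,c,d)")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(unclass(x), 2, 2, byrow = TRUE,
              dimnames = list(c("case", "control"), c("carrier", "non-carrier")))
  print(m)
  invisible(x)
}

## Hypergeometric support of the case-carrier count given fixed margins.
table_support <- function(cells) {
  n1 <- cells["a"] + cells["b"]          # cases
  n2 <- cells["c"] + cells["d"]          # controls
  m1 <- cells["a"] + cells["c"]          # carriers
  lo <- max(0, m1 - n2)
  hi <- min(m1, n1)
  list(k = seq.int(lo, hi), m1 = unname(m1), n1 = unname(n1),
       n2 = unname(n2), N = unname(n1 + n2))
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x > -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value under the hypergeometric null, using the
#' minimum-likelihood convention: the p-value is the sum of the
#' probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table (within a small
#' relative tolerance guarding floating-point ties). All sums are carried
#' out in log space, so cohort-scale margins (hundreds of thousands of
#' samples) are handled without underflow.
#'
#' @param table A [contingency_table()], 2x2 matrix, or `(a, b, c, d)` vector.
#' @param rel_tol Relative tolerance used when comparing point probabilities
#'   to the observed table's probability.
#' @return The two-sided p-value.
#' @examples
#' fisher_two_sided(contingency_table(10, 1344, 174, 179136))
#' @seealso [odds_ratio_wald()], [odds_ratio_conditional()]
#' @export
fisher_two_sided <- function(table, rel_tol = 1e-7) {
  cells <- as_table_cells(table)
  if (any(cells < 0)) stop("negative cell in contingency table")
  s <- table_support(cells)
  if (length(s$k) == 1L) return(1)   # degenerate margins: only one table
  logp <- dhyper(s$k, s$m1, s$N - s$m1, s$n1, log = TRUE)
  log_obs <- logp[match(unname(cells["a"]), s$k)]
  keep <- logp <= log_obs + log1p(rel_tol)
  min(1, exp(logsumexp(logp[keep])))
}

#' Wald odds ratio and confidence interval for a 2x2 table
#'
#' Cross-product odds ratio with a log-scale Wald interval. If any cell is
#' zero, the Haldane-Anscombe correction (add 0.5 to every cell) is applied
#' before computing both the point estimate and the interval.
#'
#' @inheritParams fisher_two_sided
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `or`, `ci_low`, `ci_high`, and `corrected` (whether
#'   the continuity correction was applied).
#' @examples
#' odds_ratio_wald(contingency_table(10, 1344, 174, 179136))
#' @export
odds_ratio_wald <- function(table, conf_level = 0.95) {
  cells <- as_table_cells(table)
  if (any(cells < 0)) stop("negative cell in contingency table")
  if (cells["a"] + cells["b"] == 0 || cells["c"] + cells["d"] == 0)
    stop("odds ratio undefined: a cohort row of the table is empty")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(or = unname(or),
       ci_low = unname(exp(log(or) - z * se)),
       ci_high = unname(exp(log(or) + z * se)),
       corrected = corrected)
}

## Normalized log-probabilities of the non-central (Fisher) hypergeometric
## distribution at log odds `logpsi`, over the support of the table.
nchg_logprob <- function(logpsi, log_dh, k) {
  lw <- log_dh + k * logpsi
  lw - logsumexp(lw)
}

nchg_mean <- function(logpsi, log_dh, k) {
  sum(k * exp(nchg_logprob(logpsi, log_dh, k)))
}

## Bisection for a monotone function f on logpsi; expands the bracket first.
bisect_logpsi <- function(f, target, increasing = TRUE, tol = 1e-8) {
  g <- if (increasing) function(x) f(x) - target else function(x) target - f(x)
  lo <- -1; hi <- 1
  while (g(lo) > 0 && lo > -500) lo <- lo * 2
  while (g(hi) < 0 && hi < 500) hi <- hi * 2
  if (g(lo) > 0 || g(hi) < 0) return(if (g(hi) < 0) Inf else -Inf)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Conditional-exact odds ratio and confidence interval
#'
#' Conditional maximum-likelihood estimate (cMLE) of the odds ratio given
#' the table margins, with an exact conditional confidence interval: the
#' interval bounds are the odds-ratio values at which the conditional upper
#' and lower tail probabilities of the observed case-carrier count equal
#' `(1 - conf_level) / 2`. This is the interval convention of the classical
#' conditional exact test, and is typically wider below than the Wald
#' interval for sparse tables. Degenerate tables (observed count at the
#' boundary of its support) return 0 or `Inf` bounds.
#'
#' @inheritParams odds_ratio_wald
#' @param tol Bisection tolerance on the log odds ratio.
#' @return A list with `or` (cMLE), `ci_low`, `ci_high`.
#' @examples
#' odds_ratio_conditional(contingency_table(10, 1344, 174, 179136))
#' @export
odds_ratio_conditional <- function(table, conf_level = 0.95, tol = 1e-8) {
  cells <- as_table_cells(table)
  if (any(cells < 0)) stop("negative cell in contingency table")
  s <- table_support(cells)
  a <- unname(cells["a"])
  if (length(s$k) == 1L) return(list(or = NaN, ci_low = 0, ci_high = Inf))
  log_dh <- dhyper(s$k, s$m1, s$N - s$m1, s$n1, log = TRUE)
  alpha2 <- (1 - conf_level) / 2
  k <- s$k

  point <- if (a == min(k)) 0 else if (a == max(k)) Inf else
    exp(bisect_logpsi(function(lp) nchg_mean(lp, log_dh, k), a, tol = tol))

  upper_tail <- function(lp) sum(exp(nchg_logprob(lp, log_dh, k)[k >= a]))
  lower_tail <- function(lp) sum(exp(nchg_logprob(lp, log_dh, k)[k <= a]))

  ci_low <- if (a == min(k)) 0 else
    exp(bisect_logpsi(upper_tail, alpha2, increasing = TRUE, tol = tol))
  ci_high <- if (a == max(k)) Inf else
    exp(bisect_logpsi(lower_tail, alpha2, increasing = FALSE, tol = tol))
  list(or = point, ci_low = ci_low, ci_high = ci_high)
}

#' Bonferroni adjustment
#'
#' Family-wise error control for the gene-level scan: each p-value is
#' multiplied by the number of tests and capped at 1 (via [stats::p.adjust]).
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length.
#' @export
bonferroni_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "bonferroni")
}

#' Expected/observed quantile pairs for a QQ plot of p-values
#'
#' @param pvals Non-empty numeric vector of p-values.
#' @return A data frame with columns `expected` and `observed`
#'   (both -log10 scale), sorted ascending in `expected`.
#' @export
qq_points <- function(pvals) {
  if (!length(pvals)) stop("empty p-value list")
  if (any(pvals == 0)) {
    message("p-values of 0 clamped to smallest representable positive value")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  m <- length(pvals)
  data.frame(expected = -log10(seq.int(m, 1) / (m + 1)),
             observed = -log10(sort(pvals, decreasing = TRUE)))
}

#' Genomic inflation factor (lambda)
#'
#' Median of the 1-df chi-square quantiles of the p-values divided by the
#' theoretical null median (0.4549...). Values near 1 indicate a calibrated
#' scan; inflation above 1 indicates systematic case/control differences.
#'
#' @param pvals Non-empty numeric vector of p-values.
#' @return Lambda, rounded to 3 decimal places.
#' @export
lambda_gc <- function(pvals) {
  if (!length(pvals)) stop("empty p-value list")
  pvals[pvals == 0] <- .Machine$double.xmin
  chisq <- qchisq(pvals, df = 1, lower.tail = FALSE)
  round(median(chisq) / qchisq(0.5, df = 1), 3)
}
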