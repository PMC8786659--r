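---
title: "Gene-level rare-variant collapsing burden analysis with rvburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level rare-variant collapsing burden analysis with rvburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

`rvburden` implements a collapsing burden analysis for case/control exome
cohorts under a dominant carrier model. The question it answers, gene by
gene: do cases carry qualifying variants (QVs) of this gene more often than
controls? The unit of inference is the 2x2 carrier table

|            | carrier | non-carrier |
|------------|---------|-------------|
| cases      | a       | b           |
| controls   | c       | d           |

where a sample is a *carrier* of a gene if it has at least one het or
hom-alt genotype, passing QC, at any QV of that gene — a sample with two
QVs in one gene counts once. The test is the two-sided Fisher exact test on
this table; effect size is the odds ratio ad/bc; multiplicity is handled by
Bonferroni correction over the genes tested; and scan-level calibration is
judged by a QQ plot and the genomic inflation factor
$\lambda = \mathrm{median}(\chi^2_{obs}) / 0.4549$.

The pipeline was built around a study design for mild congenital heart
disease (CHD) in a volunteer biobank: a heavily imbalanced cohort (order
1,300 cases against 180,000 controls), phenotypes derived from hospital
episode and primary-care diagnostic codes, and an age rule that reads
aortic valve disease (AVD) manifesting before 65 as inferred bicuspid
aortic valve (BAV), the most common mild CHD. All of these elements are
parameters, not constants, so the pipeline applies to any coded phenotype
with the same shape.

## Stages and their rules

**Phenotype classification** (`classify_samples`, `build_cohorts`). A
user-supplied code map assigns each diagnostic code to one of `chd`,
`avd`, `exclusion`, `neutral`. Per sample, in order: any `chd` code makes
a case; otherwise an `avd` code with *earliest* recorded age strictly
below the cutoff (default 65 years) makes a case flagged `inferred_bav`;
`avd` at or above the cutoff — or with no recorded age — yields unknown
status (late AVD is usually degenerative disease of a tricuspid valve, so
neither cohort is safe); otherwise an exclusion code excludes; otherwise
the sample is a control. The boundary is deliberately strict: "before 65"
means ages up to and including 64; age exactly 65 falls to unknown.
Unknown-status samples belong to neither cohort downstream. Codes absent
from the map are neutral and reported once — real code dictionaries are
never exhaustive, and treating gaps as errors would make every real
extract fail.

**Genotype QC** (`apply_genotype_qc`). A called genotype passes iff
GQ >= 20 and DP >= 7 for SNPs or DP >= 10 for indels. Failing calls are
downgraded to missing rather than dropped, preserving the matrix shape;
missing counts as non-carrier. Multi-base substitutions (MNPs) take the
indel threshold — the stricter choice, since the thresholds are defined
only for SNPs and indels. QC is idempotent by construction.

**Qualifying-variant selection** (`select_qualifying_variants`). The
primary filter keeps variants that are (i) present in strictly less than
1% of *all* samples in the input VCF (carrier-sample frequency, not allele
frequency — the denominator is deliberately the pre-cohort-QC universe),
(ii) of HIGH or MODERATE predicted impact, (iii) absent from gnomAD —
absence meaning no record at all, which is distinct from an observed
frequency of zero — and (iv) CADD PHRED >= 20, with an absent score
excluding the variant (a deleteriousness claim that cannot be certified is
not made). A subsidiary mode relaxes (iii) to gnomAD AF < 1e-4, admitting
variants seen at trace frequency. With multiple transcript annotations the
highest-impact row is canonical, ties broken by first occurrence. The
negative-control set (`select_synonymous_common`) takes synonymous
variants with gnomAD AF strictly above 0.01: common, functionally inert
variation in which cases and controls should not differ.

**Cohort QC** (`prune_related`, `compute_pcs`, `ancestry_filter`). Kinship
pairs are consumed as input; any listed pair counts as related, regardless
of coefficient, because no kinship estimator or degree cutoff is part of
this design. Pruning removes the member with more remaining relatives
first, preferring to remove controls over cases (cases are the scarce
resource at a 1:130 imbalance), then the lexicographically greater id —
fully deterministic, and the result is verified pair-free on every run.
Ancestry outliers are removed by a two-pass rule on the leading principal
components: any sample beyond `sd_threshold` (default 4) standard
deviations from the mean on any of the first `n_pcs` (default 4)
components is dropped; statistics are recomputed once on the survivors and
the rule applied a second time, after which the filter is idempotent.
Both thresholds are this package's choices, configurable and documented as
such. PCs may be supplied precomputed (as biobanks provide); otherwise
`compute_pcs` performs standard genotype PCA (mean imputation,
per-variant standardization, zero-variance columns dropped).

**Burden scan** (`burden_scan`). One result row per gene with at least one
carrier among analyzed samples; that gene count is also the Bonferroni
family. Results are ordered by ascending p, ties broken by descending odds
ratio, then gene label.

## The exact test and its intervals

`fisher_two_sided` computes the two-sided p by the minimum-likelihood
convention: the sum of the probabilities of all tables with the observed
margins whose point probability does not exceed the observed table's. All
sums run in log space via `logsumexp`, so margins in the hundreds of
thousands neither underflow nor lose precision; a relative tolerance of
1e-7 guards floating-point ties when comparing point probabilities. On
every 2x2 table with total n <= 40 the implementation agrees with full
hypergeometric enumeration to better than 1e-12 relative error (checked
exhaustively in the test suite).

Two confidence intervals are offered because they answer slightly
different needs:

* **Wald** (default): `exp(log OR ± 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`,
  closed form, reproducible with a pocket calculator. Tables with a zero
  cell take the Haldane–Anscombe correction (+0.5 to every cell) before
  both the point estimate and the interval.
* **Conditional exact**: the point estimate maximizes the non-central
  hypergeometric likelihood given the margins (the conditional MLE, found
  by bisection on the log odds ratio to 1e-8), and the bounds are the odds
  ratios at which the conditional tail probabilities of the observed count
  equal 0.025. For sparse tables this interval is noticeably wider below
  than the Wald interval — which is exactly the behaviour of published
  exact-test results on carrier tables of this shape, and why the method
  is provided. Degenerate tables (observed count at its support boundary)
  return 0 or infinite bounds.

Reported prevalences and odds ratios are rounded half-away-from-zero to
two decimals for display; all tests and orderings use full precision.

## The synthetic cohort generator

`generate_cohort` emulates the *structure* the pipeline consumes, not the
biology of exomes. Per gene, each sample is a rare-QV carrier with a
configured probability (default 0.002); one optional spiked gene takes
separate case and control carrier rates; a configurable fraction of
variants (default 1/3) forms the common-synonymous stratum at a carrier
rate of 0.05 — common enough that the exact test's discreteness is mild
and the calibration scan is informative. Phenotype codes are drawn from
the packaged toy code map; the default inferred-BAV code rate is 0.4%, the
prevalence the pipeline is designed around, with a case-code fraction of
0.75% echoing the 1:130 imbalance. Sub-threshold QC genotypes are emitted
with GQ or DP exactly one unit below threshold, so filter boundary
behaviour is exercised, and missingness is uniform at a configured rate —
a stated simplification, since real exome missingness is structured.
Kinship pairs carry coefficient 0.25; ancestry outliers are displaced by
10 SD on PC1. The generator emits bi-allelic records only (multi-allelic
splitting is the reader's concern), stores genotypes sparsely (hom-ref is
implicit — a dense matrix at biobank scale would be pointless memory), and
splits its random stream per component so adding variants does not perturb
phenotype draws. Identical configuration and seed give a byte-identical
bundle, and `write_bundle`/`read_bundle` round-trip exactly.

What passing tests on these cohorts do **not** show: robustness to linkage
disequilibrium, realistic site-frequency spectra, sequencing-error
artefacts, population substructure beyond displaced PC outliers, or
X-chromosome ploidy. Results on real data depend on those properties;
the generator's role is to verify the pipeline's logic and calibration,
not to certify it against every failure mode of real exomes.

## Numerical and design choices

* Carrier frequency uses the full input-VCF sample universe as
  denominator, before cohort QC — "present in less than 1% of samples"
  reads most naturally against all sequenced samples, and the choice is
  configurable.
* Bisection brackets for the conditional interval expand geometrically on
  the log-odds scale and cap at ±500, beyond which the bound is reported
  as 0 or infinity.
* `lambda_gc` clamps p = 0 to the smallest positive double before the
  chi-square transform and is reported to three decimals.
* QC-removed samples are moved to the excluded set rather than deleted,
  so stage counts always reconcile (samples in = retained + removed).
* A qualifying variant left with no passing carrier genotype is dropped
  from the QV set: it cannot influence any burden table.
* The scan refuses an empty QV set, and `contingency` refuses an empty
  cohort, with explicit errors; pipeline stages wrap failures with the
  stage name.

## Verification scale

The checks in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` run at a deliberately reduced scale chosen as
sufficient for their statistical resolution: the null-calibration scan
uses 2,000 genes over 2,000 cases and 20,000 controls at a baseline
carrier rate of 0.002 (type-I error resolved to about ±1% at α = 0.05;
the exact test is expected to sit *below* nominal on sparse tables), and
spiked-gene recovery uses 100 replicates of a 121-gene cohort with case
carrier rate 0.02 against control 0.0025 — a true odds ratio of
(0.02/0.98)/(0.0025/0.9975) ≈ 8.14 — resolving CI coverage to about ±4%.
The QC-failure and missingness rates are set to zero in those
configurations so the realized carrier rates are exactly the stated ones.

## Known limitations

* The exclusion-code category exists but ships empty of real content; its
  population is study-specific.
* Hemizygous X-chromosome genotypes are not treated specially; carrier
  counting is autosomal-dominant throughout.
* No covariate adjustment (logistic/Firth regression, SKAT-family tests)
  and no variant weighting; the test is the plain carrier-count Fisher
  exact.
* The conditional MLE is undefined (NaN) for tables with degenerate
  margins; callers see explicit boundary values instead of silent output.

## A worked example

```{r, eval = FALSE}
library(rvburden)

cfg <- sim_config(
  n_samples = 20000, case_fraction = 0.01,
  genes = setNames(rep(3L, 50), sprintf("G%02d", 1:50)),
  spiked_gene = list(gene = "G25", case_rate = 0.03, control_rate = 0.003),
  related_pairs = 20L, ancestry_outliers = 5L, seed = 42)
bundle <- generate_cohort(cfg)
paths <- write_bundle(bundle, "cohort")

config <- pipeline_config(
  vcf = paths[["vcf"]], annotations = paths[["annotations"]],
  codes = paths[["phenotype_codes"]], code_map = toy_code_map_path(),
  kinship = paths[["kinship"]], pcs = paths[["pcs"]],
  out_dir = "cohort/out", analysis_mode = "pathogenic",
  ci_method = "conditional", seed = 42)
manifest <- run_pipeline(config)

print(manifest$scan)
plot(manifest$scan)
```
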