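---
title: "Two-sample bi-directional Mendelian randomization with mrbidir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample bi-directional Mendelian randomization with mrbidir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Observational studies of bone mineral density (BMD) and osteoarthritis (OA)
disagree about which condition drives the other: low BMD has been reported
both as a risk factor for OA and as its consequence. Mendelian randomization
(MR) addresses this by using genetic variants as instrumental variables.
Because alleles are assorted at conception, a variant that raises the
exposure acts like a tiny randomized intervention: if genetically higher
(or lower) BMD shifts OA risk, the exposure is upstream. `mrbidir`
implements the complete two-sample summary-statistic workflow in both
directions — BMD-like quantitative exposures against OA-like binary
outcomes, and the reverse — together with the sensitivity analyses,
colocalization, and enrichment statistics that usually accompany such an
analysis.

A variant is a valid instrument if it is (1) associated with the exposure,
(2) independent of confounders, and (3) affects the outcome only through
the exposure. The estimators differ in how much of assumption (3) they can
lose before breaking; the package's panel is designed to triangulate.

## The model

For instrument $j$, let $\hat\gamma_j$ (SE $\sigma_{Xj}$) be its exposure
association and $\hat\Gamma_j$ (SE $\sigma_{Yj}$) its outcome association,
harmonized to the same effect allele. Under the instrumental-variable
assumptions $\Gamma_j = \theta\,\gamma_j$, and each variant gives a Wald
ratio $\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$ with first-order
delta-method standard error $\sigma_{Yj}/|\hat\gamma_j|$ (a second-order
version adding the exposure-uncertainty term is available but changes
little for instruments with exposure $|z| > 10$).

* **IVW (primary).** The fixed-effect inverse-variance-weighted mean of
  the ratios, algebraically identical to a zero-intercept weighted
  regression of $\hat\Gamma_j$ on $\hat\gamma_j$ with weights
  $1/\sigma_{Yj}^2$. A random-effects variant inflates the SE by the
  multiplicative factor $\max(1, \sqrt{Q/(n-1)})$, appropriate for
  subgroup analyses where extra heterogeneity is expected.
* **Cochran's Q** around the fixed-effect estimate, $df = n-1$,
  upper-tail chi-square, quantifies instrument heterogeneity.
* **MR-Egger.** Weighted regression with a free intercept after orienting
  each pair so $\hat\gamma_j \ge 0$ (the slope is not invariant to the
  arbitrary allele labeling otherwise). The intercept estimates the
  average directional pleiotropic effect; its t-test ($n-2$ df, residual
  scale factor $\max(1,\sqrt{RSS_w/(n-2)})$) is the standard check that
  the IVW estimate is not driven by directional pleiotropy.
* **Simple and weighted medians.** The (weighted) median of the ratios is
  consistent when instruments carrying at least half the (weight) count
  are valid. The weighted median interpolates the ordered ratios at
  cumulative normalized weight 0.5 with the midpoint convention; with
  equal weights it reduces exactly to the sample median. Their standard
  errors come from a parametric bootstrap (each ratio redrawn from
  $N(\hat\theta_j, se_j)$, default 1000 resamples, seed required) because
  no exact closed form exists.
* **MR-PRESSO.** A Monte-Carlo residual-sum-of-squares test: the observed
  weighted RSS around leave-one-out IVW predictions is compared with
  simulations in which outcome effects are redrawn from their null
  predictive distribution. The per-instrument version flags outliers
  (Bonferroni-adjusted Monte-Carlo p by default), the adjusted estimate is
  simply IVW on the survivors, and a distortion test checks whether
  removal materially moved the estimate (the null distribution substitutes
  random with-replacement draws of non-outliers for the removed set).

Confidence intervals are Wald-type with $z = 1.959964$ everywhere except
inside Egger, which is t-based. P-values are two-sided.

## Instrument selection and harmonization

Selection proceeds in stages, each of which is reported with per-variant
drop reasons: a strict `p < threshold` screen (defaults $5\times10^{-8}$
for a well-powered quantitative exposure; $1\times10^{-5}$ is conventional
for the reverse direction, where binary-disease GWAS yield few genome-wide
hits), greedy LD clumping (rank by p, retain the best, remove in-window
variants with $r^2 >$ 0.001 within 1 Mb), and removal of instruments whose
outcome association is itself genome-wide significant. Two clumping
policies exist for in-window pairs missing from the LD table: the default
treats them as correlated (so an empty LD table keeps one variant per
window — the conservative reading of distance-based pruning), the
alternative treats them as independent. Ties in p are broken by variant id
so results are independent of input order.

Harmonization orients every outcome record to the exposure's effect
allele: identical labels pass through, swapped labels flip the outcome
beta and frequency, strand complements are resolved, and palindromic (A/T,
C/G) variants — where labels cannot distinguish strand from swap — are
oriented by effect-allele frequency. A palindrome is deemed unresolvable
and dropped when either frequency is missing or lies within 0.08 of 0.5
(band 0.42–0.58, configurable): this is the common practice threshold; the
band is a parameter precisely because no universal value exists. Because
every ABF and every estimator is invariant to a coherent relabeling, a
correctly harmonized dataset gives bit-identical estimates whatever the
labeling of the input files — a property the test suite checks.

## Colocalization and enrichment

The eQTL stage asks whether a GWAS signal and an expression signal in the
same region share one causal variant. For each shared variant the
Wakefield approximate Bayes factor is
$\log ABF = \tfrac12\log(1-r) + \tfrac12 r z^2$ with
$r = W/(V+W)$, $V = se^2$, and prior effect variance $W$ (prior SD 0.15
for quantitative traits, 0.2 on the log-odds scale for binary ones).
Hypothesis sums H0–H4 are prior-weighted ($p_1 = p_2 = 10^{-4}$,
$p_{12} = 10^{-5}$, the canonical single-causal-variant defaults) and
evaluated in log space with log-sum-exp, since ABFs overflow past
$|z| \approx 40$. For regions of up to five variants the implementation is
checked against a plain-space exhaustive enumeration oracle to $10^{-9}$.

The enrichment module is a deliberately generic stand-in for web-based GO
tooling: an upper-tail hypergeometric over-representation test (sets
intersected with the universe first; enrichment only, so zero overlap
gives p = 1 exactly) with Benjamini–Hochberg adjustment. The SNP-to-gene
mapping is accepted as input because it requires an external annotation
database; gene-set counts therefore depend on the caller's annotation
version and are not reproduced by the package.

A Bonferroni helper covers the transcriptome-wide threshold arithmetic:
$0.05 / (20000 \times 48) \approx 5.2\times10^{-8}$ for a 20,000-gene,
48-tissue scan.

## What the synthetic generator emulates — and what it does not

`simulate_gwas_pair()` draws, per instrument: a frequency from
Uniform(0.05, 0.5); a true exposure effect from a zero-mean normal
(SD 0.08) truncated away from zero so the expected exposure z-statistic
clears the detection threshold (default the genome-wide 5.45 — without
truncation a desk-scale simulation would leave the p-value screen empty);
standard errors from the standard GWAS approximations
$1/\sqrt{2f(1-f)n}$ (quantitative) and $1/\sqrt{2f(1-f)n\,v(1-v)}$
(binary, case fraction $v = 0.2$, matching the roughly 20% case share of
large OA biobank meta-analyses); and estimates with independent normal
sampling noise. The defaults — 50 instruments, exposure $n = 30{,}000$,
outcome $n = 300{,}000$, $\theta = 0.1$ — mirror the scale of a GEFOS-era
BMD discovery GWAS against a biobank OA GWAS. Pleiotropy scenarios cover
none, balanced, directional (defined relative to the exposure-increasing
allele — the only frame in which a common direction is meaningful, and
the frame Egger's orientation estimates), and gross outliers at a chosen
multiple of the outcome SE. `perturb_for_harmonization()` injects label
swaps, strand flips, and palindromes with recorded ground truth;
`simulate_ld_blocks()` builds block LD for clumping tests;
`simulate_coloc_region()` builds shared/distinct/null region pairs.

What passing tests on these data do **not** show: robustness to real LD
(instruments are simulated independent; the LD table is synthetic),
sample overlap between the two GWAS, winner's curse from selecting
instruments in the same data that estimated them, population
stratification, or non-normal effect-size distributions. Results on real
summary statistics inherit all of those caveats.

## Numerical and design choices

* Problem sizes in the test suite — 500 replicates for recovery and
  directional-pleiotropy checks, 1000 for type-I error, 100 for outlier
  detection, Monte-Carlo size 1000 for MR-PRESSO — are chosen so each
  Monte-Carlo standard error is several times smaller than the property
  band being asserted.
* The IVW type-I error runs slightly above nominal (about 0.05–0.07
  across seed blocks) with threshold-strength instruments: the
  first-order ratio SE ignores exposure-side noise, which matters most
  when exposure z-statistics sit near the detection threshold. This is
  the standard behavior of first-order IVW implementations; the
  second-order option narrows it at the cost of a non-standard weighting.
* Monte-Carlo p-values carry add-one smoothing, $(1+k)/(n_{sim}+1)$, so
  they are never zero and never below $1/(n_{sim}+1)$.
* Cochran's Q uses the textbook convention (fixed-effect center,
  $df = n-1$, upper-tail chi-square). Published MR tables occasionally
  print Q/p pairs inconsistent with that convention (software-dependent
  df choices); this package asserts its own convention and treats such
  printed p-values as non-comparable.
* Degenerate inputs fail loudly and specifically: a single instrument
  reduces IVW to the Wald ratio with a warning; medians and Egger demand
  three instruments, MR-PRESSO four; an all-dropped harmonization raises
  rather than returning an empty fit.
* All randomness is local: every stochastic routine seeds a private RNG
  stream and restores the caller's state, so identical calls are
  bit-for-bit reproducible and never perturb the session.

## A worked run

```{r, eval = FALSE}
library(mrbidir)

sim <- simulate_gwas_pair(simulation_params(theta = 0.1, seed = 1))
h   <- harmonize_all(sim$exposure, sim$outcome)
fit <- mr_fit(h, seed = 1, exposure = "BMD", outcome = "OA")
summary(fit)
mr_presso(h, n_sim = 1000, seed = 1)

## or the orchestrated equivalent, with selection and reports:
report <- run_mr_direction(sim$exposure, sim$outcome,
                           config = direction_config(seed = 1))
report$counts
write_results_table(report$table, "results.tsv")
```

The estimator interface is a classed fit object: `print()`, `summary()`,
`coef()`, `confint()`, `residuals()` (weighted IVW residuals, the raw
material of outlier hunting) and `plot()` (scatter with IVW/Egger lines,
forest, funnel) behave as for any R model fit.

## Limitations

The package operates strictly on summary statistics: no individual-level
data, no LD reference panel computation (pairwise $r^2$ is an input), no
multi-allelic variants, no genome-build liftover, and no multivariable or
mode-based estimators. The colocalization stage implements the
single-causal-variant ABF model only; regions with multiple causal
signals need conditional approaches beyond its scope.
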