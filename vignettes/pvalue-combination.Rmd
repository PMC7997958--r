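---
title: "Combining p-values under incomplete association: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining p-values under incomplete association: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacomb)
```

## The problem

A meta-analysis combines summary statistics from $n$ studies that test the
same null hypothesis. The null being tested by a p-value combiner is

> H$_0$: *none* of the studies carries a true effect,

so rejecting it only requires *some* studies to be associated. In practice —
ancestry-specific genetic effects, batch effects, low-quality datasets —
it is common that only a subset of the combined studies carries the effect
while the rest contribute p-values that are simply Uniform(0, 1) noise. We
call this *incomplete association*, an associated study's p-value a
*p1-value*, and an unassociated (uniform) one a *p0-value*.

The popular weighted combiners behave very differently in this regime.
Stouffer's Z and its sample-size-weighted version average inverse-normal
transforms, so each appended p0-value dilutes the mean; Lancaster's method
gives study $i$ a $\chi^2$ transform with $s_i$ (sample size) degrees of
freedom, so its statistic is a sum of near-Gaussian terms and suffers the
same dilution. Fisher's classical statistic keeps only 2 df per study,
leaving each transform strongly right-skewed: a single very small p-value
dominates the sum, which is what makes Fisher robust to dilution. The two
methods implemented here keep that robustness while adding sample-size
weighting (wFisher) or adaptivity (ordmeta).

## The combiners

**Fisher.** $T = -2\sum_i \log p_i \sim \chi^2(2n)$; combined p-value is
the upper tail at the observed $T$.

**Stouffer / weighted Z.** $Z = \sum_i w_i \Phi^{-1}(1-p_i) /
\sqrt{\sum_i w_i^2}$ with $w_i = 1$ (Stouffer) or $w_i = \sqrt{s_i}$
(weighted Z). The literature the sample-size weighting comes from does not
pin down a unique normalisation; $w_i=\sqrt{s_i}$ with the root-sum-square
denominator is the standard choice and is configurable via the `weights`
argument.

**Lancaster.** Each $p_i$ is mapped to the $\chi^2(s_i)$ value whose
upper-tail probability is $p_i$; the sum is referred to $\chi^2(\sum s_i)$.
Non-integer df requests are routed through the equivalent gamma(df/2,
scale 2) machinery rather than rounded.

**wFisher.** Each $p_i$ is mapped to the gamma(shape $k_i$, scale 2) value
whose upper-tail probability is $p_i$, with

$$k_i = n\,s_i / S, \qquad S = \sum_j s_j,$$

so $\sum_i k_i = n$: the weights live in the degrees of freedom, but the
*total* df stays at $2n$ exactly as in Fisher's method. The summed
statistic is referred to the upper tail of gamma($n$, scale 2)
$\equiv \chi^2(2n)$. With equal sample sizes every $k_i = 1$ and wFisher
*is* Fisher — the test suite verifies agreement to $10^{-12}$.

*A note on tail conventions.* Writing the transform with lower-tail
quantiles and a left-tail combined probability (as one sometimes sees) is
not equivalent: it is anti-monotone in the evidence and does not reduce to
Fisher under equal weights. We use the upper-tail convention throughout,
which is the unique choice with the Fisher-reduction property; it also
reproduces the published worked examples this package is tested against.

**roP and ordmeta.** For $n$ uniform p-values the $r$-th smallest follows
Beta($r$, $n-r+1$), so each rank has a marginal probability
$F_{(r)}(p_{(r)})$. The $r$-th ordered p-value method (roP) uses one fixed,
pre-chosen rank — powerful if you happen to know how many studies are
associated, fragile otherwise. ordmeta removes the choice: its statistic is
the *minimum* marginal

$$X = \min_{1\le r\le n} F_{(r)}(p_{(r)}),$$

and its p-value is the exact null probability $P(X \le x)$ under the joint
distribution of uniform order statistics. Ordered p-values above the
optimal rank $r^*$ (the arg-min) never enter the statistic — appending
large p0-values perturbs the result only through $n$ — and $r^*$ itself is
an estimate of how many studies are associated: `predict_associated()`
flags the $r^*$ smallest inputs.

### Computing $P(X \le x)$ exactly

Inverting each marginal at the common level $x$ gives thresholds
$c_r = F_{(r)}^{-1}(x)$, non-decreasing in $r$, and

$$P(X \le x) = P(\exists r:\; p_{(r)} \le c_r),$$

a boundary-crossing probability for the empirical process of $n$ uniforms.
Rather than evaluating the $n$-fold nested integral for the survival side
and subtracting from 1 (catastrophic when the answer is tiny), we compute
the crossing probability directly with the classical first-crossing
recursion

$$h_r = c_r^{\,r} - \sum_{j<r} \binom{r}{j} h_j\,(c_r - c_j)^{\,r-j},
\qquad
P = \sum_{r=1}^{n} \binom{n}{r} h_r (1-c_r)^{\,n-r},$$

an $O(n^2)$ computation. Two properties make it numerically benign here:
every subtracted term is strictly smaller than the leading one when the
bounds come from a common marginal level, and all additions are of
positive terms, so no step cancels digits catastrophically. We validated
double-precision evaluation against an 80-digit reference implementation
of the same recursion across $n \le 100$ and levels from $10^{-300}$ to
0.99 during development; the shipped tests enforce agreement with an
independent nested-integral quadrature oracle for $n \le 4$ (relative
$10^{-8}$) and with $10^7$-draw Monte Carlo at $n = 8$ and $30$.

Numerical details worth knowing:

* marginals are computed with `pbeta(..., log.p = TRUE)`, so the minimum
  marginal is meaningful down to $10^{-300}$ and far beyond in log space;
* thresholds come from `qbeta`, round-trip-checked to a relative
  $10^{-10}$ and polished with one log-space Newton step if needed;
* below $x = 10^{-300}$ the thresholds for ranks $> 1$ are no longer
  representable, and the intersection terms of the union are negligible:
  the code switches to $P \approx n x$ (relative error $O(x^{1/n})$,
  i.e. $\le 10^{-3}$ even at $n = 100$), carried in log space;
* a combined p-value that underflows double precision entirely is
  reported as 0 with the log10 value and a formatted string in
  `p_high_precision` — this is how loci whose evidence is overwhelming
  are reported exactly rather than as an artifact of `1 - (1 - x)`
  rounding;
* ties at the arg-min resolve to the smallest rank: deterministic, and
  the sparsest explanation of the association;
* the recursion uses `choose(n, r)`, which overflows double precision
  near $n \approx 1000$; the implementation is validated for the
  $n \le 100$ range the benchmarks use.

### Two-tailed inputs

When studies report two-tailed p-values with effect directions, each
$p_i$ becomes $p_i/2$ if the study's effect points in the candidate
direction and $1 - p_i/2$ otherwise; the combiner runs on these
synchronised one-tailed values and again on their complements, and the
final p-value is $\min(1,\, 2\min(p_{\mathrm{up}}, p_{\mathrm{down}}))$.
Association summary tables sometimes ship the synchronised one-tailed
values directly; `combine_directional(..., synchronized = TRUE)` skips the
halving and runs both directions from the values as given.

## Worked example

```{r}
tab <- read_summary_table(system.file("extdata", "bmi_loci_synchronized.tsv",
                                      package = "metacomb"))
combine_table(tab, method = "ordmeta", synchronized = TRUE)
```

These are the synchronised per-cohort p-values of seven loci from a
published four-ancestry BMI exome association meta-analysis. Note
rs12243326: two cohorts are null (0.71, 0.39), yet the joint
order-statistic evidence of the two concordant $10^{-6}$-scale cohorts
(optimal order 2) yields a genome-wide significant combined value — the
incomplete-association signal the effect-size models miss. For
rs1558902/rs1421085 the exact combined values are of order $10^{-17}$;
implementations that form $1 - (1 - x)$ in double precision report them
as 0.

## Simulation benchmarks: what they emulate

**t-test design** (`ttest_sim_config`). Each associated study draws a
sample size uniformly from 30–2000 and a true mean uniformly from
0.03–0.1, samples that many standard-normal observations shifted by the
mean, and records the one-tailed one-sample t-test p-value (simulated
exactly through the sufficient statistics $\bar x \sim N(\mu, 1/s)$,
$(s-1)\hat\sigma^2 \sim \chi^2(s-1)$). Unassociated p-values are uniform
on one of [0, 1], [0.1, 1], [0.3, 1]. The source description of this
design says only that sizes are "sampled with sample sizes of 30–2000";
we read that as a uniform draw — a log-uniform reading gives a median
size near 245 and markedly weaker p1-values, inconsistent with the
operating characteristics reported for the design. The (size, mean) pairs
are drawn independently per study; the joint scheme is not specified at
the source and both ranges are configurable.

Type-I error is measured on shared Uniform(0,1) draws for all methods
(the exact null of a zero-effect one-tailed t-test), with equal sample
sizes handed to the weighted methods, under which every combiner here is
analytically exact; power is the fraction of replicates below 0.01.

**RNA-seq design** (`rnaseq_sim_config`). Twenty studies over 1000 genes
(the shipped acceptance run scales to 200 genes and 3 replicates to keep
the suite fast; the design is otherwise unchanged), of which 2, 5, or 10
are associated. Counts are negative binomial. The reference datasets the
original parameters were estimated from are not redistributable, so the
generator stands in with the same statistical structure: per-gene means
log-normal (meanlog 4, sdlog 1.5, i.e. median ≈ 55 counts with a long
right tail), dispersions following the decreasing trend
$0.15 + 2/\mu$ with Gamma(shape 10, mean 1) jitter (biological CV
≈ 0.4 for well-expressed genes), fold changes log-uniform on [1.3, 4]
with a random per-gene direction held consistent across associated
studies, and 10 samples per group. Per-study testing is a gene-wise Welch
t-test on $\log_2(\mathrm{CPM} + 0.5)$ — a deliberate, documented
stand-in for the moderated-t/voom pipeline: it preserves the contract
the combiners need (a calibrated two-tailed p and a sign per gene) without
empirical-Bayes shrinkage, so absolute per-study power is slightly lower
than a moderated analysis would give, while the *comparison between
combiners*, which all consume the same per-study p-values, is unaffected.
Effect-size baselines (inverse-variance fixed effects, DerSimonian–Laird
random effects) pool the per-gene log2 fold change and its Welch standard
error.

What these simulations do *not* emulate: between-study correlation
(all combiners assume independent studies; no Brown/Kost-type dependence
correction is provided), library-size imbalance, compositional
normalisation artifacts at extreme DE fractions, and annotation-level
noise. Passing the benchmarks therefore demonstrates calibration and the
robustness ordering under the stated generative model, not performance on
any particular real dataset.

## Input handling and other defaults

* p-values must lie in [0, 1]; exact 0 is clamped to $10^{-320}$ and
  values above $1 - 10^{-16}$ down to $1 - 10^{-16}$, with a warning —
  the quantile transforms diverge at the endpoints. All tail
  probabilities are computed via `log.p` so combined values remain
  meaningful down to the clamp floor.
* studies with missing p-values are dropped per feature and weights are
  renormalised over the survivors; at least one study must remain.
* wFisher shapes are floored at $10^{-4}$ (with a warning) when one
  study's sample size is a vanishing fraction of the total, where the
  gamma quantile transform degenerates.
* multiple testing across features uses Benjamini–Hochberg by default;
  Bonferroni is available where a family-wise threshold is conventional
  (association studies).
* the realised ("true") FDR of a significance call is only reported when
  at least five features are significant; below that the ratio is too
  unstable to interpret.
* summary tables are tab-delimited, wide (`p_<study>`, `sign_<study>`,
  `n_<study>`, `beta_<study>`, `se_<study>`) or long
  (`feature`/`study`/`p`/…), and the parser accepts scientific notation
  with either an ASCII or a Unicode minus sign, as printed association
  tables often use the latter.

## Known limitations

* Independence between studies is assumed everywhere.
* The crossing recursion is validated for $n \le 100$ combined p-values;
  it is $O(n^2)$ and binomial-coefficient-limited well before
  $n = 1000$.
* The predicted-associated mask is a by-product of the optimal order,
  not a calibrated classifier: in half-associated designs its
  specificity is near 1 while its sensitivity sits near or below one
  half, decreasing with the number of inputs, because the optimal order
  stops at the point where joint evidence is strongest rather than at
  the true number of associated studies.
* Power and AUC orderings quoted for the benchmarks are properties of
  the stated generative designs; with other effect-size distributions
  the ordering between the weighted and unweighted methods can change.
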