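---
title: "Genotype-phenotype networks for multi-trait association: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-phenotype networks for multi-trait association: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpnet)
```

## The problem

Biobank cohorts carry hundreds of related diagnoses per participant, most
of them binary with very few cases: case-control ratios of 1:1500 to 1:25
are typical for ICD-derived disease codes. Testing one trait at a time
wastes the shared genetic signal across related diseases, while joint tests
over all traits dilute signals that are confined to a genetically coherent
subset. `gpnet` takes a middle route: learn which phenotypes share genetic
architecture, partition them into modules, and test SNP association within
modules.

## The signed bipartite network

For trait $k$ and SNP $m$ (minor-allele counts $g_{im}$, traits and
genotypes residualized on covariates), the score statistic is

$$S_{km} = \sum_{i=1}^n (y_{ik} - \bar y_k)\, g_{im}, \qquad
\sigma^2_{km} = \frac{1}{n}\sum_i (y_{ik}-\bar y_k)^2 \sum_i (g_{im}-\bar g_m)^2 .$$

For quantitative traits, $z = S/\sigma$ is exactly $\sqrt n$ times the
Pearson correlation, and a two-sided normal p-value applies. For binary
traits with unbalanced case-control ratios the normal approximation is
anti-conservative in the far tail, so the tail probability of $S = \sum_i
g_i (y_i - \mu_i)$ is computed from its cumulant generating function

$$K(t) = \sum_i \log\!\big(1 - \mu_i + \mu_i e^{g_i t}\big) - t \sum_i g_i \mu_i$$

by the Barndorff-Nielsen saddlepoint formula, with the null case
probabilities $\mu_i$ from a logistic regression of the trait on the
covariates (the trait mean when there are none). A hybrid rule uses the
normal p-value when $|z| < 2$, where the two agree, and the saddlepoint
otherwise; both tails are evaluated at their own saddlepoints since the
null distribution is asymmetric. Unit tests compare the saddlepoint tail
with exhaustive enumeration of all $2^n$ outcome vectors at $n \le 12$.

The network edge weight is the signed association strength

$$T_{km} = \mathrm{sign}(S_{km})\; F^{-1}_{\chi^2_1}(1 - p_{km}),$$

computed on the upper tail directly so p-values down to $10^{-320}$ map to
finite weights. A positive weight means the minor allele is protective for
the trait. The same transform applied to a table of (direction, p-value)
pairs builds the network from GWAS summary statistics without
individual-level genotypes.

The phenotype-phenotype network is the one-mode projection
$W_{kl} = \mathrm{cor}(T_{k\cdot}, T_{l\cdot})$ across the $M$ SNPs - a
signed genetic-correlation matrix in $[-1, 1]$.

## Module detection

Phenotypes are clustered by Ward linkage (`ward.D2`) on the dissimilarity
$1 - W$, chosen so anti-correlated traits are maximally distant; the
variant and transform are the package's choices among several defensible
ones. The number of modules comes from a perturbation procedure: add
i.i.d. Gaussian noise with variance $\sigma^2 = \mathrm{median}_m\,
\mathrm{var}(T_{\cdot m})$ to every entry of $T$, re-cluster each of $B$
perturbed datasets, and for each candidate count $k_0$ compare the average
perturbed co-membership matrix $A_{k_0}$ with the unperturbed one
$C_{k_0}$ through $D_{k_0} = |A_{k_0} - C_{k_0}|$. The stability score
$AF_{k_0}$ is the area under the empirical CDF of the $K^2$ entries of
$D_{k_0}$, computed by the exact identity $AF = 1 - \mathrm{mean}(D)$. The
chosen count is the first $k$ maximizing $|AF_{k+1} - AF_k|$ - on planted
data the stability curve stays near 1 up to the true count and drops just
past it, so the largest jump sits at the true count.

Two perturbation-clustering modes are provided. Re-projecting each
perturbed matrix and clustering $1 - W^{(b)}$ turns out to be almost
non-discriminating: entrywise noise shrinks all pairwise correlations by
nearly the same factor, Ward's merge order barely changes, and the
stability curve saturates near 1 for every $k_0$. The default therefore
clusters the perturbed rows of $T$ directly on Euclidean distance, which
destabilizes exactly those splits that are at noise level while leaving
genuinely separated modules stable. `cluster_on = "projection"` switches
to the other mode.

One caveat the package's recovery experiments make explicit: when planted
modules are exchangeable (equal size, equal pairwise separation), every
coarse cut of the dendrogram is ambiguous - splitting $C$ identical blocks
into 2 groups has many equally good solutions - so the stability curve
drops immediately and the selection returns 1. This is a property of the
selection rule on symmetric inputs, not an implementation artifact. The
recovery experiments therefore plant categories with a hierarchical
sharing structure (`planted_category_effects()`): causal-SNP blocks shared
across categories according to a random ultrametric tree with pairwise
similarities in roughly [0.1, 0.6], giving a unique stable partition at
every level up to $C$. Under those conditions (N = 1000, 8 traits per
category, M = 2000, $\beta$ = 0.5, B = 100) the modal selected count over
20 seeds equals the planted $C$ for $C$ = 3, 5 and 8.

## Module-wise association tests

Per SNP, each trait contributes a signed z-score: $S/\sigma$ for
quantitative traits, and $\mathrm{sign}(S)\,\Phi^{-1}(1-p/2)$ with the
saddlepoint p-value for binary traits, so the z-scores inherit the tail
calibration. Under the no-association null the z-scores across traits are
correlated like the trait residuals; $R$ is estimated once per module from
the residual correlations (it does not depend on the SNP under the null)
and eigenvalue-floored at $10^{-6}$.

With $z$ the module's z-vector and $U$ a cluster-indicator matrix:

* O'Brien: $1'R^{-1}z / \sqrt{1'R^{-1}1}$, standard normal;
* Omnibus: $z'R^{-1}z \sim \chi^2_{K'}$;
* CLC: $(U'R^{-1}z)'(U'R^{-1}U)^{-1}(U'R^{-1}z) \sim \chi^2_L$, with
  $U = I$ recovering Omnibus and $L = 1$ the squared O'Brien statistic
  (both identities tested to $10^{-12}$);
* ceCLC: CLC at every level $L = 1..K'$ of a Ward dendrogram on $1 - R$,
  combined by the Cauchy combination
  $p = 1/2 - \arctan\!\big(\mathrm{mean}\,\tan((1/2 - p_L)\pi)\big)/\pi$,
  valid under arbitrary dependence;
* HCLC: the same combination over the merge levels $L = 2..K'$. The exact
  published constructions of ceCLC/HCLC live in sources not bundled here;
  these definitions are documented reconstructions that keep the defining
  ingredients (CLC quadratic forms along a trait dendrogram, Cauchy
  aggregation) and are validated by their null calibration rather than by
  formula identity;
* MultiPhen: proportional-odds regression of genotype on the traits,
  likelihood-ratio $\chi^2_{K'}$. Included for comparison only - with
  sparse cases its asymptotics fail and the far tail inflates, which the
  calibration experiment reproduces.

When CLC needs a cluster count and none is given, it uses the largest
relative gap between consecutive Ward merge heights - a deterministic,
documented default.

In NET mode the chosen test runs inside each of the $C$ detected modules
and the module p-values combine by Bonferroni,
$p = \min(1,\, C \min_m p_m)$; N.O. mode tests all $K$ traits jointly.

## The simulator

Quantitative traits come from the factor model
$Y_c = G B_c + c_0 f_c 1_k' + \sqrt{1 - c_0^2}\, E_c$ per category $c$:
AR(1) errors ($\Sigma_{ij} = \rho^{|i-j|}$) within category and an
exchangeable factor correlation $\rho_f$ between categories. With
$\beta = 0$ the implied correlations are $c_0^2 + (1-c_0^2)\rho^{|i-j|}$
within and $c_0^2 \rho_f$ between. The defaults are the study conditions
used throughout: $c_0^2 = 0.5$, $\rho = 0.3$, $\rho_f = 0.3/c_0^2$, so
adjacent traits within a category correlate at 0.65 and categories at
0.30; M = 2000 SNPs with MAF ~ U(0.05, 0.5), genotypes Binomial(2, MAF)
under Hardy-Weinberg equilibrium, no linkage disequilibrium.

Six effect models use two row patterns on the $k$ traits of an affected
category - $\lambda^1 = \beta(1,\dots,1)'$ and $\lambda^2 =
\tfrac{2\beta}{k+1}(1,\dots,k)'$ - with 100 causal SNPs (models 1-4) or
200 (models 5-6): one affected category ($\lambda^1$/$\lambda^2$, models
1/2), two categories in the same/opposite directions (3/4), and the causal
set split across two categories (5/6). The mapping of patterns to models
is a documented reconstruction; the calibration and power-ordering
properties it feeds are insensitive to the exact assignment.

Binary traits come from a liability threshold: for ratio $r$ the top
$n_a = \mathrm{round}(rN/(r+1))$ liabilities are cases (round-half-even;
at $N = 322{,}607$ and $r = 0.000658$ this yields exactly 212 cases).
Mixture datasets dichotomize half the traits of each category at $r = 1$;
unbalanced-binary datasets dichotomize every trait at a ratio drawn from a
pool spanning [0.000658, 0.03937], the range observed for musculoskeletal
ICD codes in a large biobank. The full pool membership is not published,
so the default is five values spanning that range; at small N the pool is
restricted to ratios yielding at least 10 cases (5 in the MultiPhen
experiment, which targets exactly the sparse-case regime).

What the simulator does not emulate: linkage disequilibrium, relatedness,
population stratification, covariate effects, and real ICD co-occurrence
structure. Passing calibration here shows the statistics are sound under
the factor model's correlation structure, not that module detection
matches clinical taxonomy on real data.

## Evaluation harness and problem sizes

Type-I error counts every null SNP of every Monte-Carlo run as one
replicate and reports the estimated rate divided by the nominal level,
judged against the binomial band
$1 \pm 1.96\sqrt{(1-\alpha)/(\alpha n)}$ - at $10^6$ replicates (0.938,
1.062) for $\alpha = 10^{-3}$ and (0.804, 1.196) for $10^{-4}$. Power is
the fraction of causal SNPs passing the Bonferroni level $0.05/n_{causal}$.

The package's own experiments run at desk scale with the bands recomputed
for the replicate count used: calibration of ceCLC/CLC/HCLC/Omnibus (both
modes) on mixture phenotypes with K = 60, N = 2000 over 50 runs x 2000
SNPs = $10^5$ replicates at nominal 0.001; MultiPhen on unbalanced binary
traits (K = 30, N = 1000, 4 x 1200 = 4800 replicates); power ordering of
NET vs N.O. for ceCLC on all six models at $\beta = 0.3$, the value where
power sits mid-curve (0.2-0.5) for every model under these conditions,
10 runs each. One caveat surfaced by this experiment: under
same-direction cross-category effects (model 3) at lower $\beta$ the
level-adaptive ceCLC already pools the affected categories in N.O. mode,
and the Bonferroni factor across modules can cost more than module
restriction gains, so the NET advantage for ceCLC is a mid-to-high-power
phenomenon there rather than universal. Full-scale reference values (the $10^6$
replicate bands) are reproduced analytically.

## Numerical choices and edge cases

* p-values clipped to $[10^{-320}, 1]$; the $\chi^2_1$ transform uses the
  upper-tail quantile on $p$ directly, never $1 - p$.
* Degenerate score inputs (constant trait or genotype) return $S = 0$,
  $p = 1$ and are logged, not raised.
* Saddlepoint root-finding is a vectorized Newton iteration confined to
  the overflow-safe range $|g t| \le 700$, with a bracketed-root fallback
  per SNP and a normal-approximation fallback (with warning) if both fail.
* Zero-variance SNP columns give zero-weight edges with a warning;
  constant network rows project to zero correlation.
* Missing genotypes are mean-imputed per SNP at analysis time; raw reads
  keep `NA`.
* Cauchy combination inputs are clipped to $[10^{-15}, 1-10^{-15}]$.
* Ties in the module-count rule resolve to the smallest count; `hclust`
  leaf order makes linkage tie-breaks deterministic.
* All generators are deterministic given (config, seed); Monte-Carlo run
  $r$ reseeds with `seed + r`.
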