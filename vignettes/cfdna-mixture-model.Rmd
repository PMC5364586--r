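---
title: "A beta-mixture model for ctDNA burden and tissue-of-origin inference"
author: "cfMethMix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A beta-mixture model for ctDNA burden and tissue-of-origin inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plasma cell-free DNA (cfDNA) of a cancer patient is a mixture: most
fragments come from normal hematopoietic turnover, a fraction
$\theta$ — the circulating-tumor-DNA (ctDNA) burden — from the tumor.
Because tumors carry tissue- and cancer-specific DNA methylation
(promoter hypermethylation, global hypomethylation), a genome-wide
bisulfite methylation profile of plasma carries information about both
*how much* tumor DNA is present and *where* it came from.  cfMethMix
models this explicitly and answers both questions at once, instead of
treating plasma profiles as i.i.d. draws from per-cancer classes the way
generic multi-class classifiers do — which is exactly why those
classifiers collapse at low burden while a mixture model does not.

## Features: CpG clusters

Array-based references measure single CpG sites, while low-pass
whole-genome bisulfite sequencing (WGBS) of plasma yields only a few
reads per site.  The unit feature is therefore a *CpG cluster*: probed
sites are extended by a flanking region (default ±100 bp) and merged
transitively wherever the flanks overlap; clusters keeping at least
three probed sites survive (`build_clusters()`).  Cluster-level
methylation is the mean of its site levels for array data (`NA` when
more than half of the sites are missing — with an even site count,
exactly half missing still yields a value, a deliberate strict reading
of "more than half") and the methylated/total cytosine ratio for
sequencing data (`NA` below 30 total cytosines).  Coordinates are
0-based half-open throughout; 1-based input must be shifted by the
caller.  A third conceivable grouping criterion (staying within one
CpG-island/shore annotation) needs an external annotation that the
method itself does not supply, so clustering here uses only the
flank-overlap and minimum-probe rules.

## The reference panel

For every cluster $k$ and class $t$ (normal plasma $t=0$, tumor types
$t=1..T$), the methylation level across reference individuals is modeled
as $\mathrm{Beta}(\alpha_{kt}, \beta_{kt})$, fitted by the method of
moments: with sample mean $\mu$ and variance $\sigma^2$,
$c = \mu(1-\mu)/\sigma^2 - 1$, $\alpha = \mu c$, $\beta = (1-\mu)c$.
Degenerate clusters are regularized so parameters stay finite and
positive: levels clamped to $[10^{-6}, 1-10^{-6}]$, variance floored at
$10^{-6}$ and capped at $0.999\,\mu(1-\mu)$.  A class fit needs at least
5 usable samples; moment estimates from fewer points are meaningless.

Features are selected by the methylation range (MR): the spread
(max − min) of the per-class mean levels, computed on the same training
samples used for fitting.  The default cutoff is MR ≥ 0.25, boundary
inclusive.

## The mixture likelihood

For a test plasma sample, cluster $k$'s level is
$x_k = (1-\theta)v_k + \theta u_k$ with $v_k \sim
\mathrm{Beta}(\alpha_{k0},\beta_{k0})$ and $u_k \sim
\mathrm{Beta}(\alpha_{kt},\beta_{kt})$, so $x_k$ follows the convolution
density $\psi(x \mid \theta, t)$.  Sequencing observes counts, not
levels: $m_k \sim \mathrm{Binomial}(n_k, x_k)$, giving the per-cluster
marginal

$$ f(m_k \mid \theta, t, n_k) = \int_0^1 \binom{n_k}{m_k}
   x^{m_k}(1-x)^{n_k-m_k}\, \psi(x \mid \theta, t)\, dx , $$

and, under feature independence,
$\log L(\theta, t) = \sum_k \log f(m_k \mid \theta, t, n_k)$.
$(\hat\theta, \hat t)$ is the argmax over the grid
$\Theta = \{0, 1/J, \dots, (J-1)/J\}$ crossed with the $T$ tumor
classes.  The cancer call uses the per-feature likelihood gain

$$ \lambda = \frac{1}{K_{\mathrm{used}}}\bigl[\log L(\hat\theta,\hat t)
   - \log L(\theta = 0)\bigr] \ge 0 , $$

with $\lambda > 0.023$ by default calling cancer.  The threshold is
advisory — the appropriate value is cohort-dependent — and is an exposed
parameter.  $K_{\mathrm{used}}$ counts clusters with
$n_k \ge 1$: the binomial marginal is defined for any positive coverage,
and low-pass data motivate using every read (the 30-cytosine floor
applies to *reporting* a methylation level, not to the likelihood).
Clusters with $n_k = 0$ contribute nothing and are excluded from
$K_{\mathrm{used}}$.  Ties in the argmax resolve to the smallest
$\theta$, then the first class — deterministic and conservative toward
non-cancer — and the tie count is reported.

## Numerical evaluation

Two implementations coexist deliberately:

* **Reference path** (`psi_density()`, `cluster_loglik()`,
  `total_loglik()`): pointwise quadrature in R.  The inner integral runs
  over the sub-interval of $u$ where $(x-\theta u)/(1-\theta) \in
  [0,1]$ — the support constraint of the convolution.  The default
  integrator is adaptive Gauss–Kronrod (`stats::integrate`), because
  beta densities with $\alpha < 1$ or $\beta < 1$ are endpoint-singular
  and a fixed-node Simpson rule cannot hold the $10^{-3}$ normalization
  everywhere; composite Simpson (201 nodes, $10^{-6}$ endpoint clipping)
  remains available via `method = "simpson"`.
* **Production path** (`predict_burden()`, `grid_mle()`, compiled):
  an exact-cell-mass discretization.  The distributions of
  $(1-\theta)v$ and $\theta u$ are reduced to cell masses on a uniform
  grid of width $1/G$ (default $G = 200$) using the incomplete beta
  function, so singular densities are integrated exactly; the mass
  vector of $x$ is their discrete convolution (support
  $[0,1]$, boundary spill folded back so every $\psi$ keeps total mass
  exactly 1); and $f(m \mid \theta,t,n)$ is the mass-weighted binomial
  pmf at the cell centers, evaluated for all samples at once as one
  matrix product per cluster.  Cell-center evaluation is accurate while
  the binomial scale $\sqrt{x(1-x)/n}$ stays well above $1/G$, i.e. for
  coverages up to a few thousand cytosines per cluster at the default
  $G$; $G$ is a parameter.  This is what makes a grid search over
  $K \approx 1500$ features, $J = 100$, $T = 5$ and thousands of samples
  run in about a minute on one core (the engine is single-threaded, so
  results are trivially independent of thread count).

The two paths are cross-checked against each other and against
Monte-Carlo oracles — including endpoint-singular regimes — in the test
suite.  A likelihood floor of $10^{-300}$ per cluster prevents `-Inf`
under extreme count/model mismatch.

## The simulator

A simulated cancer plasma sample follows the generative model plus two
realism terms, copy number and read-depth bias:

1. $\theta \sim U(\theta_L, \theta_U)$;
2. per-cluster copy number $c_k \sim \mathrm{Cat}(p_0..p_5)$, with
   $\sum p_c = 1$, $\sum c\,p_c = 2$ and extreme events rare; the
   default $(0.005, 0.16, 0.7, 0.105, 0.025, 0.005)$ puts 30%
   probability on $c_k \ne 2$.  Other CNA rates rescale the non-diploid
   part of this vector (its conditional mean is exactly 2, so both
   moment constraints survive rescaling);
3. one normal-plasma and one tumor profile drawn uniformly from the
   held-out pools;
4. local burden $\theta'_k = \theta c_k / (\theta c_k + 2(1-\theta))$
   and level $x_k = (1-\theta'_k)v_k + \theta'_k u_k$;
5. coverage $n_k \sim \mathrm{Poisson}(Z B_k)$ with
   $B_k \propto b_k (1 - \theta + \theta c_k/2)$ renormalized, where
   $b_k$ is the background alignment bias; by default
   $b_k \propto$ the cluster's probed-site count (CpG-dense clusters
   attract more reads), optionally Dirichlet-perturbed;
6. $m_k \sim \mathrm{Binomial}(n_k, x_k)$.

Normal plasma samples mix two distinct normal-pool profiles at a ratio
$r \sim U(0,1)$ (uniform being the uninformative choice) with all copy numbers fixed at 2.  Clusters whose
drawn profile level is `NA` are dropped from the sample and recorded.
Each cohort draws from one seeded stream with a fixed call order, which
makes scenarios bit-reproducible.

**Total cytosine budget.**  The default is `coverage = 150` cytosines
per cluster ($Z = 150K$).  Rationale: public plasma
WGBS references are typically ~4× depth, and a cluster spans several hundred bases of CpG-dense
sequence containing on the order of 20 CpG dinucleotides — roughly 40
cytosine positions counting both strands — so ~150 cytosine
observations per cluster is the conservative end of that regime.  A
reading of "4× coverage" as 4 cytosines *per cluster* is inconsistent
with the method's own 30-cytosine usability floor, which would then
discard essentially every cluster.

## The synthetic reference

`generate_reference()` stands in for array-based tumor/plasma reference
pools; it is synthetic by construction and labeled as such.  Each of
`K_total` clusters gets a baseline mean; an informative fraction
(default 0.75) has exactly one *deviant* class whose mean is offset by
`separation` (default 0.5), the direction drawn first and the baseline
then drawn inside that direction's feasible interval, so the true MR of
an informative cluster equals `separation` exactly.  Per-cluster,
per-class precision $\alpha+\beta \sim U(20, 200)$ spans tight
tissue-specific and noisy clusters.  The deviant class is the normal
class with probability 0.5 (otherwise a uniformly chosen tumor class):
real MR-selected features are dominated by a shared tumor-versus-plasma
axis — global hypomethylation and recurrent promoter hypermethylation
common to many cancers — and a uniform deviant choice would leave only
about a third of selected features informative for any one tumor class,
visibly weaker than what realistic references support.  The weight is a
parameter (`p_deviant_normal`), so the uniform scheme is one argument
away.

What the generator does **not** emulate: inter-cluster correlation,
batch and probe artifacts, subclonal heterogeneity, fragment-length and
nucleosome signals.  Tests passing on these pools therefore demonstrate
correctness of the *method* under its own model assumptions plus CNA
and coverage bias — not performance on real plasma.

## Evaluation protocol

`run_experiment()` runs the standard protocol: per run, pools are
split 75%/25% per class ( training fits the panel, the held-out quarter
feeds the simulator), cancer profiles are simulated per burden decade
bin $(\theta, \theta+10\%]$ (left-open/right-closed) plus normal
profiles, every profile is predicted, and predictions are pooled across
the default ten runs into a single confusion matrix; the error rate is
the fraction of misclassified samples among normal + $T$ tumor classes.
Fresh normal profiles are simulated for every bin rather than reusing
one normal set across bins — it matches the per-bin protocol literally
and keeps bins independent.  Burden recovery is summarized by Pearson
correlation and RMSE over the cancer samples.  Baselines plug in
through the `predictor` argument; the package ships a uniform
random-guess stub and a nearest-mean classifier only.

**Problem sizes.**  The shipped acceptance analysis
(`scripts/acceptance.R`) uses 5 tumor classes + normal, 2000 clusters
(~1500 selected), pools of 80 samples per class, and one
partition/fit/simulate pass: 500 cancer profiles with
$\theta \sim U(0,1)$ for burden recovery, 200 normals, 50 samples per
class in each of the two lowest bins, and 20 per class per bin over all
ten bins, all inferred in a single batched pass at $J = 100$.  The test
suite exercises the same pipeline at these and smaller sizes.  These
are the package's chosen desk-scale study conditions; a TCGA-scale
analysis would instead use hundreds of samples per class and on the
order of 14k selected features.

## Known limitations

* At most one tumor component per sample; no co-occurring cancers.
* Point estimates only; no posterior uncertainty on $\theta$.
* Feature independence is assumed by the likelihood; correlated
  clusters make $\lambda$ overconfident.
* The $\lambda$ threshold is data-set dependent; 0.023 is a default,
  not a calibration.
* Markers selected against normal plasma may be tissue-specific rather
  than tumor-specific; paired tumor/adjacent-normal refinement is out
  of scope.
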