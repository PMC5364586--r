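# cfMethMix

Joint inference of circulating tumor DNA (ctDNA) burden and tissue of
origin from plasma cell-free DNA (cfDNA) methylation profiles.

## The problem

The cfDNA in a cancer patient's plasma is a mixture of DNA shed by
normal cells and by the tumor.  Hyper-/hypomethylated tumor fragments
make genome-wide bisulfite methylation a readout for non-invasive
cancer screening — but a useful liquid-biopsy test must do two things at
once: decide whether tumor DNA is present, and say which organ it came
from.  Generic multi-class classifiers trained on tumor tissue fail at
this precisely because a plasma profile is *not* a tumor profile; at
tumor fractions below ~50% they cannot beat random guessing.
cfMethMix is for computational biologists who want the mixture treated
as a mixture: it models the plasma profile as a convex combination of a
normal-plasma component and (optionally) one solid-tumor component, and
estimates the mixing fraction and the tumor class jointly by maximum
likelihood.

## The model

Features are CpG clusters (nearby probed CpG sites merged by
±100 bp flank overlap, ≥ 3 probes).  For cluster *k* and class *t*
(normal plasma *t* = 0, tumor types *t* = 1..*T*), reference methylation
levels follow Beta(α<sub>kt</sub>, β<sub>kt</sub>), fitted by the
method of moments; features are kept when their methylation range (the
spread of per-class mean levels) is at least 0.25.  A test sample's
level at cluster *k* is

&nbsp;&nbsp;&nbsp;&nbsp;x<sub>k</sub> = (1 − θ)·v<sub>k</sub> + θ·u<sub>k</sub>,&nbsp;&nbsp;
v<sub>k</sub> ~ Beta(α<sub>k0</sub>, β<sub>k0</sub>),&nbsp;
u<sub>k</sub> ~ Beta(α<sub>kt</sub>, β<sub>kt</sub>),

so x<sub>k</sub> follows the convolution density ψ(x | θ, t).
Sequencing observes counts, m<sub>k</sub> ~ Binomial(n<sub>k</sub>,
x<sub>k</sub>), giving the marginal
f(m<sub>k</sub> | θ, t, n<sub>k</sub>) = ∫ Binom(m<sub>k</sub> |
n<sub>k</sub>, x) ψ(x | θ, t) dx and, under feature independence, the
log-likelihood Σ<sub>k</sub> log f(m<sub>k</sub> | θ, t, n<sub>k</sub>).
A grid search over θ ∈ {0, 1/J, …, (J−1)/J} × classes yields
(θ̂, t̂), and the per-feature likelihood gain

&nbsp;&nbsp;&nbsp;&nbsp;λ = [log L(θ̂, t̂) − log L(θ = 0)] / K<sub>used</sub>

calls cancer when λ > 0.023 (an advisory default).  The package also
ships the full copy-number-aware plasma simulator (categorical copy
numbers with mean 2, dosage-adjusted burden θ′ and read bias
B<sub>k</sub>, Poisson coverage, binomial counts), a synthetic
reference-pool generator, and the 75/25 multi-run evaluation harness.

## Worked example

Build a synthetic reference, fit a panel, simulate one plasma sample at
15% colon-tumor burden, and infer:

```r
library(cfMethMix)

ref   <- generate_reference(T_classes = 3, K_total = 600,
                            pool_size = 40, seed = 42)
panel <- build_panel(ref$levels, ref$manifest, ref$clusters)
panel
#> Reference methylation panel
#>   classes:   normal, breast, colon, kidney
#>   clusters: 600 total, 450 selected (MR >= 0.25)

sel   <- panel$selected
pools <- lapply(setNames(panel$class_names[-1], panel$class_names[-1]),
                function(cl) ref$levels[sel,
                  ref$manifest$sample_id[ref$manifest$class_label == cl]])
norm  <- ref$levels[sel,
           ref$manifest$sample_id[ref$manifest$class_label == "normal"]]
scen  <- sim_scenario(norm, pools, ref$clusters, coverage = 150,
                      theta_range = c(0.15, 0.15))
set.seed(7)
sim <- simulate_cancer_plasma(scen, "colon")
grid_mle(sim$profile, panel)
#> ctDNA mixture fit
#>   theta_hat: 0.140
#>   t_hat:     colon
#>   lambda:    0.6786 (threshold 0.023)
#>   call:      cancer  [K_used = 450]

grid_mle(simulate_normal_plasma(scen)$profile, panel)
#> ctDNA mixture fit
#>   theta_hat: 0.000
#>   t_hat:     -
#>   lambda:    0.0000 (threshold 0.023)
#>   call:      non-cancer  [K_used = 450]
```

The tumor sample's burden is estimated at 0.14 (true value 0.15, grid
step 0.01), the class is recovered, and λ far exceeds the cancer
threshold; the normal-plasma sample lands exactly at θ̂ = 0 with λ = 0.

A command-line front end wrapping the same functions (subcommands
`build-clusters`, `make-synth-ref`, `build-panel`, `simulate`,
`predict`, `evaluate`) is installed as
`system.file("scripts", "cfmethmix", package = "cfMethMix")`.

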