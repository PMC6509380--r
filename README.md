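# barcodiv

How much do estimates of community phylogenetic diversity depend on *which*
DNA barcodes a community phylogeny was built from, and on whether a
family-level backbone constrained that phylogeny? `barcodiv` is an R package
plus a staged analysis that answers this question with a multi-model
mixed-effects design. It is aimed at community ecologists and barcoding
practitioners who compute diversity metrics from barcode phylogenies and
want to know how sensitive their estimates are to those construction
choices.

## What it computes

The design crosses seven barcode supermatrices — rbcL+matK, rbcL+ITS,
rbcL+ITS2, matK+ITS, matK+ITS2, rbcL+matK+ITS, rbcL+matK+ITS2 — with the
presence/absence of a family-level backbone constraint, giving fourteen
sets of candidate tree topologies. The pipeline then:

1. **Selects topologies.** Unconstrained sets are ranked by Robinson–Foulds
   (symmetric) distance to the family backbone — species trees are first
   condensed to one exemplar tip per family — and the top *k* (default 500)
   are kept; constrained sets, which match the backbone exactly, get a
   random sample of *k*. Clade frequencies across each selected set
   estimate node support.
2. **Smooths to relative time.** Each selected tree is made ultrametric by
   penalized rate smoothing: minimize
   `Σ_e (b_e − r_e d_e)² + λ Σ (r_e − r_child(e))²`
   over node ages and per-branch rates (branch length `b`, rate `r`,
   duration `d`), with λ = 1000 and root age normalized to 1.
3. **Measures diversity per plot and tree.** Seven metrics: Faith's PD
   (root-inclusive), MPD and MNTD with and without abundance weighting
   (`MPD_ed`, `MNTD_ed`), phylogenetic-abundance evenness
   `PAE = [PD + Σ T_i(n_i−1)] / [PD + (N/S−1) Σ T_i]`, and the imbalance of
   abundances at higher clades `IAC = Σ|n_i − n̂_i| / v`, where `n̂_i` splits
   the community total equally among daughter lineages at every node and
   `v` counts the branching nodes of the community subtree.
4. **Attributes the variance.** For each metric it fits all 24 mixed models
   `log(diversity) = α + δ_plot + rbcL·β1 + matK·β2 + (ITS|ITS2)·β3 +
   backbone·β4` (plot as a random intercept, ML), ranks them by AICc,
   reports Akaike weights and marginal/conditional R² (Nakagawa), averages
   the standardized coefficients β/SE across models with per-term
   renormalized weights, and bootstraps the whole procedure (100
   replicates, stratified within condition × plot) for 95% intervals and a
   rank-stability estimate.

Because the empirical sequence data behind such studies are rarely
released, the package ships a first-class synthetic generator: a unit-height
Yule species tree, family clades cut from it, per-condition posterior-like
topology sets (Poisson-intensity NNI perturbation plus lognormal
branch-length jitter, with backbone conditions constrained to preserve
family structure), and a two-plot community (defaults: 114 species, plot
richnesses 75 and 73 sharing 34).

## Worked example

```r
library(barcodiv)

cfg <- run_config(
  synth = synth_config(n_species = 16, richness = c(11, 10), shared = 5,
                       n_families = 5, trees_per_condition = 8,
                       n_candidates = 16),
  topk = 8, bootstrap_B = 20, metrics = c("PD", "MPD"), seed = 42)
res <- run_all(cfg)

res$comparisons$PD
#> model_comparison: 24 models; top: ~B (wAICc = 0.213 )
#>    model      AICc    dAICc      wAICc      Rm2      Rc2
#>       ~B -416.9584 0.000000 0.21296262 2.908984 8.942397
#>   ~B + I -415.8703 1.088138 0.12359966 3.318140 9.355131
#>  ~B + I2 -415.8176 1.140857 0.12038416 3.296712 9.333497
#>   ~B + M -415.5268 1.431597 0.10409648 3.178443 9.214215
#>   ~B + R -414.8686 2.089823 0.07490385 2.910109 8.943542

res$bootstraps$PD$coefs
#>       term       mean         lo        hi
#> 1     rbcL -0.3779731 -1.5988392 0.9606152
#> 2     matK -0.7858865 -2.2472349 1.4848166
#> 3      ITS  0.9237435 -0.3394922 2.2090711
#> 4     ITS2 -0.9522677 -2.3232244 0.4376752
#> 5 backbone  2.6567381  1.9304836 3.7865857
```

Reading the output: model labels use B = backbone, M = matK, R = rbcL,
I = ITS, I2 = ITS2 (`~1` is intercept-only). Here — a small no-injected-
effect run — the backbone indicator tops the PD ranking but with a weak
weight (0.21) and little fixed-effect variance (Rm² ≈ 3%), and the
bootstrap intervals show backbone as the only term whose averaged
standardized coefficient excludes zero. With the default generator the
only systematic differences between conditions are topological (fewer
barcodes → noisier topology), so weak, mostly-backbone effects are the
expected answer.

The staged version of the same analysis lives in `analysis/01_simulate.R`
… `05_recovery.R`; each script reads its predecessor's files under
`results/analysis/` and prints what it found. `05_recovery.R` injects a
known ×1.5 ITS branch-length effect and confirms the inference recovers it
(20/20 seeds in the shipped configuration).

## Layout

- `R/` — package code: trees (I/O, RF ranking, clade support), smoothing,
  metrics, models, synthetic generator, pipeline.
- `analysis/` — numbered narrative drivers over the package.
- `tests/testthat/` — unit, property and acceptance suites with
  brute-force oracles.
- `vignettes/methods.Rmd` — the model, its assumptions, and every design
  decision with its rationale.
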