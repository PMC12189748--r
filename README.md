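# synexpr — graph-informed adversarial synthesis of gene expression

`synexpr` generates synthetic bulk gene-expression profiles with a
conditional Wasserstein GAN with gradient penalty (WGAN-GP) whose generator
performs **message passing over a prior gene graph** — a thresholded
co-expression network or a signed (activation +1 / repression −1)
regulatory network. It is aimed at computational biologists who need
realistic augmented expression data (scarce conditions, privacy-constrained
cohorts, imbalanced covariates) and want the synthetic samples to respect
known gene–gene dependencies rather than rediscover them from limited data.

## The model in brief

A latent draw **z** ~ N(0, I₆₄) is concatenated with embedded categorical
covariates **c** (one learned table per covariate; missing values are an
explicit `MISSING` class) and mapped to one initial scalar per gene node,

&nbsp;&nbsp;&nbsp;&nbsp;h⁽⁰⁾ = σ(W_I [z, c] + b_I),

which L = 4 rounds of message passing over the prior graph A refine:

* 1-hop (`graphconv`):
  hᵢ⁽ᵗ⁾ = σ(hᵢ⁽ᵗ⁻¹⁾W₁ + Σ_{j∈N(i)} A_{j,i} hⱼ⁽ᵗ⁻¹⁾W₂ + b)
* 1-hop/2-hop heterophily-aware (`h2gcn`): separate degree-normalized
  1-hop and exact-distance-2 aggregates, concatenated, with a readout over
  all intermediate representations — suited to signed regulatory priors
  where repression makes neighbours anti-similar.

An MLP critic (2 × 256 leaky-ReLU, unbounded score) is trained against the
generator on the WGAN-GP objective

&nbsp;&nbsp;&nbsp;&nbsp;E[D(x̂)] − E[D(x)] + λ E[(‖∇ₓ̃D(x̃)‖₂ − 1)²],  λ = 10,

with Adam (α = 10⁻⁴, β₁ = 0.5, β₂ = 0.9), batch 32. Baselines: fully
connected WGAN-GP and vanilla GAN, and a conditional VAE (1 × 256, latent
64). Everything — including the exact double-backprop of the gradient
penalty through the piecewise-linear critic — is implemented in plain R
matrix algebra and validated against finite differences; no deep-learning
framework is required.

The package also provides the surrounding toolchain: expression/covariate
TSV I/O, min–max and log2 z-score normalization, greedy-sample filtering,
co-expression and regulatory graph construction and interrogation (edge
homophily, exact 2-hop neighbourhoods, density), a seeded linear-SEM
simulator with planted regulatory graphs, and the full evaluation suite
(manifold precision/recall at t = 10, gene–gene correlation preservation,
detectability, train-on-synthetic-test-on-real utility, per-gene KS and
1-D Wasserstein statistics).

## Worked example

Train the graph-informed model on a simulated 50-gene, 500-sample cohort
with a planted signed regulatory network, then evaluate the synthetic
samples against the real ones:

```r
library(synexpr)

fx  <- make_fixture("small")          # 50 genes x 500 samples, planted GRN
fit <- train_wgan_gp(fx$Xn, fx$C, fx$graph,
                     generator_spec(50, "graphconv",
                                    output_activation = "sigmoid"),
                     train_config(epochs = 200, seed = 1))
gen <- generate_expression(fit, n = 500, seed = 1001)
rep <- evaluate_all(fx$Xn, gen$X, fx$C, gen$C, n_runs = 3,
                    classifiers = c("lr", "knn"), seed = 1)
print(rep)
#> <evaluation_report>
#>   precision 0.018  recall 0.964  correlation 0.937  WD2 0.0806
#>   detectability F1 [knn, full] 0.927
#>   detectability F1 [knn, pc] 0.927
#>   detectability F1 [lr, full] 0.872
#>   detectability F1 [lr, pc] 0.868
#>   TSTR [lr] balanced acc 0.645  macro F1 0.601
#>   TSTR [knn] balanced acc 0.340  macro F1 0.331
#>   KS: 44/50 genes with adjusted p < 0.05
```

Reading the numbers: **recall 0.964** — the synthetic cloud covers almost
the entire real manifold (no mode collapse; a collapsed generator scores
recall ≈ 0); **correlation 0.937** — pairwise gene–gene correlation
structure is largely preserved; **detectability F1 ≈ 0.87–0.93** — a
classifier still separates real from synthetic at this small training
budget (lower is better; 0.5 is indistinguishable); **WD2 0.08** — the
average per-gene marginal mismatch on the [0, 1] scale. `tidy(fit)` returns
the per-epoch loss history, `autoplot(fit)` plots it, and
`tidy(rep)`/`glance(rep)` give the metrics as tibbles.

## Acceptance script

`scripts/acceptance.R` re-runs the package's core pipeline from scratch —
simulate a fixture world, take its planted signed graph, train the
graph-informed conditional WGAN-GP, generate samples, and score them with
the full evaluation suite — and writes its (empty) machine-readable target
report to the path given by `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
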