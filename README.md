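# inducenet

Causal gene regulatory network inference from transcription-factor
induction timecourses.

## The problem

Inducing a single gene in a steady-state culture and tracking the whole
transcriptome over time turns each experiment into a causal cascade: the
induced regulator changes first, its direct targets next, indirect targets
later. A single experiment cannot tell a direct target from a correlated
bystander, but aggregating many experiments — each perturbing a different
regulator — can. `inducenet` is for computational biologists who want to
learn directed regulator–target networks from such perturbation
timecourses, and to test every analysis step against simulations with
known ground truth.

## What it computes

The core model predicts each target gene's rate of change as a sparse
linear combination of all genes' expression:

    Δln(y_ijt)/Δt = Σ_k α_ik (y_kjt − 1) + β_ik (y_ijt y_kjt − 1)/y_ijt

with relative expression y = 1 for every gene at t = 0 (so the predicted
rate at induction time is structurally zero), L1 (LASSO) shrinkage on the
coefficients, and per-target penalty selection by BIC or by
leave-one-experiment-out cross-validation. Around the model sit:

* a **simulator** (ground-truth networks, forced ~50-fold induction
  profiles, RK4 dynamics in log space, log-normal gene/array noise,
  duplicate spots, planted artifacts with an exact ledger);
* a **cleaning chain** for two-channel spot data (intensity-floored ratio
  aggregation, spot-disagreement and spike repair by bracketing geometric
  means, channel-crosstalk repair, per-class background subtraction,
  noise-model hard-thresholding);
* **kinetic fits**: penalized MAP estimation of sigmoid and impulse
  (double-sigmoid, shared slope, zero initial amplitude) models with
  small-sample likelihood-ratio model selection, half-max times (t_rise,
  t_fall), asymptotes (v_inter, v_final) and 5–95% saturation intervals;
* **marginal attribution**: each fitted rise/fall is decomposed into
  per-regulator contributions ψ that sum exactly to the model-predicted
  change, after a predictive-value filter
  (min(f_model, f_obs)/max(f_model, f_obs) > 0.2); drivers pass ψ > 0.2;
* **graphs and benchmarking**: per-experiment causal graphs (direct =
  attributed, indirect = induced gene to any differentially expressed
  gene), meta-graph synthesis with support counts and hub scores,
  tie-averaged ROC against reference networks with a degree-preserving
  permutation null, and hypergeometric gene-set overlap links.

## Worked example

Simulate 12 induction experiments over a 30-gene network with 6
regulators, fit the dynamical model, and benchmark the inferred edges
against the known truth:

```r
library(inducenet)
net <- generate_network(n_genes = 30, n_regulators = 6, sparsity = 0.02,
                        seed = 42)
designs <- lapply(1:12, function(j)
  induction_design(paste0("e", j), net$regulators[(j - 1) %% 6 + 1],
                   system_class = if (j %% 2) "ZEV" else "GEV"))
cube <- simulate_experiments(net, designs)
obs  <- corrupt_with_noise(cube, noise_spec(gene_log_sd = 0.07, seed = 43))

model <- fit_network(obs)
truth <- which(net$alpha != 0 | net$beta != 0, arr.ind = TRUE)
ref   <- data.frame(a = colnames(net$alpha)[truth[, 2]],
                    b = rownames(net$alpha)[truth[, 1]])
evaluate_roc(edge_scores(model), ref, n_perm = 25, seed = 7,
             directed = TRUE)
```

This prints:

```
roc_result: AUC 1.000 (870 edges, 18 positives); perm null 0.548
```

All 18 true edges outrank all 852 non-edges (AUC 1.0 at this noise
level); the degree-preserving permutation null sits slightly above 0.5
because true regulators are hubs, which is the bias that null exists to
expose. Kinetic summaries for one experiment:

```r
fits <- fit_kinetics(obs, min_signal = 1, seed = 1)
fits[fits$experiment == "e2", c("gene", "model_class", "slope", "t_rise",
                                "v_inter", "lr_pvalue")]
```

```
 gene model_class  slope t_rise v_inter lr_pvalue
 g002     sigmoid 1.0601   3.54    5.49     0.448
 g019     sigmoid 0.0601  45.82    4.13     0.187
 g021     sigmoid 0.0815  46.18    1.95     0.300
```

`g002` is the induced regulator itself — a fast (half-max 3.5 min), strong
(2^5.49 ≈ 45-fold) rise — while its targets `g019` and `g021` respond
later (half-max ~46 min) with smaller amplitudes; the likelihood-ratio
p-values show no support for the more complex impulse model in any of
them.

A thin command line wraps the same functions
(`inst/cli/inducenet.R {simulate|preprocess|fit-kinetics|fit-network|attribute|evaluate}`).

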