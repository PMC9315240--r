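# connectopool

Interpretable graph-level regression on brain connectivity networks via
hierarchical community pooling.

## What problem this solves

Predicting a continuous behavioral score from a subject's brain network —
nodes are atlas regions, weighted edges are structural (tractography) or
functional (BOLD-correlation) connectivity — and, just as importantly,
saying *which regions drove the prediction*. Flat graph convolutions embed
nodes but ignore the brain's hierarchical community organization; global
pooling throws it away. `connectopool` implements a hierarchical graph
neural network whose pooling operator is built from network communities,
for neuroimaging researchers who want both a regression model and an
interpretable, testable map of salient regions.

## The model

For each subject with adjacency `A` (symmetric, nonnegative) and node
features `X`, the model repeats, at successively coarser scales:

1. **GCN block** — `Z = relu(D̃^{-1/2} Ã D̃^{-1/2} Z θ)` with `Ã = A + I`
   (two stacked layers per block).
2. **Community pooling** — score each node by the softmax of one minus its
   min-max-normalized total L1 latent distance,
   `P = softmax(1 − normalize[Σ_j S_ij])`, `S_ij = ‖Z_i − Z_j‖₁`; keep the
   top `M = ⌈rN⌉` nodes as community centers (pooling ratio `r = 0.5`);
   assign every other node to its nearest center; aggregate
   `Ẑ_i = Z_cᵢ + Σ_{v_j∈Ω_i} Z_{v_j}/(S_{cᵢ,v_j} + ε)`; coarsen the
   adjacency by block sums over communities.
3. **Readout** — `Z_G = relu(W Ẑ)` with a per-scale trainable `1×M` weight.

Readouts from all scales are fused (concatenated by default) and an MLP
outputs the score. Training minimizes the joint loss
`L = η₁·MSE(ŷ, y) + η₂·ℓ_community` (`η₁ = 0.5`, `η₂ = 0.01`), where
`ℓ_community` pulls each community member's latent features toward its
center's — Adam, batch 256, learning rate `0.001·(1 − epoch/500)^0.9`,
weight decay `1e-5`, early stopping with patience 20, 5-fold
cross-validated MAE.

The centers chosen by the **last** pooling module, traced back to the
original atlas, are a subject's *effecting nodes*. Per-group selection
frequencies, their normalized mutual information (NMI), and a
label-permutation test quantify and test group differences in these
saliency maps.

## Worked example

Everything below runs on synthetic cohorts with planted ground truth
(`?synthConfig` describes what they emulate):

```r
library(connectopool)

# 200 subjects, 30-node atlas, 4 planted communities, 5 planted signal
# nodes whose activations drive the score
cohort <- makeCohort(synthConfig(seed = 0))
cohort
#> Cohort: 200 subjects, atlas size 30, active score 'score'

mc <- modelConfig(numPoolingModules = 2, poolingRatio = 0.5, seed = 0)
cv  <- crossValidate(cohort, mc, trainConfig(seed = 0), returnModels = TRUE)
round(c(mae = cv$maeMean, sd = cv$maeSd, baseline = cv$baselineMean), 3)
#>      mae       sd baseline
#>    0.400    0.021    0.903
```

The cross-validated MAE (0.400 ± 0.021) beats the predict-the-training-mean
baseline (0.903); the score is learnable from the planted signal nodes and
the model finds it. Which nodes does the model consider salient? Pool the
effecting nodes of each fold's held-out subjects:

```r
sets <- list()
for (k in 1:5)
  for (i in cv$testIndices[[k]])
    sets <- c(sets, list(effectingNodes(
      forwardModel(cohort[[i]], cv$models[[k]]$modelConfig,
                   cv$models[[k]]$params))))
freq <- tabulate(unlist(sets), 30) / length(sets)
sig <- attr(cohort, "groundTruth")$signalNodes
round(c(signal = mean(freq[sig]), other = mean(freq[-sig])), 3)
#> signal  other
#>  0.437  0.233
```

The planted signal nodes are selected about 1.9 times as often as the
rest — the saliency map recovers the planted ground truth. For group
comparisons, a two-group cohort with disjoint planted signal sets feeds
the permutation test:

```r
sigB  <- defaultSignalNodes(30, 4, 5) + 3
twoG  <- makeCohort(synthConfig(seed = 100, groupBSignalNodes = sigB))
set.seed(1); idx <- sample(200)
model <- trainModel(twoG@samples[idx[-(1:20)]], twoG@samples[idx[1:20]],
                    mc, trainConfig(seed = 0))
fresh <- makeCohort(synthConfig(seed = 300, nSubjects = 400,
                                groupBSignalNodes = sigB, protoSeed = 100))
gl <- groupLabel(fresh)
pt <- permutationTest(model, fresh@samples[gl == "A"],
                      fresh@samples[gl == "B"], nPerm = 100, seed = 1)
c(observed = pt$observedNmi, p = pt$pValue)
#> observed        p
#>    0.467    0.0099
```

Low NMI means the two groups' frequency profiles differ; `p ≈ 0.01` (the
minimum attainable with 100 permutations) confirms the planted group
difference. A thin CLI wraps the same functions
(`exec/connectopool simulate|validate|crossval|interpret`).

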