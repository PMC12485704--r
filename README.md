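# gaussflex

Predicting protein conformational flexibility from static structure, using
generalized Gauss integrals of the Cα backbone as the only input.

Molecular-dynamics simulation is the reference method for quantifying how
much a protein fluctuates, but it is far too expensive for proteome-scale
screening. `gaussflex` implements the alternative route: encode each chain's
Cα trace — an open polygonal curve in space — as a fixed-length vector of
30 topological shape descriptors, and train small neural networks to predict
the chain's MD-derived flexibility (its replicate- and residue-averaged
Cα RMSF) from that vector alone, either as a binary flexible/non-flexible
classification against the dataset-mean RMSF or as a continuous regression.

## The descriptors

For backbone segments *i* and *j*, the mutual Gauss integral

W(i,j) = (1/4π) ∮ᵢ∮ⱼ (dt₁ × dt₂) · r₁₂ / |r₁₂|³

is evaluated in closed form as the signed area of a spherical quadrilateral
(van Oosterom–Strackee solid angles), normalized so that |W(i,j)| is exactly
the probability that the two segments cross in a projection along a uniformly
random direction, with the sign giving the crossing handedness. From the
resulting segment-pair matrix the package evaluates chord-diagram invariants

I(a₁,b₁)(a₂,b₂)… = Σ_{i₁<…<i₂ₖ} Π_c W(i_{a_c}, i_{b_c}),

with an optional absolute value per chord. The default 30-component registry
is: chain length N; the writhe I(1,2) and average crossing number I|1,2|;
the three order-2 matchings (1,2)(3,4), (1,3)(2,4), (1,4)(2,3) in all four
abs variants; and the fifteen order-3 perfect matchings of six slots. Orders
1–2 are computed in O(n²) and order 3 in O(n³) via prefix-sum reductions
(Rcpp); a brute-force enumerator and a Monte-Carlo projection estimator act
as independent oracles in the test suite.

## The models

Four architectures share one training protocol (Adam, learning rate 1e-3,
weight decay 1e-4, batch size 32, early stopping with patience 7 in at most
50 epochs; stratified 20% holdout; 5-fold cross-validation followed by
retraining the best fold on the full pool):

* **attention-CNN** — four stacked 1D conv blocks (kernel 3, padding 1,
  channels 1→32→64→64→128, ReLU), additive attention over the 30 positions,
  weighted sum to a 128-vector, dense head (sigmoid or identity);
* **CNN** — the same trunk with mean pooling instead of attention;
* **RNN** — a single-layer GRU (hidden 64) reading the descriptor vector as
  a 30-step scalar sequence;
* **SVM-RBF** — kernel baseline via `e1071`.

Forward and backward passes, Adam and gradient clipping are implemented in
base R; evaluation includes ROC/AUC with percentile-bootstrap confidence
intervals, precision–recall and average precision, the Youden-J operating
point, calibration, per-cluster AUC, regression statistics, and Integrated
Gradients attribution over the 30 descriptor positions. PCA plus k-means in
PC space reproduce the structural clustering analysis.

## Worked example

```r
library(gaussflex)

## descriptors of an ideal alpha-helix
helix <- make_backbone("helix", n_residues = 50)
round(compute_gi_vector(helix)[1:3], 3)
#>      N I(1,2) I|1,2|
#> 50.000  6.392 12.336

## planted-signal flexibility classification at Bayes AUC 0.95
noise <- noise_for_bayes_auc(0.95)              # 0.7459
d <- make_labeled_set(1000, effect_size = 1, noise_sd = noise, seed = 7)
split <- holdout_split(1000, 0.2, seed = 7, stratify_labels = d$y)
fit <- flex_fit(d$X[split$train, ], d$y[split$train], "cnn_attention",
                config = train_config(seed = 7))
fit
#> flex_fit: cnn_attention classification on 800 proteins
#>   epochs run: 36, best epoch: 29

scores <- as.numeric(predict(fit, d$X[split$test, ]))
eval_report(d$y[split$test], scores, n_boot = 500, seed = 7)
#> AUC 0.873 (95% CI 0.824-0.916), AP 0.848, max F1 0.817
#> Youden threshold 0.551 (TPR 0.838, FPR 0.218); n = 200
```

The positive writhe of the right-handed helix flips sign on its mirror
image; the holdout AUC of 0.873 against an attainable (Bayes) 0.95 shows the
attention-CNN recovering most of the planted signal from 800 training
examples. `attention_map(fit$model, ...)` and
`integrated_gradients(fit$model, ...)` expose which descriptor positions the
model used.

A command-line front end over the same functions is installed at
`inst/scripts/gaussflex` (subcommands `gi`, `rmsf`, `pca`, `synth`, `train`,
`predict`, `eval`, `pipeline`).

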