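# nodugrowth

Uncertainty-aware prediction of future lung-nodule growth from a single
baseline CT patch.

Radiologists follow incidental lung nodules over months to years; the
decisive question is whether the longest axial diameter will grow by more
than **2 mm** before the next scan. Because follow-up measurements are noisy
(different readers disagree by about 1 mm on the same scan pair), a useful
predictor outputs a *distribution* of plausible future segmentations rather
than a single contour. `nodugrowth` implements such a predictor for
researchers in medical image analysis: a hierarchical probabilistic
segmentation network, its tailored training objective, Monte-Carlo growth
inference, multi-annotator evaluation statistics, and a synthetic cohort
generator that makes the whole loop runnable without clinical data.

## The model

Two residual U-Net subnets share one decoder architecture. The **prior**
subnet sees the baseline patch `I0`, the encoded time-to-predict `Tdiff`
and the baseline diameter `D0`; the **posterior** subnet additionally sees
the follow-up patch `I1`. Four latent blocks interleaved in the decoder
(spatial grids 1², 2², 4², 8²; latent dimensions 1, 4, 16, 64) define
diagonal Gaussians `p(z_i | z_<i, I0, Tdiff, D0)` and
`q(z_i | z_<i, I0, I1, Tdiff, D0)`; attention gates filter the skip
connections. Training minimises

```
L_ELBO = L_IoU(Y, Y') + γ·|D1 − D1'| + β·Σᵢ KL(qᵢ ‖ pᵢ)
```

where `Y'` is the prior decoder's output under posterior latents, `D1'` is
a differentiable (soft-Feret) longest diameter of the soft mask, and
`γ = 1/8`, `β = 1`, Adam at 1e-4, batch 8 are the defaults. At test time
the prior subnet is sampled `K` times (default 1000); each thresholded
sample yields a diameter `D1'_k`, growth `Δ_k = D1'_k − D0`, and logistic
growth probability `F_k = 1/(1 + e^{−(Δ_k − 2)})`. The estimate reports
`Δ̄ ± sΔ` (growth size and uncertainty), `F̄ ± sF` (growth probability and
uncertainty) and per-pixel mean/std images of the forecast appearance.

Evaluation covers point metrics (balanced accuracy, precision, recall, MAE,
Dice), distribution metrics (generalized energy distance with the `1 − IoU`
mask distance; balanced accuracy of the `Δ̄ ± 2sΔ` interval), and
closest-annotator selection (Mahalanobis on growth, mean Dice on masks).

There is no deep-learning framework dependency: the network runs on a small
reverse-mode autodiff engine inside the package (im2col convolutions over
BLAS), with gradients pinned by finite-difference tests.

## Worked example

```r
library(nodugrowth)

cohort <- generate_cohort(simulation_params(n_nodules = 30, seed = 7))
cohort
#> <growth_cohort> 81 records, 30 unique nodules, 3 annotators

parts <- split_by_nodule(cohort, train_fraction = 0.7, seed = 1)
fit <- train_hpnet(parts$train,
                   network_config(base_filters = 8, seed = 2),
                   training_config(epochs = 8, learning_rate = 1e-3, seed = 3))
tail(fit$history, 2)
#>   epoch     lrec          kl    total
#> 7     7 2.940378 0.010914169 2.951292
#> 8     8 2.716100 0.009284111 2.725385

rec <- parts$test$records[[1]]
cond <- encode_conditioning(rec$elapsed_days, rec$d0_mm)
est <- monte_carlo_predict(fit$model, rec$image_t0, cond$t_norm, cond$d_norm,
                           d0_mm = rec$d0_mm, spacing_mm = rec$spacing_mm,
                           K = 100, seed = 4)
est
#> <growth_estimate> K=100  growth 0.47 +/- 0.40 mm  P(growth) 0.18 +/- 0.06
classify_growth(est)
#> [1] 0
rec$d1_mm - rec$d0_mm   # the annotator saw 1.52 mm, below the 2 mm threshold
#> [1] 1.52
```

The estimate reads: across 100 sampled futures this nodule grows
0.47 ± 0.40 mm, the probability of exceeding the 2 mm guideline threshold
is 0.18 ± 0.06, so the model calls "no growth" — matching the annotator's
label for this held-out nodule. (An 8-epoch run is for illustration; the
test suite trains for 25 epochs and reaches a held-out balanced accuracy of
about 0.9 on the planted synthetic growth signal.)

A command-line driver over the same functions ships in
`inst/cli/nodugrowth.R`:

```sh
Rscript inst/cli/nodugrowth.R simulate --config cfg.yaml --out runs/sim --seed 1
# then: train | predict | evaluate
```

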