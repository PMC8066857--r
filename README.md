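# caedge

Supervised edge detection for grayscale images — aimed at structures like
cardiac cavities on MRI slices — using a cellular automaton (CA) whose
transition rule is tuned by particle swarm optimization (PSO) against
ground-truth edge maps. Because expert annotation of medical images is
expensive, the detector is optimized on synthetic circle phantoms that
emulate the target images' intensity structure, and the resulting rule is
transferred to real data.

## The model

Each pixel X(i,j) is a cell of a 2-D automaton over the radius-1 Moore
neighborhood. The transition rule has two steps:

1. **Edge membership.** A 9-bit *linear rule* r ∈ {0, …, 511} selects which
   neighbors contribute to the local absolute-difference sum
   φ(X(i,j)) = Σ(k,l) |X(i,j) − X(i+k,j+l)|, and the membership is the
   saturating ratio μ(X(i,j)) = φ / (Δ + φ), with damping constant
   Δ ∈ {0, …, 255} (larger Δ ⇒ fewer edges).
2. **Thresholding.** F(X(i,j)) = 1 iff μ(X(i,j)) > τ, with τ ∈ [0, 1).

One synchronous pass yields the binary edge map. The triplet (Δ, τ, r) is
optimized by PSO in its normalized form (Δ/255, τ, r/511) ∈ [0,1]³ with the
Dice similarity coefficient DSC = 2·TP / (2·TP + FP + FN) as fitness
(positive class = edge pixel), averaged over the images of an optimization
batch. Between batches the swarm's global best is reset so particles do not
stay trapped in optima of earlier units; batch size 1 is the per-image
protocol. Three pipelines are supported: the plain CA map, the CA map with
thinning plus disconnected-edge removal (`post`), and Gaussian
pre-smoothing followed by the post path (`pre_post`). A Canny baseline with
the conventional 10%/20%-of-range thresholds is included for comparison.

## Worked example

```r
library(caedge)

train <- make_optimization_set(20, "low",  master_seed = 301)
test  <- make_optimization_set(20, "low",  master_seed = 302)

fit <- caed_fit(train, batch_size = 3,
                control = swarm_config(seed = 18),
                scenario = scenario_config("pre_post", sigma_smooth = 1.5))
fit
#> Cellular-automaton edge detector (PSO-optimized)
#>   delta = 231, tau = 0.3188, rule = 181
#>   final-unit training DSC = 0.6057 (20 samples, batch size 3, 7 units)

edges <- predict(fit, test[[1]])
c(psnr = psnr(edges, test[[1]]$truth), ssim = ssim(edges, test[[1]]$truth))
#>       psnr       ssim
#> 20.6829190  0.9271641
```

The fitted triplet says: sum absolute differences over the 5 neighbors
selected by rule 181, damp by Δ = 231, and call a pixel an edge when the
membership ratio exceeds τ ≈ 0.32. A training DSC near 0.6 is typical for
1-pixel-wide ground truth against blurred, noisy phantoms; PSNR ≈ 20 dB and
SSIM ≈ 0.90 on a held-out phantom indicate most boundary pixels are found
with few spurious components.

Experiment drivers reproduce the study designs on synthetic sets:
`run_noise_robustness()` (scenario comparison under injected noise),
`run_smooth_sweep()` (pre-filter sweep vs. Canny), `run_batchsize_sweep()`
(batched optimization protocols), `run_difficulty_analysis()` (Sobel
mean-gradient difficulty vs. metrics). A thin CLI for detection, the Canny
baseline and phantom synthesis is installed at `inst/scripts/caed`.

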