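# angioseg

Segmentation of dark, roughly elliptical target regions — such as an
enlarged foveal avascular zone (FAZ) in diabetic retinopathy — in
single-channel 8-bit retinal angiography images, using a hybrid of fuzzy
C-means clustering, a genetic algorithm for seed selection, and seeded
region growing with online statistics. The package is aimed at
researchers in retinal image analysis who need a classical,
fully-inspectable (non-deep-learning) segmentation baseline with an
exact synthetic test bed and a standard eight-metric evaluation suite.

## Method

For an image `I` with pixels `x_i`:

1. **Fuzzy C-means.** Minimize
   `E = sum_k sum_i u_ki^m (c_k - x_i)^2` subject to `sum_k u_ki = 1`,
   with membership update `u_ki = 1 / sum_j (|x_i-c_k| / |x_i-c_j|)^t`,
   `t = 2/(m-1)`, and center update
   `c_k = sum_i u_ki^m x_i / sum_i u_ki^m`. The `K` centers (default
   `K = 6`) are sorted and split at the two largest inter-center gaps
   into dark / mid / bright tiers, giving a binary tri-class reference.
2. **Genetic seed search.** A chromosome is a list of 1–20 seed pixels.
   Its cost grows regions from the seeds and measures the tri-class
   disagreement fraction between the grown segmentation and the FCM
   reference (squared-difference form `(GM-I1)^2 + (WM-I2)^2 +
   (BM-I3)^2` on binary supports, normalized per pixel). Tournament
   selection, one-point crossover, jitter/insert/delete mutation
   (rate 0.2), elitism, population 20.
3. **Seeded region growing.** Breadth-first over the 8-connected
   lattice; a neighbor of intensity `I` joins the region iff (strictly)
   `mu - X_sd*sigma < I < mu + X_sd*sigma` and `|I - mu| < X_mean`,
   where `mu`, `sigma` are the running region statistics maintained
   online: `mu_N = ((N-1)mu_{N-1} + I_N)/N` and the matching Welford
   variance recurrence. Defaults `X_sd = 3` (the 99.7% Gaussian window),
   `X_mean = 30` gray levels.

The output mask is the union of grown regions whose mean falls in the
dark tier. Evaluation reports sensitivity, specificity, precision, two
FPR variants (`FP/(FP+FN)` as printed in the source protocol and the
conventional `FP/(FP+TN)`), accuracy, Dice, volume overlap error (VOE),
and relative volume difference (RVD).

## Worked example

```r
library(angioseg)

# a 96x96 synthetic angiogram: dark ellipse, 2 vessels, noise sd 3
ph  <- make_phantom(phantom_spec(height = 96, width = 96, noise_sd = 3,
                                 n_vessels = 2, rng_seed = 1))
res <- segment(ph$image, pipeline_config(
  ga = ga_config(n_generations = 15, stall_generations = 15, rng_seed = 1)))
print(res)
#> GA-FCM segmentation result
#>   target tier: dark | mask pixels: 574 of 9216
#>   regions grown: 18 | seeds: 18
#>   final GA cost: 0.001193576 after 15 generations

round(as.data.frame(evaluate(res$mask, ph$mask)), 3)
#>    tp   tn fp fn sensitivity specificity precision fpr_paper fpr_conventional
#> 1 574 8640  0  2       0.997           1         1         0                0
#>   accuracy   dice   voe    rvd
#> 1        1 99.826 0.347 -0.347
```

Reading: the GA settled on 18 seeds; the grown dark-tier mask covers 574
of the 576 true ellipse pixels with no false positives — sensitivity
0.997, Dice 99.8%, VOE 0.35%, and RVD −0.35% (the tiny negative value
means slight undersegmentation). The GA cost is the tri-class
disagreement fraction (0 = the region growing reproduces the clustering
reference exactly).

On the standard 250×250 phantom with noise sd 5 and five vessels
(`phantom_spec()` defaults), full-pipeline runs across five RNG seeds
score Dice 94–97; the residual gap to 100 is dominated by vessel pixels
that occlude the true ellipse and are unrecoverable from intensities.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "angioseg.R", package = "angioseg"))')
Rscript $CLI phantom  --out-dir data --count 3 --seed 7
Rscript $CLI segment  --image data/image_001.png --truth data/mask_001.png \
                      --out-dir out --clusters 6 --population 20 \
                      --mutation-rate 0.2 --x-sd 3 --seed 7
Rscript $CLI evaluate --pred out/mask.png --truth data/mask_001.png --out report.csv
Rscript $CLI compare  --image data/image_001.png --truth data/mask_001.png \
                      --manual-seed 10,10 --out-dir cmp --seed 7
```

`segment` writes `mask.png`, `labels.png`, `cost_history.csv`, and a
`run_log.txt` echoing every effective parameter. A JSON config file
(`--config`) mirrors the flags 1:1; unknown keys exit with status 2.

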