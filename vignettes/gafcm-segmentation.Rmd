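---
title: "GA-FCM seeded region growing: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GA-FCM seeded region growing: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angioseg)
```

## The problem

In retinal angiography (fluorescein angiography, OCT angiography), several
clinically important structures appear as *dark, roughly elliptical,
capillary-free regions* on a brighter perfused background — most
prominently the foveal avascular zone (FAZ), whose enlargement and
distortion track diabetic retinopathy. `angioseg` segments such regions in
single-channel 8-bit images with a three-stage hybrid:

1. **Fuzzy C-means (FCM)** clusters pixel intensities into `K` clusters
   (memberships sum to one per pixel), which are folded into a
   dark / mid / bright **tri-class reference** — dark avascular tissue,
   perfused background, and bright vessels.
2. A **genetic algorithm (GA)** searches over the *number and location* of
   seed points. A candidate seed set is scored by growing regions from it
   and measuring the tri-class disagreement between the grown segmentation
   and the FCM reference.
3. **Seeded region growing** expands each seed over the 8-connected
   lattice, admitting a neighbor only if it passes two similarity windows
   against the *current* region statistics, which are maintained online:

   - mean update: `mu_N = ((N-1) mu_{N-1} + I_N) / N`
   - variance update (Welford form, algebraically identical to the
     recurrence `sigma_N^2 = ((N-2) sigma_{N-1}^2 +
     (N/(N-1))(I_N - mu_N)^2) / (N-1)`):
     `M2_N = M2_{N-1} + (I_N - mu_{N-1})(I_N - mu_N)`,
     `sigma_N^2 = M2_N / (N-1)`.

   The windows are (strict inequalities):

   - **sd window**: `mu - X_sd * sigma_eff < I < mu + X_sd * sigma_eff`.
     At `X_sd = 3` and converged statistics, this admits about 99.7% of
     Gaussian-distributed in-region intensities (`2 * pnorm(3) - 1`).
   - **mean window**: `|I - mu| < X_mean` gray levels.

The final mask is the union of grown regions whose mean intensity falls in
the target tier (`dark` by default; hypofluorescent lesions).

## Parameters that matter

| Parameter | Default | Units | Why this value |
|---|---|---|---|
| `K` (clusters) | 6 | – | Low end of the useful 6–10 range; at least one cluster per tier with headroom for the broad background. |
| fuzzifier `m` | 2 | – | Standard FCM softness; membership exponent `t = 2/(m-1) = 2`. |
| `x_sd` | 3 | multiples of sigma | 3-sigma window: ~99.7% acceptance on Gaussian in-region noise. |
| `x_mean` | 30 | gray levels | Must contain within-region variation (illumination shading of roughly ±20 plus ~3 noise sigma) while staying below the smallest between-class contrast (~50, perfused tissue vs. vessel). |
| `sigma_floor` | 5 | gray levels | Bootstrap floor for the sd window while `n < 8`. It must sit at the imaging-noise scale: early acceptances happen *inside* the window, so a floor far below the noise sd truncates the sample, biases the running sigma low, and growth collapses in a shrinking-window spiral (we measured 29% of interior seeds dying at `n <= 3` with a floor of 1 on noise sd 5). |
| `max_region_fraction` | 0.9 | – | Runaway guard; a region spanning the whole image is a degenerate segmentation. |
| population | 20 | – | Fixed by the method's stated configuration. |
| mutation rate | 0.2 | – | Fixed by the method's stated configuration; applied per seed (jitter ±5 px) and per chromosome (insert/delete one seed). |
| generations | 120 (stall stop 40) | – | Structural improvements travel through delete-then-insert mutation chains; their waiting time at population 20 exceeds 50 generations. |
| `n_min`–`n_max` | 1–20 | seeds | The seed budget must exceed the number of 8-connected compartments the vessels carve the scene into (12–15 on standard phantoms); with a budget of 10 the optimizer trades small lesion lobes against larger background compartments. |

## Design choices where the design was open

**Tri-class grouping by largest center gaps.** The `K` sorted cluster
centers are split into three consecutive groups at the two largest
inter-center gaps. A fixed equal-count split (2+2+2 at `K = 6`) fails
structurally: FCM allocates clusters in proportion to intensity mass, so
the broad background claims 4–5 of 6 clusters and an equal-count split
pushes background clusters into the dark tier, which then absorbs
background fragments into the lesion mask.

**Binary tier supports in the GA cost.** The cost compares the grown
segmentation with the reference tier-by-tier as *binary supports* (the
tissue-map convention), summed as squared differences and normalized per
pixel — i.e. the tri-class disagreement fraction. Comparing raw
intensities instead weights a dark-lesion pixel by its small squared gray
level (60² vs. 180² for background), which puts the entire lesion tier
below 1% of the total cost mass; the optimizer then has no measurable
incentive to keep lesion seeds, and lesion coverage becomes genetic
drift. This was observed directly (total lesion loss in half the runs)
before the change.

**Tier-stratified initialization.** Initial chromosomes carry the full
seed budget, with seed locations drawn round-robin from the supports of
the three reference tiers. The GA's purpose here is refining seed
placement and count, not re-discovering from a uniform prior that the
image contains a small dark region; uniform initialization measurably
loses all lesion carriers before fixation.

**Classical one-point crossover.** One shared cut position recombines two
seed lists; offspring lengths swap the parents' lengths, so the count
bounds hold automatically and identical parents reproduce exactly.
Independent per-parent cuts make children of two good parents lose or
duplicate seeds, which empirically prevents the population from ever
converging.

**Single-pass growth.** A pixel rejected by a region is never re-examined
by that region, even though the region's statistics continue to drift.
This keeps growth O(pixels) and deterministic, at the price of
truncation: a region whose mean drifts across a shaded background covers
only the intensity band reachable from its seed, which is why full
coverage takes several seeds per compartment.

**Degenerate window rule.** With `sigma_eff = 0` (constant region after
the floor expires) the strict sd window is empty; the implementation
accepts exactly `I == mu`, the limit of the strict window, so constant
plateaus can still grow.

**Ties and orderings.** Defuzzification breaks membership ties toward the
lowest cluster index; BFS neighbors are pushed in the fixed order N, NE,
E, SE, S, SW, W, NW; regions grow in seed-list order with first-claim
ownership. All three choices exist to make runs bit-reproducible.

## What the phantom generator emulates — and what it does not

`make_phantom()` renders: a background at 180 gray levels with a ±20
horizontal shading ramp; a dark (60) rotated ellipse as the target; 5
bright (230) random-walk vessel tracks of width 2–4 px drawn *on top of*
the ellipse so that vessels may cross the target; and additive Gaussian
noise (sd 5) clipped to [0, 255]. Ground truth is the analytic ellipse —
exact by construction.

It does **not** emulate: speckle or multiplicative noise, capillary
texture, optic-disc or macular brightness structure, motion or blink
artifacts, vessel branching topology, or annotation noise. A green test
on phantoms therefore establishes that the algorithm recovers a
low-contrast compact region under Gaussian noise, shading, and occluding
bright structures — not clinical-grade performance on angiograms. The
clinical dataset behind the method's published figures is private, so
those figures are not reproduced here.

One consequence of drawing vessels over the target is a Dice ceiling
below 100 on noisy phantoms: pixels of the true ellipse occluded by a
vessel are not dark in the rendered image and cannot be recovered by any
intensity-driven method; at default settings this ceiling is roughly
94–97, which is the range the end-to-end acceptance run actually attains.

## Numerical choices

- FCM convergence: max absolute center shift < 1e-4, cap 300 iterations;
  objective recorded once per iteration after both half-updates, which
  guarantees a non-increasing trace (checked to 1e-8 slack).
- A pixel coinciding with a center receives crisp membership on the
  first (lowest-index) such center; an empty cluster keeps its previous
  center rather than producing NaNs (reachable on constant images).
- Online statistics are Welford-form; they match two-pass batch values to
  1e-9 relative at n = 10^6 with large offsets.
- On images above 10^5 pixels, FCM centers are fitted on a stride-2
  subsample and memberships are then recomputed at full resolution, so
  the reference is always full-resolution.
- Images are validated to [0, 255]; masks are logical matrices; all
  coordinates are 1-based (row, col).

## Known limitations

- Single-pass growth truncates coverage under strong shading; the GA
  compensates with more seeds rather than the grower re-visiting pixels.
- The tri-class reference assumes three intensity populations; scenes
  without a dark or bright population degrade to an arbitrary split of
  the middle band (the two tier breaks then fall inside one continuum).
- The GA is stochastic; medians over a few seeds are the meaningful
  statistic, and all entry points expose explicit RNG seeds.
- TIFF input is not supported (no reader in the dependency set); PNG and
  JPEG are.
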