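# canopysense

Mobile monitoring of urban street-tree canopies from a vehicle-mounted
sensor rig: upward-facing RGB video frames, radiometric thermal frames, a
nine-sensor metal-oxide gas array ("E-nose") and GPS. The package turns
these raw streams into per-tree physiological records and trains a neural
network that predicts the expensive camera-derived indices from the cheap
gas-sensor readings — the basis for low-cost, city-scale irrigation and
green-infrastructure monitoring.

## What it computes

**Canopy structure from RGB cover photography.** Each upward frame is
binarized at the valley between the sky and canopy peaks of the blue
histogram, then analysed on a 5×5 sub-image grid: sub-images at or above
75% sky are *large gaps*. With foliage cover *f_f* (1 − total gap
fraction), crown cover *f_c* (1 − large-gap fraction) and crown porosity
∅ = 1 − f_f/f_c, Beer–Lambert extinction gives

    LAI   = −f_c · ln(∅) / k            (k = 0.5)
    Ω(0)  = (1 − ∅) · ln(1 − f_f) / (ln(∅) · f_f)
    LAIe  = LAI · Ω(0)

where Ω(0) is the zenith clumping index and LAIe the effective leaf area
index.

**Water status from thermal frames.** Canopy pixels (above a 0 °C sky
cutoff in upward radiometric frames) yield the canopy temperature and
in-frame wet/dry reference temperatures (5th/95th percentiles). From
these:

    raw index = (T_canopy − T_wet) / (T_dry − T_wet)     → TWSI (clipped to [0, 1])
    Ig        = (T_dry − T_canopy) / (T_canopy − T_wet)
    CTD       = T_canopy − T_air                          (air from the E-nose)

**Per-tree fusion.** GPS tracks are densified to 10 Hz by linear
interpolation; non-overlapping circular geofences (capped half-spacing
radii) are built around tree anchors; entry/exit timestamps per region
assign every camera frame and E-nose sample to a tree, whose parameters
are then averaged per tree ID.

**Prediction.** Per-tree records are scaled to [0, 1] (voltages /5,
temperature /50, humidity /100, LAI /5, CTD mapped from ±20 °C) and fed
to a 10-20-4 feed-forward network (sigmoid hidden layer, linear output)
trained with Levenberg–Marquardt under a random 70/15/15
train/validation/test split, evaluated by MSE and pooled Pearson R.
PCA (factor loadings on the correlation matrix) and a
significance-annotated Pearson matrix summarise how gas, canopy and
weather variables co-vary.

Seed-deterministic generators (`gen_canopy_scene`, `gen_thermal_scene`,
`gen_transect`, `gen_linked_dataset`, `simulate_campaign`) produce
ground-truthed synthetic inputs for every stage.

## Worked example

```r
library(canopysense)

# a 512x512 synthetic upward scene with 60% crown cover, 30% porosity
sc <- gen_canopy_scene(0.6, 0.3, 512, 512, seed = 42)
cm <- analyze_rgb_frame(sc$frame)
cm
#> Canopy cover metrics
#>   ff (foliage cover) : 0.4198
#>   fc (crown cover)   : 0.6000
#>   phi (porosity)     : 0.3004
#>   Omega(0)           : 0.7543
#>   LAI                : 1.4435
#>   LAIe               : 1.0888
```

The detected valley threshold was 104 (between the dark-canopy and
bright-sky blue peaks); the recovered crown cover and porosity match the
scene's bookkept truth (fc 0.6000, ∅ 0.3004), and the LAI of 1.44 equals
the analytic Beer–Lambert value for that cover/porosity pair. A thermal
frame over the same canopy:

```r
th <- gen_thermal_scene(!sc$sky, t_canopy_mean = 22, t_canopy_sd = 1.5, seed = 1)
analyze_thermal_frame(th, t_average = 19.2)
#> Canopy water status
#>   T_canopy : 22.002 C   (T_wet 19.533, T_dry 24.456)
#>   raw index: 0.5015   TWSI: 0.5015   Ig: 0.9941   CTD: 2.802 C
```

A canopy sitting halfway between its wet and dry references gives a
stress index near 0.5 and Ig near 1; the canopy runs 2.8 °C above the
air, consistent with reduced transpiration.

A full campaign (frames + SRT sidecars + E-nose log + anchors) runs
through `run_pipeline()` or the `exec/canopysense` command line:

```sh
canopysense simulate --what campaign --seed 3 -o camp/
canopysense run --config campaign.yaml -o runs/day1/
```

producing per-frame tables, the fused `per_tree.csv`, a trained
`model.json` (when enough trees are recorded) and PCA/correlation
exports.

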