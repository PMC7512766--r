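# vishift

Fractional-order chaotic oscillator networks for visual selection and
shifting.

`vishift` is for computational-neuroscience and biological-image-analysis
work that treats scene segmentation and attention as *oscillatory
correlation*: features of one object are represented by synchronized
oscillators, different objects by desynchronized groups, and "attention" is
a controller that phase-locks to one group at a time.

## The model

Every pixel of an image drives one Rössler oscillator with a Caputo-type
fractional derivative of order α (default 0.9):

    D^α x = -o y - z + λ⁺ Σ_pos (x_q - x) - λ⁻ Σ_neg (x_q - x)
    D^α y =  o x + a y
    D^α z =  b + z (x - c)          (a = 0.48, b = 0.6, c = 6)

Pixel contrast C (weighted mean absolute deviation of gray/R/G/B from the
image means) sets the natural frequency, o = 1 − 0.5Δo + Δo·C, and the
coupling strengths, λ⁺ = λ⁺max·exp(−(1−C)²/2σ²) on similar 8-neighbours and
λ⁻ = λ⁻max·(1 − exp(−(1−C)²/2σ²)) repulsively on dissimilar ones. Objects
synchronize internally and drift apart from each other in phase, so sorting
pixel phases and cutting at large gaps segments the scene.

A second layer holds one central oscillator at the mean frequency o_r. Each
object group is summarized by its *hybrid system* (the componentwise mean w
of its members), and the central unit locks to one hybrid at a time by
exact-cancellation active control, u = Ω − F_r(s_r) − K e with e = s_r − w,
so the closed-loop error obeys D^α e = −K e and decays as the
Mittag-Leffler function E_α(−K t^α). Epochs are time-division scheduled in
order of salience (phase velocity): onset of epoch k is t₁ + k(F_t + 0.01).

Integration uses an explicit Grünwald–Letnikov scheme with short-memory
truncation (compiled core), plus an Adams–Bashforth–Moulton
predictor-corrector for validation.

## Worked example

The built-in three-object scene (blue, yellow, green rectangles on a dark
background, run at one-fifth scale, 42 × 30) goes through the full pipeline
— encode, simulate layer 1, segment by phase, rank salience, schedule,
attend — in under a minute:

```r
library(vishift)
run <- run_pipeline("three-object", run_config(seed = 1))
summary(run)
#> Two-layer visual selection and shifting run
#>   scene: 30 x 42 pixels; segmentation found 4 groups
#>   mean contrast by group: 0: 0.096, 1: 0.553, 2: 0.399, 3: 0.251
#>   salience order (fastest first): 1 > 2 > 3 > 0
#>   attention: 4 transitions over 4 epochs (F_t = 10, t1 = 20)
#>  group onset offset locked mean_abs_err
#>      1 20.00  30.00   TRUE   0.11930799
#>      2 30.01  40.01   TRUE   0.09242550
#>      3 40.02  50.02   TRUE   0.09977717
#>      0 50.03  60.03   TRUE   0.07601305
#>   mean object entropy: 0.0000 bits
```

Reading the output: segmentation recovered the three objects plus
background (group 1 is the yellow rectangle — highest contrast 0.553, hence
fastest phase growth and first to be attended); the central unit locked to
all four hybrid systems in salience order, i.e. four attention transitions;
the per-epoch error is the mean state distance to the attended hybrid over
the epoch's final half (order 0.1 — the fractional error decay has a
power-law tail); and the segments are perfectly homogeneous (0 bits of
gray-level entropy), as expected for uniformly coloured synthetic objects.

`plot(run)` shows the per-group phase growth with the central unit's phase
jumping between groups, and the within-group phase spread over time. The
five-object preset (`run_pipeline("five-object", ...)`) gives six groups and
six transitions the same way.

A command-line interface wrapping the same functions ships in
`inst/cli/vishift` (subcommands `synth`, `encode`, `simulate`, `attend`,
`scan-coupling`, `run`), e.g.:

```sh
Rscript inst/cli/vishift run --preset three-object --scale 0.2 --out out/
```

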