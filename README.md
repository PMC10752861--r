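# dnpflow

Fly-inspired motion detection with divisive normalization gain control, in R.

The early visual system of the fruit fly detects motion reliably across
light levels spanning many orders of magnitude, using a handful of synapses
and purely analog processing. dnpflow implements a computational account of
that ability as a cascade of two **divisive normalization processors
(DNPs)**:

1. **Gain control** (photoreceptor/amacrine-cell layer): each channel
   computes `v = T1(u) / (T2(u) + T3(v) + L4(v_pool))`, a Volterra-processed
   input divided by input, self-feedback and spatially pooled feedback
   terms. On constant input the feedforward part reduces to the sigmoid
   `v(I) = (a0 + a1 I + a2 I^2) / (c0 + c1 I + c2 I^2)` in `log10(I)`; an
   adaptive feedback state `w` with
   `dw/dt = alpha * (L4(v) - 0.5 * (b4 + r1 + r2))` re-centres the operating
   point at the middle of that sigmoid for any brightness level.
2. **Phase-based elementary motion detection** (medulla/lobula): the time
   derivative of the local phase of Gabor quadrature coefficients,
   `dphi/dt = (a*db/dt - b*da/dt) / (a^2 + b^2 + eps)`, is itself a DNP and
   is independent of image amplitude. For a scene translating at velocity
   `v` the phase-derivative field over the frequency disc `|w| <= r` is the
   plane `-vx*wx - vy*wy`; a Radon transform over that disc and the **Phase
   Motion Indicator** `PMI = max_theta \int |R(dphi/dt)/chord| drho = r^2 |v|`
   yield the motion angle, direction and speed, valid up to the phase
   aliasing bound `pi / r` px/frame (1.6 px/frame at the default
   `r = 5*pi/8`).

The package is aimed at computational neuroscientists and computer-vision
researchers who want a fully testable, self-contained reference
implementation: it ships a synthetic-video generator (seeded band-limited
textures, sub-pixel cubic-spline translation with ground-truth flow,
brightness/contrast staircases, photoreceptor saturation, additive noise),
the angular-error / end-point-error evaluation protocol, and benchmark
drivers for both the translation accuracy experiment and the five-decade
brightness-staircase cascade.

## Worked example

```r
library(dnpflow)

img  <- make_texture(seed = 0, size = 192)                 # seeded texture
seqv <- translate_sequence(img, v = c(0.6, 0.45),          # 0.75 px/frame
                           n_frames = 4, wrap = TRUE)       # at 36.9 deg
bank <- build_filter_bank()                                 # r = 5*pi/8
est  <- detect_motion(seqv, bank, pairs = 3,
                      centers = tidyr::expand_grid(y = seq(61, 131, 10),
                                                   x = seq(61, 131, 10)))
dplyr::summarise(est, detected = mean(detected),
                 mean_vx = mean(vx), mean_vy = mean(vy),
                 mean_speed = mean(speed),
                 mean_ae_deg = mean(angular_error(vx, vy, 0.6, 0.45)))
#> # A tibble: 1 x 5
#>   detected mean_vx mean_vy mean_speed mean_ae_deg
#>      <dbl>   <dbl>   <dbl>      <dbl>       <dbl>
#> 1        1   0.579   0.452      0.734        1.34
```

Every centre detects the motion; the recovered velocity (0.579, 0.452)
px/frame sits within a few percent of the true (0.6, 0.45) and the mean
angular error is 1.3 degrees. Gain-control quantities come from closed
forms and the adaptive fixed point:

```r
p <- dnp_params(a = c(0.1, 1, 1), cc = c(0.1, 1, 1))
steady_state_ff(1e12, p)          # normalized sigmoid saturates at 1
#> [1] 1
max_unaliased_speed(5 * pi / 8)   # phase-aliasing speed bound
#> [1] 1.6
ss <- adaptive_steady_state(make_texture(3, 64)[1:16, 1:16] * 20, dnp_params())
mean(ss$v)                        # adaptive feedback centres outputs
#> [1] 0.5
```

Benchmarks: `run_polar_benchmark()` translates a seeded texture over a
(direction, speed) grid and reports per-cell mean AE/EPE
(`tidy()`/`autoplot()` give the polar error maps);
`run_cascade_benchmark()` runs the five-decade brightness staircase through
a chosen first stage ("none" = static saturating photoreceptor, "adaptive"
= adaptive DNP) followed by an 8-bit sensor model, and reports per-level
detection rate and AE. A thin command-line front end over the same
functions is installed at `inst/cli/dnpflow`
(`simulate | gain-control | detect | cascade`).

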