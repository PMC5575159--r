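# emgnarx

Continuous, simultaneous decoding of multi-joint arm kinematics from
surface EMG with a small NARX recurrent network.

## What this is for

Myoelectric exoskeleton control needs joint-angle estimates that are
*continuous* (not gesture classes), *simultaneous* across joints, and
computable in real time from non-invasive signals. `emgnarx` implements
such a decoder for horizontal-plane arm movement: six muscle EMG
channels (anterior/posterior deltoid, biceps, triceps long head,
flexor/extensor carpi radialis) are reduced to linear envelopes and
mapped to shoulder, elbow and wrist angles by a nonlinear autoregressive
network with exogenous inputs (NARX).

The model: with envelopes $X_i$ and decoded angles $Y_j$ at the 20 Hz
decoding rate,

$$U_n(t) = \tanh\Big(\textstyle\sum_{i,k} A_{ni}(k) X_i(t-m-k)
 - \sum_{j,k} B_{nj}(k) Y_j(t-m-k) + b_{1n}\Big), \qquad
Y_j(t) = \textstyle\sum_n C_{jn} U_n(t) + b_{2j}$$

with 3 hidden tanh nodes, 1 input tap, 2 feedback taps and embedding
delay $m = 2$ — a prediction interval $\tau = m\Delta t = 100$ ms and
exactly **51 trainable parameters**. Training is Levenberg–Marquardt
(teacher-forced, with feedback noise injection, followed by closed-loop
refinement — see the methods vignette in `vignettes/`), and evaluation
is contiguous five-fold cross-validation scored by variance accounted
for:

$$\mathrm{VAF} = 100\,(1 - \mathrm{Var}(y-\hat y)/\mathrm{Var}(y)).$$

Because no recordings ship with the package, a synthetic arm plant
(`generate_trial()`) produces paired EMG/kinematics trials with known
ground truth: minimum-jerk reaching (range ≈ 90°, speed < 70°/s),
velocity-proportional reciprocal muscle drive leading motion by a 100 ms
electromechanical delay, and amplitude-modulated band-limited EMG
carriers.

## Worked example

```r
library(emgnarx)

## a 3-minute synthetic trial at 1000 Hz, then envelopes at 20 Hz
trial <- generate_trial(arm_plant_config(seed = 7))
env   <- preprocess_trial(trial)

## five-fold contiguous CV, closed-loop decoding at tau = 100 ms
cv <- cross_validate(narx_config(), env, narx_options(seed = 1),
                     mode = "closed_loop")
cv
#> 5-fold contiguous cross-validation (closed_loop mode), tau = 100 ms
#>       shoulder elbow wrist
#> fold1    93.75 99.51 99.02
#> fold2    99.08 99.11 98.21
#> fold3    98.80 99.64 99.46
#> fold4    99.44 98.40 98.36
#> fold5    99.10 99.12 98.47
#> mean VAF (%): shoulder 98.03 +/- 2.41, elbow 99.15 +/- 0.48, wrist 98.70 +/- 0.52

## are the joints decoded equally well?
rm_anova(cv$vaf_table)
```

Each row is one held-out 36 s segment; a VAF of 99 means the decoder,
driven only by EMG after a 200 ms seed, reproduces 99% of the measured
angle variance of that segment. Joint-wise mean VAF above 98% on all
three joints is the pipeline's headline operating point at the 100 ms
prediction interval.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/decode.R simulate --seed 7 --out out/
Rscript inst/cli/decode.R cv --trial out/trial.csv --seed 1 --out out/
```

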