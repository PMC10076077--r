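# gazehmm

Unsupervised classification of eye-tracking samples into **fixations,
saccades, post-saccadic oscillations (PSOs) and smooth pursuits** with a
generative hidden Markov model — for eye-movement researchers who want
event labels without hand-tuned velocity thresholds.

Each gaze sample is described by three features: speed $v_t$ (deg/s),
acceleration magnitude $a_t$ (deg/s²) — both from Savitzky–Golay-filtered
derivatives of the gaze position — and the sample-to-sample direction
change $z_t \in [0, 2\pi)$. A hidden state $S_t \in \{1,\dots,k\}$
follows a Markov chain with initial probabilities $\rho$ and transition
matrix $A$, and conditionally on the state

$$v_t \sim \Gamma(\alpha^{v}_{S_t}, \beta^{v}_{S_t}), \quad
  a_t \sim \Gamma(\alpha^{a}_{S_t}, \beta^{a}_{S_t}), \quad
  z_t \sim \begin{cases}
    \mathrm{Uniform}(0, 2\pi) & S_t = 1 \text{ (fixation)}\\
    \mathrm{vonMises}(\mu_{S_t}, \kappa_{S_t}) & S_t \ge 2
  \end{cases}$$

Parameters are estimated per recording by EM (exact weighted M-steps,
C++ forward–backward), states are decoded with Viterbi, and heuristic
postprocessing rules clean up implausibly short events. Blinks and other
missing samples are integrated out of the likelihood (density one) and
labeled `noise` in the output. Candidate numbers of states are compared
with BIC/ICL model weights. The package also contains the generative
simulator and the parameter-recovery study harness (RMdSPD, Cohen's
kappa, recovery regressions, label-switch resolution) used to validate
the estimation machinery.

See `vignettes/gazehmm-methods.Rmd` for the model, its assumptions and
all numerical conventions.

## Worked example

Classify a synthetic 500 Hz recording — five 0.4 s fixations separated
by 8° saccades with ~0.01° positional jitter:

```r
library(gazehmm)
set.seed(101)
fs <- 500; x <- c(); y <- c(); x0 <- 0
for (i in 1:5) {
  x <- c(x, x0 + cumsum(rnorm(200, 0, 0.01)))
  y <- c(y, cumsum(rnorm(200, 0, 0.01)))
  if (i < 5) {
    ramp <- (1 - cos(seq(0, pi, length.out = 20))) / 2
    x <- c(x, x0 + 8 * ramp); y <- c(y, rep(tail(y, 1), 20)); x0 <- x0 + 8
  }
}
gaze <- data.frame(t = (seq_along(x) - 1) / fs, x = x, y = y)

res <- gazehmm(gaze, fs = 500, n_states = 2)
res
#> gazehmm classification (2 states)
#> Gaze recording: 1080 samples at 500 Hz (2.158 s), 0 blink, 0 missing
#> log-likelihood -1637.8304 (converged)
#> sample labels:
#>
#> fixation  saccade    noise
#>      963      107       10
#> 11 events

event_descriptives(res$events)
#>       type n mean_duration sd_duration
#> 1 fixation 5        0.3852 0.003033150
#> 2    noise 2        0.0090 0.001414214
#> 3  saccade 4        0.0535 0.004434712
```

The five constructed fixations come back with mean duration 0.385 s
(0.4 s minus the filter-edge samples labeled `noise` at the recording
boundary), and the four saccades with mean duration 53.5 ms — the 40 ms
ramps plus the smoothing spread of the 20 ms derivative filter. Fitted
parameters, reported on the raw deg/s scale:

```r
round(coef(res, scale = "raw")[c("alpha_vel_1", "beta_vel_1",
                                 "alpha_vel_2", "beta_vel_2",
                                 "a_11", "a_22")], 3)
#> alpha_vel_1  beta_vel_1 alpha_vel_2  beta_vel_2        a_11        a_22
#>       3.029       0.667       1.110     134.702       0.996       0.963
```

State 1 (fixation) has mean velocity $\alpha\beta \approx 2$ deg/s,
state 2 (saccade) ≈ 150 deg/s, and both states are sticky
($a_{ii} > 0.96$), as expected for events lasting many samples. Other
entry points:

```r
cmp <- compare_models(res, k_list = 1:3)   # BIC/ICL weights across k
study <- run_recovery_study(part1_design(2, n_reps = 10), seed = 1)
recovery_rmdspd(study)                     # parameter-recovery summary
```

A thin command-line wrapper for shell use is installed at
`inst/cli/gazehmm-cli.R` (subcommands `classify`, `compare`, `recover`).

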