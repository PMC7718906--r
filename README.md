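# vemg

Voluntary-EMG extraction and proportional control under functional
electrical stimulation (FES).

Surface EMG recorded from a stimulated muscle is buried under two
stimulus-locked artifacts — the one-sample transient stimulation pulse
and the m-wave (the evoked compound muscle action potential) — with
peaks around 100x the RMS of the voluntary EMG (vEMG) underneath.
`vemg` extracts the vEMG in software and closes the loop: the extracted
signal modulates the stimulator's pulsewidth, so FES intensity follows
the user's own residual effort. The intended users are
neurorehabilitation-engineering researchers building or evaluating
EMG-controlled FES systems.

## The method

Two causal filters in series, at sampling rate `Fs = 1000` Hz and
stimulation frequency `f = 25` Hz:

* **Comb filter** `x_c(n) = x(n) + b x(n − L)` with `b = −1` and
  `L = Fs/f = 40` samples: exact nulls at the stimulation frequency and
  its harmonics, cancelling the strictly periodic pulse artifact.
* **Frame-based adaptive least-squares filter**
  `y(n) = x_c(n) − Σ_{i=1..M} b_i x_c(n − iL)`, frames of `L` samples
  (40 short / 80 long), `M = 6` previous frames. The coefficients are
  re-fitted for every frame by ridge-regularized least squares (LU
  factorization): the quasi-periodic m-wave is predictable from the
  previous frames and is subtracted; the broadband vEMG is not, and
  remains.

Around the filters: a synthetic worst-case recording generator
(band-limited Gaussian vEMG + pulses + stochastic m-wave train with
`alpha = 200 ± 20`, `tau = 20 ± 5` samples), frequency-domain
characterization of the averaged filter (equivalent FIR, group delay,
effective delay including the one-frame buffering latency), evaluation
metrics (muscle response index, power reductions, Welch
magnitude-squared coherence with its analytic 95% confidence limit),
and the proportional controller (power envelope → MVC-normalized
reference → intent detection → pulsewidth with the slew recurrence
`p_a[n] = p_a[n−1] + sign(p_c[n] − p_a[n−1])·η`, `η = 0.1` µs/tick).

## Worked example

Run the five-variant simulation study — one 35 s worst-case recording,
filtered by comb+adaptive and adaptive-only at both frame lengths and
by the comb alone, each scored against the clean vEMG:

```r
library(vemg)
study <- run_simulation_study(seed = 1)
study
#>          variant mri_x_db mri_y_db pr_clean_db pr_artifact_db avg_coherence coherence_conf95
#> 1     both-short   -31.64   -2.869       2.316         -29.33        0.4706          0.08678
#> 2 adaptive-short   -31.64   -3.008       2.463         -29.18        0.4574          0.08678
#> 3      both-long   -31.64   -6.342       6.216         -25.43        0.3727          0.08678
#> 4  adaptive-long   -31.64   -4.248       4.118         -27.52        0.3954          0.08678
#> 5           comb   -31.64  -15.575      15.573         -16.07        0.8180          0.08678
```

Reading the rows: `mri_x_db` scores the contaminated input (≈ −32 dB —
the artifact utterly dominates), `mri_y_db` the filter output (0 =
perfect). The adaptive variants recover the vEMG to within a few dB and
their extractions are strongly coherent with the clean signal
(`avg_coherence` far above the 0.087 significance limit for 34
segments); the comb alone leaves ~16 dB of m-wave residual. Note that
on flat-band *synthetic* vEMG the comb-only coherence is high — see the
methods vignette (`vignettes/extracting-voluntary-emg.Rmd`) for why
that column behaves differently on real recordings.

Delay accounting for the short filter — pass-band group delay 9 samples,
stop-band 73, plus one 40-sample frame of buffering:

```r
effective_delay(9, 73, L = 40, fs = 1000)
#>   min_samples max_samples min_ms max_ms
#> 1          49         113     49    113
```

A command-line surface over the same functions is installed at
`inst/cli/vemg` (subcommands `simulate`, `filter`, `characterize`,
`evaluate`, `study`, `control`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","vemg",package="vemg"))')" \
  study --seed 7
```

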