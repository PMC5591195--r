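# smSweep

Simulation, decoding and kinetic analysis of **mirror-swept
single-molecule fluorescence movies**.

Camera-based single-molecule imaging is limited to 50–100 frames per
second, and cropping the field of view to go faster sacrifices the
number of molecules observed. Stepping a galvo mirror N times during one
camera exposure spreads each molecule into N laterally offset spots, so
one frame carries N time points per molecule: a 20-ms exposure with
N = 5 steps yields 4-ms resolution over the full chip (Δt/N). The
adjacent-spot spacing is `slope × V / (N − 1)` pixels (slope
0.25 pixel/mV) and decoding is unambiguous when it is at least about
twice the PSF FWHM.

The package is written for single-molecule biophysicists who want to
prototype, validate, or run this encoding:

* **Simulator** — two-state telegraph kinetics (photoblinking with rates
  `k_on`, `k_off`; transient DNA binding; two-state FRET with
  efficiencies `E_1`, `E_2`) rendered as EMCCD movies: pixel-integrated
  Gaussian PSFs, Poisson photons, Gamma EM gain, read noise, a 30:70
  conventional/swept beamsplitter or donor/acceptor dual channel.
* **Decoder** — spot detection with sub-pixel Gaussian refinement,
  bead-based affine channel mapping, 7 × 7 sliding-window extraction
  with background subtraction and neighbour-spot crosstalk
  compensation, overlap filtering over the swept footprint.
* **Kinetics** — blinking autocorrelation fitted with
  `(k_off/k_on)·exp[−(k_on + k_off)t]`; threshold (`I_B + 3σ_B`) dwell
  detection with censoring-aware exponential maximum likelihood
  (`τ_on = 1/k_off`); FRET proximity ratio `E = I_A/(I_D + I_A)` with
  background and leakage correction; two-state Gaussian hidden Markov
  model (Baum–Welch + BIC + Viterbi) with exact discrete-time rate
  inversion.

## Worked example

Simulate fast photoblinking (mean off-time 4.6 ms, i.e. `k_on`
= 217 s⁻¹, `k_off` = 80 s⁻¹), decode the swept movie, and recover the
rates from the autocorrelation of the 4-ms traces:

```r
library(smSweep)

cfg <- sweep_config(n_steps = 5, voltage_mV = 96)
cfg
#> <sweep_config> N = 5 steps, V = 96 mV, slope = 0.25 px/mV
#>   exposure 20 ms + lag 1.7 ms; substep 4 ms; sweep 24 px; spacing 6 px

sim <- simulate_scenario("blinking", n_frames = 500, seed = 42,
                         n_molecules = 10)
sim$stack
#> <frame_stack> 500 frames of 110 x 88 px, exposure 20 ms
#>   channels: conventional | swept

dec <- decode_stack(sim$stack)
dec$traces[[1]]
#> <spot_trace> 2500 samples (500 frames x 5 substeps of 4 ms)
#>   I_B = 5461, sigma_B = 274.6 per 7x7 window

acf_avg <- blinking_acf(dec$traces, max_lag = 15, frame_lag_ms = 1.7)
fit <- fit_blinking_acf(acf_avg$acf, acf_avg$lags_ms,
                        binning_correction = TRUE, bin_ms = acf_avg$bin_ms)
fit
#> <acf_fit> k_on = 213.7 /s (off-time 4.68 ms), k_off = 84.9 /s (on-time 11.8 ms)
#>   amplitude k_off/k_on = 0.3972, decay 298.6 /s (finite-bin model)
```

The decoded 4-ms traces recover the simulated off-time (4.68 ms vs the
configured 4.61 ms) from a movie whose frame time is 20 ms — the
information a conventional readout of the same camera cannot resolve.
The same movie's traces, block-averaged back to 20 ms, show fewer than a
tenth as many detected dark events.

Binding kinetics and FRET work the same way (see the methods vignette in
`vignettes/`): `simulate_scenario("binding", ...)` →
`detect_dwells_threshold()` → `fit_dwell_histogram()`, and
`simulate_scenario("fret", ...)` → `decode_fret_stack()` →
`fret_efficiency()` → `fit_two_state_hmm()` / `pool_hmm_rates()`.

## Command line

A thin launcher is installed at `exec/smsweep`:

```sh
SMSWEEP=$(Rscript -e 'cat(system.file("exec", "smsweep", package = "smSweep"))')
Rscript "$SMSWEEP" simulate --scenario blinking --n-frames 200 --seed 7 --out run1
Rscript "$SMSWEEP" decode --stack run1/stack.tif --out run1/decoded
Rscript "$SMSWEEP" analyze-blinking --traces run1/decoded/traces.csv \
    --substep-ms 4 --out run1/blinking.json
```

Movies travel as 16-bit multi-page TIFF plus a JSON sidecar (config,
layout, seed); every command writes a provenance record and identical
seeds give bit-identical outputs.

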