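# dcse — Dual-Channel Speech Enhancement for Cochlear-Implant Front Ends

Cochlear-implant (CI) users need 5–15 dB of signal-to-noise ratio for 50 %
sentence understanding, while everyday environments offer roughly 5–10 dB —
and a single directional interferer (a lecturer, a screen, a passing talker)
is the typical offender. `dcse` implements a two-microphone front-end
enhancement algorithm designed for the CI size constraint (two omnidirectional
microphones ~1 cm apart): it suppresses one directional noise source while
preserving frontal speech, and feeds the result to a CIS (continuous
interleaved sampling) sine-vocoder stage that models the implant's own
processing. It is aimed at auditory-prosthetics and speech-enhancement
researchers who want a tested, reproducible reference implementation with a
matching synthetic-scene simulator and evaluation metrics.

## The algorithm

With speech `s(t)` from azimuth θ ≈ 0° and noise `n(t)` from azimuth φ,
the microphones record

```
MIC1(t) = s(t) + n(t)
MIC2(t) = s(t − d/c·cosθ) + n(t − d/c·cosφ)
```

where `d` is the spacing and `c` the sound speed. Two first-order
differential channels are formed with a cross delay of `d/c`
(1.297 samples at 44.1 kHz, realized by a 4th-order maximally-flat /
Lagrange FIR fractional-delay filter):

```
ch1(t) = MIC1(t) − MIC2(t − d/c)      # null toward the rear (180°)
ch2(t) = MIC2(t) − MIC1(t − d/c)      # null toward the front (0°)
```

`ch2` carries essentially no frontal speech, so during noise-only frames —
detected by a cepstral-distance detector with template update weight
β = 0.85 — the per-bin power ratio

```
E|CH1|² / E|CH2|²  ≈  cot⁴(φ/2)
```

(the **directivity coefficient**) measures the interferer's azimuth and is
tracked recursively so it follows a moving source. Each frame's speech
magnitude spectrum is then estimated by directivity-weighted power
subtraction,

```
|Ŝ(ω)| = sqrt( max(0, P₁(ω) − r(ω)·P₂(ω)) ) / (2·sin(2πf·d/c))
```

where the `1/(2 sin(2πf d/c))` factor — λ(f), applied per CI filter-bank
band via 16 published adjusting coefficients (12.53 at 216 Hz down to 0.614
at 5148 Hz), or by a 1st-order Butterworth band-pass with a 30× (29.54 dB)
post-gain — compensates the differential array's low-frequency roll-off.
The enhanced signal is reconstructed by overlap-add (1024-point Hamming
frames, 50 % overlap) using the channel-1 phase.

Evaluation uses shadow decomposition (the mixture-derived gain mask applied
separately to the clean speech and noise components) to compute broadband
ΔSNR, plus a clean-power-weighted speech-distortion index.

## Worked example

```r
library(dcse)

geom <- array_geometry()          # d = 0.01 m, c = 340 m/s, fs = 44.1 kHz
delay_samples(geom)
#> [1] 1.297059

design_maxflat_delay(delay_samples(geom), 4)$taps
#> [1] -0.0400  0.6995  0.4434 -0.1220  0.0192

100 * response_error(design_maxflat_delay(1.297, 4), 0, 6000, 44100)
#> max_mag_err max_phase_err
#>       0.206         0.344        # percent, inside the 0.3 / 0.4 design band

# end-to-end: 0 dB tonal-music interferer at 90°, 3 s noise lead-in
res <- demo_run(seed = 1, dir = "demo_out")
print(res$fit)
#> <dcse_enhance> 5.20 s @ 44100 Hz | 446 frames (319 noise-only)
#>   directivity: scalar ratio 3629, median azimuth est. 90.0 deg
#>   compensation: band_table | phase: ch1
print(res$report)
#> <metrics_report> SNR in -7.10 dB -> out 14.06 dB | broadband dSNR 21.17 dB
#>   speech distortion index -7.57 dB
```

The input SNR is −7.1 dB because the whole 5.2 s session (including the
noise-only lead-in and tail) counts toward the noise energy while the 1.2 s
utterance is mixed at 0 dB over its own extent. The pipeline recovers a
21.2 dB broadband improvement, and the median directivity-trace azimuth
lands on the true interferer direction (90°). `demo_out/` holds the
two-channel scene, the enhanced and vocoded WAVs, per-frame diagnostics and
`report.json`.

The same stages are scriptable from a shell via the bundled CLI
(`inst/cli/dcse`): `simulate`, `enhance`, `vocode`, `evaluate`, `demo`.

```sh
Rscript inst/cli/dcse simulate --noise-azimuth 120 --snr-db 0 --seed 3 --out-prefix scene
Rscript inst/cli/dcse enhance  --in scene_mics.wav --out enhanced.wav --dump-diagnostics diag.json
Rscript inst/cli/dcse evaluate --scene-prefix scene --enhanced enhanced.wav --report report.json
```

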