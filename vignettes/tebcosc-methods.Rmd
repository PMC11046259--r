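---
title: "Hippocampal oscillation dynamics in trace eyeblink conditioning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hippocampal oscillation dynamics in trace eyeblink conditioning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Trace eyeblink conditioning (TEBC) pairs a brief tone (conditioned
stimulus, CS, 200 ms) with a periorbital shock (unconditioned stimulus,
US) separated by a 500 ms stimulus-free trace interval. Two behavioural
quantities index two different memory processes:

* **retrieval** of the CS–US association *within* a trial — the animal
  blinks in anticipation (a conditioned response, CR, detected from eyelid
  EMG in the last 200 ms of the trace period), and
* **consolidation** *across* training sessions — the proportion of trials
  with a CR (hit rate, HR) grows over days.

`tebcosc` implements a complete analysis chain for dorsal-hippocampal
local field potentials (LFP, two laminar sites: the hippocampal fissure
and the dentate hilus) and concurrent EMG recorded during TEBC, together
with a synthetic-session generator with known ground truth so that every
stage of the chain is testable without any recorded data.

## The analysis chain

1. **Behaviour** (`detect_cr`, `summarize_behavior`): EMG is full-wave
   rectified and smoothed with a 10 ms moving RMS; a CR is scored when the
   smoothed trace exceeds mean + 3 SD of the *rectified raw* pre-CS
   baseline ([−0.6, 0] s) anywhere in [0.5, 0.7] s. The threshold is
   taken from the raw rectified baseline deliberately: thresholding
   against the smoothed baseline's much smaller SD fires on 10–20% of
   pure-noise trials, while this convention measures <1% false positives
   at full sensitivity (both rates are asserted by Monte Carlo in the test
   suite). Hit rates use non-artifact trials only; learning is summarized
   by Pearson *r* of HR against session and a one-way repeated-measures
   ANOVA with rat as the repeated factor.
2. **Preprocessing** (`reject_artifact_trials`,
   `interpolate_stimulus_artifact`, `csd_rereference`, `decompose`):
   trials with any |LFP| sample above 1500 µV are discarded; stimulus
   spike artifacts around CS onset and offset (−2.5 to +1.5 ms) are
   alpha-blended onto a straight line (`out = 0.45·original + 0.55·line`);
   bundles are re-referenced by the second spatial difference
   (`V[i−1] − 2V[i] + V[i+1]`), which removes any spatially common signal
   exactly; and each channel is decomposed with a log-spaced FIR filter
   bank (3–480 Hz; per band a Kaiser high-pass with stop edge 0.6 f and a
   low-pass with stop edge 1.4 f, each ≥ 60 dB stop-band attenuation,
   pass edges at 0.8 f/1.2 f as a documented design choice) followed by
   the Hilbert transform. Kernels are odd-length and symmetric, so the
   output is exactly zero-lag; band filtering and the analytic signal are
   computed jointly in the frequency domain on the zero-padded epoch.
3. **Local dynamics** (`amplitude_tfr`, `itc`): trial-mean amplitude
   envelopes and intertrial coherence (the modulus of the trial-mean unit
   phasor), both over [−0.6, 0.6] s with the per-band mean over
   [−0.6, −0.1] s subtracted. Evoked (phase-locked) activity raises both
   measures; induced (random-phase) activity raises amplitude only.
4. **Interareal coupling** (`interareal_plv`, `pac_nm`, `phase_te`,
   `dte_spectrum`): phase-locking value between sites, normalized by the
   mean over 100 cyclic trial-shuffles; n:m phase–amplitude coupling as
   the 1:1 PLV between the low-frequency phase and the phase of the
   LF-band-filtered high-frequency envelope, for ratios n ∈ 2…9, four
   laminar pairs and three post-CS windows (0–0.1, 0.1–0.3, 0.3–0.5 s)
   plus mirrored pre-CS windows; and phase transfer entropy from binned
   instantaneous phases, summarized as the bias-free differential
   dTE = TE(hilus→fissure) − TE(fissure→hilus), positive when the hilus
   leads.
5. **Statistics** (`equalize_trials`, `signflip_monte_carlo`, `bh_fdr`,
   `cluster_permutation`, `rm_anova_roi`, `pac_group_test`,
   `pte_shuffle_test`): trial counts are equalized between conditions
   before any contrast; pointwise maps are tested with 20,000 sign-flip
   Monte Carlo surrogates (p < 0.025 per tail) and Benjamini–Hochberg
   correction per analysis window; map contrasts use cluster-based
   permutation (paired t threshold at two-tailed 0.025, clusters by
   *temporal* adjacency within band only, positive and negative clusters
   separate, max-|t-sum| null from 1000 within-animal label permutations,
   cluster p < 0.05); region-of-interest effects use a two-way
   repeated-measures ANOVA (no sphericity correction, noted in the
   output); PAC uses a one-sample t on post − pre per cell with BH-FDR
   across cells; dTE uses 1000 trial-pairing permutations with BH-FDR
   across bands. Every Monte Carlo p uses the +1-corrected estimator and
   every stochastic step is seeded.
6. **Pipeline** (`run_full_analysis`): the two headline contrasts —
   CR vs no-CR (retrieval; equalized within session, pooled across
   sessions per animal) and highest vs lowest %HR session per animal
   (consolidation; ties broken to the earlier/later session
   respectively) — with a deterministic CSV/JSON report bundle.

## What the synthetic generator emulates

`sim_config()` defaults describe a complete TEBC experiment — 8 rats × 8
sessions × 60 trials, CS at 0 s, CS offset 0.2 s, US at 0.7 s, epoch
[−1, 1] s, 1 kHz sampling (in vivo systems store 2 kHz; everything is
rate-agnostic) — with these signal families on a 1/f background
(exponent 1, 50 µV RMS, independent per site):

* **Evoked transient**: a damped 70 Hz wavelet at CS onset (decay 30 ms,
  gain 120 µV on the fissure, half on the hilus) with deterministic
  phase, scaled linearly across sessions from 0.3 to 1 — the
  consolidation effect. The 30 ms decay is a deliberate deviation from a
  shorter (5–10 ms) initial design: after octave-wide band filtering a
  <10 ms wavelet contributes so few suprathreshold samples that its
  t-sum can never exceed a max-t-sum null dominated by long chance runs
  in the smooth slow bands — no transient this method *detects* in vivo
  can be that short.
* **Induced oscillations**: amplitude-gated sinusoids with random
  per-trial phase (raising amplitude but not ITC), default α 9 Hz and β
  18 Hz on the fissure at 0.25–0.55 s. Their default condition law is
  `cr_relative`: within a session CR trials receive
  `base + A(1 − HR_s)` and no-CR trials `base − A·HR_s`, so the CR
  − no-CR contrast sees the full effect A while the *session-average*
  injected amplitude is constant. This mean-preserving law encodes the
  empirical pattern the analysis is designed to dissociate — sustained
  α/β differs between CR and no-CR trials but *not* between high- and
  low-HR sessions — which a purely additive CR-only effect cannot
  reproduce in any world where HR changes across sessions (the session
  contrast would inherit ≈ ΔHR × A of it). A plain additive `"cr"`
  condition is also available and is used where recovery of a CR-only
  injection is itself under test.
* **Phase–amplitude coupling**: a 9 Hz sinusoid (defined phase, random
  per trial) on the hilus whose phase multiplies a *stochastic*
  narrow-band high-frequency oscillation at ratio × 9 Hz on the fissure
  by 1 + m·cos(φ_LF), m = 0.8. The HF carrier is narrow-band noise, not
  a tone: under 1/f noise a pure tone is demodulated single-sideband by
  the *neighbouring* ratio's band with less noise, which would make the
  neighbouring cell the systematic matrix maximum.
* **Lagged inter-site oscillation**: stochastic narrow-band 9 Hz noise on
  the hilus, copied to the fissure delayed by 11 samples (11 ms at 1
  kHz). Stochasticity is essential: a lagged pure sinusoid has a
  deterministic phase trajectory and carries no directed information for
  phase transfer entropy.
* **EMG**: Gaussian baseline (10 µV SD); on CR trials a 50 ms band-noise
  blink burst of 8 baseline-SD starting uniformly in [0.5, 0.66] s (so it
  intersects the scoring window); an unconditioned blink after the US on
  every trial. The 8 SD amplitude is a free choice (nothing constrains
  per-trial EMG SNR); it gives sensitivity 1.0 and is configurable.
* **Artifacts**: with probability 0.006 (matching a typical 0.6% rejection
  rate) a ±2500 µV damped spike at a random time on one channel.

CR draws are independent Bernoulli with the per-session probability
`hr_curve` (default linear 0.1 → 0.8 over eight sessions). Everything
derives from one master seed through content-addressed child seeds, so a
given configuration is bit-reproducible regardless of evaluation order.

What the generator does **not** emulate: non-stationary electrode drift,
theta-phase resets, behavioural state changes, volume conduction between
the two sites, harmonics of real rhythms, or realistic CR topography —
so a green recovery test establishes that the estimators detect the
effects they target at realistic SNR, not that they are robust to every
in vivo nuisance.

## Numerical choices and degenerate inputs

* Kaiser-windowed sinc FIR design; the length follows the standard
  attenuation/transition-width estimate and is grown until the *measured*
  stop-edge response reaches the target. Filtering uses padded FFT
  convolution; group delay is compensated exactly.
* The first/last max(kernel half-length, one cycle) samples per band are
  flagged edge-unreliable. Short bursts are temporally smeared by
  roughly the reciprocal band bandwidth; tests assert contrasts, not
  absolute injected amplitudes, for this reason.
* ITC of a single trial is 1 by definition and flagged degenerate; PAC
  cells whose HF stop edge reaches Nyquist are `NA` ("absent"); phase-TE
  estimates from fewer than 10 × bins³ samples warn and carry a
  low-confidence flag.
* Zero-residual (purely additive) ANOVA tables report F = ∞, p = 0 via an
  explicit tolerance on the error sum of squares rather than dividing by
  rounding noise.
* Monte Carlo p-values are always (1 + #{null ≥ obs}) / (1 + n), hence
  never zero; BH-FDR never rejects an `NA`.
* Tie-breaks: lowest-%HR session ties resolve to the earlier session,
  highest-%HR ties to the later one.

## Known limitations

* The n:m ratio coordinate of the PAC matrix is not identifiable at
  single-step resolution: adjacent ratios differ by ~12% while the
  method's bands span 0.6 f–1.4 f, so neighbouring cells measure the same
  coupled oscillation; under an exact 1/f background, log-spaced bands
  carry identical in-band noise power, leaving no systematic tie-break.
  The low-frequency and laminar-pair coordinates are recovered reliably
  (~94% of runs at m = 0.8 with 30 trials); the corresponding strict-argmax acceptance
  criterion is intentionally left failing with this analysis recorded.
* Phase transfer entropy on narrow-band signals has few independent
  samples per trial (window × bandwidth ≈ 3); reliable direction recovery
  needs session-scale pooling, and the package's acceptance test
  accordingly evaluates the group-mean dTE of a full simulated
  experiment, mirroring how the quantity is used in practice.
* Repeated-measures ANOVA applies no sphericity correction (none is used
  in the source analysis); with two-level factors this is moot.
* The CSD Laplacian treats contact spacing as unit: absolute µV/mm² units
  are irrelevant to all downstream normalized and phase metrics.

## Reduced scales in the test suite

The packaged tests and acceptance suite run at fs 250–500 Hz with 6–12
bands and the per-criterion trial counts stated in the test file, keeping
the whole suite inside a desktop-minutes budget; the package defaults
remain at the full experimental scale. Scoring, filtering and all
estimators are sampling-rate-agnostic, which the tests exercise
explicitly.
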