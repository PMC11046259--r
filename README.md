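# tebcosc

Analysis of rat hippocampal oscillation dynamics during **trace eyeblink
conditioning (TEBC)** — for electrophysiologists who want a tested,
scriptable pipeline from raw LFP/EMG epochs to the statistics that
dissociate two memory processes:

* **retrieval** of the CS–US association within a trial, indexed by the
  conditioned response (CR) detected from eyelid EMG, and
* **consolidation** across training sessions, indexed by the growth of
  the hit rate (HR, the fraction of trials with a CR).

The package covers behaviour scoring, artifact handling, Laplacian (CSD)
re-referencing, a log-spaced zero-phase FIR filter bank with Hilbert
analytic signals, time–frequency amplitude and intertrial coherence
(ITC), interareal phase synchronization, n:m phase–amplitude coupling
(PAC), differential phase transfer entropy (dTE), and the full surrogate
and permutation machinery — plus a synthetic TEBC generator with known
ground truth, so every stage is testable without recorded data.

## The statistics at the core

With `A(f, t)` and `φ(f, t)` the Hilbert amplitude and phase of each
narrow band (FIR band-pass, stop edges 0.6 f and 1.4 f, ≥ 60 dB
attenuation, zero lag):

* **ITC** (phase-locking factor): `|⟨exp(i φ_trial)⟩_trials|` — 1 for
  perfect stimulus locking, ~`√π/(2√N)` for N random-phase trials.
* **PLV** between sites: `|⟨exp(i(φ_A − φ_B))⟩_trials|`, divided by its
  mean over 100 trial-shuffled surrogates.
* **n:m PAC**: 1:1 PLV between the low-frequency phase and the phase of
  the LF-band-filtered envelope of the band at `n·f_LF`, `n ∈ 2…9`, per
  laminar pair and analysis window.
* **Phase TE / dTE**:
  `TE(X→Y) = Σ p(y', y, x) log2[p(y'|y, x)/p(y'|y)]` from binned phases;
  `dTE = TE(hilus→fissure) − TE(fissure→hilus)`, positive when the hilus
  leads; tested against trial-shuffle surrogates.
* **Inference**: trial-count equalization, 20,000 sign-flip Monte Carlo
  surrogates (p < 0.025, two-tailed), Benjamini–Hochberg FDR per window,
  cluster-based permutation on temporal adjacency (paired-t threshold,
  max-|t-sum| null from 1,000 within-animal permutations, p < 0.05), and
  two-way repeated-measures ANOVA on regions of interest.

## Worked example

```r
library(tebcosc)

sim <- sim_config(n_rats = 4, n_sessions = 3, n_trials = 30, fs = 500,
                  epoch = c(-0.8, 0.8), evoked = list(freq = 40),
                  hr_curve = c(0.2, 0.5, 0.8), seed = 42)
exp <- simulate_experiment(sim)
tt  <- score_experiment(exp)           # CR detection on every EMG epoch
beh <- summarize_behavior(tt)

bank <- build_filter_bank(fs = 500, f_min = 4, f_max = 80, n_bands = 10)
rec  <- reject_artifact_trials(exp$recordings[[1]][[3]])
tfrs <- decompose(rec, bank)           # analytic signal per band/site

a   <- amplitude_tfr(tfrs$fissure, trials = which(tt$cr[tt$rat == 1 & tt$session == 3]))
plv <- interareal_plv(tfrs$fissure, tfrs$hilus, n_shuffles = 100, seed = 1)
dte <- dte_spectrum(tfrs$hilus, tfrs$fissure, n_bins = 8)
```

This prints (seed 42):

```
<tebc_experiment> 4 rats x 3 sessions x 30 trials @ 500 Hz
  true CR fraction: 0.469, artifacts: 0
mean RT 593.2 +/- 3.7 ms; HR~session r = 0.94; rm-ANOVA F(2,6) = 46.35, p = 0.00022
CR-trial 9 Hz amplitude rise at 0.3-0.5 s: 20.2 uV over baseline
normalized 9 Hz fissure-hilus PLV, 0.1-0.5 s: 1.97
dTE at 7.8 Hz: +0.072 bits (positive = hilus leads)
```

Reading: detected reaction times sit just before the US (the anticipatory
blink); HR rises across sessions exactly as programmed (rm-ANOVA session
effect p < 0.001); CR trials carry the injected induced 9 Hz amplitude;
the two sites phase-synchronize at 9 Hz well above their trial-shuffle
floor (normalized PLV ≈ 2); and dTE is positive, recovering the
programmed hilus→fissure lead.

The full two-contrast analysis (CR vs no-CR; highest vs lowest %HR
session) is one call:

```r
run <- run_full_analysis(run_config(sim = sim, f_min = 4, f_max = 40,
                                    n_bands = 8, seed = 7,
                                    out_dir = "tebc_out"))
print(run)   # significant clusters per metric/site/contrast
```

A command-line interface is installed at `exec/tebc`
(`tebc simulate|behavior|run --config cfg.json --seed N --out DIR`).

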