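---
title: "Modeling stimulus responsiveness during absence seizures: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling stimulus responsiveness during absence seizures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gaersim)
```

# What the package models

Absence seizures in the GAERS rat appear on the EEG as spike-and-wave
discharges (SWD): a rhythmic 7-12 Hz pattern with a sharp spike and a slow
wave per cycle, during which the animal is transiently unresponsive to
sensory input. `gaersim` implements the computational chain needed to study
this phenomenon end to end on synthetic data:

1. a conductance-based **mean-field model** of one cortical region (coupled
   excitatory regular-spiking and inhibitory fast-spiking AdEx populations
   with spike-frequency adaptation) that switches between
   asynchronous-irregular (AI, interictal) and SWD-like (ictal) dynamics as
   a function of a single parameter, the spike-triggered adaptation
   increment `b`;
2. a **whole-brain network** of such regions coupled by a directed
   connectome, stimulated with square-pulse sensory input, and scored with
   per-region responsiveness statistics;
3. **EEG event machinery**: band-pass/notch filtering, automated SWD
   detection with the study field's merging and minimum-duration rules, and
   an 8-way taxonomy of stimulation blocks relative to seizures;
4. an **fMRI GLM**: designs built from classified events convolved with
   three gamma basis functions, mass-univariate OLS, F/T contrasts,
   cluster-level correction, framewise displacement and motion scrubbing;
5. **synthetic-data generators** with exact ground truth for every stage.

# The mean-field model

Each population is summarized by its firing rate; the membrane-potential
statistics of a neuron receiving Poisson input at rates
$(\nu_e, \nu_i)$ through $K_e = 400$ excitatory and $K_i = 100$ inhibitory
synapses are computed in closed form (`conductance_stats()`): mean
$\mu_V$, fluctuation $\sigma_V$, autocorrelation time $\tau_V$, with the
adaptation current $W$ entering $\mu_V$ as a hyperpolarizing offset. The
population transfer function is semi-analytic,

$$F = \frac{1}{2\tau_V}\,\mathrm{erfc}\!\left(\frac{V_{thr}^{eff}-\mu_V}
{\sqrt{2}\,\sigma_V}\right),$$

with an effective threshold $V_{thr}^{eff}$ given by a second-order
polynomial in the normalized $(\mu_V, \sigma_V, \tau_V \mu_G / C_m)$ plus
one trilinear term (11 coefficients per population). The coefficients are
not hand-set: `fit_transfer_coefficients()` inverts the erfc relation at
each point of a Monte-Carlo single-neuron rate grid (a spiking AdEx neuron
under matched Poisson bombardment, `mc_neuron_rate()`) and least-squares
fits the polynomial. The shipped table
(`inst/extdata/transfer_coefficients.tsv`) achieves 4-6 Hz RMS against its
oracle over ~130 sub-saturation grid points; `analysis/01_fit_transfer.R`
regenerates it.

Rate dynamics follow first-order relaxation with time constant
$T = 5$ ms, an adaptation current $dW/dt = -W/\tau_w + b\,\nu_e$, and
additive Gaussian rate noise on the excitatory population. We deliberately
ship a **first-order** mean field (no covariance dynamics): the study-level
quantities are mean traces and block-averaged rates, which the second
moment does not change qualitatively.

## Choices that create the AI/SWD dichotomy

The calibration target is fixed: with everything else equal, a single
parameter `b` must separate a low-rate irregular state from a 7-12 Hz
spike-and-wave oscillation, because that is how the two brain states are
modeled. The shipped configuration achieves it with:

* **Depressed inhibition.** The fast-spiking oracle neuron has its spike
  threshold at -49 mV versus -50 mV for the excitatory cell, encoding the
  reduced cortical GABAergic efficacy hypothesized in this epilepsy model.
  This lets recurrent excitation transiently escape before inhibition
  catches up — the spike of the SWD cycle.
* **Refractory ceilings.** The transfer functions are bounded by the
  single-cell refractory limits (100 Hz for regular-spiking at
  $t_{ref} = 10$ ms; 400 Hz for fast-spiking at 2.5 ms). Beyond being
  physiology, the asymmetry guarantees that sustained runaway excitation
  cannot form a stable attractor: at extreme rates inhibition always wins.
  Without the ceilings, the threshold polynomial — evaluated far outside
  its fitted domain — admitted a spurious balanced state near 190 Hz that
  latched permanently once reached.
* **Adaptation timescale.** $\tau_w = 50$ ms puts the relaxation cycle
  (escape, adaptation build-up, collapse, recovery) at ~8 Hz. The SWD
  frequency is essentially $1/\tau_w$-scaled; slower recovery gives 4-5 Hz
  rhythms, the human rather than the rat phenotype.
* **Ambient drive** $\nu_{ext} = 0.5$ Hz and **rate noise** 0.02 Hz. The
  SWD cycle exists in a narrow window of mean drive (it collapses to a
  fixed point above ~1 Hz extra input); small noise keeps the AI state
  irregular without destroying the rhythm's spectral coherence.

With these in place, `analysis/02_scan_adaptation.R` runs the prescribed
calibration: scan `b` over {0, 100, 200, 300, 400} pA/Hz, label each
regime with `classify_regime()`, and fix the defaults as the largest AI
value (`b = 300`) and the smallest value whose spectral peak lies inside
7-12 Hz (`b = 400`, measured 8.0-8.5 Hz with oscillation index ~0.9 across
seeds). The transition is monotone: once SWD appears it never reverts at
larger `b`.

`classify_regime()` calls a trace SWD when the Welch-spectral power
fraction within ±1.5 Hz of the 1-20 Hz peak exceeds 0.4 **and** the
peak-to-trough excursion exceeds 5 Hz. The excursion floor separates the
regimes by an order of magnitude (AI excursions stay below ~2 Hz, SWD
cycles reach ~8-10 Hz); the oscillation index alone would be ambiguous
because the spike waveform puts harmonic energy inside the 1-20 Hz band.

## Spike, wave, and the LFP

The kernel-method LFP (`compute_lfp()`) is a weighted sum of the two
population rates convolved with unit-area Gaussian kernels; the inhibitory
amplitude is negative and larger ($A_i = -1.6$ vs $A_e = 1$). In the SWD
cycle this produces a sharp **negative deflection at the spike phase**
(when the inhibitory population surges) and a plateau during the silent
wave. Membrane hyperpolarization is deepest in the wave: the per-cycle
minima of $\mu_V$ coincide with the minima of $\nu_e$ to ~5 ms (tested at
15 ms tolerance), and they fall in the LFP's upper (plateau) half, a half
cycle away from the spike deflection. Tests assert exactly this phase
structure rather than naive trough-to-trough alignment, because the two
kinds of LFP minima (spike deflection vs wave plateau) are distinct
objects.

# The whole-brain network

Regions are coupled through the row-normalized connectome scaled by a
global gain `S`; long-range input is excitatory and reaches both
populations, and stimulation enters the target region the same way as a
square-pulse train (the study's two protocols, 3 Hz/166 ms light pulses
and 2 Hz/250 ms air puffs in 6 s blocks, are presets). Integration is
stochastic Heun at `dt = 0.1` ms (0.2 ms for the large 496-region runs;
regime labels are unchanged between the two), with per-region
counter-based noise streams so that a region's trajectory is bit-identical
whether or not other regions exist — this makes the zero-coupling
decoupling equivalence and the isolated-region invariance exact, not
statistical. Networks start from a settled single-node state; cold starts
can overshoot basins during the initial transient.

`S = 0.05` is deliberately small: the SWD cycle tolerates only ~0.5 Hz of
added mean drive, and row-normalized coupling contributes $S \bar\nu$ of
it. At 0.05 the coupled ictal network keeps a coherent ~7 Hz rhythm; at
0.2 it sits at a fixed point and the whole ictal phenotype disappears.

## Responsiveness statistics

`responsiveness_map()` runs jittered stimulation trials (gaps of
20 + U(0,6) s, mirroring manually initiated stimulations and avoiding
phase-locking to slow network modes) and computes, per region, the paired
difference of mean excitatory rate between each 6 s block and the
preceding 6 s baseline, tested with a paired t across trials and
Benjamini-Hochberg correction. A region counts as **responsive** only if,
in addition, its mean rate change reaches the region's own ongoing
fluctuation scale (the median within-baseline temporal SD). The second
criterion is the operative definition of "the stimulus alters the ongoing
dynamics": during SWD the network entrains weakly to periodic input,
producing small but trial-consistent mean shifts that a plain t-test flags
in every region even though they are buried an order of magnitude below
the ongoing rhythm. Without the floor the statistical map comes out
*backwards* (more "significant" regions ictally than interictally).

At the shipped stimulus amplitude (20 Hz drive), the interictal stimulated
region responds at ~34 times its ongoing fluctuation; the ictal one stays
below its floor (measured 2.8 vs 3.4 Hz). Stronger stimuli (≥ ~50 Hz)
trigger transient population bursts in both states and are deliberately
not the default: they probe a different question (can a strong stimulus
break the rhythm) than the study's (is a sensory-scale stimulus
processed).

# EEG events

`preprocess_eeg()` applies a 50 Hz notch and a 1-90 Hz Butterworth
band-pass, both forward-backward with odd-reflection padding (plain
zero-phase filtering leaves edge transients that dwarf the notch
specification). `detect_swd()` automates the study field's manual
criteria: 0.5 s windows at 50% overlap are flagged when the 7-12 Hz power
fraction exceeds 0.3 and the window amplitude reaches twice (inclusive)
the rolling baseline amplitude (median over ±5 s of non-SWD-like windows);
flagged runs are merged when separated by under 1 s of baseline and kept
only if at least 2 s long — so no reported interval is ever shorter than
the minimum absence-seizure duration. On generator fixtures the detector
recovers every scheduled epoch to within one window hop (0.25 s) with no
false positives on seizure-free traces.

`classify_stimulations()` assigns each block exactly one of the eight
labels, with precedence: ended-seizure (seizure terminates within 0-2 s of
block onset), fully-inside, started-during (>50% vs ≤50% inside),
started-before (same split), right-after-seizure (onset within 2 s after
a seizure end; this window is not defined in the source field and is a
configurable choice), baseline. Exact 50% overlaps go to the
"mostly outside" branch.

# fMRI GLM

Effects of interest — interictal stimulation, ictal (fully-inside)
stimulation, stimulation that ended a seizure, and seizures without
stimulation — are each convolved with **three gamma basis functions**
(unit-peak gamma densities; defaults peak at 2, 4 and 6 s, the early rat
hemodynamic response) giving three regressors per condition; intermediate
block labels, six motion parameters and an intercept enter as confounds of
no interest. Fitting is mass-univariate OLS with unbiased residual
variance; F-contrasts jointly test a condition's three betas and
difference contrasts weight matched basis columns +1/-1, with the
first-basis T map providing direction.

Cluster correction thresholds the voxelwise F map (p < 0.01), forms
26-connected clusters, and compares the maximum cluster size with a
model-based null: per-voxel AR(1) parameters estimated from full-model
residuals, fresh noise simulated onto the confounds-only fit, full model
refitted (999 draws by default; tests use fewer). Two superficially
attractive resampling schemes fail structurally for periodic block
designs: circularly shifting the *regressors* leaks the periodic signal
into the null (inflating it ~25-fold), while circularly shifting
*residuals* preserves frequency content exactly and therefore keeps the
residuals' engineered orthogonality to the design (deflating the null).
The AR(1) bootstrap reproduces the suprathreshold-count distribution of
fresh null data. Serial correlation is ignored in the OLS point estimates
(classical approach); with AR(1) noise of the generator's default 0.3 the
cluster FWE is mildly anti-conservative (~0.1 at nominal 0.05 on 150-frame
desk-scale runs, an AR-estimation small-sample effect), and exact on white
noise — the type-I property tests run on white noise and the limitation is
stated here rather than hidden.

Framewise displacement sums absolute motion-parameter differentials with
rotations converted to millimeters; both the standard conversion
(radius x radians) and the source field's verbatim "divide degrees by the
5 mm radius" are implemented, because the quoted formula is dimensionally
anomalous; the default is the standard form. Motion scrubbing drops a
stimulation block when any of its frames exceeds 0.3% of the in-plane
voxel size — read literally as a fraction of the voxel edge (1.5 µm at
0.5 mm voxels), flagged as ambiguous and configurable.

# Synthetic data

All generators are pure functions of (parameters, seed):

* `make_connectome()`: modular log-normal-weight directed graphs with
  atlas-like labels (including `V1` and `S1BF`); 496 regions by default to
  match the atlas scale of the real analysis.
* `make_eeg()`: 1/f background **band-limited to 1-90 Hz** (so the
  generator's amplitude ratio and the detector's post-filter criterion
  share a reference) with harmonic spike-wave epochs at a set multiple of
  the background RMS; construction is checked at generation time.
* `make_stim_schedule()`: blocks separated by ≥ 20 s alternating ictal and
  interictal targets, with the intended state recorded as truth.
* `make_fmri()`: voxel series as beta-weighted convolved boxcars inside
  known ROIs plus AR(1) noise and motion spikes; defaults mirror a 45 min
  run at ~2 s volume time (1350 volumes) on a desk-scale 20x20x12 grid.

What the generators do **not** emulate: recorded SWD morphology (the
spike-wave shape is a harmonic stack, not a template), EEG gradient or
ballistocardiogram artifacts, MR physics, spatial autocorrelation of fMRI
noise, and hemodynamic forward modeling of the simulated rates. Passing
tests therefore demonstrate the correctness and calibration of the
*analysis chain*, not performance on real recordings.

# Problem sizes

The shipped tests and scripts use: 10-11 s single-node runs (1 kHz
effective sampling); 10 jittered trials per state for the 496-region maps
at dt = 0.2 ms; 120-300 volume fMRI runs on 10-16 voxel grids with 99-199
null draws; 1000-instance property sweeps for the event taxonomy. These
sizes were chosen so the full chain reruns comfortably on a laptop core.

# Known limitations

* The transfer polynomial is only trusted inside its fitted cone
  (inhibition/excitation ratio 0.25-4.5, W ≤ 600 pA); monotonicity holds
  strictly for excitation and within ~2.5 Hz (the fit's RMS scale)
  elsewhere in the cone, and is enforced physiologically at extremes by
  the refractory ceilings rather than by the polynomial itself.
* The SWD regime lives in a narrow ambient-drive window; large coupling
  gains or tonic drives quench it. This mirrors the fragility of the
  biological rhythm but means network experiments should keep `S` near its
  default.
* Cluster-level inference is exactly calibrated for white noise and mildly
  anti-conservative under strong serial correlation at short run lengths.
* Simulated statistical maps are computed on firing rates; no
  hemodynamic forward model links them to the GLM side quantitatively.
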