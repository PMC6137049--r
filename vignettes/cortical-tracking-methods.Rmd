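---
title: "Methods: simulating and measuring cortical tracking of the speech envelope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring cortical tracking of the speech envelope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechtrf)
```

# The scientific problem

When a listener hears continuous speech, low-frequency cortical activity
follows the slow amplitude modulations of the acoustic signal -- the
*speech envelope* -- a phenomenon called cortical tracking or
entrainment. In infancy this is of particular interest because
infant-directed speech (IDS), the exaggerated register caregivers use
with babies, differs acoustically from adult-directed speech (ADS):
slower syllable rate, deeper and slower utterance-level modulation,
larger pitch excursions. If IDS recruits attention more effectively,
its envelope should be tracked more faithfully by the infant cortex.

`speechtrf` implements the full measurement chain for a two-register
listening study on multichannel EEG -- forward temporal response
function (TRF) modelling with ridge regression, cross-validated EEG
prediction, theta-band spectral power with a repeated-measures ANOVA,
and cluster-mass permutation statistics -- together with a synthetic
data generator that implants a known stimulus-response coupling, so
every stage can be validated against ground truth without access to any
real infant recordings.

# The forward model

The simulated EEG at channel $c$ is

$$y_c(t) = g \sum_{\tau} k_c(\tau)\, s(t-\tau) \;+\; n_c(t) \;+\; a_c(t),$$

where $s$ is the nonnegative stimulus envelope, $k_c$ the ground-truth
kernel (the "true TRF") supported on lags 0--500 ms, $g$ a register-
specific coupling gain, $n_c$ spatially correlated $1/f^2$ background
noise, and $a_c$ occasional boxcar artifact bursts. The analysis-side
TRF estimator solves the ridge problem per channel

$$\hat w_c = (X^\top X + \lambda\, m\, I)^{-1} X^\top y_c,$$

with $X$ the time-lagged envelope design matrix (intercept column
unpenalized) and $m$ the mean diagonal of $X^\top X$ over lag columns.
Normalizing the penalty by $m$ makes $\lambda = 1$ comparable across
inputs of different scale; all defaults use $\lambda = 1$.

# The synthetic generator

**Envelope.** Syllables are modelled as Gamma-shaped pulses (shape 2)
arriving as a Poisson process, multiplied by a slow utterance-level
modulator (low-pass filtered Gaussian noise, rectified). The register
contrast is carried by three parameters chosen once to mirror the
acoustics of the two registers: pulse rate 2.9/s (IDS) vs 3.8/s (ADS),
matching the registers' word rates of 2.85 and 3.76 words/s; pulse
scale 60 vs 45 ms; modulator depth 0.9 vs 0.35 with cutoff 0.5 vs 0.8
Hz. Envelopes are standardized to unit variance, so the contrast is one
of spectral *shape*: at matched total variance the IDS setting always
carries more modulation power below 2 Hz (verified over seeds with zero
overlap in the tests).

**Kernel.** The temporal shape is biphasic: a positive raised-cosine
component of half-width 60 ms centred on the peak latency (default 85
ms) followed by a negative trough of half-width 80 ms at +120 ms. The
trough amplitude is 0.75 = 60/80 of the peak so the two phases have
equal area: the kernel integrates to approximately zero and the
nonnegative envelope produces no standing DC offset in the EEG -- a
property real auditory responses share and one that matters here
because the epoch-rejection rule works on absolute amplitude. Spatially
the kernel is weighted by a smooth gain field centred over the
left-frontal scalp (gain $0.15 + 0.85\, e^{-(d/0.8)^2}$ in great-circle
distance $d$), with a small seeded per-channel jitter. The peak
amplitude default is 2 µV per unit envelope, which at the default
signal-to-noise ratio yields background EEG in the realistic
tens-of-microvolts range, comfortably inside the ±100 µV rejection
bound.

**Noise.** Eight independent sources with amplitude spectrum
$1/\sqrt{f^2 + 1}$ (i.e. $1/f^2$ power above 1 Hz, flat below so drift
stays bounded) are mixed through smooth random scalp maps, plus 25%
independent sensor noise for full rank. `snr_db` fixes the noise floor
relative to the *unit-coupling* response variance. This deliberate
convention keeps the noise floor register-independent: lowering the
coupling gain lowers the effective SNR instead of quieting the noise.

**Registers and coupling.** The default gains are IDS = 1, ADS = 0,
with log-normal between-subject jitter (SD 0.15 on the log scale). The
ADS default sits at the detection floor on purpose: with a paired
max-mass permutation test across 12 subjects, the between-subject
variance of a per-channel prediction correlation is so small that any
common nonzero coupling is detected almost surely, so emulating the
qualitative study outcome -- a significant prediction cluster for IDS
and none for ADS -- requires the ADS register to carry no coherent
coupling. Users probing graded contrasts can set any nonnegative pair
of gains.

**Artifacts and bad channels.** Bursts arrive at `artifact_rate` per
minute (default 2), last 0.3--1 s, hit a contiguous group of 3--8
channels, and have 30 times the background noise SD -- well above both
the ASR detection threshold and the ±100 µV epoch-rejection bound, so
the two cleaning stages have a well-defined target. `bad_channel_count`
channels are replaced outright by high-variance white noise and flagged.

**What the generator does not emulate.** Acoustic realism of the
envelope (no pitch, no phonetic content), infant head geometry or
source-space leadfields (the layout is an idealized mirror-symmetric
spherical net), non-stationary arousal states, eye or cardiac
artifacts. Passing tests therefore show that the *analysis chain* is
correct and calibrated, not that it would behave identically on real
infant EEG.

# Preprocessing

Artifact subspace reconstruction self-calibrates on the cleanest 50% of
500 ms windows ranked by RMS (no separate baseline recording exists in
this design), then slides a 500 ms window with 50% overlap; per window,
principal directions whose variance exceeds $20^2$ times the
calibration variance along that direction are reconstructed from the
calibration statistics via $R = M\,(\mathrm{trunc}(V^\top M))^{+}
V^\top$ with $M$ the symmetric square root of the calibration
covariance. Windows are blended with raised-cosine overlap-add to avoid
boundary discontinuities; a window with no flagged direction passes
through bit-identically. Bad channels are then interpolated from their
6 nearest good neighbours with inverse-great-circle-distance weights
(nonnegative, summing to one, hence exact for spatially constant
fields).

The two analysis branches then follow the order each analysis lists:
the power branch downsamples to 250 Hz, cuts 1 s epochs from the
recording onset, rejects any epoch whose absolute amplitude exceeds 100
µV anywhere, and average-references the surviving epochs; the TRF
branch average-references, removes the periphery-flagged electrodes
(face/neck channels, conventionally discarded in infant work), and
downsamples to 128 Hz. Resampling is Fourier-domain (spectrum truncated
at the new Nyquist, inverse-transformed at length
$\lfloor n\,f_{new}/f_{old}\rfloor$): the implicit anti-aliasing filter
is a brick wall, and in-band amplitudes are preserved exactly up to
leakage.

# Power analysis

Spectra use a Hanning window of one epoch width with 50% overlap,
energy-normalized so summed per-bin power equals time-domain variance
for stationary signals. Overlapping segments are formed only within
runs of contiguous kept epochs -- overlap never straddles a rejected
epoch, which avoids synthesizing discontinuous data at the cost of a
few segments. Theta power (4--8 Hz, inclusive bin edges) is averaged
over the channels of each frontal region, and the register ×
hemisphere table is tested with a within-subjects ANOVA
(`Error(subject/(register*hemisphere))`), df (1, n−1) per effect.
Effect size is reported as partial eta squared,
$SS_{\rm eff}/(SS_{\rm eff}+SS_{\rm err})$ -- the variant is a package
choice since "eta squared" is ambiguous in a within design. Note that
with the default coupling contrast the synthetic theta power *does*
differ by register (the coupled response adds theta-band power), and
shows a left-hemisphere advantage inherited from the kernel's spatial
weighting.

# TRF estimation and prediction

The envelope is prepared by taking the magnitude of the analytic signal
(FFT Hilbert construction), band-pass filtering 1--8 Hz with a
3rd-order zero-phase Butterworth (applied forward-backward), and
resampling to 128 Hz. Filtering Hilbert-then-band-pass (rather than the
reverse) treats the 1--8 Hz interval as a property of the envelope, not
the carrier; the band-pass removes DC, so small negative excursions are
expected and harmless. In cross-validation the recording is split into
5 contiguous time folds (a fold must span at least 10 s); envelope and
EEG are z-scored with training-fold statistics, the design matrix is
built per contiguous segment so no training sample leaks across a fold
boundary, and the held-out fold is scored by per-channel Pearson
correlation, averaged over folds. Where a single-fit latency analysis
is reported (e.g. kernel recovery), the same conventions are used:
band-passed EEG, standardized band-passed envelope, $\lambda = 1$.

# Cluster-mass permutation inference

Pointwise paired (or one-sample) t statistics are thresholded at the
two-sided $\alpha = 0.05$ quantile of the $t_{n-1}$ distribution -- the
cluster-forming threshold is a package choice. Suprathreshold
same-sign points are grouped by spatial adjacency within each time
point and merged across consecutive time points sharing an electrode;
adjacency is great-circle distance below 1.6 times the layout's median
nearest-neighbour distance, which yields 4--8 neighbours per channel on
dense layouts. Each cluster's statistic is its mass (summed t). The
permutation null (condition-label swap or sign flip per subject, 1000
draws by default) is summarized by the *maximum absolute mass* per
draw, giving family-wise control; each observed cluster's p-value uses
the add-one rank rule $p = (1 + \#\{|\text{null}| \ge
|\text{mass}|\})/(N+1)$, counting ties conservatively, so p is bounded
below by $1/(N+1)$ and a cluster is significant at $p \le 0.05$, i.e.
in the top or bottom 2.5th percentile. Degenerate (zero-variance)
points yield NA and never enter clusters. One subtlety worth knowing:
after average referencing, a left-frontal effect reappears mirrored
with opposite sign on the remaining scalp, so a strong implanted
contrast legitimately produces two positive and two negative clusters
(early/late × frontal/mirrored).

# Problem sizes, determinism and numerical choices

Every random stage derives its seed from one master seed through a
fixed linear congruence (`child_seed`), making whole-pipeline runs
bit-reproducible; reports echo the full configuration and a config
fingerprint. Defaults simulate 12 subjects at 250 Hz with 64 channels
and 300 s per register; the validation suite exercises reduced sizes
chosen to keep each property measurable (e.g. 32 channels / 120 s for
the twenty-seed register-contrast replication, 16 channels for the
200-replicate calibration studies, 12 × 300 s at 128 Hz for kernel
recovery). These sizes are package choices balancing statistical
resolution against desk-scale runtimes. Ridge systems are solved by
Cholesky-backed `solve` on the (lags+1)² normal equations; ASR
pseudo-inverses use an SVD cutoff at $10^{-10}$ of the largest singular
value; eigenvalues are clipped at zero before matrix square roots.

# Known limitations

The ASR implementation is the offline, self-calibrating variant; it
does not model the calibration-free streaming case. The spherical
layout approximates a real sensor net's adjacency but not its exact
geometry, so electrode-level findings do not transfer to vendor channel
numbering. The generator's ADS-at-floor default means the register
contrast is qualitative; graded dose-response studies should set both
gains nonzero and expect both registers to reach significance at
realistic sample sizes. Envelope extraction assumes the input is either
broadband audio or an already-computed envelope; no source separation
or denoising of the audio is attempted.
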