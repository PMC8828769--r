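---
title: "sonopipe: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sonopipe: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonopipe)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters with their units
and defaults, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The experimental setting

Sonogenetics makes cells selectively responsive to focused ultrasound by
expressing a mechanosensitive channel (the flagship candidate being human
TRPA1). The desk-side analyses such an experiment needs are:

1. **Calcium imaging**: segment cells on a static transfection-marker
   channel (dTomato), read activity on a GCaMP6f channel at 16.6 frames/s,
   normalise to ΔF/F, call responders against a fixed threshold, and
   measure kinetics.
2. **Screen statistics**: compare response probabilities between channel
   clones while respecting that the same cell is recorded repeatedly.
3. **EMG**: detect ultrasound-evoked muscle bursts at 40 kHz sampling under
   a stimulus-artifact exclusion rule.
4. **Sequence analysis**: consensus/identity across TRPA1 homologs and
   fuzzy CRAC/CARC cholesterol-recognition motifs, plus the codon
   arithmetic of mutant constructs.
5. **Acoustics**: wavelength, focal dimension, tissue attenuation and
   mechanical index of the stimulus.

## Synthetic movies: the stated world

`simulate_movie()` renders the world the downstream analyses assume:

- **Geometry.** Cells are hard disks (radius 6 ± 0.5 px by default)
  convolved with a Gaussian PSF of σ = radius/3, placed uniformly with a
  minimum centre separation of 1.5 × (rᵢ + rⱼ). Plans that cannot be packed
  (fraction > 0.5, or 500 failed placement draws) fail loudly naming the
  limit.
- **Channels.** The segmentation channel carries static blobs for
  transfected cells only; the activity channel carries all cells at
  baseline F0 = 100 a.u. over a background of 10 a.u.
- **Transients.** Responders (a subset of transfected cells) are modulated
  multiplicatively, F(x,t) = S(x)·(1 + A·g(t − t_on)), with g a
  difference of exponentials g(t) ∝ e^(−t/τ_d) − e^(−t/τ_r) normalised to
  peak 1 (defaults τ_r = 0.5 s, τ_d = 2 s, onset latency 0.1 s after the
  stimulus). The kernel was chosen because its peak and peak time are
  analytic (`transient_peak_time()`), so planted amplitudes are exact
  oracles. Modulation extends over the disk plus 2 PSF σ: every pixel a
  segmented ROI can plausibly claim obeys the same multiplicative law, so
  the ROI-mean ΔF/F peak equals A exactly in the noiseless limit. This is
  the one deliberate departure from optical realism (real out-of-cell blur
  is not modulated); it is what makes "recovered amplitude = planted
  amplitude" a well-defined 100%-accuracy benchmark. The default
  `min_separation = 1.5` keeps these modulated footprints clear of
  neighbouring ROIs; lowering it (e.g. to 0.75) deliberately produces
  touching cells for watershed tests, at the cost of that exactness.
- **Noise.** Poisson shot noise (variance = gain × intensity) followed by
  additive Gaussian read noise. The benchmarks define SNR as the peak
  per-pixel signal amplitude A·F0 over the read-noise SD; SNR 5 with
  A = 0.5, F0 = 100 means read_sd = 10.
- **Not emulated**: photobleaching, motion, neuropil contamination, depth
  effects, cavitation or heating. A green pipeline test therefore
  establishes correctness of the analysis chain on well-behaved data, not
  robustness to those artifacts.

`simulate_dose_cohort()` draws iid Bernoulli responses with
p(P) = p_max·P^h/(P^h + EC50^h) (defaults p_max = 0.8, EC50 = 0.5 MPa,
h = 3 — a plateau below 1 and a half-max near the middle of the 0.35–1.05
MPa range used experimentally). No coverslip-level random effect is
planted; coverslip is carried as a label only. `simulate_screen()` plants
the exact data-generating process of the screen model below.

`simulate_emg()` plants Hann-windowed 600 Hz bursts (inside the 300–1000 Hz
analysis band) over Gaussian noise, plus a rectangular artifact spanning
each stimulus — the feature the exclusion rule exists for.

## Segmentation chain

`segment_cells()` applies, in order, on the **temporal median** frame of the
marker channel (the paper-style chain; the median is used because the
marker is static and the median rejects transients and outlier frames):

1. Gaussian filter (σ = 2 px);
2. background subtraction by grey-scale morphological opening with a
   square structuring element of radius 50 px (the square window is the
   separable approximation of a rolling-ball background);
3. **Otsu** auto-threshold (the common default of ImageJ-style "auto
   thresholding"), with a no-signal guard: if the Otsu threshold does not
   clear median + 3·MAD of the background-subtracted image, the field is
   declared empty rather than splitting pure noise;
4. distance-transform watershed: exact Euclidean distance transform,
   seeds from its local maxima thinned to a minimum separation
   (default 8 px ≈ the smallest expected cell diameter), and components
   holding several seeds split by nearest-seed assignment;
5. an area filter (defaults 20–2500 px).

All coordinates are 1-based (row, col) in the R convention. The
`total_cells` denominator of `percent_transfected()` is supplied by the
caller (manual count or a second segmentation of the activity-channel
baseline) — which denominator to use is an acquisition-protocol decision,
not something the marker channel alone can decide.

## ΔF/F and responder calling

- F0 is the mean over the 6 s **immediately preceding the first stimulus**
  (window length and placement both exposed; the placement is the natural
  reading of "a 6-s baseline" and is configurable because recordings with
  late stimuli admit alternatives). F0 ≤ 0 is a hard error.
- Responder rule: peak ΔF/F in `(onset, onset + window]` **≥ 0.25**, with
  the window 60 s for HEK-like and 5 s for neuron-like recordings. The
  comparison is inclusive (ties respond) and peak ties break to the
  earliest frame; no prominence or width requirement is added beyond the
  threshold.
- 63% kinetics: latency is the first post-stimulus crossing of 0.63 × peak,
  width the distance from that crossing to the first post-peak downward
  crossing, both by **linear interpolation** between frames (at 16.6
  frames/s the frame period, 60 ms, would otherwise dominate). A trace that
  never decays below the level within the recording yields a **censored**
  width (flagged, measured to trace end), not an error.
- "Percent responsive over 3 consecutive recordings" uses **union
  semantics** — a cell counts once if it responded in at least one
  recording — because the quantity is a percent of *cells*; a pooled
  per-trial mode is available behind `mode = "pooled"`.

## The screen statistic

`fit_response_glmm()` fits logit P(response) = clone (fixed, reference =
first level, conventionally the dTomato-only control) + cell (Gaussian
random intercept), by adaptive Gauss–Hermite quadrature with 25 nodes
(`lme4::glmer`; any `nagq ≥ 20` reproduces the reported likelihoods to
well under 1e-6 — the test suite cross-checks the marginal likelihood
against dense-grid numerical integration on small data). Coverslip is
carried as a column but not modelled by default; whether the original
analysis stratified by coverslip is unknowable from the methods text, so a
coverslip term is left to the caller's formula-level judgement rather than
silently added. With `collapse_random = TRUE` the model collapses to plain
logistic regression (σ² ≡ 0), which the tests verify against a
hand-written IRLS oracle.

`pairwise_odds_ratios()` forms all clone-pair contrasts, reports
OR = exp(contrast), and controls the family-wise error with the
**single-step (Tukey-style) adjustment**: p-values and simultaneous CIs use
equicoordinate probabilities/quantiles of the contrasts' joint normal
distribution, computed by `mvtnorm`'s deterministic quasi-Monte-Carlo
integration under a fixed private seed (reproducible to ~1e-6). For a
two-clone family the adjusted and unadjusted p coincide exactly. Adjusted
p-values are clamped to be ≥ unadjusted.

`dose_response_table()` reports exact Clopper–Pearson intervals per dose
level — at screen-level counts (tens of cells) the exact interval's
conservatism is preferable to a normal approximation.

## EMG detection

The acquisition band (300–1000 Hz) is re-applied digitally as a
**zero-phase** 4th-order Butterworth band-pass (forward–backward over
second-order sections, odd-reflection padding). Zero-phase filtering is
deliberately *not* what the causal acquisition hardware does: it avoids
biasing onset latencies by the filter's group delay.

The envelope is a 5-ms moving RMS of the filtered signal. Onset threshold
is baseline mean + k·SD (k = 3) taken from ≥ 1 s of pre-stimulus envelope.
The detector searches **only after stimulus cessation** (the
artifact-exclusion rule: activity during the pulse is unquantifiable), plus
a 20-ms guard for the artifact-edge ringing the zero-phase filter itself
spreads past cessation. A crossing must hold for ≥ 10 ms (two RMS windows)
to count — at 40 kHz, mean + 3 SD alone is crossed by noise excursions —
and the event ends when the envelope stays below threshold for ≥ 10 ms.
One event (the first) is called per stimulus, which makes the event count
provably non-increasing in k. Latency is referenced to stimulus **onset**
(the convention for evoked-response latencies) even though onsets before
stimulus offset are excluded; duration runs from onset to
return-to-baseline.

The detector's accuracy bound on synthetic bursts — latency within the RMS
window plus the envelope's rise to threshold (≲ 15 ms at SNR ≥ 5) — is what
the acceptance suite checks; the true threshold criterion of the original
analysis is not quantified anywhere, so k, window, guard and hold are all
exposed configuration with these defaults.

## Sequence analyses

- **Consensus** (`consensus_sequence()`): per column, the most frequent
  symbol if its frequency ≥ 0.65, else `X`; ties are `X`. Gaps count as a
  21st symbol by default (the conservative reading — a mostly-gap column
  should not be called from its few residues); `count_gaps = FALSE` drops
  them, and an all-gap column then stays `-`.
- **Percent identity** (`percent_identity()`): over alignment columns where
  the human reference is un-gapped (optionally restricted to a domain in
  ungapped reference coordinates), the percentage of columns whose
  consensus equals the reference; `X` always counts as a mismatch. How the
  original analysis treated gap columns is unstated, so exact reproduction
  of its printed domain percentages is not promised; both gap conventions
  are exposed.
- **Motifs** (`scan_motifs()`): CRAC `[LV]-X(1,5)-Y-X(1,5)-[RK]` and CARC
  `[RK]-X(1,5)-[YF]-X(1,5)-[LV]`. Spacer `X` matches **any** residue by
  default — the fuzzy-search semantics of the EMBOSS-style tool such scans
  are run with; `strict_spacers = TRUE` restricts spacers to the nonpolar
  set {A,V,L,I,P,F,M,W,G,C} for the narrower literature definition. Every
  (start, central, end) combination is enumerated, overlapping and nested
  hits included (lengths 5–13). The implementation is index-set
  intersection; the tests prove it identical to brute-force regex
  enumeration on 1,000 random peptides.
- **Construct arithmetic** (`aa_to_cds()`/`cds_to_aa()`): residue r ↔ CDS
  nucleotides 3r−2…3r, 1-based inclusive, with an exact round-trip
  property. Note two quirks of published construct tables this module
  deliberately does not reproduce: a 61-residue deletion spans 183 nt (a
  printed "1–182" is an off-by-one), and deletion coordinates quoted
  against a transcript accession include the 5′ UTR offset, whereas this
  module computes CDS coordinates.
- The bundled TM2 FASTA fragment is a **synthetic stand-in** (so labelled
  in its filename and header): offline builds cannot fetch RefSeq/UniProt,
  so the fragment reproduces only the coordinate structure that matters —
  a CRAC motif whose central tyrosine maps to full-protein residue 785 via
  the recorded offset. Conclusions about the real TRPA1 sequence require
  feeding the real alignment through `read_alignment()`.

## Acoustics

λ = c/f with c = 1500 m/s (speed of sound in brain tissue); the
diffraction-limited focal dimension is λ/2 (≈ 107 μm at 7 MHz, the figure
that makes 7 MHz attractive for millimetre-scale targeting); attenuation is
0.8 dB·cm⁻¹·MHz⁻¹ × depth. Two deliberate double-reportings where
conventions are ambiguous in print: the transmitted fraction is given under
both the pressure (10^(−dB/20)) and intensity (10^(−dB/10)) conventions,
and the focal volume under both (λ/2)³ and λ³ readings. The mechanical
index PNP/√f_MHz uses in-situ pressure with no additional derating.

## Numerical choices and degenerate inputs

- One private RNG stream per generator (`with_seed`): seeded calls are
  bit-for-bit reproducible and never perturb the caller's `.Random.seed`.
- Segmentation of an all-zero or pure-noise field returns an empty ROI set;
  NaN pixels are an error.
- `crossing_time()` interpolates linearly and returns the first frame time
  when the level is already exceeded at the window start (step responses
  thus get latency ≤ one frame).
- Complete-separation logistic fits surface through `converged = FALSE`;
  `pairwise_odds_ratios()` refuses non-converged fits.
- Filters are designed as second-order sections, not transfer functions, to
  stay numerically stable at 300 Hz/40 kHz normalised frequencies.

## Known limitations

- The watershed splits multi-seed components by nearest-seed (Voronoi)
  assignment, which is exact for convex blobs but approximate for strongly
  concave clumps.
- The EMG artifact model is a rectangle; real transducer artifacts have
  structure that may require a longer `guard_s`.
- Percent-identity figures depend on the alignment fed in; the module does
  not align.
- The GLMM assumes a Gaussian random intercept on the logit scale; no GEE
  or Bayesian alternative is provided.
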