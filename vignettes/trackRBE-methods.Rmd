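---
title: "Methods: track-structure emulation, microdosimetry and DSB-based RBE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: track-structure emulation, microdosimetry and DSB-based RBE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models: what is
simulated, what is calibrated, which choices were genuinely open, and
what the results do and do not show. The companion drivers under
`analysis/` run the study; every number quoted here is computed by those
scripts or by the test suite, not asserted.

## 1. What question the pipeline answers

A flattening-filter-free (FFF) 6 MV beam is spectrally softer than its
flattened (FF) counterpart, increasingly so away from the central axis.
Softer photon spectra produce lower-energy secondary electrons, whose
ionization events cluster more densely at the nanometre scale. Two
consequences are computed here for a grid of positions in a water
phantom (depths 3, 5, 10 cm; lateral offsets 0, 6, 8, 10 cm):

* the **dose-mean lineal energy** `y_D`, a microdosimetric beam-quality
  index, and
* the **initial DNA strand-break yields** — single-strand breaks (SSB),
  double-strand breaks (DSB), their ratio — and the DSB-based relative
  biological effectiveness `RBE_DSB` against 220 kVp X-rays.

The package replaces the heavy transport chain that would normally feed
such a calculation (linac head model, phase-space files, Monte-Carlo
photon/electron transport, physics-grade track structure) with two
deliberately simple, calibrated components: a parametric spectrum
family and a compound-cluster track process. Everything downstream of
those two components — scoring, distributions, yield arithmetic, RBE —
is exact implementation, not emulation.

## 2. Secondary-electron spectra

`generate_spectrum()` evaluates a dose-weighted density on a log-spaced
grid (default 200 bins on [1 keV, 1 MeV]) and normalizes. The
`"gamma_exp"` family mixes

* a gamma density with mean `mean_energy_keV` and shape 1.6 (the bulk
  Compton-electron component), and
* an exponential tail of scale 8 keV with mixture weight
  `low_energy_fraction` (the build-up of multiply scattered, low-energy
  electrons),

truncated to `[e_min_keV, e_max_keV]`. Two knobs per point suffice
because the downstream damage model consumes only two spectral moments
in practice (see §4). The floor of 1 keV matches the tracking cut-off;
the 220 kVp reference is capped at 220 keV.

The shipped calibration table (`inst/extdata/spectrum_calibration.csv`)
fixes the tail weight per field as a linear ramp in lateral distance
(FF: 0.04 + 0.012/cm; FFF: 0.05 + 0.015/cm — FFF always the larger) and
solves the mean energy per point so that the pipeline reproduces the
published per-point DSB yields (§5). The solved means fall from
~370 keV in-field to ~40–120 keV at 10 cm lateral, and the FFF mean is
strictly below the FF mean at every point, in-field included. Both
orderings are enforced by tests on the shipped defaults.

The 220 kVp reference is a single position-independent spectrum: one
reference beam quality defines the RBE denominator everywhere.

## 3. Track structure as a compound cluster process

`simulate_track()` follows one electron to full stop:

1. cluster centres advance along a polyline with isotropic random
   directions and exponential spacings of mean `cluster_spacing_nm(E)`;
2. each cluster holds `1 + Poisson(m - 1)` events (default mean
   multiplicity `m = 5`) displaced isotropically with standard
   deviation `cluster_sigma_nm(E)`;
3. per-event deposits are exponential with mean `ev_per_event(E)`;
4. the final event absorbs the residual energy exactly, and an incident
   energy below the 1 keV cut-off becomes a single local deposit.

All three curves are evaluated at the electron's *current* residual
energy, so every track carries its own slowing-down end — a 300 keV
track ends in a dense low-energy segment, as a real one does.

Three design points deserve comment.

* **Spacing is physical.** `cluster_spacing_nm(E)` equals the mean
  cluster energy divided by the collision stopping power of water, so
  the model's linear energy density along the track matches water LET
  from ~12.6 eV/nm at 1 keV to ~0.19 eV/nm at 1 MeV. This single choice
  makes the microdosimetric magnitudes land in the right range without
  separate tuning (in-field `y_D` ≈ 2.2 keV/µm for a 1 µm site).
* **Events per keV is a calibrated curve, not a constant.** The
  published yield tables require the spectrum-averaged event density to
  vary between ~38.8 /keV (in-field) and ~47 /keV (softest point), so
  the mean energy per event falls from ~30 eV at 1 MeV to ~17.6 eV at
  1 keV. A constant-per-event model cannot reproduce the published
  SSB yields at both ends; this is the package's main deviation from a
  scalar-parameter description.
* **Cluster width is the linkage dial.** The probability that two
  events of one cluster fall within the 3.4 nm pairing distance is set
  by `cluster_sigma_nm`; with `m = 5` the intra-cluster pair budget is
  `λ(λ+2)/(2(1+λ)) = 2.4` per event (`λ = m − 1`), and σ ≈ 1.0–1.7 nm
  dials the realized link-to-event ratio into the published 1.97–2.15
  band, rising as tracks soften (exponential spacings also let adjacent
  clusters overlap at low energy, which adds inter-cluster pairs
  exactly where the published DSB/SSB ratios demand them).

Ionization vs excitation is tagged per event (Bernoulli, default 0.5)
and carried in the data model, but the damage arithmetic counts both:
the published proportionality coefficients absorb any per-kind
sampling convention of the original transport code.

Randomness: one master seed; per-track and per-bin streams are derived
by a counter scheme (`derive_seed()`), so cohorts are reproducible and
independent of iteration order, and the fused generate-and-count path
consumes the generator identically to the event-list path.

## 4. Calibration protocol

Calibration happened once, in two stages, and ships as data — the
package never re-tunes itself.

1. **Track response.** With the energy-per-event and spacing curves
   fixed as above, the within-cluster σ was solved per tabulated energy
   (secant iteration over simulated cohorts, sweeps until stable) so
   that the link-to-event ratio at energy E follows the line
   `r(g_e) = 1.2338 + 0.01905 · g_e(E)` — the least-squares relation
   between event density and link ratio implied jointly by the
   published per-point DSB yields and DSB/SSB ratios with the printed
   coefficients. Because the relation is nearly linear, any spectrum's
   weighted averages inherit it, which is what lets two spectral knobs
   per point reproduce two published numbers per point.
2. **Spectra.** With track response frozen, the per-bin link density
   was measured once on the 200-bin grid, and each point's
   `mean_energy_keV` was solved (deterministic root-find on the
   interpolated response) so the spectrum-weighted DSB yield equals the
   published value at that point.

Two anchors need explanation:

* **In-field split.** The published in-field DSB yield is 1.23 (in
  units of 1e-11 /Gy/Da) for both fields at every depth, yet the
  published in-field RBE differs (0.74 vs 0.75) and the spectral model
  requires FFF strictly softer. The calibration therefore anchors FF at
  1.2255 and FFF at 1.2345 — both round to the published 1.23 — keeping
  a small positive FFF−FF gap unrounded.
* **Reference yield.** The published tables imply different 220 kVp
  reference yields at different points (1.23/0.74 ≈ 1.66e-11 in-field
  vs 1.62/1.07 ≈ 1.51e-11 at the deepest out-of-field point): they are
  internally inconsistent with a single reference. The pipeline uses
  one reference (as the ratio's definition requires) anchored at the
  deep out-of-field consistency point, Y_DSB(ref) = 1.514e-11 /Gy/Da.
  Consequently the out-of-field RBE values and all FFF-vs-FF yield
  contrasts reproduce the published picture, while the in-field RBE
  computes to ≈ 0.81 rather than the published 0.74. The discrepancy is
  a property of the published numbers, not of the calibration; we chose
  to document it rather than hide it by per-point references.

## 5. Microdosimetry

`lineal_energy_samples()` scores spherical sites (default diameter
1 µm, mean chord `2d/3` by the Cauchy formula) under the uniform-volume
measure: each scored site carries the volume it represents, sites with
no event inside are not scored (single-event convention), and
`y = ε / l̄` in keV/µm. The published work does not state its scoring
site; 1 µm is the conventional microdosimetry choice and lands MV-beam
`y_D` at the printed magnitude, and the diameter is a config knob.

Site placement defaults to an importance-sampled estimator of the same
measure: centres are uniform offsets within one site radius (Chebyshev)
of a randomly chosen event, weighted by the inverse placement density
`V_cube / m(c)`. The naive uniform-over-bounding-box estimator remains
available (`method = "uniform"`) and the two agree on compact tracks
(tested), but for centimetre-range electrons the naive estimator
almost never hits the track and its `y_D` is unusable at any feasible
site count — the importance estimator is a variance fix, not a change
of definition.

`build_distribution()` histograms samples into log-spaced bins (50 per
decade over 0.01–1000 keV/µm), normalizes `f(y)`, forms
`d(y) ∝ y f(y)`, and evaluates `y_F` and `y_D` on geometric bin
midpoints. Moments are binned on purpose (the conventional tabular
definition); the suite guards that binned `y_D` stays within 1% of the
raw moment ratio, and the analytic limit (uniform density on (0, 2],
`y_D = 4/3`) is reproduced within 0.5% at 10⁶ samples. Samples outside
the binning range are dropped and counted.

Numerical conventions: bins are `(low, high]`; a sample exactly on a
shared edge goes to the lower bin; degenerate sample sets (all equal)
give `y_F = y_D` at the midpoint of one bin, so equality is exact but
the value carries up to half a bin width (~2.3%) of quantization.

## 6. Strand breaks and RBE

`count_linkages()` counts *all* unordered event pairs within 3.4 nm,
boundary inclusive, via an exact cell-list spatial hash (the all-pairs
O(n²) oracle is enforced on random instances in the tests). No
adjacency restriction and no deduplication: one event may participate
in many pairs, which is precisely what lets the link count exceed the
event count, as the published numbers require.

Yields follow the published linear forms with
`k_SSB = 5.66e-12` and `k_DSB = 1.61e-13` keV/Gy/Da;
`spectrum_averaged_yields()` stratifies tracks per spectrum bin and
combines per-bin means with the spectrum's dose weights (the published
work does not state its weighting; dose weighting is the documented
choice). The identity
`Y_DSB/Y_SSB = (k_DSB/k_SSB) · (N_link/N_event)` holds exactly on every
aggregate by construction and is asserted to 1e-12. Standard errors are
per-bin delta-method combinations; the RBE standard error uses the
first-order ratio formula
`se(R) = R·sqrt(se_t²/Y_t² + se_r²/Y_r²)`.

Genome mass never enters: both numerator and denominator of `RBE_DSB`
are per-gray-per-dalton yields at 1 Gy, so the per-nucleus conversion
cancels.

## 7. Sample sizes and runtime

Chosen so the full default study is a coffee-break run on one CPU:

* yields: 200 spectrum bins × 8 tracks/bin (default config; 10–20 per
  bin in the analysis drivers and acceptance script, i.e. 2000–4000
  tracks per cohort) — the dominant cost is the ~39 000-event tracks in
  the top energy decade;
* microdosimetry: 240-track cohorts, 60 000 sites (≈250 per track),
  giving `y_D` standard errors around 1–2% in-field;
* the full grid (`analysis/05_rbe.R`): about 4 minutes; the acceptance
  script: well under a minute.

## 8. What passing tests show — and what they do not

The synthetic generator emulates *the consequences* of spectral
softening that the damage model consumes: event density and linkage
density as smooth functions of electron energy, and spectra whose
weighted responses match published per-point yields. It does not
transport photons, does not model the linac head or phantom scatter
geometry, has no angular physics, no cross-sections, and no chemical
stage. Passing tests therefore show that the published computational
chain — lineal-energy bookkeeping, pair counting, yield arithmetic,
spectrum averaging, RBE — is implemented correctly and lands the
published in-field/out-of-field numbers under a calibrated, physically
scaled stand-in for the transport; they do not validate the transport
itself.

Known limitations, deliberate:

* Out-of-field `y_D` overshoots the published 3.2–3.6 keV/µm (we find
  4–8 keV/µm): the cluster process concentrates low-energy electron
  energy more than real transport does, and `y_D`'s second moment is
  sensitive to exactly that tail. The yield chain is insensitive to
  this because it was calibrated directly; the `y_D` grid is reported
  as a qualitative reproduction (orderings and trends, which all hold).
* The in-field FFF−FF `y_D` gap (~1%) is below the Monte-Carlo
  resolution of default sample sizes; its sign can fluctuate between
  runs. The out-of-field gaps (5–60%) are well resolved.
* DSB/SSB ratios at off-anchor points inherit up to ~2% from the
  linearized link-ratio relation — inside the published rounding at
  every point.
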