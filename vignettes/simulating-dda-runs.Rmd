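---
title: "Simulating data-dependent LC-MS/MS runs with mzsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating data-dependent LC-MS/MS runs with mzsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzsim)
```

`mzsim` generates complete data-dependent-acquisition (DDA) LC-MS/MS runs
with known ground truth. This vignette explains the model behind the
simulator, the parameters that matter, and the design decisions taken
where several defensible choices existed — so that users know precisely
what a simulated run does and does not represent.

## The model

### Isotope envelopes

Everything runs off the chemical formula. For a molecule with elemental
composition $\{(e, n_e)\}$ the isotopologue distribution is the convolution
of the per-element distributions, each element's distribution raised to its
atom-count power (computed by binary exponentiation of convolutions).
Isotope masses and natural abundances come from a plain-text NIST-derived
table shipped with the package (`inst/extdata/isotopes.tsv`), which is the
single source of truth for all masses — amino-acid residues are stored as
formulas, never as a second mass list.

After convolution the pattern is normalized so the base peak is exactly 1,
peaks below a relative abundance of `prune = 1e-4` are dropped, and
neighbouring isotopologues closer than $10^{-5}$ Th are merged into an
abundance-weighted centroid. The merge prevents pattern explosion from
isotope fine structure in large formulas; the prune threshold keeps peak
counts realistic for a centroided instrument. Both defaults are this
package's own choice; they are exposed as arguments. Ionization is
protonation only: $m/z = (M + z \cdot 1.00727646688)/z$ with the CODATA
proton mass. Spectra are centroided — there is no profile-mode peak shape
in the m/z dimension, because peaks are written directly from envelope m/z
values.

Correctness is checked against an independent oracle: for formulas up to
12 atoms, exhaustive enumeration over every per-atom isotope choice
reproduces the convolution's m/z and abundances to within $10^{-9}$
relative.

### Elution profiles

Each molecule elutes over the half-open window
$[\mu - w/2,\; \mu + w/2)$ where $\mu$ is `rt_apex` and $w$ the
`peak_width` (seconds). Centring the window on the apex is an assumption —
one could also start it at the apex — and the half-open convention
prevents double membership at shared boundaries.

Within the window, intensity follows a peak-shape function normalized to 1
at its mode, so the apex intensity equals `scale_intensity` for every
shape. Three shapes are available:

* **EMG** (default): the exponentially modified Gaussian, parameterized by
  $(\mu, \sigma, \tau)$ with $\tau$ the exponential tailing constant. The
  density is evaluated in log space via the normal log-CDF
  ($\log f = -\log\tau + (\mu - t)/\tau + \sigma^2/2\tau^2 +
  \log\Phi((t-\mu)/\sigma - \sigma/\tau)$), which is stable for small
  $\tau$; as $\tau \to 0$ it converges to the Gaussian. The mode has no
  closed form and is located numerically once per shape
  (`optimize`, tolerance $10^{-9}$ s) and cached in the shape object.
* **Gaussian**: $\exp(-(t-\mu)^2/2\sigma^2)$.
* **gamma**: a Gamma$(k, \theta)$ density shifted so its mode
  $(k-1)\theta$ sits at $\mu$; $k \le 1$ is rejected because the mode is
  then undefined and the apex could not land at the stated retention time.

When explicit shape parameters are not given they are derived from the
window width so that essentially all profile mass falls inside it:
$\sigma = w/6$ (Gaussian), $\sigma = \tau = w/8$ (EMG), $k = 4,
\theta = w/12$ (gamma).

The "which molecules elute now" query is answered by an index over the
pre-sorted interval bounds using vectorized comparisons. This is exact and,
at the molecule counts a desk-scale simulation handles (thousands), as
fast as a tree structure; the tests verify equivalence with a brute-force
linear scan.

### Noise

Two intensity-dependent noise components act on every peak, following the
model family established by earlier MS simulators:

* intensity: $i' \sim \mathcal N(i, \sigma_I)$ with
  $\sigma_I = m\,(1 - e^{-c i}) + d$ — $d$ is the noise floor, $m + d$ the
  saturation level, $c$ the growth rate;
* m/z: $mz' \sim \mathcal N(mz, \sigma_{mz})$ with
  $\sigma_{mz} = m_{mz}\, i^{-y}$ — strong peaks are located more
  precisely; $m_{mz}$ is the sigma at unit intensity.

The package's default m/z-noise constants are $m_{mz} = 0.001701$ Th and
$y = 0.2$, the values of its nucleoside simulation protocol. There is no
canonical default for the intensity-noise constants — they vary with the
instrument — so intensity noise is off until configured. A uniform-noise
alternative (`kind = "uniform"`) perturbs m/z within a fixed half-width
and intensity within a relative band.

Negative noisy intensities are truncated at zero rather than resampled;
truncation is simple and its bias is negligible at the intensities where
the model is meant to operate (signal-to-sigma ratios well above 3). Peaks
at zero intensity are removed by the scan assembly's positivity filter.

Each isotope envelope is normalized to its own base peak (= 1) *before*
shape scaling. The alternative — normalizing across the whole composite
spectrum — would couple co-eluting molecules' absolute abundances and
destroy the ground-truth quantification the simulator exists to provide,
so per-envelope normalization was chosen deliberately.

On top of the per-peak model, every spectrum can receive **white noise**:
a fixed intensity budget (default 1000 units) split over a uniformly drawn
number of peaks (default 1–100) at uniform m/z positions (default
50–1500 Th), with shares from a uniform stick-breaking (flat Dirichlet).
The shares sum to the budget *exactly*: the last share absorbs the
floating-point remainder, with a correction pass that closes any residual
rounding ulp. Finally, each fragment ion in an MS2 scan is omitted
independently with probability `fragment_omission_p` (default 0.1),
emulating fragments that fall below detectability.

All draws use R's global RNG, seeded once per run from `cfg$seed`;
identical inputs give bit-identical runs.

### The acquisition loop

A scan clock starts at 0 and advances by `scan_diff` (default 0.05 s =
50 ms) for *every* scan, MS1 or MS2. At each MS1 tick:

1. the envelopes of all eluting molecules are scaled by shape value times
   `scale_intensity`, noise is injected, white noise appended, peaks closer
   than $10^{-4}$ Th merged into abundance-weighted centroids (co-eluting
   isomers share exact theoretical m/z), and non-positive intensities
   dropped;
2. precursor candidates — one per eluting molecule and charge, at the
   envelope's *base peak* m/z with its current scaled intensity — are
   sorted by decreasing intensity; candidates below `min_intensity` or
   within 10 ppm of an active dynamic-exclusion entry are skipped; up to
   `top_n` survivors each trigger one MS2 scan and enter the exclusion
   list until `rt + exclusion_time`;
3. each MS2 scan contains the fragments of *every* molecule whose base
   peak lies within half the isolation width of the selected m/z —
   chimeric spectra arise naturally and are recorded in the ground truth.
   Fragment intensities are `relative_intensity` × shape value (at the MS2
   scan's own clock time) × `scale_intensity` × `fragmentation_efficiency`.

With a full cycle of 1 MS1 + 19 MS2 scans at 50 ms this gives exactly 1 s
between consecutive MS1 scans — the cycle is read as 20 scans *in total*,
which keeps the arithmetic exact. The run stops when the clock reaches
`gradient_length`.

Several selection rules deserve explicit statement because real
instruments vary:

* selection operates on envelope base peaks (one candidate per species),
  not on raw spectrum peaks — the simplest defensible reading of "top N
  peaks";
* `top_n` counts selection events, not co-isolated molecules;
* dynamic exclusion is keyed by precursor m/z with a ±10 ppm match window,
  not by molecule identity, which is how instruments behave.

### Fragmentation

Peptides produce the full b and y series (indices $1..n-1$, charges up to
`max_fragment_charge`, default 1), the CID convention; modification deltas
(carbamidomethyl, oxidation, N-terminal acetyl) travel with the residues
carrying them. All relative fragment intensities default to 1 because no
general intensity model exists at this level of abstraction — fragment
intensity structure is exactly the kind of thing downstream tools should
not be tuned to here. Ribonucleosides use the dominant fragmentation
channel, the ribose neutral loss ($-$C5H8O4, 132.04226 Da), leaving the
protonated base. Any other molecule can bring a fragment library CSV
mapping a key to labelled fragments (formula or fixed m/z).

## Output

The scan stream is written as indexed mzML 1.1 through the ProteoWizard
writer behind Bioconductor's `mzR`: centroid-spectrum flags, per-scan ms
level and retention time (stored in seconds), full precursor metadata, and
zlib-compressed 64-bit binary arrays. A zero-scan run is written as a
minimal valid indexed mzML directly, since the backend requires at least
one spectrum. Round trips are tested both through `mzR` and through an
independent decode path (raw XML plus base64/zlib) that does not touch the
ProteoWizard stack.

The ground truth is a CSV with one row per molecule × charge: elution
window, apex time and intensity, the number of MS1 scans covering the
window, and the ids of every MS2 scan that sampled the feature (including
chimeric events). Together with the config JSON (which round-trips through
`read_config`/`write_config`) this fully documents the run.

## The synthetic-input generator

`digest_fasta()` performs an in-silico tryptic digest (cleavage after K/R
except before P, configurable missed cleavages, length filter);
`randomize_run()` assigns run parameters from the distributions used for
benchmark-style simulations: peak width $\sim U(30, 120)$ s, apex
intensity $\sim U(10^5, 10^6)$, charge from a multinomial over 2+/3+/4+
(defaults 0.6/0.3/0.1 — the multinomial weights themselves are this
package's choice and configurable), and retention times uniform over the
gradient. Uniform RTs are a deliberate *testing* stand-in, not a realism
claim: real elution order is strongly structured, and the `rt_apex`
argument exists precisely so externally predicted or measured RTs can be
injected for realistic simulations. `nucleoside_mix()` bundles a
representative ten-ribonucleoside standard mix (not a reproduction of any
specific commercial mix) including the three isomeric methylcytidines.

What passing tests on these inputs do **not** show about real data:
contaminant and background ion populations, ion suppression, injection
time and AGC effects, RT structure, charge-state correlation with peptide
properties, and realistic fragment intensity patterns are all absent by
design. The simulator provides *known truth under a stated model*, which
is the property benchmarking needs — not spectral realism.

## Numerical choices and degenerate inputs

* Convolution intermediates are merged at $10^{-8}$ Da and floored at
  $10^{-12}$ relative abundance, far below the final prune, so the
  published tolerance ($10^{-9}$ relative against brute force) holds.
* Scan retention times are computed as `tick * scan_diff` from an integer
  tick counter — never accumulated — so cycle arithmetic is exact.
* Ties in precursor ordering are broken by ascending m/z for determinism.
* The empty formula, the empty molecule list, a header-only CSV, a
  zero-scan run, `top_n = 0`, and `white_total = 0` are all defined,
  tested degenerate cases rather than errors; `p_omit = 1`,
  `k <= 1` (gamma), and non-positive intensities for the m/z-noise law are
  rejected.
* Machine ppm offset is applied to the precomputed theoretical m/z values
  (envelope and fragment ladders); noise is then drawn around the offset
  values. At the ppm magnitudes involved the difference from offsetting
  after the noise draw is far below the noise itself.

## Problem sizes

The shipped tests simulate runs of up to 100 peptides over a 10-minute
gradient with a top-10 method (about 12,000 scans), asserted to complete
within three minutes on one core; the protocol checks use runs totalling
roughly 27,000 fragment ions and 1,000 white-noise spectra. These sizes
were chosen to exercise every code path at full fidelity while keeping the
suite quick to run; the simulator itself has no hard-coded scale limits,
and cost grows linearly in scan count and eluting species.

## Known limitations

* Protonation is the only adduct; no electron-mass correction, no isotope
  fine structure beyond the merge tolerance, no average masses.
* No DIA, MS3, ion mobility, or isotope-aware charge determination.
* Fragment relative intensities are flat unless a library provides them.
* The exclusion list matches on m/z alone, so isomers co-excluded within
  10 ppm are indistinguishable to the selection logic — as on real
  hardware.
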