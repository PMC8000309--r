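# mzsim

Simulation of data-dependent LC-MS/MS runs with known ground truth.

Feature detection and quantification software for mass spectrometry is hard
to benchmark: hand-annotated gold-standard datasets are expensive to make,
tied to one instrument configuration, and rarely cover the analyte class of
interest. `mzsim` takes the opposite route — it *generates* the raw data.
From a table of analytes (chemical formula or peptide sequence, retention
time, charge, abundance) and a run-parameter configuration it simulates a
complete data-dependent-acquisition (DDA) LC-MS/MS run and writes it as
standard indexed mzML together with a ground-truth feature table, so that
any analysis tool can be scored against exactly known truth. Because every
calculation runs off the chemical formula, the same machinery serves
proteomics, metabolomics and the analysis of modified ribonucleosides.

## What is simulated

* **Isotope envelopes.** For every molecule and charge state the centroided
  isotope pattern is computed by iterated convolution of the elemental
  isotope distributions (bundled NIST-derived table), normalized to a unit
  base peak, pruned at 1e-4 relative abundance, with
  m/z = (M + z·1.00727646688)/z.
* **Chromatography.** Each analyte elutes over a finite window centred on
  its retention-time apex; within it the signal follows an exponentially
  modified Gaussian (the standard chromatographic peak model), or
  optionally a Gaussian or gamma profile, normalized so the apex intensity
  equals the configured `scale_intensity`.
* **Noise.** Per-peak intensity noise is normal with the saturating
  standard deviation σ = m·(1 − e^(−c·i)) + d; per-peak m/z noise is normal
  with the power-law σ = m·i^(−y) (precise peaks where the signal is
  strong). A fixed white-noise budget per spectrum is spread over a random
  number of peaks at random m/z, and a constant machine miscalibration in
  ppm can be applied to every m/z value.
* **Acquisition.** A scan clock advances in fixed steps (default 50 ms).
  Each MS1 scan is followed by MS2 scans for the top-N most intense
  precursor candidates above the minimum intensity and not on the dynamic
  exclusion list; every molecule whose envelope base peak falls inside the
  isolation window contributes its fragments (chimeric spectra arise
  naturally). Peptides fragment into b/y ions, ribonucleosides by the
  ribose neutral loss (−132.04226 Da), and arbitrary molecules via a
  user-supplied fragment library; fragment intensities are scaled by the
  elution profile and a per-molecule fragmentation efficiency, and a
  configurable fraction of fragments is randomly omitted.

The whole run is reproducible from the integer seed in the configuration.

## Worked example

The classic hard case for nucleoside analysis: three isomeric
methylcytidines that share the formula C10H15N3O5 — identical masses and
isotope envelopes — distinguishable only by retention time and MS2.

```r
library(mzsim)

mols <- list(
  molecule("m5C", formula = "C10H15N3O5", charges = 1, rt_apex = 60,
           peak_width = 30, scale_intensity = 5e5,
           fragment_source = "nucleoside"),
  molecule("m3C", formula = "C10H15N3O5", charges = 1, rt_apex = 75,
           peak_width = 30, scale_intensity = 3e5,
           fragment_source = "nucleoside"),
  molecule("Cm",  formula = "C10H15N3O5", charges = 1, rt_apex = 95,
           peak_width = 30, scale_intensity = 4e5,
           fragment_source = "nucleoside"))

cfg <- run_config(gradient_length = 150, top_n = 5, isolation_width = 2,
                  exclusion_time = 10, min_intensity = 1000, seed = 42)
run <- simulate_run(mols, cfg)
run
#> <sim_run> 3000 scans (2993 MS1, 7 MS2), 3 features, gradient 150 s

isotope_pattern("C10H15N3O5", charge = 1)
#> <isotope_pattern> z=1, 13 peaks, base 258.10845 Th

run$features[, c("id", "rt_apex", "apex_intensity", "ms1_scans", "ms2_scan_ids")]
#>    id rt_apex apex_intensity ms1_scans   ms2_scan_ids
#> 1 m5C      60          5e+05       597  966;1167;1368
#> 2 m3C      75          3e+05       597 1368;1568;1769
#> 3  Cm      95          4e+05       597 1769;1970;2171

write_mzml(run$scans, "run.mzML", meta = run_metadata(cfg))
write_feature_csv(run$features, "features.csv")
```

150 s of gradient at 50 ms spacing give 3000 scans. Each isomer is covered
by 597 MS1 spectra (its 30 s elution window) and is sampled three times by
MS2 — the 10 s dynamic exclusion prevents denser resampling. Scan 1368 and
1769 appear under two features each: at the elution overlaps the 2 Th
isolation window co-isolates both isomers, producing chimeric MS2 spectra —
exactly the situation analysis software must untangle, and here the truth
is recorded. The extracted ion chromatogram of the shared base peak
recovers the configured apex intensity within the simulated noise
(`xic(run, 258.10845)` peaks at 500360 for the 5e5 molecule).

A command-line front end wrapping the same functions is installed with the
package (`system.file("scripts", "mzsim", package = "mzsim")`):

```sh
mzsim simulate --molecules mix.csv --config run.json \
      --out-mzml run.mzML --out-features features.csv --seed 42
```

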