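Package: mzsim
Title: Simulation of Data-Dependent LC-MS/MS Runs with Known Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates liquid-chromatography tandem mass spectrometry
    (LC-MS/MS) runs acquired with a data-dependent (top-N) method. From a
    table of analytes (chemical formula or peptide sequence, retention
    time, charge, abundance) and a run-parameter configuration, the
    simulator computes isotope envelopes from elemental isotope
    distributions, scales them along exponentially modified Gaussian
    (or Gaussian / gamma) elution profiles, injects intensity-dependent
    m/z and intensity noise plus spectrum-level white noise, performs
    top-N precursor selection with isolation windows and dynamic
    exclusion, and writes an indexed mzML file together with a
    ground-truth feature table, so that feature detection and
    quantification software can be benchmarked against known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mzR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse,
    withr,
    xml2
Config/testthat/edition: 3
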