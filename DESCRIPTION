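Package: rgelquant
Title: Quantitation of Genome-Embedded Ribonucleotides from Alkaline-Gel
    Densitometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the number of ribonucleotides embedded in genomic DNA
    from densitometry of alkali-fragmented DNA resolved on denaturing agarose
    gels.  Lane intensity profiles are background-subtracted, smoothed with a
    penalized cubic spline, calibrated against a DNA ladder through the
    log-linear electrophoretic mobility model, and converted to molar fragment
    counts.  Per-genome ribonucleotide totals are derived with a truncation
    correction for fragments migrating beyond the signal-to-noise cutoff,
    control-lane breakage is subtracted, and densities are reported per Gb of
    DNA.  Includes a synthetic gel simulator (random genome breakage, band
    rendering, detector noise) for validation, binned fragment-size
    distributions, within-lane fraction profiles, and the deconvolution of
    replicative polymerase contributions to genome synthesis from strain
    ribonucleotide totals and steric-gate incorporation frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
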