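Package: mrellg
Title: Molecular-Replacement Feasibility from the Expected Log-Likelihood Gain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative machinery for judging whether a predicted protein
    model can phase a crystal structure by molecular replacement. Implements
    the sigma-A curve relating model coordinate error (r.m.s.d.), fraction of
    total scattering (fm) and resolution to the expected log-likelihood gain
    (eLLG); a synthetic diffraction laboratory (direct-summation structure
    factors, Wilson normalization, controlled target/model simulation); the
    Rice/Woolfson amplitude log-likelihood-gain engine with effective-r.m.s.d.
    (VRMS) refinement and pose-significance classification; predicted-model
    preparation (error-to-B-factor weighting, error-threshold trimming,
    ensemble divergence trimming, scattering-fraction estimation); structural
    model-quality scores (superposition r.m.s.d., GDT_TS/GDT_HA, LCS, an
    LGA_S-style combination, helix-axis geometry); and a phasing-method survey
    classifier for PDB-style metadata tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    yaml
Config/testthat/edition: 3
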