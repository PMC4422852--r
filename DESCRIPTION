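Package: ecdims
Title: Rationalizing Phosphopeptide Electron Capture Dissociation with Ion
    Mobility and Conformer Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for interpreting the electron capture dissociation (ECD)
    behaviour of doubly protonated phosphopeptides in the light of traveling
    wave ion mobility spectrometry (TWIMS) and model conformer ensembles.
    Generates theoretical c/z fragment ions for (phospho)peptides, assigns
    centroided peak lists, computes relative fragment-ion abundances and
    cleavage-site coverage maps with gap detection; calibrates TWIMS drift
    times against peptides of known collision cross section (CCS) by the
    corrected power-law method and measures deviations from a random-coil
    trendline; estimates orientation-averaged projection-approximation CCS
    of atomic structures; filters conformer ensembles to an experimental CCS
    window, clusters them after rigid superposition, and classifies
    phosphate-to-basic-site contacts as salt bridges or (ionic) hydrogen
    bonds with a 4 Angstrom charged-atom distance criterion under competing
    protonation hypotheses; and scores each hypothesis against the observed
    ECD cleavage coverage.  Includes seeded synthetic generators for
    conformer ensembles with planted contacts, calibrant tables, fragment
    peak lists and arrival-time profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
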