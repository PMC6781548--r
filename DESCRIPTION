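Package: saxakin
Type: Package
Title: Mechanistic Degradation Kinetics of Saxagliptin in PEG-Plasticized
    Tablet Film Coats
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Simulates and regresses a mechanistic kinetic model of coupled
    polyethylene-glycol (PEG) autoxidation and saxagliptin degradation in an
    active tablet film coat. PEG oxidation generates reactive low molecular
    weight impurities (glycolic acid, acetaldehyde, formaldehyde, formic
    acid); formic acid lowers the micro-environmental pH, which steers
    saxagliptin between hydroxide-catalyzed intramolecular cyclization
    (cyclic amidine and its epimer) and proton-catalyzed formylation (formyl
    amide). The package provides fixed-step Runge-Kutta integration of the
    reaction network with step-halving convergence control, staged
    Levenberg-Marquardt regression of Arrhenius parameters against
    multi-condition accelerated stability data, a synthetic stability-study
    generator with observation noise and quantitation-limit censoring, and
    scaled-and-centered multiple-linear-regression and response-correlation
    analysis of study tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
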