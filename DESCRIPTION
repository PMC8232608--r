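Package: protonRBE
Title: Relative Biological Effectiveness and Oxygen Enhancement Ratio of
    Proton Beams from DNA Damage Yields
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Estimates the relative biological effectiveness (RBE) and the
    oxygen enhancement ratio (OER) of a 62-MeV therapeutic proton beam from
    clustered DNA damage yields.  Implements the standard seven-category
    classification of clustered lesions on duplex DNA, conversion of non-DSB
    clusters into enzymatic double-strand breaks during base- and
    nucleotide-excision repair, repair-misrepair-fixation (RMF) model
    linear-quadratic coefficients, and survival-level RBE and OER at 21%, 2%
    and 0.1% oxygen.  Ships seedable Monte Carlo emulators of damage induction
    and per-cluster excision-repair outcomes so the full pipeline runs without
    external damage-simulation software, together with packaged damage-yield
    and repair-outcome tables for six depths along the proton track and the
    cobalt-60 reference radiation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
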