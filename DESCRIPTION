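Package: empathynet
Title: Spiking Neural Circuit Models of Empathically Motivated Caregiving
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Izhikevich spiking-network models of the limbic
    circuitry proposed to mediate personal distress, weak and strong
    empathic concern, and compassion (BLMA-AI-aMCC-mPFC plus the
    mPOA-VTA-NAc-VP caregiving pathway, with an mOFC extension for
    self-attachment therapy). Implements the phase-structured
    current-injection protocol (low/medium/high stimulation bands, 10%
    per-step target perturbation, linear ramp rules), a ventral-dorsal
    negative-binomial gradient for self-other representations in mPFC,
    windowed mean-firing-rate summaries with rule-based network-state
    classification, and random-search calibration of projection weights
    against a packaged reference table of firing rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    optparse,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
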