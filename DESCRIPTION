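Package: circadopa
Title: Circadian Clock and Dopamine Enzyme Rhythm Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulator for a mammalian circadian clock model
    coupled to the dopaminergic system. Implements a 16-state ordinary
    differential equation network comprising the core
    BMAL1-CLOCK/PER/CRY protein-sequestration loop, the REV-ERB/ROR
    secondary feedback loop acting on Bmal1, and downstream tyrosine
    hydroxylase (TH), monoamine oxidase (MAO) and dopamine D3 receptor
    (DRD3) expression. Provides sinusoidal light entrainment,
    constant-darkness protocols, CRY-deficiency and REV-ERB-agonist
    perturbation experiments, rhythm analysis (periods, peak phases,
    trough-to-peak ratios, phase shifts, re-entrainment times), scaled
    TH/MAO expression profiles for driving external dopamine
    synthesis/release models, and a plain-text configuration format with
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
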