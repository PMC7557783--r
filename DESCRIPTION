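Package: loomdiscrim
Title: Speed and Speed-Change Discrimination for Looming Stimuli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of two-interval forced-choice (2IFC)
    experiments on motion-in-depth perception with looming stimuli. Provides
    a stimulus geometry engine mapping constant world speed in depth to
    retinal angular expansion, signal-detection observer models for
    candidate decision strategies (within-interval speed change, start/end
    speed comparison, mean speed, distance and duration cues), cumulative
    normal psychometric fitting with 75 percent thresholds under two
    speed-change parameterizations, exact binomial catch-trial cue
    classification, a group statistics layer (pooled and paired t tests,
    JZS default Bayes factors with a Cauchy(0, 0.707) prior, Pearson
    correlation, Bonferroni correction), and a synthetic cohort generator
    that reproduces the trial structure of a method-of-constant-stimuli
    design (7 levels x 30 trials per condition plus interleaved catch
    trials).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
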