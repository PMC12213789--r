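Package: goalgrow
Title: Goal-Neuron Growth in a Foraging Neural Agent
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discrete-time simulation of a neural-network organism wandering
    a square field of colored objects. The organism's recurrent goal layer can
    learn in four modes of increasing plasticity: no learning, touch-triggered
    multiplicative weight updates, gradient reinforcement gated by a global
    activity estimate, and coherence-gated structural growth that generates
    new goal neurons from low-instability donors. Includes the batch
    mode-comparison experiment with nonparametric statistics (Friedman,
    Wilcoxon matched pairs, two-sample t with Cohen's d), trajectory-level
    trap/confinement metrics, a relocation ("come back") probe, deterministic
    seeded substreams, and JSON/CSV/JSONL serialization of runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
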