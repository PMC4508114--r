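Package: oncosim
Title: Agent-Based Simulation of Tumor Growth and Angiogenesis Driven by
    Hierarchical Statecharts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A deterministic, seedable three-dimensional agent-based
    simulator of avascular tumor growth, hypoxia-driven VEGF signalling and
    sprouting angiogenesis.  Tumor cells and endothelial cells are driven by
    hierarchical statecharts (nested states and orthogonal regions, executed
    with run-to-completion semantics) and are coupled to oxygen and VEGF
    concentration fields evolved by explicit finite-difference
    reaction-diffusion on a shared lattice.  The package also implements a
    reactive-animation wire protocol: per-step object diffs are serialized
    as XML messages, runs can be recorded to and replayed from
    newline-delimited stream files, and inbound XML commands (parameter
    changes, kill/create, queries) can be applied to a running simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
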