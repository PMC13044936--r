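Package: sampleflow
Title: Hybrid Command-Line and R Workflow Management with Sample Metadata
    Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A workflow management engine for multi-step data analyses that
    mix external command-line tools with native R code. Command-line steps
    are declared with a subset of the Common Workflow Language (CWL)
    CommandLineTool standard and rendered into concrete per-sample command
    lines driven by a tabular sample sheet (targets file); R steps run in a
    shared session. Workflows are defined in literate Markdown documents,
    executed as a directed acyclic graph with per-step and per-sample status
    tracking, checkpointing and resume, and summarised as topology graphs
    (DOT, mermaid, SVG/HTML) plus technical and scientific run reports.
    Bundled templates, including a mock variant-calling (VAR-Seq) workflow,
    demonstrate scatter/gather execution with mock tools and toy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    commonmark,
    processx,
    parallel,
    utils,
    stats,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
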