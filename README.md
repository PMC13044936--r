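# sampleflow

A workflow management engine for multi-step data analyses that mix
external command-line tools with native R code — the common shape of
omics pipelines, where read processing, alignment and variant calling run
as subprocesses while statistics, plots and reports are produced in R.

`sampleflow` is aimed at analysts who want one reproducible artifact per
project: a literate Markdown document that *is* the workflow definition,
drives execution as a directed acyclic graph (DAG) with per-step and
per-sample status tracking and resume, and re-renders afterwards as the
scientific report of the analysis.

## What it does

* **Command-line steps via CWL.** External tools are described with a
  subset of the Common Workflow Language `CommandLineTool` class. The
  engine implements the CWL argument-binding rules — `position`,
  `prefix`, `separate`, `itemSeparator`, boolean and array handling — and
  renders one concrete `argv` per sample, with no shell interpretation
  ever (reproducibility and injection safety). A one-line template
  grammar (`tool_from_template("echo -m <msg:string:hello>")`) generates
  tool descriptions for simple cases.
* **R steps.** Code chunks run in a session shared across the run, so
  later steps see objects defined by earlier ones, with warnings and
  errors captured per unit.
* **Sample-sheet propagation.** A tab-separated *targets* file (unique
  `SampleName` plus arbitrary metadata columns) drives per-sample
  execution; `_Column_` placeholders are substituted per row, and a
  step's declared outputs can become the targets of a downstream step, so
  sample identity is carried through the whole pipeline.
* **Execution with checkpointing.** Units — (step, sample) pairs — run in
  topological order; samples within a step may run concurrently (scatter)
  and a step completes before dependents start (gather). State is
  persisted to `.sprproject/status.json` after every unit; `resume`
  skips units recorded successful whose output files are intact and
  re-runs exactly the downstream closure of anything invalidated.
* **Topology graphs and reports.** Deterministic DOT, mermaid and SVG/
  HTML topology graphs with color-coded status and per-node tooltips
  (success fraction, mean duration), a technical report (commands, tool
  versions, per-unit status, stderr excerpts) and a scientific report
  (the literate narrative with status badges and embedded artifacts).

A command unit is *successful* only if it exits 0 **and** all declared
outputs exist; exit 0 with a missing declared output is a *warning*,
non-zero exit an *error*. Step status rolls up as the worst unit state
(error > warning > running > pending > success).

## Worked example

The bundled `varseq_mock` template is a 35-step mock variant-calling
(VAR-Seq) cohort workflow: per-sample QC, trimming, alignment and
gVCF-style calling fan into cohort-level joint genotyping, filtering and
annotation, followed by gene-burden, pathway-enrichment and drug-target
steps. All tools are deterministic mock scripts on toy text data — the
point is the workflow structure, not the biology.

```r
library(sampleflow)
init_project("demo", template = "varseq_mock")   # data, param/, tools/, workflow.md
wf <- import_workflow("demo/workflow.md", "demo")
wf
#> <sf_workflow> 35 step(s) in /.../demo
#>   load_config              code    pending  deps: -
#>   check_input              code    pending  deps: load_config
#>   fastq_stats              command pending  deps: check_input
#>   ...
wf <- run_workflow(wf)
table(wf_status(wf)$state)
#>
#> success
#>      51
wf$last_run$executed
#> [1] 51
```

51 units = 3 samples across the per-sample steps plus the single-unit
cohort and code steps. A second `run_workflow(wf, resume = TRUE)`
executes 0 units; deleting `demo/results/S2.sorted.sam` and resuming
re-executes exactly the 25 units downstream of that alignment.

Graphs and reports:

```r
g <- build_graph(wf)
writeLines(to_dot(g), "demo/results/reports/topology.dot")
writeLines(to_html_graph(g), "demo/results/reports/topology.html")
write_report(technical_report(wf), "demo/results/reports/technical_report.html")
write_report(scientific_report(wf), "demo/results/reports/scientific_report.html")
```

The same lifecycle is available from a shell via the bundled CLI
(`system.file("cli", "sampleflow", package = "sampleflow")`):

```sh
sampleflow init --template varseq_mock demo && cd demo
sampleflow run                 # exit 0 all-success, 1 any error, 2 precondition
sampleflow status
sampleflow plot -f html -o results/reports/topology.html
sampleflow report
```

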