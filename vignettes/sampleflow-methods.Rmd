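---
title: "sampleflow: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sampleflow: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sampleflow` is a workflow management engine for hybrid pipelines that
mix external command-line tools with native R code. This vignette
documents the model behind it: what the core objects mean, the rules the
engine follows, the numerical and design choices that were genuinely
open, and what the bundled mock workflows do and do not demonstrate.

## The workflow model

A workflow is an ordered registry of *steps* over a shared *project
directory* (`data/`, `param/`, `results/`, `targets.tsv`,
`workflow.md`, and a hidden state directory `.sprproject/`). Steps come
in two kinds:

* a **command step** wraps a CWL `CommandLineTool` description, a set of
  job values, and a *targets* table (sample sheet); it renders one
  concrete command per sample row;
* a **code step** wraps R source evaluated in a session shared by all
  code steps of a run.

Execution is tracked per *unit* — a (step, sample) pair; code steps use
the single pseudo-sample `"_step_"` so both kinds share one bookkeeping
scheme. Unit states are `pending`, `running`, `success`, `warning`,
`error`, and a step's rolled-up state is the worst of its units under
the order error > warning > running > pending > success — a conservative
roll-up chosen so a partially failed scatter step colours as failed in
the topology graph.

### Acyclicity by construction

Steps are appended one at a time and every dependency must already be
registered. This single local rule replaces global cycle detection: the
registry order is a topological order by construction, and a cycle can
never be introduced. `topological_order()` still runs Kahn's algorithm
(with lexicographic tie-breaking among ready steps) so that graphs,
reports and partial runs are reproducible regardless of append order
among independent branches; it also detects cycles defensively if a
workflow object is manipulated outside the public API. Literate imports
inherit the same guarantee because chunk dependencies must point to
*earlier* chunks.

## Sample metadata

The targets file is a UTF-8 TSV whose comment lines (leading `#`)
precede the header. Only `SampleName` is mandatory; it must be unique
and non-empty because it is the join key for status records, output
naming and reports. Values may not contain tabs — this keeps the dialect
unambiguous without quoting rules — and empty cells are allowed for
optional metadata. Columns `FileName1`/`FileName2` are the conventional
paired-end spelling; the engine itself is agnostic and treats all
columns uniformly.

Metadata propagates downstream via `outputs_to_targets()`: the expected
outputs of a rendered command step become columns of a derived targets
table with the same `SampleName` set, so the sample lineage is invariant
along any chain of steps. This is tested as a property (the SampleName
multiset never changes) rather than per-pipeline.

## Command-line steps and the CWL subset

Command steps are declared with a subset of CWL `CommandLineTool`
(versions v1.0–v1.2 accepted): typed inputs (`string`, `int`,
`boolean`, `File`, `Directory`, `string[]`, `File[]`, optional `?`
variants), input bindings (`position`, `prefix`, `separate`,
`itemSeparator`), literal and positioned `arguments`, `File` outputs
located by glob patterns, and `stdout` capture. Anything outside the
subset — `Workflow` documents, JavaScript/parameter expressions,
scatter directives, schema imports — is rejected with a named error
rather than silently misinterpreted; `requirements`/`hints` are parsed,
stored and ignored with a warning.

Binding follows the CWL rules: bindings are collected from arguments and
bound inputs and stably sorted by `position`. CWL leaves the tie order
underspecified, so it is fixed here: arguments in declaration order
before inputs, inputs lexicographic by id. Booleans emit their prefix
only when true; `separate: false` concatenates prefix and value into one
token; arrays with an `itemSeparator` emit one joined token, arrays
without one repeat the prefix per element (the simplest behaviour within
the subset, covered by conformance fixtures). `argv` is passed to
process creation verbatim — there is never a shell between the engine
and the tool.

The test suite cross-checks `bind_command()` token-for-token against an
independent Python implementation of the same standard on a battery of
fixture tool/job pairs covering every binding feature; the two
implementations share no code.

### Placeholders and gather inputs

Job values may contain `_Column_` placeholders — an uppercase-initial
alphanumeric token between single underscores — substituted per sample
from the targets row, with case-insensitive column matching. The
uppercase-initial restriction exists to avoid false positives on
ordinary snake_case file names. Output globs and `stdout` patterns
undergo the same substitution (typically `_SampleName_`), and relative
output paths are placed under `results/`.

A gather step can reference the complete set of an upstream step's
outputs with a value `{from_step: <id>, output: <output-id>}`, resolved
at append time to the list of expected output paths — this is how the
mock joint-genotyping step receives all per-sample gVCF files as a
`File[]` input.

## Literate workflow documents

Workflows are written as plain Markdown with annotated fences:
```` ```{lang step="name" kind="cmd|code" deps="a,b" run="true"} ````.
Fences without `step=` are narrative. `cmd` bodies are small YAML
mappings (`tool`, `targets`, `inputs`, `outputs_map`); routing all
command steps through CWL files rather than raw shell keeps the
document declarative and the rendering auditable. Chunks annotated
`run="false"` are kept as documentation and not registered as steps.

Parsing is line-based and lossless: segments concatenate back to the
exact source bytes. A tokenizing Markdown renderer is deliberately not
used for parsing, because renderers normalise whitespace and would break
the byte-exact round trip; `commonmark` is used only to render reports
to HTML. `export_workflow()` writes one fence per step with its verbatim
body, so export–parse–import preserves the step registry (ids, kinds,
dependencies, bodies) — verified on randomized synthetic documents.

## Execution, state, and resume

Units run in topological order; within a command step, samples may run
concurrently via `parallel::mclapply` (local scatter), and a step
completes before dependents start (gather). Code steps always run
serially in the shared session. The engine is deterministic; code steps
wanting randomness must seed themselves.

After every unit the state store (`.sprproject/status.json`: schema
version, per-unit state/timestamps/durations, rendered argv, log paths,
captured tool versions) is rewritten, which is what makes crash
recovery cheap. Timestamps are recorded at millisecond resolution — the
exact value a JSON round trip preserves — so a reloaded status matrix is
equal, not merely close, to the in-memory one.

*Success* for a command unit requires exit 0 **and** the presence of all
declared outputs: output existence is the only tool-agnostic
completeness check available, and it doubles as the resume criterion.
Exit 0 with a missing declared output is a *warning* (the tool claimed
success but the contract was not met); non-zero exit is an *error*.
This rule is a normative choice of this engine.

With `resume = TRUE` a unit is skipped iff its recorded state is
`success`, all its expected outputs exist, **and** no upstream unit it
consumes was re-executed in this run — the third condition makes the
re-run set equal to the downstream closure of whatever was invalidated,
computed at unit granularity (per-sample chains re-run only the affected
sample; gather steps re-run whenever any feeding sample does).

Two consequences worth knowing:

* the shared R session is per-run, so a code step that consumes
  *in-memory* objects from an earlier code step must re-run together
  with it; steps that communicate through files under `results/` (as all
  bundled templates do downstream of setup) resume cleanly;
* version capture runs `<exe> --version` once per distinct executable
  with a 5 s timeout and stores the first output line, or `"unknown"` on
  failure — enough for the technical report without per-tool knowledge.

On unit failure the default policy cancels pending units in the failed
step's downstream closure while independent branches continue
(maximizing useful work per run, consistent with DAG semantics);
`halt_all = TRUE` gives the strict alternative. Dry runs render and log
the would-be commands under `.sprproject/logs/` and touch nothing else.

Remote/HPC executors are represented only by the per-step resource
declaration (`cores`, `memory_mb`, `walltime_min`, defaults 1/1024/60);
scheduler integration is environment-specific and out of scope — the
local engine consumes `cores` to cap scatter concurrency.

## Graphs and reports

Topology graphs are emitted as DOT, mermaid, and a self-contained
layered SVG (longest-path layering; native `<title>` tooltips carry the
success fraction, mean unit duration and attention-worthy samples).
Status colours: pending gray `#cccccc`, running blue `#74a9cf`, success
green `#a1d99b`, warning orange `#fdae6b`, error red `#fb6a4a` — the
palette itself is a free choice. All text outputs are deterministic for
a fixed run state; the only timestamp lives in one front-matter line of
the reports, and the report's run window is derived from the persisted
unit records rather than the wall clock so regeneration is stable.

The technical report lists, per step in topological order, the unit
status table, the rendered argv verbatim, captured tool versions, and
the last 20 stderr lines of any unit that did not succeed. The
scientific report re-renders the literate source: narrative preserved,
each chunk replaced by its body, a status badge, and the artifacts the
step wrote (SVG/PNG images embedded, tables inlined up to 50 rows —
a readability threshold, full files always linked). Mismatches between
document and workflow are listed in an appendix, not fatal. HTML output
is generated with `commonmark` in a static template; interactivity is
limited to native SVG tooltips, keeping reports fully offline.

## Templates and toy data

`init_project()` materializes a complete offline project.
The fixture generator writes, per sample, a toy reads file (30
`id sequence` records, lengths 8–20, alphabet ACGT), a 10-line toy
reference, and a matching `targets.tsv` — three samples and seed 1 by
default; small enough that the full demo runs in seconds while still
producing non-trivial per-sample variation. The same seed always yields
byte-identical files.

The `varseq_mock` template is a 35-step mock VAR-Seq cohort analysis
reproducing the scatter/gather shape of a gVCF-based pipeline: QC,
trimming, reference indexing, alignment, sorting, duplicate marking and
per-sample variant calling (scatter) feed a cohort-level joint
genotyping step (gather: a `File[]` input collecting every per-sample
gVCF), then filtering, annotation, per-sample tables, frequency and
sharing patterns, gene-level burden, a hypergeometric pathway
enrichment (`phyper` over a bundled 20-gene / 3-pathway table with
Benjamini–Hochberg adjustment via `p.adjust`), and drug-target mapping
over a toy gene–drug table. The decomposition into exactly 35 steps is
fixed in the template document. All tools are deterministic shell text
transforms (positions, qualities and gene assignments derived
arithmetically from the input), so every engine feature is exercised —
scatter/gather, command+code mixing, targets inheritance — without any
bioinformatics dependency and without claiming biological validity.

What passing the mock workflow does **not** show: behaviour with real
tool output volumes, with tools that write outside their declared
outputs, with flaky or non-deterministic tools, or at cohort sizes
where scheduling and I/O dominate. The mock tools always honour their
output contract; real tools sometimes do not, which is exactly why the
success rule checks output existence.

## Numerical and degenerate-input choices

* Timestamps/durations: milliseconds (see above); durations are
  reported with `%.3f`.
* Empty workflow: valid; empty graph, empty reports, no-op runs.
* Header-only targets tables: valid; command steps over them render
  zero units.
* Empty arrays bind to zero tokens; absent optional inputs bind to
  nothing; boolean false binds to nothing.
* Corrupt state files raise an explicit error with a recovery hint
  (`ignore_state = TRUE` discards the state).
* Tie-breaks everywhere (topological order, binding order, report and
  graph ordering) are lexicographic and documented, never incidental.

## Problem sizes used in the checks

The shipped test-and-measurement suite runs the full 35-step mock
workflow with 3 samples (51 units), compares CWL binding on 11 fixture
pairs against the independent oracle, and exercises round trips on 20
randomized targets tables and 100 randomized literate documents —
sizes chosen so the complete suite documents the engine's behaviour in
seconds while covering every feature path.
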