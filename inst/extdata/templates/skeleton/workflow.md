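# Skeleton workflow

A minimal outline for building custom analyses: one R setup step, one
per-sample command-line step, and one R gather step. Replace the steps
with your own and extend the chain as needed.

## Setup

Load the sample sheet and make its sample identifiers available to later
code steps (all R steps share one session per run).

```{r step="setup" kind="code"}
dir.create("results", showWarnings = FALSE)
targets <- read.delim("targets.tsv", comment.char = "#",
                      stringsAsFactors = FALSE)
sample_ids <- targets$SampleName
cat("loaded", length(sample_ids), "samples\n")
```

## Per-sample greeting

A command-line step: one `echo` invocation per sample, with stdout
captured to a per-sample results file.

```{yaml step="greet" kind="cmd" deps="setup"}
tool: param/greet.cwl
targets: targets.tsv
```

## Gather

Collect the per-sample outputs into a summary.

```{r step="summarize" kind="code" deps="greet"}
files <- sort(Sys.glob("results/*.greeting.txt"))
lines <- unlist(lapply(files, readLines))
writeLines(c(paste("greetings:", length(lines)), lines),
           "results/summary.txt")
cat("summarized", length(files), "greeting files\n")
```
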