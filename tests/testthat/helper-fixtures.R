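# shared test helpers: project scaffolding, CWL conformance fixtures,
# the independent Python oracle, and random literate documents

make_project <- function(dir = tempfile("proj")) {
  for (d in c("data", "results", "param", "tools"))
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  t <- sf_targets(data.frame(
    FileName = c("data/a.txt", "data/b.txt"),
    SampleName = c("S1", "S2"),
    Factor = c("A", "B"), stringsAsFactors = FALSE))
  write_targets(t, file.path(dir, "targets.tsv"))
  writeLines(c("r1 ACGTACGT", "r2 TTGGCCAA"), file.path(dir, "data", "a.txt"))
  writeLines(c("r1 GGGGCCCC", "r2 AATTAATT"), file.path(dir, "data", "b.txt"))
  dir
}

oracle_path <- function() {
  p <- testthat::test_path("cwl-oracle.py")
  stopifnot(file.exists(p))
  normalizePath(p)
}

oracle_bind <- function(tool_path, job_path) {
  out <- processx::run("python", c(oracle_path(), "bind",
                                   normalizePath(tool_path),
                                   normalizePath(job_path)))
  strsplit(sub("\n$", "", out$stdout), "\n", fixed = TRUE)[[1]]
}

oracle_dot_valid <- function(dot_path) {
  res <- processx::run("python", c(oracle_path(), "dot",
                                   normalizePath(dot_path)),
                       error_on_status = FALSE)
  res$status == 0L
}

# >= 10 tool/job pairs covering position sorting, prefixes,
# separate: false, booleans, arrays with and without itemSeparator,
# File values, literal arguments, tie-breaking, and stdout capture
cwl_fixtures <- function() {
  list(
    minimal = list(
      tool = "
cwlVersion: v1.2
class: CommandLineTool
baseCommand: echo
inputs:
  msg:
    type: string
    inputBinding: {position: 1}
outputs: []
",
      job = "msg: hello\n"),
    position_sorting = list(
      tool = "
cwlVersion: v1.2
class: CommandLineTool
baseCommand: tool
inputs:
  third:
    type: string
    inputBinding: {position: 3, prefix: -c}
  first:
    type: string
    inputBinding: {position: 1, prefix: -a}
  second:
    type: string
    inputBinding: {position: 2, prefix: -b}
outputs: []
",
      job = "third: vz\nfirst: vx\nsecond: vy\n"),
    prefix_and_bare = list(
      tool = "
cwlVersion: v1.2
class: CommandLineTool
baseCommand: [aligner, map]
inputs:
  threads:
    type: int
    inputBinding: {position: 2, prefix: -p}
  reads:
    type: File
    inputBinding: {position: 1}
outputs: []
",
      job = "threads: 4\nreads: {class: File, path: data/r.fq}\n"),
    separate_false = list(
      tool = "
cwlVersion: v1.2
class: CommandLineTool
baseCommand: prog
inputs:
  out:
    type: string
    inputBinding: {position: 1, prefix: '--out=', separate: false}
outputs: []
",
      job = "out: a.txt\n"),
    booleans = list(
      tool = "
cwlVersion: v1.2
class: CommandLineTool
baseCommand: prog
inputs:
  verbose:
    type: boolean
    inputBinding: {position: 1, prefix: -v}
  quiet:
    type: boolean
    inputBinding: {position: 2, prefix: -q}
  name:
    type: string
    inputBinding: {position: 3, prefix: -n}
outputs: []
",
      job = "verbose: true\nquiet: false\nname: x\n"),
    array_item_separator = list(
      tool = "
cwlVersion: v1.2
class: CommandLineTool
baseCommand: prog
inputs:
  libs:
    type: string[]
    inputBinding: {position: 1, prefix: -l, itemSeparator: ','}
outputs: []
",
      job = "libs: [m, z, pthread]\n"),
    array_repeat_prefix = list(
      tool = "
cwlVersion: v1.2
class: CommandLineTool
baseCommand: prog
inputs:
  incs:
    type: string[]
    inputBinding: {position: 1, prefix: -I}
outputs: []
",
      job = "incs: [a, b]\n"),
    array_positional_files = list(
      tool = "
cwlVersion: v1.2
class: CommandLineTool
baseCommand: merge
inputs:
  outfile:
    type: string
    inputBinding: {position: 1, prefix: -o}
  parts:
    type: File[]
    inputBinding: {position: 2}
outputs: []
",
      job = "
outfile: all.txt
parts:
  - {class: File, path: p1.txt}
  - {class: File, path: p2.txt}
  - {class: File, path: p3.txt}
"),
    literal_arguments = list(
      tool = "
cwlVersion: v1.2
class: CommandLineTool
baseCommand: prog
arguments:
  - --strict
  - {position: 2, prefix: --mode, valueFrom: fast}
inputs:
  inp:
    type: string
    inputBinding: {position: 1}
outputs: []
",
      job = "inp: data.txt\n"),
    tie_breaking = list(
      tool = "
cwlVersion: v1.2
class: CommandLineTool
baseCommand: prog
arguments:
  - {position: 1, valueFrom: argfirst}
inputs:
  zeta:
    type: string
    inputBinding: {position: 1}
  alpha:
    type: string
    inputBinding: {position: 1}
outputs: []
",
      job = "zeta: zz\nalpha: aa\n"),
    defaults_and_optional = list(
      tool = "
cwlVersion: v1.2
class: CommandLineTool
baseCommand: prog
inputs:
  level:
    type: int
    default: 3
    inputBinding: {position: 1, prefix: --level}
  tag:
    type: string?
    inputBinding: {position: 2, prefix: --tag}
outputs: []
",
      job = "{}\n"),
    stdout_capture = list(
      tool = "
cwlVersion: v1.2
class: CommandLineTool
baseCommand: echo
stdout: results/_SampleName_.log
inputs:
  msg:
    type: string
    inputBinding: {position: 1}
outputs:
  log:
    type: stdout
",
      job = "msg: captured\n"))
}

write_fixture <- function(fx, dir = tempfile("cwlfx")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tool_path <- file.path(dir, "tool.cwl")
  job_path <- file.path(dir, "job.yml")
  writeLines(fx$tool, tool_path)
  writeLines(fx$job, job_path)
  list(tool = tool_path, job = job_path)
}

# random literate documents for round-trip property tests
random_doc_text <- function(n_steps = 5) {
  ids <- paste0("step_", letters[seq_len(n_steps)])
  parts <- c("# Random workflow", "")
  for (i in seq_along(ids)) {
    deps <- if (i > 1 && stats::runif(1) < 0.7)
      sample(ids[seq_len(i - 1)], sample(seq_len(min(2, i - 1)), 1))
    else character()
    body <- paste0("x_", i, " <- ", sample(1:100, 1),
                   if (stats::runif(1) < 0.5)
                     paste0("\ncat('step ", i, "\\n')") else "")
    attrs <- paste0('r step="', ids[i], '" kind="code"')
    if (length(deps))
      attrs <- paste0(attrs, ' deps="', paste(deps, collapse = ","), '"')
    parts <- c(parts,
               if (stats::runif(1) < 0.5) c(paste("Narrative", i), ""),
               paste0("```{", attrs, "}"), body, "```", "")
  }
  paste0(paste(parts, collapse = "\n"), "\n")
}

step_registry <- function(wf) {
  lapply(wf$steps, function(s)
    list(id = s$id, kind = s$kind, deps = sort(s$deps), body = s$body))
}
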