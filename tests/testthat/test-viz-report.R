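demo_wf <- function() {
  dir <- make_project()
  wf <- new_workflow(dir)
  wf <- append_step(wf, code_step("A", "1"))
  wf <- append_step(wf, code_step("B", "1", deps = "A"))
  wf <- append_step(wf, code_step("C", "1", deps = "A"))
  wf <- append_step(wf, code_step("D", "1", deps = c("B", "C")))
  wf
}

test_that("graphs mirror the workflow structure exactly", {
  wf <- demo_wf()
  g <- build_graph(wf)
  expect_equal(g$nodes$id, c("A", "B", "C", "D"))
  expect_equal(nrow(g$edges), 4)
  expect_setequal(paste(g$edges$from, g$edges$to),
                  c("A B", "A C", "B D", "C D"))
  expect_true(all(g$nodes$state == "pending"))
  expect_equal(g$nodes$frac, rep("0/1", 4))

  empty <- build_graph(new_workflow(make_project()))
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)
})

test_that("graph faithfulness holds on random workflows", {
  set.seed(3)
  for (rep in 1:10) {
    dir <- make_project()
    wf <- new_workflow(dir)
    n <- sample(2:7, 1)
    ids <- paste0("s", seq_len(n))
    for (i in seq_len(n)) {
      prev <- ids[seq_len(i - 1)]
      deps <- prev[stats::runif(length(prev)) < 0.4]
      wf <- append_step(wf, code_step(ids[i], "1", deps = deps))
    }
    g <- build_graph(wf)
    expect_setequal(g$nodes$id, names(wf$steps))
    want_edges <- sampleflow:::wf_edges(wf)
    expect_setequal(paste(g$edges$from, g$edges$to),
                    paste(want_edges$from, want_edges$to))
  }
})

test_that("node labels and colors reflect per-sample status counts", {
  dir <- make_project()
  wf <- new_workflow(dir)
  tool <- parse_tool(paste0(
    "cwlVersion: v1.2\nclass: CommandLineTool\nbaseCommand: echo\n",
    "inputs:\n  m: {type: string, default: hi,\n",
    "      inputBinding: {position: 1}}\noutputs: []\n"))
  targets <- sf_targets(data.frame(SampleName = c("S1", "S2", "S3")))
  wf <- append_step(wf, command_step("call", tool, targets))
  wf <- sampleflow:::set_unit_state(wf, "call", "S1", "success",
                                    duration_s = 0.2)
  wf <- sampleflow:::set_unit_state(wf, "call", "S2", "success",
                                    duration_s = 0.4)
  wf <- sampleflow:::set_unit_state(wf, "call", "S3", "error",
                                    duration_s = 0.1)
  g <- build_graph(wf)
  expect_equal(g$nodes$frac, "2/3")
  expect_equal(g$nodes$state, "error")
  expect_match(g$nodes$tooltip, "success 2/3")
  expect_match(g$nodes$tooltip, "attention: S3")
  dot <- to_dot(g)
  expect_match(dot, '"call" \\[label="call\\\\n2/3", fillcolor="#fb6a4a"')
})

test_that("DOT output is deterministic, structured, and grammatical", {
  wf <- demo_wf()
  g <- build_graph(wf)
  dot <- to_dot(g)
  expect_identical(dot, to_dot(build_graph(wf)))
  expect_match(dot, '"A" -> "B";', fixed = TRUE)
  p <- tempfile(fileext = ".dot")
  writeLines(dot, p)
  expect_true(oracle_dot_valid(p))
  mer <- to_mermaid(g)
  expect_match(mer, "flowchart TD")
  expect_match(mer, "A --> B")
  svg <- to_svg(g)
  expect_match(svg, "<svg")
  expect_match(svg, "<title>")
  html <- to_html_graph(g)
  expect_match(html, "<!DOCTYPE html>")
})

test_that("technical reports cover every unit, argv and failures", {
  dir <- make_project()
  wf <- new_workflow(dir)
  targets <- read_targets(file.path(dir, "targets.tsv"))
  tool <- parse_tool(paste0(
    "cwlVersion: v1.2\nclass: CommandLineTool\nbaseCommand: echo\n",
    "inputs:\n  m:\n    type: string\n    default: hi _SampleName_\n",
    "    inputBinding: {position: 1}\noutputs: []\n",
    "stdout: results/_SampleName_.txt\n"))
  wf <- append_step(wf, command_step("say", tool, targets))
  wf <- append_step(wf, code_step("oops", "stop('kaput')", deps = "say"))
  wf <- run_workflow(wf)
  rep <- technical_report(wf)
  expect_s3_class(rep, "sf_report")
  txt <- rep$text
  expect_match(txt, "## Step `say` \\(command\\)")
  expect_match(txt, "\\[S1\\] echo hi S1 > results/S1.txt")
  expect_match(txt, "\\[S2\\] echo hi S2 > results/S2.txt")
  expect_match(txt, "## Step `oops`")
  expect_match(txt, "kaput")      # stderr excerpt of the failed unit
  expect_match(txt, "Tool versions")
  # every unit appears exactly once in the status tables
  for (s in c("S1", "S2"))
    expect_equal(lengths(regmatches(txt, gregexpr(
      paste0("\\| ", s, " \\|"), txt))), 1)
  # regeneration without rerun is identical except the timestamp line
  rep2 <- technical_report(wf)
  strip_ts <- function(x) grep("^Generated: ", strsplit(x, "\n")[[1]],
                               value = TRUE, invert = TRUE)
  expect_identical(strip_ts(rep2$text), strip_ts(rep$text))
})

test_that("scientific reports keep narrative, badge steps, and embed artifacts", {
  dir <- make_project()
  doc_path <- file.path(dir, "workflow.md")
  writeLines(c("# My analysis", "", "Intro text stays.", "",
               "```{r step=\"draw\" kind=\"code\"}",
               "writeLines('<svg xmlns=\"http://www.w3.org/2000/svg\"/>',",
               "           'results/plot.svg')", "```", "",
               "Closing remarks."), doc_path)
  wf <- import_workflow(doc_path, dir)
  wf <- run_workflow(wf)
  rep <- scientific_report(wf)
  expect_match(rep$text, "Intro text stays.")
  expect_match(rep$text, "Closing remarks.")
  expect_match(rep$text, "### Step `draw` \\*\\*Status: success\\*\\*")
  # edited narrative is reflected without re-execution
  writeLines(sub("Intro text stays.", "Edited intro.",
                 readLines(doc_path)), doc_path)
  rep2 <- scientific_report(wf, doc_path)
  expect_match(rep2$text, "Edited intro.")
  # html writing is self-contained
  out <- file.path(dir, "results", "reports", "sci.html")
  write_report(rep, out)
  expect_match(paste(readLines(out), collapse = ""), "<html>")
})

test_that("scientific reports embed image artifacts of command steps", {
  dir <- make_project()
  wf <- new_workflow(dir)
  targets <- sf_targets(data.frame(SampleName = "S1"))
  tool <- parse_tool(paste0(
    "cwlVersion: v1.2\nclass: CommandLineTool\nbaseCommand: echo\n",
    "inputs:\n  m: {type: string,\n",
    "      default: '<svg xmlns=\"http://www.w3.org/2000/svg\"/>',\n",
    "      inputBinding: {position: 1}}\n",
    "outputs:\n  img: {type: stdout}\nstdout: results/pic.svg\n"))
  wf <- append_step(wf, command_step("draw", tool, targets,
                                     body = "tool: param/x.cwl"))
  wf <- run_workflow(wf)
  doc <- file.path(dir, "workflow.md")
  writeLines(c("```{yaml step=\"draw\" kind=\"cmd\"}",
               "tool: param/x.cwl", "```"), doc)
  rep <- scientific_report(wf, doc)
  expect_match(rep$text, "!\\[pic.svg\\]\\(results/pic.svg\\)")
})
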