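simple_tool <- function(extra = "") {
  parse_tool(paste0(
    "cwlVersion: v1.2\nclass: CommandLineTool\nbaseCommand: echo\n",
    "inputs:\n  msg:\n    type: string\n    inputBinding: {position: 1}\n",
    extra, "outputs: []\n"))
}

test_that("parse_tool accepts the subset and applies defaults", {
  tool <- simple_tool()
  expect_s3_class(tool, "sf_tool")
  expect_equal(tool$base_command, "echo")
  expect_equal(names(tool$inputs), "msg")
  expect_equal(tool$inputs$msg$binding$position, 1L)
  expect_true(tool$inputs$msg$binding$separate)
  expect_length(tool$outputs, 0)

  arr <- parse_tool(paste0(
    "cwlVersion: v1.2\nclass: CommandLineTool\nbaseCommand: cat\n",
    "inputs:\n  files:\n    type: File[]\n",
    "    inputBinding: {position: 1, itemSeparator: ','}\noutputs: []\n"))
  expect_equal(arr$inputs$files$type, "File[]")
  expect_equal(arr$inputs$files$binding$item_separator, ",")
})

test_that("parse_tool rejects documents outside the subset", {
  expect_error(parse_tool("cwlVersion: v1.2\nclass: Workflow\nsteps: []\n"),
               "unsupported CWL class 'Workflow'")
  expect_error(parse_tool(paste0(
    "cwlVersion: v1.2\nclass: CommandLineTool\nbaseCommand: x\n",
    "inputs:\n  v:\n    type: float\noutputs: []\n")),
    "unsupported CWL type 'float'.*'v'")
  expect_error(parse_tool(paste0(
    "cwlVersion: v1.2\nclass: CommandLineTool\nbaseCommand: x\n",
    "arguments: ['$(inputs.v)']\ninputs: {}\noutputs: []\n")),
    "expression")
  expect_error(parse_tool("class: CommandLineTool\nbaseCommand: x\n"),
               "cwlVersion")
  expect_warning(parse_tool(paste0(
    "cwlVersion: v1.2\nclass: CommandLineTool\nbaseCommand: x\n",
    "hints:\n  DockerRequirement: {dockerPull: img}\n",
    "inputs: {}\noutputs: []\n")), "ignoring CWL requirements/hints")
})

test_that("bind_command follows the binding rules", {
  tool <- simple_tool()
  expect_equal(bind_command(tool, list(msg = "hello"))$argv,
               c("echo", "hello"))

  tool2 <- simple_tool(paste0(
    "  threads:\n    type: int\n",
    "    inputBinding: {position: 2, prefix: -p}\n"))
  expect_equal(bind_command(tool2, list(msg = "x", threads = 4))$argv,
               c("echo", "x", "-p", "4"))

  sep <- parse_tool(paste0(
    "cwlVersion: v1.2\nclass: CommandLineTool\nbaseCommand: prog\n",
    "inputs:\n  out:\n    type: string\n",
    "    inputBinding: {position: 1, prefix: '--out=', separate: false}\n",
    "  verbose:\n    type: boolean\n",
    "    inputBinding: {position: 2, prefix: -v}\noutputs: []\n"))
  cmd <- bind_command(sep, list(out = "a.txt", verbose = FALSE))
  expect_equal(cmd$argv, c("prog", "--out=a.txt"))
  cmd2 <- bind_command(sep, list(out = "a.txt", verbose = TRUE))
  expect_equal(cmd2$argv, c("prog", "--out=a.txt", "-v"))

  expect_error(bind_command(tool, list()), "missing required input.*msg")
  expect_error(bind_command(tool, list(msg = "x", ghost = 1)),
               "undeclared input.*ghost")
})

test_that("bind_command argv matches the independent oracle on all fixtures", {
  fixtures <- cwl_fixtures()
  expect_gte(length(fixtures), 10)
  for (nm in names(fixtures)) {
    fx <- write_fixture(fixtures[[nm]])
    tool <- suppressWarnings(parse_tool(fx$tool))
    values <- yaml::read_yaml(fx$job)
    if (is.null(values)) values <- list()
    got <- bind_command(tool, values)$argv
    want <- oracle_bind(fx$tool, fx$job)
    expect_equal(got, want, label = paste("fixture", nm))
  }
})

test_that("input declaration order does not affect argv beyond the tie-break", {
  base <- paste0("cwlVersion: v1.2\nclass: CommandLineTool\n",
                 "baseCommand: prog\noutputs: []\n")
  a <- "  alpha: {type: string, inputBinding: {position: 1, prefix: -a}}\n"
  b <- "  beta: {type: string, inputBinding: {position: 2, prefix: -b}}\n"
  t1 <- parse_tool(paste0(base, "inputs:\n", a, b))
  t2 <- parse_tool(paste0(base, "inputs:\n", b, a))
  vals <- list(alpha = "1", beta = "2")
  expect_equal(bind_command(t1, vals)$argv, bind_command(t2, vals)$argv)
})

test_that("render_step_commands substitutes per-sample placeholders", {
  t <- sf_targets(data.frame(FileName = c("data/a.fq", "data/b.fq"),
                             SampleName = c("S1", "S2")))
  tool <- parse_tool(paste0(
    "cwlVersion: v1.2\nclass: CommandLineTool\nbaseCommand: align\n",
    "inputs:\n  reads: {type: File, inputBinding: {position: 1}}\n",
    "outputs:\n  sam: {type: File,\n",
    "        outputBinding: {glob: results/_SampleName_.sam}}\n"))
  cmds <- render_step_commands(tool, list(reads = "_FileName_"), t)
  expect_length(cmds, 2)
  expect_equal(cmds[[1]]$argv, c("align", "data/a.fq"))
  expect_equal(cmds[[2]]$argv, c("align", "data/b.fq"))
  expect_equal(unname(cmds[[1]]$expected_outputs["sam"]), "results/S1.sam")
  expect_equal(cmds[[2]]$sample, "S2")
  # case-insensitive column match
  cmds2 <- render_step_commands(tool, list(reads = "_FILENAME_"), t)
  expect_equal(cmds2[[1]]$argv, cmds[[1]]$argv)
  expect_error(render_step_commands(tool, list(reads = "_Missing_"), t),
               "placeholder _Missing_.*available columns.*SampleName")
})

test_that("tool_from_template round-trips its own defaults", {
  tv <- tool_from_template("echo -m <msg:string:hello>")
  expect_equal(tv$tool$base_command, "echo")
  expect_equal(tv$tool$inputs$msg$binding$prefix, "-m")
  expect_equal(tv$tool$inputs$msg$binding$position, 1L)
  expect_equal(bind_command(tv$tool, tv$values)$argv,
               c("echo", "-m", "hello"))

  tv2 <- tool_from_template(
    "align -x <idx:File:data/ref.fa> -S <sam:out:results/_SampleName_.sam>")
  expect_equal(names(tv2$tool$inputs), c("idx", "sam"))
  expect_equal(names(tv2$tool$outputs), "sam")
  expect_equal(tv2$tool$outputs$sam$glob, "_SampleName_.sam")
  expect_equal(bind_command(tv2$tool, tv2$values)$argv,
               c("align", "-x", "data/ref.fa", "-S",
                 "results/_SampleName_.sam"))

  expect_error(tool_from_template("echo <bad"),
               "malformed placeholder.*character 6")
})

test_that("template round trip reproduces literal tokens for varied grammars", {
  templates <- c(
    "wc -l <inp:File:data/x.txt>",
    "prog sub --flag <a:int:3> plain <b:string:v> tail",
    "tool <first:string:one> -k <second:string:two>")
  for (tpl in templates) {
    tv <- tool_from_template(tpl)
    rendered <- bind_command(tv$tool, tv$values)$argv
    want <- strsplit(gsub("<[^>]*:([^:>]*)>", "\\1", tpl), "\\s+")[[1]]
    expect_equal(rendered, want, label = tpl)
  }
})

test_that("written tool descriptions re-parse to the same binding behaviour", {
  fixtures <- cwl_fixtures()
  for (nm in c("position_sorting", "booleans", "array_item_separator")) {
    fx <- write_fixture(fixtures[[nm]])
    tool <- parse_tool(fx$tool)
    p <- tempfile(fileext = ".cwl")
    write_tool(tool, p)
    tool2 <- parse_tool(p)
    values <- yaml::read_yaml(fx$job)
    expect_equal(bind_command(tool2, values)$argv,
                 bind_command(tool, values)$argv, label = nm)
  }
})
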