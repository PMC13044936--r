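echo_tool <- function(stdout_pattern = NULL, glob = NULL) {
  parse_tool(paste0(
    "cwlVersion: v1.2\nclass: CommandLineTool\nbaseCommand: echo\n",
    "inputs:\n  msg:\n    type: string\n    default: hi _SampleName_\n",
    "    inputBinding: {position: 1}\n",
    "outputs:",
    if (!is.null(glob)) paste0("\n  out:\n    type: File\n",
                               "    outputBinding: {glob: ", glob, "}\n")
    else " []\n",
    if (!is.null(stdout_pattern)) paste0("stdout: ", stdout_pattern, "\n")))
}

chain_project <- function() {
  dir <- make_project()
  wf <- new_workflow(dir)
  targets <- read_targets(file.path(dir, "targets.tsv"))
  wf <- append_step(wf, code_step("setup", "x <- 2"))
  wf <- append_step(wf, command_step(
    "greet", echo_tool("results/_SampleName_.greeting.txt",
                       "results/_SampleName_.greeting.txt"),
    targets, deps = "setup"))
  # the gather step works from files, not session objects, so it stays
  # valid when upstream code steps are skipped by resume
  wf <- append_step(wf, code_step("gather", paste0(
    "files <- sort(Sys.glob('results/*.greeting.txt'))\n",
    "writeLines(as.character(length(files) + 3), 'results/val.txt')"),
    deps = "greet"))
  list(dir = dir, wf = wf)
}

test_that("a fresh chain runs to success and creates outputs", {
  cp <- chain_project()
  wf <- run_workflow(cp$wf)
  st <- wf_status(wf)
  expect_true(all(st$state == "success"))
  expect_equal(wf$last_run$executed, 4)  # 1 + 2 samples + 1
  expect_equal(readLines(file.path(cp$dir, "results", "S1.greeting.txt")),
               "hi S1")
  expect_equal(readLines(file.path(cp$dir, "results", "val.txt")), "5")
  expect_true(all(!is.na(st$duration_s)))
})

test_that("command unit states follow the exit-code and output rules", {
  dir <- make_project()
  log <- function(f) file.path(dir, f)
  # success: exit 0, stdout captured, declared output exists
  ok <- bind_command(echo_tool("results/x.txt", "x.txt"), list(msg = "hi"))
  r <- execute_command_unit(ok, dir, log("o1"), log("e1"))
  expect_equal(r$state, "success")
  expect_equal(readLines(file.path(dir, "results", "x.txt")), "hi")
  # error: non-zero exit
  fail_tool <- parse_tool(paste0(
    "cwlVersion: v1.2\nclass: CommandLineTool\nbaseCommand: false\n",
    "inputs: {}\noutputs: []\n"))
  r2 <- execute_command_unit(bind_command(fail_tool), dir,
                             log("o2"), log("e2"))
  expect_equal(r2$state, "error")
  # warning: exit 0 but declared output never created
  miss <- bind_command(echo_tool(NULL, "never_made.txt"), list(msg = "hi"))
  r3 <- execute_command_unit(miss, dir, log("o3"), log("e3"))
  expect_equal(r3$state, "warning")
  # executable not found
  ghost <- parse_tool(paste0(
    "cwlVersion: v1.2\nclass: CommandLineTool\n",
    "baseCommand: no_such_tool_zz\ninputs: {}\noutputs: []\n"))
  r4 <- execute_command_unit(bind_command(ghost), dir, log("o4"), log("e4"))
  expect_equal(r4$state, "error")
  expect_match(readLines(log("e4"))[1], "executable not found")
})

test_that("code units share a session and classify warnings and errors", {
  dir <- make_project()
  session <- new.env()
  log <- function(f) file.path(dir, f)
  r1 <- execute_code_unit("x <- 2", session, dir, log("o1"), log("e1"))
  expect_equal(r1$state, "success")
  r2 <- execute_code_unit(
    "writeLines(as.character(x + 3), 'results/val.txt')",
    session, dir, log("o2"), log("e2"))
  expect_equal(r2$state, "success")
  expect_equal(readLines(file.path(dir, "results", "val.txt")), "5")
  r3 <- execute_code_unit("warning('careful'); 1", session, dir,
                          log("o3"), log("e3"))
  expect_equal(r3$state, "warning")
  expect_match(paste(readLines(log("e3")), collapse = " "), "careful")
  r4 <- execute_code_unit("stop('boom')", session, dir, log("o4"), log("e4"))
  expect_equal(r4$state, "error")
  err <- paste(readLines(log("e4")), collapse = "\n")
  expect_match(err, "boom")
  expect_match(err, "traceback")
})

test_that("resume skips completed units and re-runs invalidated closures", {
  cp <- chain_project()
  wf <- run_workflow(cp$wf)
  wf2 <- run_workflow(wf, resume = TRUE)
  expect_equal(wf2$last_run$executed, 0)
  expect_equal(wf_status(wf2), wf_status(wf))
  # invalidate one mid-chain per-sample output
  file.remove(file.path(cp$dir, "results", "S2.greeting.txt"))
  wf3 <- run_workflow(wf2, resume = TRUE)
  # expected: the invalidated unit plus its downstream closure (gather)
  expect_equal(wf3$last_run$executed, 2)
  expect_true(file.exists(file.path(cp$dir, "results",
                                    "S2.greeting.txt")))
})

test_that("a failing unit cancels its downstream closure but not branches", {
  dir <- make_project()
  wf <- new_workflow(dir)
  wf <- append_step(wf, code_step("root", "1"))
  wf <- append_step(wf, code_step("bad", "stop('no')", deps = "root"))
  wf <- append_step(wf, code_step("after_bad", "1", deps = "bad"))
  wf <- append_step(wf, code_step("side", "1", deps = "root"))
  wf <- run_workflow(wf)
  st <- wf_status(wf)
  states <- setNames(st$state, st$step)
  expect_equal(unname(states["bad"]), "error")
  expect_equal(unname(states["after_bad"]), "pending")  # cancelled
  expect_equal(unname(states["side"]), "success")
  # strict policy halts everything pending
  wf2h <- new_workflow(make_project())
  wf2h <- append_step(wf2h, code_step("bad", "stop('no')"))
  wf2h <- append_step(wf2h, code_step("independent", "1"))
  wf2h <- run_workflow(wf2h, halt_all = TRUE)
  expect_equal(wf_status(wf2h)$state[wf_status(wf2h)$step == "independent"],
               "pending")
})

test_that("non-closed step selections are rejected before execution", {
  cp <- chain_project()
  expect_error(run_workflow(cp$wf, steps = "gather"),
               class = "sf_precondition_error")
  st <- wf_status(cp$wf)
  expect_true(all(st$state == "pending"))  # nothing ran
  # but resume over recorded successes covers the gap
  wf <- run_workflow(cp$wf)
  wf2 <- run_workflow(wf, steps = "gather", resume = TRUE)
  expect_equal(wf2$last_run$executed, 0)
})

test_that("dry runs log commands and leave the project byte-identical", {
  cp <- chain_project()
  snapshot <- function(dir) {
    files <- sort(list.files(dir, recursive = TRUE, all.files = TRUE))
    files <- files[!startsWith(files, ".sprproject")]
    vapply(file.path(dir, files), function(f)
      unname(tools::md5sum(f)), character(1))
  }
  before <- snapshot(cp$dir)
  wf <- run_workflow(cp$wf, dry_run = TRUE)
  expect_equal(wf$last_run$executed, 0)
  expect_true(all(wf_status(wf)$state == "pending"))
  expect_identical(snapshot(cp$dir), before)
  log <- readLines(file.path(cp$dir, ".sprproject", "logs", "dry_run.log"))
  expect_length(log, 4)
  expect_match(log[2],
               "\\[greet:S1\\] echo hi S1 > results/S1.greeting.txt")
})

test_that("serial and parallel executors agree on the final status matrix", {
  cp1 <- chain_project()
  cp2 <- chain_project()
  w1 <- run_workflow(cp1$wf, workers = 1)
  w2 <- run_workflow(cp2$wf, workers = 2)
  s1 <- wf_status(w1)[, c("step", "sample", "state")]
  s2 <- wf_status(w2)[, c("step", "sample", "state")]
  expect_equal(s2[order(s2$step, s2$sample), ],
               s1[order(s1$step, s1$sample), ], ignore_attr = TRUE)
})

test_that("run traces respect dependency ordering", {
  cp <- chain_project()
  wf <- run_workflow(cp$wf)
  st <- wf_status(wf)
  end_of <- function(step) {
    rows <- st[st$step == step, ]
    max(rows$started_at + rows$duration_s)
  }
  start_of <- function(step) min(st$started_at[st$step == step])
  expect_lte(end_of("setup"), start_of("greet") + 1e-6)
  expect_lte(end_of("greet"), start_of("gather") + 1e-6)
})

test_that("state persists across save/load and corrupt files are reported", {
  cp <- chain_project()
  wf <- run_workflow(cp$wf)
  st <- load_state(cp$dir)
  expect_equal(st[order(st$step, st$sample), ],
               wf_status(wf)[order(wf_status(wf)$step,
                                   wf_status(wf)$sample), ],
               ignore_attr = TRUE)
  expect_true(length(attr(st, "versions")) >= 1)

  empty <- make_project()
  expect_equal(nrow(load_state(empty)), 0)

  writeLines("{ truncated", file.path(cp$dir, ".sprproject", "status.json"))
  expect_error(load_state(cp$dir), "corrupt run state.*ignore_state")
  expect_equal(nrow(load_state(cp$dir, ignore_state = TRUE)), 0)
})

test_that("an interrupted run resumes without re-executing intact units", {
  # simulate a crash by running only the first part of the chain, as a
  # truncated run would have persisted it
  cp <- chain_project()
  wf <- run_workflow(cp$wf, steps = c("setup", "greet"))
  expect_equal(wf$last_run$executed, 3)
  # "restart": reopen the project from disk and run everything
  wf2 <- new_workflow(cp$dir)
  for (s in cp$wf$steps) wf2 <- append_step(wf2, s)
  wf3 <- run_workflow(wf2, resume = TRUE)
  expect_equal(wf3$last_run$executed, 1)  # only the gather step
  expect_true(all(wf_status(wf3)$state == "success"))
})
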