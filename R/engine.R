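#' Workflow execution engine
#'
#' Executes workflow units — one (step, sample) pair per unit — in
#' topological order: within a command step, samples may run concurrently
#' (scatter) and the whole step completes before any dependent starts
#' (gather). Command units run as real subprocesses without a shell, with
#' stdout/stderr captured to per-unit log files; code units are evaluated
#' in one R environment shared across the run so later code steps see
#' objects defined by earlier ones. After every unit the run state is
#' persisted to `.sprproject/status.json`, which is what makes pause,
#' crash recovery and `resume` work.
#'
#' A command unit is `success` only when it exits 0 *and* all its declared
#' output files exist — output existence is the only tool-agnostic
#' completeness check and is also the resume criterion; exit 0 with a
#' missing declared output is a `warning`, non-zero exit is an `error`.
#' When a unit fails, pending units in the failed step's downstream
#' closure are cancelled while independent branches continue
#' (`halt_all = TRUE` stops everything instead).
#'
#' @name engine
NULL

#' Run a workflow (fully or partially)
#'
#' @param wf an `sf_workflow` with steps registered.
#' @param steps step ids to run (default: all). The set must be closed
#'   under upstream dependencies unless `resume = TRUE` and the missing
#'   upstream units are recorded successful with intact outputs.
#' @param samples restrict command steps to these sample names
#'   (default: all).
#' @param resume skip units already recorded `success` whose expected
#'   outputs all still exist.
#' @param dry_run render and log the would-be commands without executing
#'   anything or touching any state.
#' @param workers maximum concurrent sample subprocesses within a command
#'   step (local parallel scatter; `1` = serial).
#' @param halt_all on the first failed unit, cancel everything remaining
#'   instead of only the failure's downstream closure.
#' @return The updated workflow; `wf$last_run$executed` counts the units
#'   actually executed and `wf_status(wf)` is the refreshed status matrix.
#' @export
run_workflow <- function(wf, steps = NULL, samples = NULL, resume = FALSE,
                         dry_run = FALSE, workers = 1L, halt_all = FALSE) {
  stopifnot(inherits(wf, "sf_workflow"))
  workers <- max(1L, as.integer(workers))
  all_ids <- names(wf$steps)
  sel <- if (is.null(steps)) all_ids else as.character(steps)
  unknown <- setdiff(sel, all_ids)
  if (length(unknown))
    precondition_stop("unknown step id(s): ", paste(unknown, collapse = ", "))
  if (!is.null(samples)) {
    known_samples <- unique(wf$status$sample)
    bad <- setdiff(samples, known_samples)
    if (length(bad))
      precondition_stop("unknown sample(s): ", paste(bad, collapse = ", "))
  }
  missing_up <- setdiff(dependency_closure(wf, sel, "upstream"), sel)
  if (length(missing_up)) {
    ok <- resume && all(vapply(missing_up, function(id)
      step_recorded_complete(wf, id), logical(1)))
    if (!ok)
      precondition_stop("selected steps are not closed under upstream ",
                        "dependencies; missing: ",
                        paste(sort(missing_up), collapse = ", "),
                        if (!resume) " (or pass resume = TRUE with prior ",
                        if (!resume) "successful runs covering them)")
  }
  order_sel <- intersect(topological_order(wf), sel)

  # mock/project-local tools take precedence on the search path
  tools_dir <- file.path(wf$project_dir, "tools")
  old_path <- Sys.getenv("PATH")
  if (dir.exists(tools_dir)) {
    Sys.setenv(PATH = paste(tools_dir, old_path, sep = .Platform$path.sep))
    on.exit(Sys.setenv(PATH = old_path), add = TRUE)
  }

  if (dry_run) {
    lines <- character()
    for (id in order_sel) {
      s <- wf$steps[[id]]
      if (s$kind == "command") {
        for (cmd in s$commands) {
          if (!is.null(samples) && !cmd$sample %in% samples) next
          lines <- c(lines, paste0(
            "[", id, ":", cmd$sample, "] ",
            paste(cmd$argv, collapse = " "),
            if (!is.null(cmd$stdout_to)) paste(" >", cmd$stdout_to) else ""))
        }
      } else {
        lines <- c(lines, paste0("[", id, ":", SF_CODE_SAMPLE, "] <R code: ",
                                 length(strsplit(s$code, "\n")[[1]]),
                                 " line(s)>"))
      }
    }
    log <- file.path(wf$project_dir, SF_STATE_DIR, "logs", "dry_run.log")
    writeLines(lines, log)
    wf$last_run <- list(executed = 0L, dry_run = TRUE, steps = order_sel)
    return(wf)
  }

  session <- new.env(parent = globalenv())
  executed <- 0L
  cancelled <- character()
  started <- Sys.time()
  run_versions <- wf$versions
  # units executed in this run; a downstream unit consuming a re-executed
  # unit's outputs must itself re-run even if its own outputs look intact
  invalid <- character()
  upstream_invalid <- function(step_id, sample) {
    for (d in wf$steps[[step_id]]$deps) {
      dsamples <- step_samples(wf$steps[[d]])
      keys <- if (sample %in% dsamples) paste0(d, ":", sample)
              else paste0(d, ":", dsamples)
      if (any(keys %in% invalid)) return(TRUE)
    }
    FALSE
  }

  for (id in order_sel) {
    if (id %in% cancelled) next
    s <- wf$steps[[id]]
    log_dir <- file.path(wf$project_dir, SF_STATE_DIR, "logs", id)
    dir.create(log_dir, recursive = TRUE, showWarnings = FALSE)

    if (s$kind == "command") {
      units <- s$commands
      if (!is.null(samples))
        units <- Filter(function(c) c$sample %in% samples, units)
      todo <- Filter(function(c) {
        !(resume && unit_complete(wf, id, c$sample, c) &&
            !upstream_invalid(id, c$sample))
      }, units)
      if (!length(todo)) next
      invalid <- c(invalid, paste0(id, ":", vapply(todo, `[[`, character(1),
                                                   "sample")))
      for (c in todo)
        wf <- set_unit_state(wf, id, c$sample, "running",
                             started_at = now_s())
      save_state(wf)
      nw <- min(workers, s$resources$cores, length(todo))
      runner <- function(c) execute_command_unit(
        c, project_dir = wf$project_dir,
        log_out = file.path(log_dir, paste0(c$sample, ".out")),
        log_err = file.path(log_dir, paste0(c$sample, ".err")))
      results <- if (nw > 1L) {
        parallel::mclapply(todo, runner, mc.cores = nw)
      } else lapply(todo, runner)
      for (k in seq_along(todo)) {
        r <- results[[k]]
        if (inherits(r, "try-error") || !is.list(r))
          r <- list(state = "error", started_at = now_s(),
                    duration_s = 0)
        wf <- set_unit_state(wf, id, todo[[k]]$sample, r$state,
                             started_at = r$started_at,
                             duration_s = r$duration_s)
        executed <- executed + 1L
        exe <- todo[[k]]$argv[1]
        if (!exe %in% names(run_versions))
          run_versions[exe] <- capture_tool_version(exe)
        save_state(within_versions(wf, run_versions))
      }
    } else {
      if (resume && unit_complete(wf, id, SF_CODE_SAMPLE, NULL) &&
          !upstream_invalid(id, SF_CODE_SAMPLE)) next
      invalid <- c(invalid, paste0(id, ":", SF_CODE_SAMPLE))
      wf <- set_unit_state(wf, id, SF_CODE_SAMPLE, "running",
                           started_at = now_s())
      save_state(wf)
      r <- execute_code_unit(
        s$code, session, project_dir = wf$project_dir,
        log_out = file.path(log_dir, paste0(SF_CODE_SAMPLE, ".out")),
        log_err = file.path(log_dir, paste0(SF_CODE_SAMPLE, ".err")))
      wf <- set_unit_state(wf, id, SF_CODE_SAMPLE, r$state,
                           started_at = r$started_at,
                           duration_s = r$duration_s)
      executed <- executed + 1L
      save_state(wf)
    }

    if (step_state(wf, id) == "error") {
      if (halt_all) {
        cancelled <- union(cancelled, setdiff(order_sel, id))
      } else {
        down <- dependency_closure(wf, id, "downstream")
        cancelled <- union(cancelled, setdiff(down, id))
      }
    }
  }

  wf$versions <- run_versions
  wf$last_run <- list(executed = executed, dry_run = FALSE,
                      steps = order_sel,
                      started = as.numeric(started),
                      ended = now_s(),
                      cancelled = sort(cancelled))
  save_state(wf)
  wf
}

within_versions <- function(wf, versions) { wf$versions <- versions; wf }

# wall-clock seconds at millisecond resolution: coarse enough to
# serialize exactly through the JSON state file, fine enough for timing
now_s <- function() round(as.numeric(Sys.time()), 3)

precondition_stop <- function(...) {
  stop(structure(class = c("sf_precondition_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

step_recorded_complete <- function(wf, id) {
  s <- wf$steps[[id]]
  if (s$kind == "command")
    all(vapply(s$commands, function(c) unit_complete(wf, id, c$sample, c),
               logical(1)))
  else unit_complete(wf, id, SF_CODE_SAMPLE, NULL)
}

# resume criterion: recorded success AND (for command units) all expected
# output files still exist
unit_complete <- function(wf, step, sample, cmd) {
  i <- which(wf$status$step == step & wf$status$sample == sample)
  if (!length(i) || wf$status$state[i] != "success") return(FALSE)
  if (is.null(cmd)) return(TRUE)
  paths <- project_paths(wf$project_dir, cmd$expected_outputs)
  all(file.exists(paths))
}

project_paths <- function(project_dir, paths) {
  vapply(paths, function(p)
    if (startsWith(p, "/")) p else file.path(project_dir, p), character(1),
    USE.NAMES = FALSE)
}

capture_tool_version <- function(exe) {
  out <- tryCatch(
    suppressWarnings(processx::run(exe, "--version", error_on_status = FALSE,
                                   timeout = 5)),
    error = function(e) NULL)
  if (is.null(out) || !identical(out$status, 0L)) return("unknown")
  txt <- paste0(out$stdout, out$stderr)
  line <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  line <- line[nzchar(line)]
  if (!length(line)) "unknown" else line[1]
}

#' Execute one command unit
#'
#' Runs the rendered argv as a subprocess (no shell) with working
#' directory `project_dir`; stdout goes to the tool's declared `stdout`
#' file when present, otherwise to the unit's `.out` log, and stderr
#' always to the `.err` log.
#'
#' @param cmd an `sf_command`.
#' @param project_dir working directory for the subprocess.
#' @param log_out,log_err log file paths.
#' @return list with `state` ("success"/"warning"/"error"), `started_at`,
#'   `duration_s`, `exit_status`.
#' @export
execute_command_unit <- function(cmd, project_dir, log_out, log_err) {
  t0 <- Sys.time()
  exe <- cmd$argv[1]
  found <- nzchar(Sys.which(exe)) ||
    (grepl("/", exe, fixed = TRUE) &&
       file.exists(if (startsWith(exe, "/")) exe
                   else file.path(project_dir, exe)))
  if (!found) {
    writeLines(paste0("executable not found: ", exe), log_err)
    writeLines(character(), log_out)
    return(list(state = "error", started_at = round(as.numeric(t0), 3),
                duration_s = round(as.numeric(Sys.time() - t0, units = "secs"), 3),
                exit_status = 127L))
  }
  stdout_dest <- log_out
  if (!is.null(cmd$stdout_to)) {
    dest <- project_paths(project_dir, cmd$stdout_to)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    stdout_dest <- dest
    writeLines(paste0("stdout redirected to ", cmd$stdout_to), log_out)
  }
  res <- tryCatch(
    processx::run(exe, cmd$argv[-1], wd = project_dir,
                  stdout = stdout_dest, stderr = log_err,
                  error_on_status = FALSE),
    error = function(e) {
      writeLines(conditionMessage(e), log_err)
      list(status = 126L)
    })
  dur <- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
  state <- if (res$status != 0L) "error" else {
    outs <- project_paths(project_dir, cmd$expected_outputs)
    if (all(file.exists(outs))) "success" else "warning"
  }
  list(state = state, started_at = round(as.numeric(t0), 3), duration_s = dur,
       exit_status = res$status)
}

#' Execute one code unit
#'
#' Evaluates R source inside the shared run session with the project
#' directory as working directory. Printed output is captured to the
#' `.out` log; warnings and error messages (with the failing call) to the
#' `.err` log. A completed evaluation that raised warnings yields state
#' `warning`; an uncaught error yields `error`.
#'
#' @param code R source text.
#' @param session the shared environment for this run.
#' @param project_dir working directory during evaluation.
#' @param log_out,log_err log file paths.
#' @return list with `state`, `started_at`, `duration_s`.
#' @export
execute_code_unit <- function(code, session, project_dir, log_out, log_err) {
  t0 <- Sys.time()
  owd <- setwd(project_dir)
  on.exit(setwd(owd), add = TRUE)
  warnings_seen <- character()
  err <- NULL
  output <- utils::capture.output({
    tryCatch(
      withCallingHandlers(
        eval(parse(text = code), envir = session),
        warning = function(w) {
          warnings_seen <<- c(warnings_seen, conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) {
        calls <- vapply(sys.calls(), function(cl)
          paste(deparse(cl, nlines = 1L), collapse = ""), character(1))
        err <<- list(message = conditionMessage(e),
                     call = if (!is.null(conditionCall(e)))
                       paste(deparse(conditionCall(e), nlines = 1L),
                             collapse = "") else NA_character_,
                     trace = utils::tail(calls, 10))
      })
  })
  writeLines(output, log_out)
  err_lines <- as.character(c(
    if (length(warnings_seen)) paste0("warning: ", warnings_seen),
    if (!is.null(err)) c(paste0("error: ", err$message),
                         if (!is.na(err$call))
                           paste0("  in call: ", err$call),
                         "traceback:", paste0("  ", err$trace))))
  writeLines(err_lines, log_err)
  dur <- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
  state <- if (!is.null(err)) "error" else if (length(warnings_seen))
    "warning" else "success"
  list(state = state, started_at = round(as.numeric(t0), 3), duration_s = dur)
}

#' Persist and restore run state
#'
#' The run state lives in `.sprproject/status.json`: a schema version, one
#' record per (step, sample) unit with state, start timestamp, duration,
#' the rendered argv for command units and the log paths, plus captured
#' tool version strings. `load_state()` restores an equal status matrix;
#' a corrupt file raises an explicit error suggesting `ignore_state`.
#'
#' @param wf an `sf_workflow`.
#' @return `save_state()`: the state file path, invisibly.
#' @export
save_state <- function(wf) {
  state_dir <- file.path(wf$project_dir, SF_STATE_DIR)
  dir.create(state_dir, recursive = TRUE, showWarnings = FALSE)
  st <- wf$status
  units <- lapply(seq_len(nrow(st)), function(i) {
    step <- st$step[i]; sample <- st$sample[i]
    rec <- list(step = step, sample = sample, state = st$state[i],
                started_at = st$started_at[i], duration_s = st$duration_s[i],
                logs = list(
                  stdout = file.path(SF_STATE_DIR, "logs", step,
                                     paste0(sample, ".out")),
                  stderr = file.path(SF_STATE_DIR, "logs", step,
                                     paste0(sample, ".err"))))
    s <- wf$steps[[step]]
    if (!is.null(s) && s$kind == "command") {
      cmd <- Filter(function(c) identical(c$sample, sample), s$commands)
      if (length(cmd)) rec$argv <- as.list(cmd[[1]]$argv)
    }
    rec
  })
  doc <- list(schema_version = 1L,
              saved_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              versions = as.list(wf$versions),
              units = units)
  path <- file.path(state_dir, "status.json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_state
#' @param project_dir project directory containing `.sprproject/`.
#' @param ignore_state if TRUE, a corrupt state file is discarded and an
#'   all-pending (empty) matrix returned instead of an error.
#' @return `load_state()`: a status data.frame (with captured tool
#'   versions as the `"versions"` attribute).
#' @export
load_state <- function(project_dir, ignore_state = FALSE) {
  path <- file.path(project_dir, SF_STATE_DIR, "status.json")
  if (!file.exists(path)) return(empty_status())
  doc <- tryCatch(jsonlite::read_json(path), error = function(e) e)
  if (inherits(doc, "error") || is.null(doc$schema_version)) {
    if (ignore_state) return(empty_status())
    stop("corrupt run state file ", path,
         "; re-run load_state() with ignore_state = TRUE to discard it",
         call. = FALSE)
  }
  units <- doc$units %||% list()
  st <- if (length(units)) data.frame(
    step = vapply(units, function(u) u$step, character(1)),
    sample = vapply(units, function(u) u$sample, character(1)),
    state = vapply(units, function(u) u$state, character(1)),
    started_at = vapply(units, function(u)
      if (is.null(u$started_at)) NA_real_ else as.numeric(u$started_at),
      numeric(1)),
    duration_s = vapply(units, function(u)
      if (is.null(u$duration_s)) NA_real_ else as.numeric(u$duration_s),
      numeric(1)),
    stringsAsFactors = FALSE) else empty_status()
  bad <- setdiff(st$state, SF_STATES)
  if (length(bad))
    stop("corrupt run state file ", path, ": unknown state(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  attr(st, "versions") <- unlist(doc$versions) %||% character()
  st
}
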