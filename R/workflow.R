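#' Workflow management objects
#'
#' An `sf_workflow` is the central control object of the engine: an ordered
#' registry of steps (command-line or code), their dependency graph, the
#' sample metadata attached to each command step, and a status matrix with
#' one record per (step, sample) unit. Steps are appended one at a time and
#' a step's dependencies must already be present, which certifies at append
#' time that the graph stays acyclic and that registry order is a valid
#' topological order — mirroring interactive, one-step-at-a-time workflow
#' construction.
#'
#' @name sf_workflow
NULL

SF_STATES <- c("pending", "running", "success", "warning", "error")
# worst-first roll-up order for step-level status
SF_STATE_SEVERITY <- c(error = 5, warning = 4, running = 3, pending = 2,
                       success = 1)
SF_STATE_DIR <- ".sprproject"
SF_CODE_SAMPLE <- "_step_"

empty_status <- function() {
  data.frame(step = character(), sample = character(),
             state = character(), started_at = numeric(),
             duration_s = numeric(), stringsAsFactors = FALSE)
}

#' Per-step resource requirements
#'
#' Declares the CPU cores, memory and wall time a step may use. The engine
#' itself only consumes `cores` (to cap local parallel workers); the full
#' triple is stored so the same logical workflow can be handed to heavier
#' executors.
#'
#' @param cores,memory_mb,walltime_min positive integers.
#' @return An object of class `sf_resources`.
#' @export
resource_spec <- function(cores = 1L, memory_mb = 1024L, walltime_min = 60L) {
  cores <- as.integer(cores); memory_mb <- as.integer(memory_mb)
  walltime_min <- as.integer(walltime_min)
  if (any(c(cores, memory_mb, walltime_min) < 1L) ||
      anyNA(c(cores, memory_mb, walltime_min)))
    stop("resource fields must be integers >= 1", call. = FALSE)
  structure(list(cores = cores, memory_mb = memory_mb,
                 walltime_min = walltime_min), class = "sf_resources")
}

check_step_id <- function(id) {
  if (length(id) != 1 || !grepl("^[A-Za-z][A-Za-z0-9_]*$", id))
    stop("invalid step id '", id,
         "': must match [A-Za-z][A-Za-z0-9_]*", call. = FALSE)
  id
}

#' Construct workflow steps
#'
#' `command_step()` wraps a CWL-described command-line tool, the job values
#' feeding it, and the targets table that drives one command per sample.
#' `code_step()` wraps native R code evaluated in a session shared by all
#' code steps of a run, so later steps see objects defined by earlier ones.
#'
#' Job values may contain `_Column_` placeholders resolved per sample, and
#' gather steps may reference the complete set of an upstream step's
#' expected outputs with a value of the form
#' `list(from_step = "id", output = "output-id")`, resolved when the step
#' is appended.
#'
#' @param id step identifier (`[A-Za-z][A-Za-z0-9_]*`, unique per workflow).
#' @param tool an `sf_tool` or path to a CWL file.
#' @param targets an `sf_targets` table (or, inside literate documents, the
#'   id of an upstream step whose outputs define the samples).
#' @param inputs named list of job-value overrides on the tool defaults.
#' @param outputs_map named map output id -> targets column, used when a
#'   downstream step derives its targets from this step.
#' @param deps character vector of step ids this step depends on.
#' @param resources an [resource_spec()].
#' @param doc free-text description used in reports.
#' @param body verbatim chunk body for literate round trips (optional).
#' @return An object of class `sf_step`.
#' @export
command_step <- function(id, tool, targets, inputs = list(),
                         outputs_map = NULL, deps = character(),
                         resources = resource_spec(), doc = "",
                         body = NULL) {
  check_step_id(id)
  if (is.character(tool)) tool <- parse_tool(tool)
  stopifnot(inherits(tool, "sf_tool"))
  values <- lapply(tool$inputs, `[[`, "default")
  values <- values[!vapply(values, is.null, logical(1))]
  for (nm in names(inputs)) values[[nm]] <- inputs[[nm]]
  structure(list(id = id, kind = "command", deps = unique(as.character(deps)),
                 resources = resources, doc = doc, tool = tool,
                 values = values, targets = targets,
                 outputs_map = outputs_map, commands = NULL, body = body),
            class = "sf_step")
}

#' @rdname command_step
#' @param code R source code (character; lines or single string).
#' @export
code_step <- function(id, code, deps = character(),
                      resources = resource_spec(), doc = "", body = NULL) {
  check_step_id(id)
  code <- paste(code, collapse = "\n")
  structure(list(id = id, kind = "code", deps = unique(as.character(deps)),
                 resources = resources, doc = doc, code = code,
                 body = body %||% code), class = "sf_step")
}

step_samples <- function(step) {
  if (step$kind == "code") SF_CODE_SAMPLE else sample_names(step$targets)
}

#' Create (or reopen) a workflow bound to a project directory
#'
#' The project directory must follow the standard layout with `data/`,
#' `results/` and `param/` subdirectories (see [init_project()]). A hidden
#' state directory `.sprproject/` is created if absent; if it already
#' contains a saved run state, the persisted status matrix is loaded so a
#' reopened project resumes where it left off.
#'
#' @param project_dir path to an initialized project.
#' @return An empty `sf_workflow` bound to `project_dir`.
#' @export
new_workflow <- function(project_dir) {
  if (!dir.exists(project_dir))
    stop("project directory does not exist: ", project_dir, call. = FALSE)
  need <- c("data", "results", "param")
  missing <- need[!dir.exists(file.path(project_dir, need))]
  if (length(missing))
    stop("not a workflow project (missing ",
         paste0(missing, "/", collapse = ", "), "): ", project_dir,
         call. = FALSE)
  state_dir <- file.path(project_dir, SF_STATE_DIR)
  dir.create(file.path(state_dir, "logs"), recursive = TRUE,
             showWarnings = FALSE)
  status <- empty_status()
  versions <- character()
  state_file <- file.path(state_dir, "status.json")
  if (file.exists(state_file)) {
    st <- load_state(project_dir)
    status <- st
    versions <- attr(st, "versions") %||% character()
    attr(status, "versions") <- NULL
  }
  structure(list(project_dir = normalizePath(project_dir),
                 steps = list(), status = status,
                 versions = versions, source_doc = NULL, last_run = NULL),
            class = "sf_workflow")
}

wf_get_step <- function(wf, id) {
  if (!id %in% names(wf$steps))
    stop("unknown step '", id, "'", call. = FALSE)
  wf$steps[[id]]
}

resolve_from_step_values <- function(wf, values) {
  lapply(values, function(v) {
    if (is.list(v) && !is.null(v[["from_step"]])) {
      up <- wf_get_step(wf, v$from_step)
      if (up$kind != "command" || is.null(up$commands))
        stop("from_step reference '", v$from_step,
             "' is not a rendered command step", call. = FALSE)
      oid <- v$output
      paths <- lapply(up$commands, function(c) {
        if (!oid %in% names(c$expected_outputs))
          stop("step '", v$from_step, "' has no output '", oid, "'",
               call. = FALSE)
        unname(c$expected_outputs[[oid]])
      })
      paths
    } else v
  })
}

#' Append a step to a workflow
#'
#' The step id must be new and every dependency must already be registered
#' (so append order certifies a valid topological order and the graph can
#' never acquire a cycle). Command steps are rendered on append: one
#' concrete command per targets row, with `_Column_` placeholders and
#' `from_step` output references resolved. Status records for the step's
#' units are initialized to `pending` unless a persisted record already
#' exists for that (step, sample) — existing records are never modified.
#'
#' @param wf an `sf_workflow`.
#' @param step an `sf_step` from [command_step()] or [code_step()].
#' @return The updated workflow.
#' @export
append_step <- function(wf, step) {
  stopifnot(inherits(wf, "sf_workflow"), inherits(step, "sf_step"))
  if (step$id %in% names(wf$steps))
    stop("duplicate step id '", step$id, "'", call. = FALSE)
  if (step$id %in% step$deps)
    stop("step '", step$id, "' cannot depend on itself", call. = FALSE)
  unknown <- setdiff(step$deps, names(wf$steps))
  if (length(unknown))
    stop("unknown dependency '", paste(unknown, collapse = "', '"),
         "' for step '", step$id, "'", call. = FALSE)
  if (step$kind == "command") {
    stopifnot(inherits(step$targets, "sf_targets"))
    vals <- resolve_from_step_values(wf, step$values)
    step$commands <- render_step_commands(step$tool, vals, step$targets)
  }
  wf$steps[[step$id]] <- step
  samples <- step_samples(step)
  have <- wf$status$sample[wf$status$step == step$id]
  new_samples <- setdiff(samples, have)
  if (length(new_samples)) {
    wf$status <- rbind(wf$status, data.frame(
      step = step$id, sample = new_samples, state = "pending",
      started_at = NA_real_, duration_s = NA_real_,
      stringsAsFactors = FALSE))
    rownames(wf$status) <- NULL
  }
  wf
}

#' Deterministic topological order of workflow steps
#'
#' Kahn's algorithm with lexicographic tie-breaking by step id, so the
#' order (and everything derived from it: graphs, reports) is reproducible
#' regardless of append order among independent steps.
#'
#' @param wf an `sf_workflow`.
#' @return Character vector of step ids.
#' @export
topological_order <- function(wf) {
  ids <- names(wf$steps)
  if (!length(ids)) return(character())
  deps <- lapply(wf$steps, function(s) intersect(s$deps, ids))
  indeg <- vapply(deps, length, integer(1))
  out <- character(0)
  remaining <- ids
  while (length(remaining)) {
    ready <- sort(remaining[indeg[remaining] == 0L])
    if (!length(ready))
      stop("cycle detected in workflow dependency graph", call. = FALSE)
    nxt <- ready[1]
    out <- c(out, nxt)
    remaining <- setdiff(remaining, nxt)
    for (id in remaining)
      if (nxt %in% deps[[id]]) indeg[id] <- indeg[id] - 1L
  }
  out
}

wf_edges <- function(wf) {
  ids <- names(wf$steps)
  from <- character(); to <- character()
  for (id in ids) for (d in wf$steps[[id]]$deps) {
    from <- c(from, d); to <- c(to, id)
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' Transitive dependency closure
#'
#' @param wf an `sf_workflow`.
#' @param ids step ids to start from.
#' @param direction `"upstream"` (all dependencies, recursively) or
#'   `"downstream"` (all dependents).
#' @return Character vector of step ids including `ids` themselves, in
#'   registry order.
#' @export
dependency_closure <- function(wf, ids,
                               direction = c("upstream", "downstream")) {
  direction <- match.arg(direction)
  unknown <- setdiff(ids, names(wf$steps))
  if (length(unknown))
    stop("unknown step id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  adj <- if (direction == "upstream") {
    lapply(wf$steps, `[[`, "deps")
  } else {
    ids_all <- names(wf$steps)
    stats::setNames(lapply(ids_all, function(id)
      ids_all[vapply(wf$steps, function(s) id %in% s$deps, logical(1))]),
      ids_all)
  }
  seen <- unique(ids)
  frontier <- seen
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  intersect(names(wf$steps), seen)
}

#' Restrict a workflow to a subset of steps
#'
#' The subset must be closed under upstream dependencies unless
#' `allow_external = TRUE`, in which case dependencies outside the subset
#' are recorded on each step as `external_deps` (their outputs are assumed
#' present). The original workflow is untouched.
#'
#' @param wf an `sf_workflow`.
#' @param ids step ids to keep.
#' @param allow_external permit upstream dependencies outside `ids`.
#' @return A new `sf_workflow` view.
#' @export
subset_steps <- function(wf, ids, allow_external = FALSE) {
  unknown <- setdiff(ids, names(wf$steps))
  if (length(unknown))
    stop("unknown step id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  up <- dependency_closure(wf, ids, "upstream")
  missing <- setdiff(up, ids)
  if (length(missing) && !allow_external)
    stop("subset is not closed under dependencies; missing upstream ",
         "step(s): ", paste(sort(missing), collapse = ", "), call. = FALSE)
  keep <- intersect(names(wf$steps), ids)
  wf$steps <- lapply(wf$steps[keep], function(s) {
    s$external_deps <- setdiff(s$deps, keep)
    s$deps <- intersect(s$deps, keep)
    s
  })
  wf$status <- wf$status[wf$status$step %in% keep, , drop = FALSE]
  rownames(wf$status) <- NULL
  wf
}

#' Step and unit status access
#'
#' `wf_status()` returns the status matrix (one row per step/sample unit);
#' `step_state()` rolls a step's unit states up to the worst one under the
#' order error > warning > running > pending > success.
#'
#' @param wf an `sf_workflow`.
#' @return `wf_status()`: a data.frame with columns `step`, `sample`,
#'   `state`, `started_at`, `duration_s`.
#' @export
wf_status <- function(wf) wf$status

#' @rdname wf_status
#' @param id step id.
#' @export
step_state <- function(wf, id) {
  states <- wf$status$state[wf$status$step == id]
  if (!length(states)) return("pending")
  names(which.max(SF_STATE_SEVERITY[states]))
}

set_unit_state <- function(wf, step, sample, state, started_at = NA_real_,
                           duration_s = NA_real_) {
  i <- which(wf$status$step == step & wf$status$sample == sample)
  if (!length(i)) {
    wf$status <- rbind(wf$status, data.frame(
      step = step, sample = sample, state = state, started_at = started_at,
      duration_s = duration_s, stringsAsFactors = FALSE))
  } else {
    wf$status$state[i] <- state
    wf$status$started_at[i] <- started_at
    wf$status$duration_s[i] <- duration_s
  }
  wf
}

#' @export
print.sf_workflow <- function(x, ...) {
  cat("<sf_workflow> ", length(x$steps), " step(s) in ", x$project_dir,
      "\n", sep = "")
  if (length(x$steps)) {
    for (id in names(x$steps)) {
      s <- x$steps[[id]]
      cat(sprintf("  %-24s %-7s %-8s deps: %s\n", id, s$kind,
                  step_state(x, id),
                  if (length(s$deps)) paste(s$deps, collapse = ",")
                  else "-"))
    }
  }
  invisible(x)
}

#' @export
summary.sf_workflow <- function(object, ...) {
  st <- object$status
  tab <- table(factor(st$state, levels = SF_STATES))
  cat("workflow with", length(object$steps), "steps,", nrow(st),
      "unit(s):\n")
  print(tab)
  invisible(tab)
}
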