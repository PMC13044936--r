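#' Technical and scientific run reports
#'
#' Two complementary documents are generated per run. The *technical
#' report* is the machine-facing audit trail: per step (in topological
#' order) the unit status table, the exact rendered command lines,
#' captured tool version strings, and stderr excerpts for units that did
#' not succeed. The *scientific report* re-renders the literate source
#' document: narrative text is preserved, and each step chunk is replaced
#' by its code, a status badge, and the artifacts it wrote under
#' `results/` (images embedded, small tables inlined, everything else
#' linked). Both can be regenerated at any time without re-running the
#' workflow; the only non-deterministic content is a single generation
#' timestamp line in the front matter.
#'
#' @name run-reports
NULL

report_timestamp <- function() {
  paste0("Generated: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
}

md_table <- function(df) {
  if (!nrow(df)) return("(no rows)")
  fmt_row <- function(v) paste0("| ", paste(v, collapse = " | "), " |")
  c(fmt_row(names(df)),
    fmt_row(rep("---", ncol(df))),
    vapply(seq_len(nrow(df)), function(i)
      fmt_row(vapply(df[i, , drop = FALSE], as.character, character(1))),
      character(1)))
}

#' Generate the technical report
#'
#' @param wf an `sf_workflow` (typically after [run_workflow()]).
#' @param stderr_lines how many trailing stderr lines to embed for units
#'   that are not successful.
#' @return An object of class `sf_report` (`kind = "technical"`) whose
#'   `text` field is the Markdown source.
#' @export
technical_report <- function(wf, stderr_lines = 20L) {
  st <- wf$status
  # run window and id derive from the persisted unit records, so the
  # report is reproducible for a fixed state (only the generation
  # timestamp line changes)
  started <- st$started_at[!is.na(st$started_at)]
  ended <- (st$started_at + st$duration_s)[!is.na(st$duration_s)]
  fmt_t <- function(x) format(as.POSIXct(x, origin = "1970-01-01"),
                              "%Y-%m-%d %H:%M:%S")
  run_id <- if (length(started))
    paste0(basename(wf$project_dir), "-",
           format(round(min(started))))
  else paste0(basename(wf$project_dir), "-unstarted")
  lines <- c("# Technical report", "",
             report_timestamp(),
             paste0("Run id: ", run_id),
             paste0("Engine: sampleflow ",
                    as.character(utils::packageVersion("sampleflow"))),
             paste0("Project: ", wf$project_dir),
             if (length(started))
               paste0("Run window: ", fmt_t(min(started)), " -> ",
                      fmt_t(max(ended)), " (",
                      sum(st$state == "success"), "/", nrow(st),
                      " unit(s) successful)"),
             "")
  if (length(wf$versions)) {
    lines <- c(lines, "## Tool versions", "",
               paste0("- `", names(wf$versions), "`: ",
                      unname(wf$versions)), "")
  }
  for (id in topological_order(wf)) {
    s <- wf$steps[[id]]
    rows <- st[st$step == id, , drop = FALSE]
    tab <- data.frame(sample = rows$sample, state = rows$state,
                      duration_s = ifelse(is.na(rows$duration_s), "-",
                                          sprintf("%.3f", rows$duration_s)),
                      stringsAsFactors = FALSE)
    lines <- c(lines, paste0("## Step `", id, "` (", s$kind, ")"), "",
               if (nzchar(s$doc)) c(s$doc, ""),
               md_table(tab), "")
    if (s$kind == "command") {
      lines <- c(lines, "Rendered commands:", "", "```")
      for (cmd in s$commands)
        lines <- c(lines, paste0("[", cmd$sample, "] ",
                                 paste(cmd$argv, collapse = " "),
                                 if (!is.null(cmd$stdout_to))
                                   paste(" >", cmd$stdout_to) else ""))
      lines <- c(lines, "```", "")
    }
    bad <- rows[!rows$state %in% c("success", "pending"), , drop = FALSE]
    for (i in seq_len(nrow(bad))) {
      errfile <- file.path(wf$project_dir, SF_STATE_DIR, "logs", id,
                           paste0(bad$sample[i], ".err"))
      lines <- c(lines, paste0("stderr excerpt for `", bad$sample[i],
                               "` (", bad$state[i], "):"), "", "```")
      if (file.exists(errfile)) {
        txt <- readLines(errfile, warn = FALSE)
        lines <- c(lines, utils::tail(txt, stderr_lines))
      } else lines <- c(lines, "(log file missing)")
      lines <- c(lines, "```", "")
    }
  }
  structure(list(kind = "technical", text = paste(lines, collapse = "\n")),
            class = "sf_report")
}

state_badge <- function(state) {
  paste0("**Status: ", state, "**")
}

step_artifacts <- function(wf, id) {
  s <- wf$steps[[id]]
  if (s$kind != "command" || is.null(s$commands)) return(character())
  unique(unlist(lapply(s$commands, function(c)
    c(unname(c$expected_outputs), c$stdout_to))))
}

render_artifact <- function(path, project_dir, max_rows = 50L) {
  ext <- tolower(tools::file_ext(path))
  abs <- if (startsWith(path, "/")) path else file.path(project_dir, path)
  if (!file.exists(abs))
    return(paste0("- `", path, "` (not present)"))
  if (ext %in% c("svg", "png", "jpg", "jpeg"))
    return(c(paste0("![", basename(path), "](", path, ")"), ""))
  if (ext %in% c("tsv", "csv", "txt")) {
    n <- length(readLines(abs, warn = FALSE))
    if (ext %in% c("tsv", "csv") && n >= 2 && n - 1 <= max_rows) {
      sep <- if (ext == "csv") "," else "\t"
      df <- utils::read.table(abs, sep = sep, header = TRUE,
                              stringsAsFactors = FALSE, comment.char = "",
                              check.names = FALSE)
      return(c(paste0("Table `", path, "`:"), "", md_table(df), ""))
    }
  }
  paste0("- [", basename(path), "](", path, ")")
}

#' Generate the scientific report
#'
#' @param wf an `sf_workflow`.
#' @param doc the literate source document (an `sf_doc` or path); defaults
#'   to the document the workflow was imported from. May be an edited
#'   revision — mismatched steps are listed in an appendix, not fatal.
#' @param include_graph embed the topology SVG at the top.
#' @param max_rows inline tables with at most this many data rows;
#'   larger files are linked.
#' @return An object of class `sf_report` (`kind = "scientific"`).
#' @export
scientific_report <- function(wf, doc = NULL, include_graph = TRUE,
                              max_rows = 50L) {
  if (is.null(doc)) {
    if (is.null(wf$source_doc))
      stop("workflow has no source document; pass `doc`", call. = FALSE)
    doc <- wf$source_doc
  }
  if (is.character(doc)) doc <- parse_doc(doc)
  lines <- c("# Scientific report", "", report_timestamp(), "")
  if (include_graph)
    lines <- c(lines, "## Workflow topology", "",
               to_svg(build_graph(wf)), "")
  doc_steps <- vapply(doc_chunks(doc), function(c) c$ann$step, character(1))
  mismatches <- character()
  for (seg in doc$segments) {
    if (seg$type == "narrative") {
      lines <- c(lines, seg$lines)
    } else {
      id <- seg$ann$step
      if (!id %in% names(wf$steps)) {
        mismatches <- c(mismatches, paste0(
          "step '", id, "' appears in the document but not in the workflow"))
        lines <- c(lines, paste0("### Step `", id, "`"), "",
                   "*(not registered in this workflow run)*", "")
        next
      }
      s <- wf$steps[[id]]
      lang <- if (s$kind == "code") "r" else "yaml"
      lines <- c(lines,
                 paste0("### Step `", id, "` ",
                        state_badge(step_state(wf, id))), "",
                 paste0("```", lang),
                 strsplit(s$body %||% "", "\n", fixed = TRUE)[[1]],
                 "```", "")
      arts <- step_artifacts(wf, id)
      if (length(arts)) {
        lines <- c(lines, "Artifacts:", "")
        for (a in sort(arts))
          lines <- c(lines, render_artifact(a, wf$project_dir, max_rows))
        lines <- c(lines, "")
      }
    }
  }
  extra <- setdiff(names(wf$steps), doc_steps)
  if (length(extra))
    mismatches <- c(mismatches, paste0(
      "step '", extra, "' is registered in the workflow but absent from ",
      "the document"))
  if (length(mismatches))
    lines <- c(lines, "## Appendix: document/workflow mismatches", "",
               paste0("- ", mismatches), "")
  structure(list(kind = "scientific", text = paste(lines, collapse = "\n")),
            class = "sf_report")
}

#' Write a report to disk
#'
#' Markdown is written as-is; HTML is rendered with commonmark inside a
#' minimal self-contained template (no external assets).
#'
#' @param report an `sf_report`.
#' @param path output file; the extension (`.md` or `.html`) selects the
#'   format.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "sf_report"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (tolower(tools::file_ext(path)) == "html") {
    body <- commonmark::markdown_html(report$text, extensions = "table")
    html <- paste0(
      "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">",
      "<title>", report$kind, " report</title>",
      "<style>body{font-family:Helvetica,sans-serif;max-width:60em;",
      "margin:2em auto;padding:0 1em}pre{background:#f5f5f5;",
      "padding:0.7em;overflow:auto}table{border-collapse:collapse}",
      "td,th{border:1px solid #999;padding:0.25em 0.6em}</style>",
      "</head>\n<body>\n", body, "</body></html>\n")
    writeLines(html, path)
  } else {
    writeLines(report$text, path)
  }
  invisible(path)
}

#' @export
print.sf_report <- function(x, ...) {
  cat("<sf_report> kind:", x$kind, "-", nchar(x$text), "characters\n")
  cat(paste(utils::head(strsplit(x$text, "\n")[[1]], 12), collapse = "\n"),
      "\n...\n")
  invisible(x)
}
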