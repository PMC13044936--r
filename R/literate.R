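#' Literate workflow documents
#'
#' Workflows are written as ordinary Markdown with annotated fenced code
#' blocks. A fence of the form
#' ```` ```{lang step="align" kind="cmd" deps="trim,index"} ````
#' declares a workflow step; fences without a `step=` attribute are plain
#' narrative. `kind="code"` chunks hold R source executed in the shared
#' run session; `kind="cmd"` chunks hold a small YAML mapping:
#'
#' ```yaml
#' tool: param/aligner.cwl      # CWL CommandLineTool description
#' targets: targets.tsv         # sample sheet, or the id of an upstream step
#' inputs:                      # job-value overrides (placeholders allowed)
#'   reads: _FileName_
#' outputs_map:                 # used when a downstream step inherits
#'   sam: FileName              #   this step's outputs as its targets
#' ```
#'
#' Dependencies must reference earlier chunks only, mirroring interactive
#' one-step-at-a-time import; parsing is lossless (segments concatenate
#' back to the source bytes).
#'
#' @name literate-workflows
NULL

parse_fence_attrs <- function(attr_text, line_no) {
  rest <- trimws(attr_text)
  # optional leading language token (no '=')
  lang_m <- regmatches(rest, regexec("^([A-Za-z][A-Za-z0-9_.+-]*)(\\s|$)", rest))[[1]]
  lang <- NULL
  if (length(lang_m)) {
    lang <- lang_m[2]
    rest <- trimws(substring(rest, nchar(lang_m[1]) + 1))
  }
  attrs <- list()
  pat <- '^([A-Za-z][A-Za-z0-9_]*)\\s*=\\s*"([^"]*)"\\s*'
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec(pat, rest))[[1]]
    if (!length(m))
      stop("malformed fence attribute string at line ", line_no, ": '",
           rest, "'", call. = FALSE)
    attrs[[m[2]]] <- m[3]
    rest <- substring(rest, nchar(m[1]) + 1)
  }
  list(lang = lang, attrs = attrs)
}

#' Parse a literate workflow document
#'
#' @param path path to a Markdown file.
#' @return An object of class `sf_doc`: a list of segments, each either
#'   `list(type = "narrative", lines = ...)` or `list(type = "chunk",
#'   ann = ..., lines = ..., body = ...)`, plus the raw text. Segment
#'   lines concatenate to the exact source.
#' @export
parse_doc <- function(path) {
  if (!file.exists(path)) stop("document not found: ", path, call. = FALSE)
  raw <- readChar(path, file.size(path), useBytes = TRUE)
  Encoding(raw) <- "UTF-8"
  trailing_nl <- grepl("\n$", raw)
  lines <- if (nzchar(raw)) strsplit(raw, "\n", fixed = TRUE)[[1]] else character()

  segments <- list()
  seen_steps <- list()  # step name -> line number
  narrative_buf <- integer()
  flush_narrative <- function() {
    if (length(narrative_buf)) {
      segments[[length(segments) + 1]] <<-
        list(type = "narrative", lines = lines[narrative_buf])
      narrative_buf <<- integer()
    }
  }

  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- lines[i]
    open <- regmatches(line, regexec("^```\\{(.*)\\}\\s*$", line))[[1]]
    plain_open <- grepl("^```", line)
    if (length(open)) {
      parsed <- parse_fence_attrs(open[2], i)
      j <- i + 1L
      while (j <= n && !grepl("^```\\s*$", lines[j])) j <- j + 1L
      if (j > n) stop("unterminated code fence opened at line ", i,
                      call. = FALSE)
      if (!is.null(parsed$attrs$step)) {
        step <- parsed$attrs$step
        if (!is.null(seen_steps[[step]]))
          stop("duplicate step name '", step, "' at lines ",
               seen_steps[[step]], " and ", i, call. = FALSE)
        seen_steps[[step]] <- i
        deps <- parsed$attrs$deps %||% ""
        deps <- trimws(strsplit(deps, ",", fixed = TRUE)[[1]])
        deps <- deps[nzchar(deps)]
        ann <- list(step = step,
                    kind = parsed$attrs$kind %||%
                      if (identical(parsed$lang, "yaml")) "cmd" else "code",
                    deps = deps,
                    run = !identical(tolower(parsed$attrs$run %||% "true"),
                                     "false"),
                    lang = parsed$lang)
        if (!ann$kind %in% c("cmd", "code"))
          stop("unknown chunk kind '", ann$kind, "' at line ", i,
               call. = FALSE)
        flush_narrative()
        body <- if (j > i + 1L) lines[seq(i + 1L, j - 1L)] else character()
        segments[[length(segments) + 1]] <-
          list(type = "chunk", ann = ann, lines = lines[i:j],
               body = paste(body, collapse = "\n"))
      } else {
        narrative_buf <- c(narrative_buf, i:j)
      }
      i <- j + 1L
    } else if (plain_open) {
      # unannotated fence: narrative, but skip to its close so inner
      # backticks are not misread
      j <- i + 1L
      while (j <= n && !grepl("^```\\s*$", lines[j])) j <- j + 1L
      if (j > n) j <- n
      narrative_buf <- c(narrative_buf, i:j)
      i <- j + 1L
    } else {
      narrative_buf <- c(narrative_buf, i)
      i <- i + 1L
    }
  }
  flush_narrative()
  structure(list(segments = segments, path = path, text = raw,
                 trailing_newline = trailing_nl), class = "sf_doc")
}

#' @export
print.sf_doc <- function(x, ...) {
  ch <- doc_chunks(x)
  cat("<sf_doc> ", length(x$segments), " segment(s), ", length(ch),
      " step chunk(s)", if (!is.null(x$path)) paste0(" from ", x$path),
      "\n", sep = "")
  for (c in ch)
    cat(sprintf("  %-24s %-5s deps: %s\n", c$ann$step, c$ann$kind,
                if (length(c$ann$deps)) paste(c$ann$deps, collapse = ",")
                else "-"))
  invisible(x)
}

doc_chunks <- function(doc) {
  Filter(function(s) s$type == "chunk", doc$segments)
}

doc_text <- function(doc) {
  all_lines <- unlist(lapply(doc$segments, `[[`, "lines"))
  paste0(paste(all_lines, collapse = "\n"),
         if (isTRUE(doc$trailing_newline)) "\n" else "")
}

#' Import a workflow from a literate document
#'
#' Appends one step per annotated chunk, in document order, via
#' [append_step()]; because chunk dependencies must reference earlier
#' chunks, every imported workflow satisfies the acyclicity invariant by
#' construction. For `cmd` chunks, the YAML body is resolved against the
#' project directory: the `tool` file is parsed, `targets` is either a
#' sample-sheet path or the id of an upstream step (whose expected outputs
#' then become input columns via [outputs_to_targets()] and the chunk's
#' `outputs_map`).
#'
#' @param doc an `sf_doc` from [parse_doc()], or a path to one.
#' @param project_dir project directory the workflow binds to.
#' @return An `sf_workflow` with all runnable chunks registered.
#' @export
import_workflow <- function(doc, project_dir) {
  if (is.character(doc)) doc <- parse_doc(doc)
  stopifnot(inherits(doc, "sf_doc"))
  wf <- new_workflow(project_dir)
  for (chunk in doc_chunks(doc)) {
    ann <- chunk$ann
    if (!ann$run) next
    missing <- setdiff(ann$deps, names(wf$steps))
    if (length(missing))
      stop("step '", ann$step, "': deps reference earlier chunks only; '",
           paste(missing, collapse = "', '"),
           "' is not defined by an earlier chunk", call. = FALSE)
    if (ann$kind == "code") {
      wf <- append_step(wf, code_step(ann$step, chunk$body, deps = ann$deps,
                                      body = chunk$body))
    } else {
      spec <- yaml::yaml.load(chunk$body)
      if (!is.list(spec) || is.null(spec$tool) || is.null(spec$targets))
        stop("cmd chunk '", ann$step,
             "' must be a YAML mapping with 'tool' and 'targets'",
             call. = FALSE)
      tool_path <- file.path(project_dir, spec$tool)
      if (!file.exists(tool_path))
        stop("tool file not found for step '", ann$step, "': ", spec$tool,
             call. = FALSE)
      tool <- parse_tool(tool_path)
      targets <- if (spec$targets %in% names(wf$steps)) {
        outputs_to_targets(wf, spec$targets, spec$outputs_map)
      } else {
        tpath <- file.path(project_dir, spec$targets)
        if (!file.exists(tpath))
          stop("targets file not found for step '", ann$step, "': ",
               spec$targets, call. = FALSE)
        read_targets(tpath)
      }
      wf <- append_step(wf, command_step(
        ann$step, tool, targets, inputs = spec$inputs %||% list(),
        outputs_map = spec$outputs_map, deps = ann$deps,
        body = chunk$body))
    }
  }
  wf$source_doc <- doc$path
  wf
}

#' Export a workflow back to literate Markdown
#'
#' Writes one annotated fence per step, in registry order, with the step's
#' verbatim body, so that `import_workflow(parse_doc(export_workflow(wf)))`
#' reproduces the step registry (ids, kinds, deps, bodies). Output is
#' deterministic: exporting twice yields byte-identical text.
#'
#' @param wf an `sf_workflow`.
#' @param path optional file to write to.
#' @return The Markdown text (invisibly when `path` is given).
#' @export
export_workflow <- function(wf, path = NULL) {
  out <- c("# Workflow", "")
  for (id in names(wf$steps)) {
    s <- wf$steps[[id]]
    lang <- if (s$kind == "code") "r" else "yaml"
    kind <- if (s$kind == "code") "code" else "cmd"
    attrs <- sprintf('%s step="%s" kind="%s"', lang, id, kind)
    if (length(s$deps))
      attrs <- paste0(attrs, sprintf(' deps="%s"',
                                     paste(s$deps, collapse = ",")))
    body <- s$body %||% if (s$kind == "code") s$code else
      yaml::as.yaml(list(tool = "param/unknown.cwl", targets = "targets.tsv"))
    out <- c(out, paste0("```{", attrs, "}"),
             strsplit(body, "\n", fixed = TRUE)[[1]], "```", "")
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(txt, con, sep = "", useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}
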