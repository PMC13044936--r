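#' CWL CommandLineTool subset
#'
#' Command-line steps are described declaratively with a subset of the
#' Common Workflow Language (CWL) `CommandLineTool` class: a base command,
#' typed inputs with argument bindings (`position`, `prefix`, `separate`,
#' `itemSeparator`), literal `arguments`, `File` outputs located by glob
#' patterns, and optional `stdout` capture. Features outside the subset
#' (JavaScript expressions, `Workflow` documents, scatter, schema imports)
#' are rejected loudly rather than silently mis-executed; `hints` and
#' `requirements` are parsed, stored and ignored with a warning.
#'
#' @name cwl-subset
NULL

SF_CWL_TYPES <- c("string", "int", "boolean", "File", "Directory",
                  "string[]", "File[]")

#' Parse a CWL CommandLineTool description
#'
#' @param x path to a YAML file, or a YAML document as a single string.
#' @return An object of class `sf_tool` with fields `tool_id`,
#'   `cwl_version`, `base_command`, `inputs`, `arguments`, `outputs`,
#'   `stdout`.
#' @export
parse_tool <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    doc <- yaml::read_yaml(x)
    src <- x
  } else {
    doc <- yaml::yaml.load(paste(x, collapse = "\n"))
    src <- "<text>"
  }
  if (!is.list(doc)) stop("not a CWL document: ", src, call. = FALSE)
  cls <- doc[["class"]]
  if (is.null(cls) || !identical(cls, "CommandLineTool"))
    stop("unsupported CWL class '", if (is.null(cls)) "<none>" else cls,
         "' in ", src, ": only CommandLineTool is supported", call. = FALSE)
  if (is.null(doc[["cwlVersion"]]))
    stop("missing cwlVersion in ", src, call. = FALSE)
  base <- doc[["baseCommand"]]
  if (is.null(base) || !length(base))
    stop("baseCommand is required in ", src, call. = FALSE)
  base <- as.character(unlist(base))

  check_no_expression <- function(v, where) {
    if (is.character(v) && any(grepl("\\$[({]", v)))
      stop("unsupported feature in ", src, ": JavaScript/parameter ",
           "expression in ", where, " ('", v[grepl("\\$[({]", v)][1], "')",
           call. = FALSE)
    invisible(v)
  }

  inputs <- parse_cwl_ports(doc[["inputs"]], src)
  inputs <- lapply(inputs, function(inp) {
    type <- normalise_cwl_type(inp$raw_type, inp$id, src)
    b <- inp$raw[["inputBinding"]]
    binding <- NULL
    if (!is.null(b)) {
      if (!is.null(b[["valueFrom"]])) check_no_expression(b[["valueFrom"]],
        paste0("inputBinding of '", inp$id, "'"))
      binding <- list(
        position = as.integer(b[["position"]] %||% 0L),
        prefix = b[["prefix"]],
        separate = isTRUE(b[["separate"]] %||% TRUE),
        item_separator = b[["itemSeparator"]])
      if (!is.null(binding$item_separator) && !grepl("\\[\\]$", type$type))
        stop("itemSeparator on non-array input '", inp$id, "' in ", src,
             call. = FALSE)
      if (!binding$separate && is.null(binding$prefix))
        stop("separate: false requires a prefix on input '", inp$id,
             "' in ", src, call. = FALSE)
    }
    list(id = inp$id, type = type$type, optional = type$optional,
         default = inp$raw[["default"]], binding = binding)
  })
  names(inputs) <- vapply(inputs, `[[`, character(1), "id")
  if (anyDuplicated(names(inputs)))
    stop("duplicate input ids in ", src, call. = FALSE)

  arguments <- lapply(doc[["arguments"]] %||% list(), function(a) {
    if (is.character(a) || is.numeric(a)) {
      check_no_expression(as.character(a), "arguments")
      list(position = 0L, prefix = NULL, separate = TRUE,
           value = as.character(a))
    } else if (is.list(a)) {
      check_no_expression(a[["valueFrom"]], "arguments")
      list(position = as.integer(a[["position"]] %||% 0L),
           prefix = a[["prefix"]],
           separate = isTRUE(a[["separate"]] %||% TRUE),
           value = a[["valueFrom"]])
    } else stop("malformed arguments entry in ", src, call. = FALSE)
  })

  outputs <- parse_cwl_ports(doc[["outputs"]] %||% list(), src)
  outputs <- lapply(outputs, function(o) {
    type <- o$raw_type
    if (identical(type, "stdout")) {
      if (is.null(doc[["stdout"]]))
        stop("output '", o$id, "' has type stdout but the tool declares no ",
             "stdout filename in ", src, call. = FALSE)
      return(list(id = o$id, glob = doc[["stdout"]]))
    }
    if (!identical(type, "File"))
      stop("unsupported output type for '", o$id, "' in ", src,
           ": only File outputs with a glob are supported", call. = FALSE)
    glob <- o$raw[["outputBinding"]][["glob"]]
    if (is.null(glob) || !nzchar(glob))
      stop("output '", o$id, "' lacks an outputBinding glob in ", src,
           call. = FALSE)
    check_no_expression(glob, paste0("glob of '", o$id, "'"))
    list(id = o$id, glob = glob)
  })
  names(outputs) <- vapply(outputs, `[[`, character(1), "id")

  if (!is.null(doc[["stdout"]])) check_no_expression(doc[["stdout"]], "stdout")
  ignored <- doc[names(doc) %in% c("requirements", "hints")]
  if (length(ignored))
    warning("ignoring CWL requirements/hints in ", src, call. = FALSE)

  structure(list(
    tool_id = doc[["id"]] %||% tools::file_path_sans_ext(basename(src)),
    cwl_version = doc[["cwlVersion"]],
    base_command = base,
    inputs = inputs,
    arguments = arguments,
    outputs = outputs,
    stdout = doc[["stdout"]],
    ignored = ignored), class = "sf_tool")
}

# CWL ports (inputs/outputs) may be a map id -> spec, a map id -> type
# shorthand, or a list of {id: ...} records; normalise to a list of
# list(id, raw, raw_type).
parse_cwl_ports <- function(ports, src) {
  if (is.null(ports)) return(list())
  if (!is.list(ports)) stop("malformed inputs/outputs in ", src, call. = FALSE)
  nm <- names(ports)
  if (!is.null(nm) && all(nzchar(nm))) {
    out <- lapply(nm, function(id) {
      p <- ports[[id]]
      if (!is.list(p)) p <- list(type = p)
      list(id = id, raw = p, raw_type = p[["type"]])
    })
  } else {
    out <- lapply(ports, function(p) {
      if (is.null(p[["id"]])) stop("port without id in ", src, call. = FALSE)
      list(id = p[["id"]], raw = p, raw_type = p[["type"]])
    })
  }
  out
}

# "string?" / ["null","string"] -> optional; {type: array, items: T} -> "T[]"
normalise_cwl_type <- function(type, id, src) {
  optional <- FALSE
  if (is.list(type) && !is.null(type[["type"]])) {
    if (identical(type[["type"]], "array")) {
      items <- type[["items"]]
      if (!is.character(items) || !items %in% c("string", "File"))
        stop("unsupported array item type for input '", id, "' in ", src,
             call. = FALSE)
      return(list(type = paste0(items, "[]"), optional = FALSE))
    }
    stop("unsupported type for input '", id, "' in ", src, call. = FALSE)
  }
  if (is.list(type) || length(type) > 1) {
    type <- as.character(unlist(type))
    if ("null" %in% type && length(type) == 2) {
      optional <- TRUE
      type <- setdiff(type, "null")
    } else stop("unsupported union type for input '", id, "' in ", src,
                call. = FALSE)
  }
  type <- as.character(type)
  if (endsWith(type, "?")) {
    optional <- TRUE
    type <- sub("\\?$", "", type)
  }
  if (!type %in% SF_CWL_TYPES)
    stop("unsupported CWL type '", type, "' for input '", id, "' in ", src,
         call. = FALSE)
  list(type = type, optional = optional)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cwl_value_string <- function(v) {
  if (is.list(v) && identical(v[["class"]], "File")) return(v[["path"]])
  if (is.logical(v)) return(tolower(as.character(v)))
  as.character(v)
}

#' Render the concrete command line for one job
#'
#' Applies the CWL argument-binding rules to a tool description and a set
#' of input values: bindings are collected from `arguments` and from bound
#' inputs, stably sorted by `position` with ties broken by placing
#' arguments (in declaration order) before inputs (lexicographic by id).
#' Boolean `TRUE` emits its prefix only; `FALSE` or absent emits nothing.
#' `separate: false` joins prefix and value into one token. Arrays with an
#' `itemSeparator` emit one joined token; without one, the prefix is
#' repeated before each element. `File` values render as their path.
#'
#' @param tool an `sf_tool`.
#' @param values named list of input values (scalars, logicals, lists, or
#'   `{class: File, path: ...}` maps). Defaults from the tool description
#'   are applied first.
#' @param sample optional sample label carried on the result.
#' @return An object of class `sf_command`: `sample`, `argv`, `stdout_to`,
#'   `expected_outputs` (named character, output id -> path).
#' @export
bind_command <- function(tool, values = list(), sample = NA_character_) {
  stopifnot(inherits(tool, "sf_tool"))
  vals <- lapply(tool$inputs, `[[`, "default")
  for (id in names(values)) vals[[id]] <- values[[id]]
  extra <- setdiff(names(values), names(tool$inputs))
  if (length(extra))
    stop("value(s) for undeclared input(s): ", paste(extra, collapse = ", "),
         call. = FALSE)

  missing <- names(tool$inputs)[vapply(names(tool$inputs), function(id) {
    is.null(vals[[id]]) && !tool$inputs[[id]]$optional
  }, logical(1))]
  if (length(missing))
    stop("missing required input(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  entries <- list()
  for (i in seq_along(tool$arguments)) {
    a <- tool$arguments[[i]]
    tokens <- binding_tokens(a$value, "string", a$prefix, a$separate, NULL)
    if (length(tokens))
      entries[[length(entries) + 1]] <-
        list(position = a$position, src = 0L, key = sprintf("%06d", i),
             tokens = tokens)
  }
  for (id in names(tool$inputs)) {
    inp <- tool$inputs[[id]]
    if (is.null(inp$binding)) next
    v <- vals[[id]]
    if (is.null(v)) next
    b <- inp$binding
    tokens <- binding_tokens(v, inp$type, b$prefix, b$separate,
                             b$item_separator)
    if (length(tokens))
      entries[[length(entries) + 1]] <-
        list(position = b$position, src = 1L, key = id, tokens = tokens)
  }
  if (length(entries)) {
    ord <- order(vapply(entries, `[[`, integer(1), "position"),
                 vapply(entries, `[[`, integer(1), "src"),
                 vapply(entries, `[[`, character(1), "key"))
    entries <- entries[ord]
  }
  argv <- c(tool$base_command, unlist(lapply(entries, `[[`, "tokens")))

  outs <- vapply(tool$outputs, function(o) resolve_output_path(o$glob),
                 character(1))
  structure(list(sample = sample, argv = as.character(argv),
                 stdout_to = if (!is.null(tool$stdout))
                   resolve_output_path(tool$stdout) else NULL,
                 expected_outputs = outs),
            class = "sf_command")
}

binding_tokens <- function(v, type, prefix, separate, item_separator) {
  if (identical(type, "boolean") || is.logical(v)) {
    if (isTRUE(v) || identical(v, "true"))
      return(if (!is.null(prefix)) prefix else character())
    return(character())
  }
  is_file_map <- is.list(v) && identical(v[["class"]], "File")
  is_array <- !is_file_map &&
    (grepl("\\[\\]$", type) || is.list(v) || length(v) > 1)
  if (is_array) {
    elems <- vapply(if (is.list(v)) v else as.list(v), cwl_value_string,
                    character(1))
    if (!length(elems)) return(character())
    if (!is.null(item_separator)) {
      joined <- paste(elems, collapse = item_separator)
      if (is.null(prefix)) return(joined)
      if (separate) return(c(prefix, joined))
      return(paste0(prefix, joined))
    }
    if (is.null(prefix)) return(elems)
    if (separate) return(as.character(rbind(prefix, elems)))
    return(paste0(prefix, elems))
  }
  s <- cwl_value_string(v)
  if (is.null(prefix)) return(s)
  if (separate) return(c(prefix, s))
  paste0(prefix, s)
}

# Relative output globs land under results/ unless they already point there
# or are absolute.
resolve_output_path <- function(glob) {
  if (startsWith(glob, "/") || startsWith(glob, "results/")) return(glob)
  file.path("results", glob)
}

# `_Token_` placeholders: an uppercase-initial alphanumeric token between
# single underscores, matched case-insensitively against targets columns.
find_placeholders <- function(s) {
  m <- gregexpr("_([A-Z][A-Za-z0-9]*)_", s)
  toks <- regmatches(s, m)[[1]]
  if (!length(toks)) return(character())
  gsub("^_|_$", "", toks)
}

substitute_placeholders <- function(s, row, available) {
  toks <- find_placeholders(s)
  for (tok in toks) {
    hit <- which(tolower(available) == tolower(tok))
    if (!length(hit))
      stop("placeholder _", tok, "_ names no targets column; available ",
           "columns: ", paste(available, collapse = ", "), call. = FALSE)
    s <- gsub(paste0("_", tok, "_"), row[[available[hit[1]]]], s, fixed = TRUE)
  }
  s
}

#' Render per-sample commands for a command step
#'
#' Produces one rendered command per row of the targets table. `_Column_`
#' placeholders in input values (and in output globs / stdout patterns,
#' notably `_SampleName_`) are replaced with that row's value for the
#' named column (matched case-insensitively).
#'
#' @param tool an `sf_tool`.
#' @param values named list of job values, possibly containing
#'   `_Column_` placeholders.
#' @param targets an `sf_targets` table.
#' @return List of `sf_command`, in targets row order.
#' @export
render_step_commands <- function(tool, values, targets) {
  stopifnot(inherits(tool, "sf_tool"), inherits(targets, "sf_targets"))
  cols <- names(targets$data)
  lapply(seq_len(nrow(targets$data)), function(i) {
    row <- as.list(targets$data[i, , drop = FALSE])
    vals <- lapply(values, function(v) {
      if (is.character(v) && length(v) == 1)
        substitute_placeholders(v, row, cols)
      else if (is.list(v) && is.null(v[["class"]]))
        lapply(v, function(e) if (is.character(e))
          substitute_placeholders(e, row, cols) else e)
      else v
    })
    cmd <- bind_command(tool, vals, sample = row$SampleName)
    cmd$expected_outputs <- vapply(cmd$expected_outputs, function(p)
      substitute_placeholders(p, row, cols), character(1))
    if (!is.null(cmd$stdout_to))
      cmd$stdout_to <- substitute_placeholders(cmd$stdout_to, row, cols)
    cmd
  })
}

#' Generate a tool description from an annotated command template
#'
#' A one-line shortcut for writing CWL descriptions: whitespace-separated
#' tokens where plain tokens become the base command / literal arguments,
#' `<id:type:default>` declares an input (the immediately preceding literal
#' is consumed as its prefix when it starts with `-`), and
#' `<id:out:default>` declares a `File` output whose glob is the default's
#' basename (the path itself is passed as a bound string input). Positions
#' are assigned by order of appearance starting at 1, so re-rendering with
#' the returned defaults reproduces the template.
#'
#' @param template the annotated command string.
#' @return List with elements `tool` (an `sf_tool`) and `values` (the
#'   defaults as job values).
#' @examples
#' tv <- tool_from_template("echo -m <msg:string:hello>")
#' bind_command(tv$tool, tv$values)$argv
#' @export
tool_from_template <- function(template) {
  m <- gregexpr("\\S+", template)[[1]]
  tokens <- regmatches(template, gregexpr("\\S+", template))[[1]]
  offsets <- as.integer(m)
  if (!length(tokens)) stop("empty command template", call. = FALSE)

  base <- NULL
  arguments <- list()
  inputs <- list()
  outputs <- list()
  values <- list()
  pending <- NULL
  pos <- 0L

  commit_pending <- function() {
    if (!is.null(pending)) {
      pos <<- pos + 1L
      arguments[[length(arguments) + 1]] <<-
        list(position = pos, prefix = NULL, separate = TRUE, value = pending)
      pending <<- NULL
    }
  }

  ph_re <- "^<([A-Za-z][A-Za-z0-9_]*):(string|int|boolean|File|Directory|out):(.*)>$"
  for (k in seq_along(tokens)) {
    tok <- tokens[k]
    if (startsWith(tok, "<")) {
      mm <- regmatches(tok, regexec(ph_re, tok))[[1]]
      if (!length(mm))
        stop("malformed placeholder '", tok, "' at character ", offsets[k],
             call. = FALSE)
      id <- mm[2]; type <- mm[3]; default <- mm[4]
      prefix <- NULL
      if (!is.null(pending) && startsWith(pending, "-")) {
        prefix <- pending
        pending <- NULL
      } else commit_pending()
      pos <- pos + 1L
      binding <- list(position = pos, prefix = prefix, separate = TRUE,
                      item_separator = NULL)
      if (type == "out") {
        inputs[[id]] <- list(id = id, type = "string", optional = FALSE,
                             default = NULL, binding = binding)
        outputs[[id]] <- list(id = id, glob = basename(default))
        values[[id]] <- default
      } else {
        dv <- switch(type,
                     int = default,
                     boolean = identical(tolower(default), "true"),
                     default)
        inputs[[id]] <- list(id = id, type = type, optional = FALSE,
                             default = NULL, binding = binding)
        values[[id]] <- dv
      }
    } else {
      if (is.null(base)) base <- tok
      else { commit_pending(); pending <- tok }
    }
  }
  commit_pending()
  if (is.null(base)) stop("command template has no base command", call. = FALSE)
  if (anyDuplicated(names(inputs)))
    stop("duplicate placeholder id in template", call. = FALSE)

  tool <- structure(list(
    tool_id = base, cwl_version = "v1.2", base_command = base,
    inputs = inputs, arguments = arguments, outputs = outputs,
    stdout = NULL, ignored = list()), class = "sf_tool")
  list(tool = tool, values = values)
}

#' Serialise a tool description back to CWL YAML
#'
#' @param tool an `sf_tool`.
#' @param path optional file to write to.
#' @return The YAML text (invisibly if `path` given).
#' @export
write_tool <- function(tool, path = NULL) {
  doc <- list(cwlVersion = tool$cwl_version, class = "CommandLineTool",
              baseCommand = as.list(tool$base_command))
  doc$inputs <- lapply(tool$inputs, function(inp) {
    o <- list(type = if (inp$optional) paste0(inp$type, "?") else inp$type)
    if (!is.null(inp$default)) o$default <- inp$default
    if (!is.null(inp$binding)) {
      b <- list(position = inp$binding$position)
      if (!is.null(inp$binding$prefix)) b$prefix <- inp$binding$prefix
      if (!inp$binding$separate) b$separate <- FALSE
      if (!is.null(inp$binding$item_separator))
        b$itemSeparator <- inp$binding$item_separator
      o$inputBinding <- b
    }
    o
  })
  if (length(tool$arguments))
    doc$arguments <- lapply(tool$arguments, function(a) {
      if (a$position == 0L && is.null(a$prefix)) a$value
      else {
        o <- list(position = a$position, valueFrom = a$value)
        if (!is.null(a$prefix)) o$prefix <- a$prefix
        o
      }
    })
  doc$outputs <- lapply(tool$outputs, function(o)
    list(type = "File", outputBinding = list(glob = o$glob)))
  if (!length(doc$outputs)) doc$outputs <- list()
  if (!is.null(tool$stdout)) doc$stdout <- tool$stdout
  txt <- yaml::as.yaml(doc)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @export
print.sf_tool <- function(x, ...) {
  cat("<sf_tool> ", x$tool_id, " (", x$cwl_version, ")\n",
      "  base command: ", paste(x$base_command, collapse = " "), "\n",
      "  inputs: ", paste(names(x$inputs), collapse = ", "), "\n",
      "  outputs: ", paste(names(x$outputs), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
print.sf_command <- function(x, ...) {
  cat("<sf_command>", if (!is.na(x$sample)) paste0("[", x$sample, "]"), "\n ",
      paste(shQuote(x$argv), collapse = " "),
      if (!is.null(x$stdout_to)) paste(" >", x$stdout_to), "\n")
  invisible(x)
}
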