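#' Sample metadata tables (targets files)
#'
#' A targets table is the tab-separated sample sheet that drives per-sample
#' execution and labelling. It must contain a `SampleName` column whose
#' values are unique and non-empty; all other columns are free-form sample
#' metadata (input file paths, experimental factors, ...). Comment lines
#' (starting with `#`) preceding the header are preserved verbatim so that
#' provenance notes survive round trips.
#'
#' @param data a data.frame of character columns, one row per sample.
#' @param comments character vector of comment lines, each starting `#`.
#' @return An object of class `sf_targets` with fields `comments` and
#'   `data`.
#' @examples
#' t <- sf_targets(data.frame(SampleName = c("S1", "S2"),
#'                            Factor = c("A", "B")))
#' sample_names(t)
#' @export
sf_targets <- function(data, comments = character()) {
  stopifnot(is.data.frame(data))
  data[] <- lapply(data, as.character)
  rownames(data) <- NULL
  t <- structure(list(comments = as.character(comments), data = data),
                 class = "sf_targets")
  validate_targets(t)
  t
}

validate_targets <- function(t) {
  d <- t$data
  if (!"SampleName" %in% names(d))
    stop("targets table must contain a 'SampleName' column", call. = FALSE)
  sn <- d$SampleName
  if (any(is.na(sn)) || any(!nzchar(sn)))
    stop("SampleName values must be non-empty", call. = FALSE)
  dup <- unique(sn[duplicated(sn)])
  if (length(dup))
    stop("duplicate SampleName value(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (length(t$comments) && any(!startsWith(t$comments, "#")))
    stop("comment lines must start with '#'", call. = FALSE)
  bad <- vapply(d, function(col) any(grepl("\t", col, fixed = TRUE)), logical(1))
  if (any(bad))
    stop("tab characters are not allowed in targets values (column ",
         paste(names(d)[bad], collapse = ", "), ")", call. = FALSE)
  invisible(t)
}

#' Read a targets file
#'
#' Parses a UTF-8 TSV sample sheet. Lines starting with `#` before the
#' header are kept as comments; the first non-comment line is the header.
#' Fields must not be ragged: every row needs exactly as many values as the
#' header (empty strings are allowed, but `SampleName` must be non-empty
#' and unique).
#'
#' @param path path to the targets file.
#' @return An `sf_targets` object.
#' @export
read_targets <- function(path) {
  if (!file.exists(path))
    stop("targets file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- startsWith(lines, "#")
  # comments must precede the header
  first_data <- which(!is_comment)[1]
  if (is.na(first_data))
    stop("targets file has no header line: ", path, call. = FALSE)
  comments <- lines[seq_len(first_data - 1)]
  body <- lines[seq(first_data, length(lines))]
  while (length(body) > 1 && !nzchar(body[length(body)]))
    body <- body[-length(body)]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!length(header) || any(!nzchar(header)))
    stop("malformed header line in ", path, call. = FALSE)
  n <- length(header)
  rows <- lapply(seq_along(body)[-1], function(i) {
    fields <- strsplit(paste0(body[i], "\x01"), "\t", fixed = TRUE)[[1]]
    fields[length(fields)] <- sub("\x01$", "", fields[length(fields)])
    if (length(fields) != n)
      stop("ragged row at line ", first_data + i - 1L, " of ", path,
           ": expected ", n, " fields, found ", length(fields), call. = FALSE)
    fields
  })
  if (length(rows)) {
    d <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  } else {
    d <- as.data.frame(matrix(character(), nrow = 0, ncol = n),
                       stringsAsFactors = FALSE)
  }
  names(d) <- header
  sf_targets(d, comments = comments)
}

#' Write a targets file
#'
#' Inverse of [read_targets()]: comments, column order and row order are
#' written back so that `read_targets(write_targets(t, p))` reproduces `t`
#' exactly.
#'
#' @param t an `sf_targets` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(t, path) {
  validate_targets(t)
  d <- t$data
  lines <- c(t$comments,
             paste(names(d), collapse = "\t"),
             if (nrow(d)) apply(d, 1, paste, collapse = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Extract a column from a targets table
#'
#' @param t an `sf_targets` object.
#' @param name column name.
#' @return Character vector of values in row order.
#' @export
get_column <- function(t, name) {
  stopifnot(inherits(t, "sf_targets"))
  if (!name %in% names(t$data))
    stop("unknown targets column '", name, "'; available columns: ",
         paste(names(t$data), collapse = ", "), call. = FALSE)
  t$data[[name]]
}

#' @rdname sf_targets
#' @param t an `sf_targets` object.
#' @export
sample_names <- function(t) get_column(t, "SampleName")

#' Derive a targets table from a step's expected outputs
#'
#' Propagates sample metadata downstream: for a command step that has been
#' rendered (one command per sample), builds a new targets table with one
#' row per sample, carrying over all metadata columns of the upstream
#' step's targets and adding one column per mapped output id containing
#' that sample's expected output path. This is how output files of one
#' step become input files of the next while the `SampleName` lineage is
#' preserved.
#'
#' @param wf an `sf_workflow`.
#' @param upstream id of a command step already in `wf`.
#' @param column_map named list/character: output id -> new column name.
#' @return An `sf_targets` object.
#' @export
outputs_to_targets <- function(wf, upstream, column_map) {
  step <- wf_get_step(wf, upstream)
  if (step$kind != "command")
    stop("step '", upstream, "' is not a command step", call. = FALSE)
  cmds <- step$commands
  if (is.null(cmds))
    stop("step '", upstream, "' has no rendered commands", call. = FALSE)
  column_map <- unlist(column_map)
  out_ids <- unique(unlist(lapply(cmds, function(c) names(c$expected_outputs))))
  missing <- setdiff(names(column_map), out_ids)
  if (length(missing))
    stop("unknown output id(s) in column map: ",
         paste(missing, collapse = ", "), "; step '", upstream,
         "' declares: ", paste(out_ids, collapse = ", "), call. = FALSE)
  d <- step$targets$data
  for (oid in names(column_map)) {
    col <- vapply(cmds, function(c) unname(c$expected_outputs[[oid]]),
                  character(1))
    d[[column_map[[oid]]]] <- col
  }
  # mapped columns replace same-named originals; order: SampleName first
  first <- "SampleName"
  d <- d[, c(first, setdiff(names(d), first)), drop = FALSE]
  sf_targets(d, comments = step$targets$comments)
}

#' @export
print.sf_targets <- function(x, ...) {
  cat("<sf_targets> ", nrow(x$data), " sample(s), ",
      ncol(x$data), " column(s)", sep = "")
  if (length(x$comments)) cat(", ", length(x$comments), " comment line(s)",
                              sep = "")
  cat("\n")
  print(utils::head(x$data, 10))
  invisible(x)
}
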