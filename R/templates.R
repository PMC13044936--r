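#' Project templates and toy fixtures
#'
#' Templates instantiate complete, runnable workflow projects offline: the
#' literate `workflow.md`, CWL tool descriptions under `param/`, mock tool
#' scripts under `tools/` (plain-text transforms standing in for heavy
#' bioinformatics tools), toy reference tables under `data/`, and a
#' generated sample sheet. Two templates ship with the package:
#' `skeleton`, a minimal three-step outline, and `varseq_mock`, a 35-step
#' mock variant-calling (VAR-Seq) workflow reproducing the scatter/gather
#' shape of a cohort gVCF analysis — per-sample alignment and gVCF calling
#' fanning into cohort-level joint genotyping, filtering, annotation, and
#' downstream gene-burden, pathway-enrichment and drug-target steps.
#'
#' @name templates
NULL

sf_templates <- function() {
  base <- system.file("extdata", "templates", package = "sampleflow")
  list.dirs(base, recursive = FALSE, full.names = FALSE)
}

#' Initialize a workflow project from a template
#'
#' Materializes the full project layout (`data/`, `results/`, `param/`,
#' `tools/`, `targets.tsv`, `workflow.md`) into `dir`, which must not
#' exist or be empty. Mock tool scripts are installed executable under
#' `tools/`; the engine prepends that directory to the search path at run
#' time. Sample data files and the sample sheet are generated
#' deterministically by [generate_fixtures()].
#'
#' @param dir target project directory.
#' @param template template name; see `sf_templates()`.
#' @param n_samples number of toy samples to generate.
#' @param seed RNG seed for the fixture generator.
#' @return The project directory, invisibly.
#' @export
init_project <- function(dir, template = "skeleton", n_samples = 3L,
                         seed = 1L) {
  available <- sf_templates()
  if (!template %in% available)
    stop("unknown template '", template, "'; available templates: ",
         paste(available, collapse = ", "), call. = FALSE)
  if (dir.exists(dir) &&
      length(list.files(dir, all.files = TRUE, no.. = TRUE)))
    stop("refusing to initialize into non-empty directory: ", dir,
         call. = FALSE)
  for (d in c("data", "results", "param", "tools"))
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  src <- system.file("extdata", "templates", template,
                     package = "sampleflow")
  files <- list.files(src, recursive = TRUE)
  for (f in files) {
    dest <- file.path(dir, f)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    file.copy(file.path(src, f), dest, overwrite = TRUE)
  }
  tool_scripts <- list.files(file.path(dir, "tools"), full.names = TRUE)
  if (length(tool_scripts)) Sys.chmod(tool_scripts, "0755")
  generate_fixtures(dir, n_samples = n_samples, seed = seed)
  invisible(dir)
}

#' Generate deterministic toy input data
#'
#' Writes one toy reads file per sample (plain text, one `id sequence`
#' record per line), a toy reference file, and a matching `targets.tsv`
#' with unique sample names. The same seed always produces byte-identical
#' files, so fixture-driven tests and demos are fully reproducible.
#'
#' @param dir project directory (its `data/` subdirectory receives the
#'   files).
#' @param n_samples number of samples, >= 1.
#' @param seed RNG seed.
#' @param reads_per_sample toy reads per sample.
#' @return The generated `sf_targets`, invisibly.
#' @export
generate_fixtures <- function(dir, n_samples = 3L, seed = 1L,
                              reads_per_sample = 30L) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L)
    stop("n_samples must be >= 1", call. = FALSE)
  dir.create(file.path(dir, "data"), recursive = TRUE, showWarnings = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  bases <- c("A", "C", "G", "T")
  samples <- sprintf("S%d", seq_len(n_samples))
  files <- character(n_samples)
  for (i in seq_len(n_samples)) {
    lens <- sample(8:20, reads_per_sample, replace = TRUE)
    recs <- vapply(seq_len(reads_per_sample), function(j)
      paste0(sprintf("R%03d ", j),
             paste(sample(bases, lens[j], replace = TRUE), collapse = "")),
      character(1))
    files[i] <- file.path("data", paste0(samples[i], "_reads.txt"))
    writeLines(recs, file.path(dir, files[i]))
  }
  ref <- vapply(1:10, function(j)
    paste0(sprintf("ref%02d ", j),
           paste(sample(bases, 40, replace = TRUE), collapse = "")),
    character(1))
  writeLines(ref, file.path(dir, "data", "reference.txt"))

  t <- sf_targets(data.frame(
    FileName = files, SampleName = samples,
    Factor = rep(c("A", "B"), length.out = n_samples),
    stringsAsFactors = FALSE),
    comments = c("# toy sequencing project",
                 paste0("# generated with seed ", as.integer(seed))))
  write_targets(t, file.path(dir, "targets.tsv"))
  invisible(t)
}
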