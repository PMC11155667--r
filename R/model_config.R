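# Declarative model input: a document with top-level `settings` and
# `fitting` blocks. `fitting$peaks` maps string-integer indices to a
# single lineshape kind, whose attributes each carry a
# {min, max, vary, value, expr} spec. The same structure is accepted from
# JSON, YAML or TOML and always yields the same fit_project.

PARAMETER_SPEC_FIELDS <- c("min", "max", "vary", "value", "expr")

SETTINGS_KEYS <- c("x_column", "y_column", "energy_shift", "energy_range",
                   "method", "method_kwargs", "outfile", "plot", "verbose")

#' Parse a declarative fit model
#'
#' Reads a model/settings document and validates it into a `fit_project`.
#' The document has two top-level blocks: `settings` (column names, energy
#' shift and range, optimizer method and its keyword arguments) and
#' `fitting` with `description` (free metadata), optional `parameters`
#' (kept as metadata) and `peaks`, where
#' `peaks$"1"$gaussian$amplitude$value` style entries initialize the
#' components. Unknown top-level keys are preserved as metadata.
#'
#' @param input path to a model file, or the document text itself.
#' @param format `"json"`, `"yaml"` or `"toml"`; inferred from the file
#'   extension when `input` is a path and `format` is `NULL`.
#' @return a `fit_project`: list with `settings`, `description`,
#'   `components` (ordered by ascending integer index) and `metadata`.
#' @export
parse_input <- function(input, format = NULL) {
  is_path <- length(input) == 1L && !grepl("[\n{]", input) && file.exists(input)
  text <- if (is_path) paste(readLines(input, warn = FALSE), collapse = "\n") else input
  if (is.null(format)) {
    if (!is_path) stop_invalid("format must be given when parsing from text")
    format <- switch(tolower(tools::file_ext(input)),
                     json = "json", yaml = "yaml", yml = "yaml",
                     toml = "toml", lock = "toml",
                     stop_invalid("cannot infer format from extension of '%s'", input))
  }
  format <- match.arg(format, c("json", "yaml", "toml"))
  doc <- switch(format,
    json = tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                    error = function(e) stop_parse("malformed JSON: %s",
                                                   conditionMessage(e))),
    yaml = tryCatch(yaml::yaml.load(text),
                    error = function(e) stop_parse("malformed YAML: %s",
                                                   conditionMessage(e))),
    toml = toml_read(text))
  if (!is.list(doc)) stop_parse("model document is not a mapping")
  project_from_document(doc)
}

project_from_document <- function(doc) {
  settings <- validate_settings(doc$settings %||% list())
  fitting <- doc$fitting %||% list()
  peaks <- fitting$peaks %||% doc$peaks
  if (is.null(peaks) || !length(peaks)) {
    stop_invalid("model defines no components under fitting$peaks")
  }
  components <- parse_components(peaks)
  metadata <- doc[setdiff(names(doc), c("settings", "fitting"))]
  if (!is.null(fitting$parameters)) metadata$parameters <- fitting$parameters
  structure(list(settings = settings,
                 description = fitting$description %||% list(),
                 components = components,
                 metadata = metadata),
            class = "fit_project")
}

validate_settings <- function(settings) {
  if (!is.list(settings)) stop_invalid("settings block must be a mapping")
  rng <- settings$energy_range
  if (!is.null(rng)) {
    rng <- as.numeric(unlist(rng))
    if (length(rng) != 2L || !all(is.finite(rng)) || rng[1] >= rng[2]) {
      stop_invalid("settings$energy_range must be [lo, hi] with lo < hi")
    }
    settings$energy_range <- rng
  }
  if (!is.null(settings$energy_shift)) {
    settings$energy_shift <- as.numeric(settings$energy_shift)
  }
  if (!is.null(settings$y_column)) {
    settings$y_column <- as.character(unlist(settings$y_column))
  }
  settings
}

parse_components <- function(peaks) {
  idx <- names(peaks)
  if (is.null(idx) || any(!nzchar(idx))) {
    stop_invalid("fitting$peaks must map string-integer indices to components")
  }
  if (any(is.na(suppressWarnings(as.integer(idx))))) {
    stop_invalid("component indices must be string integers (got: %s)",
                 paste(idx, collapse = ", "))
  }
  if (anyDuplicated(idx)) stop_invalid("duplicate component index")
  components <- lapply(idx, function(i) {
    entry <- peaks[[i]]
    if (!is.list(entry) || length(entry) != 1L || is.null(names(entry))) {
      stop_invalid("fitting$peaks$\"%s\" must hold exactly one lineshape kind", i)
    }
    kind <- names(entry)
    if (!(kind %in% supported_kinds())) {
      stop_invalid("fitting$peaks$\"%s\": unsupported kind '%s'", i, kind)
    }
    attrs <- entry[[kind]]
    if (!is.list(attrs) || is.null(names(attrs)) || !length(attrs)) {
      stop_invalid("fitting$peaks$\"%s\"$%s must define at least one attribute", i, kind)
    }
    allowed <- KIND_ATTRIBUTES[[kind]]
    bad <- setdiff(names(attrs), allowed)
    if (length(bad)) {
      stop_invalid("fitting$peaks$\"%s\"$%s: unknown attribute(s) %s (allowed: %s)",
                   i, kind, paste(bad, collapse = ", "), paste(allowed, collapse = ", "))
    }
    attrs <- lapply(stats::setNames(names(attrs), names(attrs)), function(an) {
      validate_parameter_spec(attrs[[an]], sprintf("peaks$\"%s\"$%s$%s", i, kind, an))
    })
    list(index = i, kind = kind, attributes = attrs)
  })
  components[order(as.integer(idx))]
}

validate_parameter_spec <- function(spec, path) {
  if (is.numeric(spec) && length(spec) == 1L) spec <- list(value = spec)
  if (!is.list(spec)) stop_invalid("%s must be a {min,max,vary,value,expr} mapping", path)
  bad <- setdiff(names(spec), PARAMETER_SPEC_FIELDS)
  if (length(bad)) {
    stop_invalid("%s: unknown field(s) %s", path, paste(bad, collapse = ", "))
  }
  for (f in c("min", "max", "value")) {
    if (!is.null(spec[[f]])) spec[[f]] <- as.numeric(spec[[f]])
  }
  if (!is.null(spec$expr)) {
    spec$expr <- as.character(spec$expr)
    if (isTRUE(spec$vary)) {
      stop_invalid("%s: expr and vary = true are mutually exclusive", path)
    }
    spec$vary <- FALSE
  }
  lo <- spec$min %||% -Inf; hi <- spec$max %||% Inf
  if (lo > hi) stop_invalid("%s: min > max", path)
  if (!is.null(spec$value) && (spec$value < lo || spec$value > hi)) {
    stop_invalid("%s: value outside [min, max]", path)
  }
  spec
}

#' Serialize a fit project back to a model document
#'
#' Inverse of [parse_input()]: the returned text reparsed in the same
#' format yields an identical `fit_project`.
#'
#' @param project a `fit_project`.
#' @param format `"json"`, `"yaml"` or `"toml"`.
#' @return a single character string in the requested format.
#' @export
serialize_project <- function(project, format = c("json", "yaml", "toml")) {
  format <- match.arg(format)
  peaks <- list()
  for (co in project$components) {
    attrs <- lapply(co$attributes, function(a) a[!vapply(a, is.null, TRUE)])
    peaks[[co$index]] <- stats::setNames(list(attrs), co$kind)
  }
  doc <- c(list(settings = project$settings,
                fitting = list(description = project$description, peaks = peaks)),
           project$metadata)
  doc <- doc[!vapply(doc, function(v) is.null(v) || (is.list(v) && !length(v)), TRUE)]
  switch(format,
    json = as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                         null = "null")),
    yaml = yaml::as.yaml(doc),
    toml = toml_write(doc))
}

# --- spectra ---------------------------------------------------------------

#' Construct a spectrum
#'
#' @param x numeric abscissa (e.g. energy in eV); must end up strictly
#'   increasing and finite.
#' @param y numeric intensity, same length.
#' @param x_label,y_label axis labels.
#' @return a `spectrum` object.
#' @export
new_spectrum <- function(x, y, x_label = "energy", y_label = "intensity") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_invalid("x and y lengths differ")
  if (!length(x)) stop_invalid("spectrum is empty")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_invalid("spectrum contains non-finite values")
  }
  if (is.unsorted(x)) {
    o <- order(x)
    x <- x[o]; y <- y[o]
    message("spectrum abscissa was not ascending; rows reordered")
  }
  dup <- duplicated(x)
  if (any(dup)) {
    warning(sprintf("%d duplicate abscissa value(s) dropped (first kept)", sum(dup)))
    x <- x[!dup]; y <- y[!dup]
  }
  structure(list(x = x, y = y, x_label = x_label, y_label = y_label),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %d points, %s in [%g, %g]>\n",
              length(x$x), x$x_label, min(x$x), max(x$x)))
  invisible(x)
}

detect_separator <- function(header_line) {
  counts <- vapply(c(",", "\t", ";"), function(s) {
    lengths(regmatches(header_line, gregexpr(s, header_line, fixed = TRUE)))
  }, 0L)
  if (all(counts == 0L)) return(",")
  names(counts)[which.max(counts)]
}

#' Read a spectrum from delimited text
#'
#' The delimiter (comma, tab or semicolon) is auto-detected from the
#' header row unless `sep` is given. Rows with non-numeric cells in the
#' requested columns are dropped with a message; a descending abscissa is
#' sorted ascending with a notice.
#'
#' @param path file path.
#' @param x_column,y_column column names; default: first and second column.
#' @param sep optional explicit delimiter.
#' @return a `spectrum`.
#' @export
read_spectrum <- function(path, x_column = NULL, y_column = NULL, sep = NULL) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("data file not found: %s", path),
                        class = c("peakfitr_io_error", "error")))
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (is.null(sep)) sep <- detect_separator(first)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE,
                          comment.char = "")
  x_column <- x_column %||% names(df)[1]
  y_column <- y_column %||% names(df)[2]
  missing_cols <- setdiff(c(x_column, y_column), names(df))
  if (length(missing_cols)) {
    stop_invalid("column(s) %s not found; available: %s",
                 paste(missing_cols, collapse = ", "),
                 paste(names(df), collapse = ", "))
  }
  xv <- suppressWarnings(as.numeric(df[[x_column]]))
  yv <- suppressWarnings(as.numeric(df[[y_column]]))
  ok <- is.finite(xv) & is.finite(yv)
  if (any(!ok)) message(sprintf("%d row(s) with non-numeric cells dropped", sum(!ok)))
  if (!any(ok)) stop_invalid("no numeric rows in columns %s/%s", x_column, y_column)
  new_spectrum(xv[ok], yv[ok], x_label = x_column, y_label = y_column)
}

#' Shift and window a spectrum
#'
#' Applies the energy shift first, then keeps only points with
#' `lo <= x <= hi`. Idempotent for `shift = 0` and a fixed range.
#'
#' @param s a `spectrum`.
#' @param shift additive abscissa shift (eV).
#' @param range optional `c(lo, hi)` closed window applied after the shift.
#' @return the filtered `spectrum`.
#' @export
preprocess <- function(s, shift = 0, range = NULL) {
  stopifnot(inherits(s, "spectrum"))
  x <- s$x + shift
  keep <- rep(TRUE, length(x))
  if (!is.null(range)) {
    range <- as.numeric(range)
    if (length(range) != 2L || range[1] >= range[2]) {
      stop_invalid("range must be c(lo, hi) with lo < hi")
    }
    keep <- x >= range[1] & x <= range[2]
    if (!any(keep)) stop_invalid("no points remain after range filtering")
  }
  structure(list(x = x[keep], y = s$y[keep],
                 x_label = s$x_label, y_label = s$y_label),
            class = "spectrum")
}

#' Write a spectrum (or several intensity columns) as CSV
#'
#' Emits the exact dialect [read_spectrum()] ingests, for end-to-end runs.
#'
#' @param spectra a `spectrum` or list of spectra sharing a grid.
#' @param path output file.
#' @param x_label name of the abscissa column.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectra, path, x_label = NULL) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  x <- spectra[[1]]$x
  df <- data.frame(x = x, check.names = FALSE)
  names(df) <- x_label %||% spectra[[1]]$x_label
  for (s in spectra) {
    if (!isTRUE(all.equal(s$x, x))) stop_invalid("spectra do not share a grid")
    df[[s$y_label]] <- s$y
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
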