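# Result persistence: CSV + JSON outputs and the tamper-evident single-file
# TOML lock report. The lock ID is a SHA-256 over a canonical rendering
# (sorted keys, floats at 17 significant digits) of every field except the
# ID itself and the timestamp, so re-exports of identical science carry
# identical IDs and any byte change to the content changes the ID.

LOCK_SCHEMA_VERSION <- "1.0"

# canonical, serialization-stable rendering of a nested list
canonical_render <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    nm <- names(x)
    if (is.null(nm)) {
      inner <- vapply(x, canonical_render, "")
      return(paste0("[", paste(inner, collapse = ","), "]"))
    }
    o <- order(nm)
    inner <- vapply(o, function(i) {
      paste0("\"", toml_escape(nm[i]), "\":", canonical_render(x[[i]]))
    }, "")
    return(paste0("{", paste(inner, collapse = ","), "}"))
  }
  if (is.character(x)) {
    s <- paste0("\"", vapply(x, toml_escape, ""), "\"")
  } else if (is.logical(x)) {
    s <- ifelse(x, "true", "false")
  } else if (is.numeric(x)) {
    s <- vapply(as.numeric(x), function(v) {
      if (is.na(v)) "nan" else if (v == Inf) "inf" else if (v == -Inf) "-inf"
      else sprintf("%.17g", v)
    }, "")
  } else {
    stop_invalid("cannot canonicalize value of class %s", class(x)[1])
  }
  if (length(s) == 1L) s else paste0("[", paste(s, collapse = ","), "]")
}

lock_id <- function(content) {
  content$id <- NULL
  content$timestamp <- NULL
  digest::digest(canonical_render(content), algo = "sha256", serialize = FALSE)
}

params_record <- function(ps) {
  lapply(seq_len(nrow(ps)), function(i) {
    rec <- list(name = ps$name[i], value = ps$value[i],
                min = ps$min[i], max = ps$max[i], vary = ps$vary[i])
    if (!is.na(ps$expr[i])) rec$expr <- ps$expr[i]
    if (!is.na(ps$stderr[i])) rec$stderr <- ps$stderr[i]
    rec
  })
}

components_record <- function(components) {
  lapply(components, function(co) {
    list(index = co$index, kind = co$kind,
         attributes = lapply(co$attributes, function(a) {
           a[!vapply(a, is.null, TRUE)]
         }))
  })
}

correlation_record <- function(cm) {
  list(labels = colnames(cm),
       rows = lapply(seq_len(nrow(cm)), function(i) as.numeric(cm[i, ])))
}

#' Write the standard CSV/JSON output set of a fit
#'
#' Emits `<basename>_fit.csv` (abscissa, data, fit, each component,
#' residual), `<basename>_errors.csv` (parameter values and standard
#' errors), `<basename>_correlation.csv` (overall Pearson matrix) and
#' `<basename>.json` holding the entire fitting record: user input,
#' fit statistics and fit results.
#'
#' @param result a `fit_result`.
#' @param s the fitted `spectrum`.
#' @param project the `fit_project` that produced the fit.
#' @param basename output path prefix.
#' @return character vector of the four file paths, invisibly.
#' @export
write_outputs <- function(result, s, project, basename) {
  stopifnot(inherits(result, "fit_result"), inherits(s, "spectrum"))
  fit_df <- data.frame(x = s$x, data = s$y, fit = result$model_curve,
                       check.names = FALSE)
  for (nm in names(result$components)) fit_df[[nm]] <- result$components[[nm]]
  fit_df$residual <- result$residual
  names(fit_df)[1] <- s$x_label
  ps <- result$params
  err_df <- data.frame(name = ps$name, value = ps$value, stderr = ps$stderr,
                       rel_err = abs(ps$stderr / ps$value), vary = ps$vary,
                       expr = ifelse(is.na(ps$expr), "", ps$expr))
  tables <- report_tables(result, s)
  cm <- as.data.frame(unclass(tables$overall_correlation))
  cm <- cbind(series = rownames(cm), cm)
  paths <- paste0(basename, c("_fit.csv", "_errors.csv", "_correlation.csv", ".json"))
  tryCatch({
    utils::write.csv(fit_df, paths[1], row.names = FALSE)
    utils::write.csv(err_df, paths[2], row.names = FALSE)
    utils::write.csv(cm, paths[3], row.names = FALSE)
    jsonlite::write_json(fit_record(project, list(s), result),
                         paths[4], auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }, error = function(e) {
    stop(errorCondition(sprintf("cannot write outputs at '%s': %s",
                                basename, conditionMessage(e)),
                        class = c("peakfitr_io_error", "error")))
  })
  invisible(paths)
}

# the single nested record shared by the JSON export and the lock file
fit_record <- function(project, spectra, result) {
  gof <- result$gof
  list(
    schema_version = LOCK_SCHEMA_VERSION,
    input = list(settings = project$settings,
                 description = project$description,
                 components = components_record(project$components)),
    data = lapply(spectra, function(s) {
      list(x_label = s$x_label, y_label = s$y_label,
           x = as.numeric(s$x), y = as.numeric(s$y))
    }),
    results = list(
      parameters = params_record(result$params),
      goodness_of_fit = list(chi2 = gof$chi2, red_chi2 = gof$red_chi2,
                             aic = gof$aic, bic = gof$bic,
                             N = gof$N, k = gof$k),
      regression = regression_metrics(result$model_curve + result$residual,
                                      result$model_curve),
      success = result$success))
}

#' Write the tamper-evident lock report
#'
#' A single TOML document (conventionally suffixed `.lock`) recording the
#' input echo, the data, and the results, stamped with a unique content ID:
#' a SHA-256 over the canonical form of all fields except the ID and
#' timestamp. Identical science re-exported yields the identical ID; any
#' value change yields a different one.
#'
#' @param project the `fit_project`.
#' @param spectra list of fitted `spectrum` objects (or a single one).
#' @param result the `fit_result`.
#' @param path output path (a `.lock` suffix is appended when absent).
#' @return the lock record (list, including `id`), invisibly.
#' @export
write_lock <- function(project, spectra, result, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  if (!grepl("\\.lock$", path)) path <- paste0(path, ".lock")
  content <- fit_record(project, spectra, result)
  content$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  content$id <- lock_id(content)
  txt <- toml_write(content)
  ok <- tryCatch({ writeLines(txt, path, sep = ""); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) {
    stop(errorCondition(sprintf("cannot write lock file '%s': %s", path,
                                conditionMessage(ok)),
                        class = c("peakfitr_io_error", "error")))
  }
  invisible(content)
}

#' Verify a lock report's content ID
#'
#' Re-parses the TOML document, recomputes the content hash over the
#' canonical form (which is independent of key order and whitespace) and
#' compares it with the stored ID. A file that does not parse raises a
#' parse error, which is distinct from a verification failure.
#'
#' @param path path to a `.lock` file.
#' @return list with `valid`, `recomputed_id`, `stored_id`.
#' @export
verify_lock <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("lock file not found: %s", path),
                        class = c("peakfitr_io_error", "error")))
  }
  content <- toml_read(paste(readLines(path, warn = FALSE), collapse = "\n"))
  stored <- content$id
  if (is.null(stored)) stop_parse("lock file has no id field")
  recomputed <- lock_id(content)
  list(valid = identical(recomputed, stored),
       recomputed_id = recomputed, stored_id = stored)
}
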