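# Flat named-parameter registry. A parameter_set is a data.frame with one
# row per parameter: name, value, min, max, vary, expr, stderr. Parameters
# carrying an expression are never free: their value is recomputed from the
# expression in dependency order.

EXPR_FUNS <- c("sin", "cos", "exp", "log", "sqrt", "abs")
EXPR_OPS <- c("+", "-", "*", "/", "^", "(")

stop_expr <- function(...) {
  stop(errorCondition(sprintf(...), class = c("peakfitr_expression_error", "error")))
}

#' Construct a parameter set
#'
#' @param name character vector of unique parameter names.
#' @param value,min,max numeric vectors (recycled); defaults 1, -Inf, Inf.
#' @param vary logical vector; forced to `FALSE` wherever `expr` is set.
#' @param expr character vector of constraint expressions (`NA` for none).
#' @return a `parameter_set` data.frame.
#' @export
parameter_set <- function(name, value = 1, min = -Inf, max = Inf,
                          vary = TRUE, expr = NA_character_) {
  if (anyDuplicated(name)) {
    stop_invalid("duplicate parameter names: %s",
                 paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  ps <- data.frame(name = as.character(name), value = as.numeric(value),
                   min = as.numeric(min), max = as.numeric(max),
                   vary = as.logical(vary), expr = as.character(expr),
                   stderr = NA_real_, stringsAsFactors = FALSE)
  ps$vary[!is.na(ps$expr)] <- FALSE
  bad <- !is.na(ps$value) & (ps$value < ps$min | ps$value > ps$max)
  if (any(bad)) {
    stop_invalid("parameter value outside [min, max] for: %s",
                 paste(ps$name[bad], collapse = ", "))
  }
  class(ps) <- c("parameter_set", "data.frame")
  ps
}

#' Build the parameter set implied by a component list
#'
#' One parameter per (component, attribute), named
#' `<kind>_<attribute>_<index>` (e.g. `gaussian_amplitude_1`), in component
#' order.
#'
#' @param components list of component specs as produced by
#'   [parse_input()]: each has `index`, `kind` and `attributes` (a named
#'   list of `{min, max, vary, value, expr}` lists).
#' @return a `parameter_set`.
#' @export
build_names <- function(components) {
  if (!length(components)) stop_invalid("component list is empty")
  idx <- vapply(components, function(co) co$index, "")
  if (anyDuplicated(idx)) {
    stop_invalid("duplicate component indices: %s",
                 paste(unique(idx[duplicated(idx)]), collapse = ", "))
  }
  rows <- lapply(components, function(co) {
    attrs <- co$attributes
    nm <- sprintf("%s_%s_%s", co$kind, names(attrs), co$index)
    data.frame(
      name = nm,
      value = mapply(function(a, an) a$value %||% default_attr_value(an),
                     attrs, names(attrs)),
      min = vapply(attrs, function(a) a$min %||% -Inf, 0),
      max = vapply(attrs, function(a) a$max %||% Inf, 0),
      vary = vapply(attrs, function(a) isTRUE(a$vary %||% TRUE), TRUE),
      expr = vapply(attrs, function(a) a$expr %||% NA_character_, ""),
      stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  parameter_set(rows$name, rows$value, rows$min, rows$max, rows$vary, rows$expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_attr_value <- function(attr) {
  if (is.null(attr)) return(1)
  switch(attr, amplitude = 1, center = 0, fraction = 0.5,
         intercept = 0, slope = 0, 1)
}

# --- expression engine ------------------------------------------------------

# validate the AST of a constraint expression: arithmetic operators, the
# whitelisted elementary functions, numeric literals and bare parameter
# names only. Anything else (calls, indexing, assignment, `::`) is refused.
check_expr_ast <- function(e, expr_string) {
  if (is.numeric(e) || is.integer(e)) return(invisible(character(0)))
  if (is.name(e)) return(invisible(as.character(e)))
  if (is.call(e)) {
    head <- e[[1]]
    if (!is.name(head)) {
      stop_expr("disallowed construct in expression '%s'", expr_string)
    }
    fn <- as.character(head)
    if (!(fn %in% c(EXPR_OPS, EXPR_FUNS))) {
      stop_expr("disallowed function or operator '%s' in expression '%s'",
                fn, expr_string)
    }
    syms <- character(0)
    for (i in seq_along(e)[-1]) {
      syms <- c(syms, check_expr_ast(e[[i]], expr_string))
    }
    return(invisible(syms))
  }
  stop_expr("disallowed construct in expression '%s'", expr_string)
}

parse_constraint <- function(expr_string) {
  # accept python-style "**" for exponentiation
  txt <- gsub("**", "^", expr_string, fixed = TRUE)
  e <- tryCatch(str2lang(txt),
                error = function(err) stop_expr("cannot parse expression '%s': %s",
                                                expr_string, conditionMessage(err)))
  syms <- check_expr_ast(e, expr_string)
  list(lang = e, deps = unique(syms))
}

expr_dependencies <- function(ps) {
  deps <- vector("list", nrow(ps))
  names(deps) <- ps$name
  for (i in which(!is.na(ps$expr))) {
    pc <- parse_constraint(ps$expr[i])
    unknown <- setdiff(pc$deps, ps$name)
    if (length(unknown)) {
      stop_expr("expression for '%s' references unknown parameter(s): %s",
                ps$name[i], paste(unknown, collapse = ", "))
    }
    deps[[i]] <- pc$deps
  }
  deps
}

# Kahn topological sort over expression-bound parameters, registry order as
# tie-break; reports the offending cycle on failure.
expr_order <- function(ps, deps) {
  bound <- ps$name[!is.na(ps$expr)]
  remaining <- bound
  resolved <- ps$name[is.na(ps$expr)]
  ordering <- character(0)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nm) {
      all(deps[[nm]] %in% c(resolved, ordering))
    }, TRUE)]
    if (!length(ready)) {
      stop_expr("cyclic parameter expressions involving: %s",
                paste(remaining, collapse = " -> "))
    }
    ordering <- c(ordering, ready[1])
    remaining <- setdiff(remaining, ready[1])
  }
  ordering
}

#' Resolve constraint expressions in a parameter set
#'
#' Expression-bound parameters are recomputed from their expressions in
#' topological dependency order; free parameters are untouched. Applying
#' the function twice is a no-op.
#'
#' @param ps a `parameter_set`.
#' @return the `parameter_set` with expression-bound values updated.
#' @export
resolve_expressions <- function(ps) {
  if (!any(!is.na(ps$expr))) return(ps)
  deps <- expr_dependencies(ps)
  ordering <- expr_order(ps, deps)
  env <- new.env(parent = emptyenv())
  for (fn in EXPR_FUNS) assign(fn, get(fn, baseenv()), envir = env)
  for (op in EXPR_OPS[EXPR_OPS != "("]) assign(op, get(op, baseenv()), envir = env)
  assign("(", get("(", baseenv()), envir = env)
  for (i in seq_len(nrow(ps))) assign(ps$name[i], ps$value[i], envir = env)
  for (nm in ordering) {
    i <- match(nm, ps$name)
    val <- eval(parse_constraint(ps$expr[i])$lang, envir = env)
    if (!is.numeric(val) || length(val) != 1L) {
      stop_expr("expression for '%s' did not evaluate to a scalar", nm)
    }
    ps$value[i] <- as.numeric(val)
    assign(nm, ps$value[i], envir = env)
  }
  ps
}

#' Names of the free (optimized) parameters
#'
#' Free means `vary = TRUE` and no constraint expression, in registry
#' order. This is the `k` entering AIC/BIC and the covariance dimension.
#'
#' @param ps a `parameter_set`.
#' @return character vector (possibly empty).
#' @export
free_parameters <- function(ps) ps$name[ps$vary & is.na(ps$expr)]

#' Read parameter values as a named vector
#' @param ps a `parameter_set`.
#' @return named numeric vector.
#' @export
param_values <- function(ps) stats::setNames(ps$value, ps$name)

# replace the values of the named free parameters, then re-resolve
set_free_values <- function(ps, values) {
  i <- match(names(values), ps$name)
  ps$value[i] <- as.numeric(values)
  resolve_expressions(ps)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set: %d parameters, %d free>\n",
              nrow(x), length(free_parameters(x))))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}
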