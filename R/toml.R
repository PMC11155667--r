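# Minimal TOML subset: enough to express model files and lock reports.
# Supported: [table] and [[array-of-tables]] headers with dotted keys,
# bare or double-quoted keys, values that are strings, numbers (incl. inf,
# -inf, nan), booleans, and single-line (possibly nested) arrays.
# Deliberately not supported: dates, multi-line strings, inline tables.

stop_parse <- function(...) {
  stop(errorCondition(sprintf(...), class = c("peakfitr_parse_error", "error")))
}

toml_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  s
}

toml_unescape <- function(s) {
  out <- character(length(s))
  for (k in seq_along(s)) {
    chars <- strsplit(s[k], "", fixed = TRUE)[[1]]
    buf <- character(0)
    i <- 1
    while (i <= length(chars)) {
      ch <- chars[i]
      if (ch == "\\" && i < length(chars)) {
        nxt <- chars[i + 1]
        buf <- c(buf, switch(nxt, n = "\n", t = "\t", "\"" = "\"", "\\" = "\\",
                             stop_parse("unsupported escape \\%s", nxt)))
        i <- i + 2
      } else {
        buf <- c(buf, ch)
        i <- i + 1
      }
    }
    out[k] <- paste(buf, collapse = "")
  }
  out
}

toml_format_number <- function(x) {
  if (is.na(x)) return("nan")
  if (x == Inf) return("inf")
  if (x == -Inf) return("-inf")
  if (is.integer(x) || (is.finite(x) && x == round(x) && abs(x) < 2^53)) {
    # integral values still rendered as floats when the input is double,
    # so that read->write round-trips preserve type
    if (is.integer(x)) return(sprintf("%d", x))
    return(sprintf("%.1f", x))
  }
  sprintf("%.17g", x)
}

toml_format_value <- function(v) {
  if (is.list(v)) {
    inner <- vapply(v, toml_format_value, "")
    return(paste0("[", paste(inner, collapse = ", "), "]"))
  }
  if (is.character(v)) {
    if (length(v) == 1L) return(paste0("\"", toml_escape(v), "\""))
    return(paste0("[", paste0("\"", toml_escape(v), "\"", collapse = ", "), "]"))
  }
  if (is.logical(v)) {
    s <- ifelse(v, "true", "false")
    if (length(v) == 1L) return(s)
    return(paste0("[", paste(s, collapse = ", "), "]"))
  }
  if (is.numeric(v)) {
    s <- vapply(v, toml_format_number, "")
    if (length(v) == 1L) return(s)
    return(paste0("[", paste(s, collapse = ", "), "]"))
  }
  stop_invalid("cannot serialize value of class %s to TOML", class(v)[1])
}

toml_format_key <- function(k) {
  if (grepl("^[A-Za-z0-9_-]+$", k)) k else paste0("\"", toml_escape(k), "\"")
}

is_plain_table <- function(v) is.list(v) && !is.null(names(v)) && length(v) > 0
is_table_array <- function(v) {
  is.list(v) && is.null(names(v)) && length(v) > 0 &&
    all(vapply(v, is_plain_table, TRUE))
}

toml_render <- function(x, prefix = character(0)) {
  stopifnot(is.list(x))
  lines <- character(0)
  nm <- names(x)
  scalar_keys <- nm[!vapply(x, function(v) is_plain_table(v) || is_table_array(v), TRUE)]
  for (k in scalar_keys) {
    v <- x[[k]]
    if (is.null(v)) next
    lines <- c(lines, paste0(toml_format_key(k), " = ", toml_format_value(v)))
  }
  for (k in nm[vapply(x, is_plain_table, TRUE)]) {
    path <- c(prefix, k)
    header <- paste0("[", paste(vapply(path, toml_format_key, ""), collapse = "."), "]")
    lines <- c(lines, "", header, toml_render(x[[k]], path))
  }
  for (k in nm[vapply(x, is_table_array, TRUE)]) {
    path <- c(prefix, k)
    header <- paste0("[[", paste(vapply(path, toml_format_key, ""), collapse = "."), "]]")
    for (el in x[[k]]) lines <- c(lines, "", header, toml_render(el, path))
  }
  lines
}

#' Serialize a nested list to a TOML string
#'
#' @param x named list; unnamed lists of named lists become arrays of
#'   tables, atomic vectors become inline arrays.
#' @return a single TOML character string.
#' @export
toml_write <- function(x) paste0(paste(toml_render(x), collapse = "\n"), "\n")

# --- parsing ---------------------------------------------------------------

# split a TOML value string into top-level array elements
split_array_elems <- function(body, lineno) {
  elems <- character(0)
  depth <- 0; in_str <- FALSE; buf <- ""
  chars <- strsplit(body, "", fixed = TRUE)[[1]]
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (in_str) {
      buf <- paste0(buf, ch)
      if (ch == "\\") { buf <- paste0(buf, chars[i + 1]); i <- i + 1 }
      else if (ch == "\"") in_str <- FALSE
    } else if (ch == "\"") { buf <- paste0(buf, ch); in_str <- TRUE }
    else if (ch == "[") { depth <- depth + 1; buf <- paste0(buf, ch) }
    else if (ch == "]") { depth <- depth - 1; buf <- paste0(buf, ch) }
    else if (ch == "," && depth == 0) { elems <- c(elems, buf); buf <- "" }
    else buf <- paste0(buf, ch)
    i <- i + 1
  }
  if (in_str || depth != 0) stop_parse("unterminated array or string on line %d", lineno)
  if (nzchar(trimws(buf))) elems <- c(elems, buf)
  trimws(elems)
}

toml_parse_value <- function(s, lineno) {
  s <- trimws(s)
  if (!nzchar(s)) stop_parse("empty value on line %d", lineno)
  if (startsWith(s, "\"")) {
    if (!grepl('^"(\\\\.|[^"\\\\])*"$', s)) {
      stop_parse("malformed string on line %d", lineno)
    }
    return(toml_unescape(substr(s, 2, nchar(s) - 1)))
  }
  if (startsWith(s, "[")) {
    if (!endsWith(s, "]")) stop_parse("unterminated array on line %d", lineno)
    body <- substr(s, 2, nchar(s) - 1)
    if (!nzchar(trimws(body))) return(list())
    vals <- lapply(split_array_elems(body, lineno), toml_parse_value, lineno = lineno)
    if (all(vapply(vals, function(v) is.numeric(v) && length(v) == 1L, TRUE))) {
      return(unlist(vals))
    }
    if (all(vapply(vals, function(v) is.character(v) && length(v) == 1L, TRUE))) {
      return(unlist(vals))
    }
    if (all(vapply(vals, function(v) is.logical(v) && length(v) == 1L, TRUE))) {
      return(unlist(vals))
    }
    return(vals)
  }
  if (s == "true") return(TRUE)
  if (s == "false") return(FALSE)
  if (s %in% c("inf", "+inf")) return(Inf)
  if (s == "-inf") return(-Inf)
  if (s %in% c("nan", "+nan", "-nan")) return(NaN)
  num <- suppressWarnings(as.numeric(gsub("_", "", s)))
  if (!is.na(num)) {
    if (grepl("^[+-]?[0-9_]+$", s)) {
      return(if (abs(num) <= .Machine$integer.max) as.integer(num) else num)
    }
    return(num)
  }
  stop_parse("cannot parse value '%s' on line %d", s, lineno)
}

# split a dotted key path honoring quoted segments
toml_split_key <- function(s, lineno) {
  parts <- character(0); buf <- ""; in_str <- FALSE
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (in_str) {
      if (ch == "\\") { buf <- paste0(buf, chars[i + 1]); i <- i + 1 }
      else if (ch == "\"") in_str <- FALSE
      else buf <- paste0(buf, ch)
    } else if (ch == "\"") in_str <- TRUE
    else if (ch == ".") { parts <- c(parts, trimws(buf)); buf <- "" }
    else buf <- paste0(buf, ch)
    i <- i + 1
  }
  if (in_str) stop_parse("unterminated quoted key on line %d", lineno)
  parts <- c(parts, trimws(buf))
  if (any(!nzchar(parts))) stop_parse("empty key segment on line %d", lineno)
  toml_unescape(parts)
}

# strip a trailing comment not inside a string
strip_comment <- function(line) {
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  in_str <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_str) {
      if (ch == "\\") in_str <- in_str  # escape consumed below
      if (ch == "\"" && chars[max(1, i - 1)] != "\\") in_str <- FALSE
    } else if (ch == "\"") in_str <- TRUE
    else if (ch == "#") return(substr(line, 1, i - 1))
  }
  line
}

assign_path <- function(doc, path, value, lineno) {
  if (length(path) == 1L) {
    if (!is.null(doc[[path]])) stop_parse("duplicate key '%s' on line %d", path, lineno)
    doc[[path]] <- value
    return(doc)
  }
  head <- path[1]
  sub <- doc[[head]]
  if (is.null(sub)) sub <- list()
  if (!is.list(sub) || is.null(names(sub)) && length(sub)) {
    stop_parse("key '%s' redefined as table on line %d", head, lineno)
  }
  doc[[head]] <- assign_path(sub, path[-1], value, lineno)
  doc
}

#' Parse a TOML string into a nested list
#'
#' @param text TOML document as a single string or character vector of
#'   lines.
#' @return named list; arrays of tables become unnamed lists.
#' @export
toml_read <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  doc <- list()
  ctx_path <- character(0)   # current [table] path
  ctx_array <- FALSE
  pending <- list()          # key/value pairs of the current table
  flush <- function(doc) {
    if (!length(ctx_path)) {
      for (k in names(pending)) doc <- assign_path(doc, k, pending[[k]], 0)
      return(doc)
    }
    node <- doc
    # walk/create the table path
    set_at <- function(lst, path, fn) {
      if (!length(path)) return(fn(lst))
      h <- path[1]
      cur <- lst[[h]]
      if (is.null(cur)) cur <- list()
      if (is_table_array(cur)) {
        cur[[length(cur)]] <- set_at(cur[[length(cur)]], path[-1], fn)
      } else {
        cur <- set_at(cur, path[-1], fn)
      }
      lst[[h]] <- cur
      lst
    }
    if (ctx_array) {
      doc <- set_at(doc, ctx_path[-length(ctx_path)], function(parent) {
        k <- ctx_path[length(ctx_path)]
        arr <- parent[[k]]
        if (is.null(arr)) arr <- list()
        arr[[length(arr) + 1]] <- pending
        parent[k] <- list(arr)
        parent
      })
    } else {
      doc <- set_at(doc, ctx_path, function(tbl) {
        for (k in names(pending)) tbl[[k]] <- pending[[k]]
        tbl
      })
    }
    doc
  }
  for (i in seq_along(lines)) {
    line <- trimws(strip_comment(lines[i]))
    if (!nzchar(line)) next
    if (grepl("^\\[\\[.*\\]\\]$", line)) {
      doc <- flush(doc)
      ctx_path <- toml_split_key(substr(line, 3, nchar(line) - 2), i)
      ctx_array <- TRUE
      pending <- list()
    } else if (grepl("^\\[.*\\]$", line)) {
      doc <- flush(doc)
      ctx_path <- toml_split_key(substr(line, 2, nchar(line) - 1), i)
      ctx_array <- FALSE
      pending <- list()
    } else {
      eq <- regexpr("=", line, fixed = TRUE)
      if (eq < 0) stop_parse("expected 'key = value' on line %d: %s", i, line)
      key <- toml_split_key(trimws(substr(line, 1, eq - 1)), i)
      val <- toml_parse_value(substr(line, eq + 1, nchar(line)), i)
      if (length(key) == 1L) {
        if (!is.null(pending[[key]])) stop_parse("duplicate key '%s' on line %d", key, i)
        pending[[key]] <- val
      } else {
        pending <- assign_path(pending, key, val, i)
      }
    }
  }
  flush(doc)
}
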