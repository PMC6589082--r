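#' Parameter value expressions
#'
#' Template parameters are usually hard-coded values (numbers, quoted
#' strings), but they can also reference variables bound by already-matched
#' patterns (`%name.field%`), pull subpatterns from a list file (`f"path"`),
#' or select a single entry from a list file (`f"path"[selector]`, the
#' selection operator).  `value_expr()` constructs such an expression;
#' [resolve_value()] evaluates it against a variable store.
#'
#' @param kind One of `"literal"`, `"variable_ref"`, `"file_ref"`,
#'   `"file_ref_selected"`.
#' @param payload The literal value, the `name.field` string of a variable
#'   reference, or the list-file path.
#' @param selector For `file_ref_selected`, another `value_expr` (an integer
#'   literal or a variable reference) giving the 0-based entry index.
#' @return An object of class `value_expr`.
#' @export
value_expr <- function(kind, payload, selector = NULL) {
  kind <- match.arg(kind,
                    c("literal", "variable_ref", "file_ref", "file_ref_selected"))
  if (kind == "variable_ref") {
    parts <- strsplit(payload, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("variable reference must be of the form %name.field%, got %",
           payload, "%", call. = FALSE)
    }
  }
  if (kind == "file_ref_selected" && is.null(selector)) {
    stop("file_ref_selected needs a selector", call. = FALSE)
  }
  structure(list(kind = kind, payload = payload, selector = selector),
            class = "value_expr")
}

is_value_expr <- function(x) inherits(x, "value_expr")

# Parse one parameter value token from the template DSL.  Accepted forms:
#   123                integer literal
#   "text"             string literal
#   f"path"            list-file reference
#   f"path"[sel]       selection operator; sel is an integer or %var.field%
#   %name.field%       variable reference
#   bareword           keyword literal (auto, none, levenshtein, ...)
parse_value <- function(token) {
  token <- trimws(token)
  if (grepl("^-?[0-9]+$", token)) {
    return(value_expr("literal", as.integer(token)))
  }
  if (grepl('^"[^"]*"$', token)) {
    return(value_expr("literal", substr(token, 2L, nchar(token) - 1L)))
  }
  m <- regmatches(token, regexec('^f"([^"]+)"$', token))[[1]]
  if (length(m) == 2L) {
    return(value_expr("file_ref", m[2]))
  }
  m <- regmatches(token, regexec('^f"([^"]+)"\\[(.+)\\]$', token))[[1]]
  if (length(m) == 3L) {
    sel <- parse_value(m[3])
    if (!(sel$kind %in% c("literal", "variable_ref")) ||
        (sel$kind == "literal" && !is.numeric(sel$payload))) {
      stop("selection operator takes an integer or a variable reference: ",
           token, call. = FALSE)
    }
    return(value_expr("file_ref_selected", m[2], selector = sel))
  }
  m <- regmatches(token, regexec("^%([^%]+)%$", token))[[1]]
  if (length(m) == 2L) {
    return(value_expr("variable_ref", m[2]))
  }
  if (grepl("^[A-Za-z_][A-Za-z0-9_]*$", token)) {
    return(value_expr("literal", token))
  }
  stop("malformed parameter value: ", token, call. = FALSE)
}

#' Resolve a value expression
#'
#' Evaluates a [value_expr()] against a [var_store()] (and a list-file
#' cache).  A literal resolves to itself; `%name.field%` to the stored
#' statistic; `f"path"` to the full subpattern list of the file;
#' `f"path"[sel]` to a single-entry subpattern list at the resolved 0-based
#' selector index.
#'
#' @param expr A `value_expr`, or a plain literal (returned unchanged).
#' @param vars A [var_store()] used for variable references.
#' @param lists An environment caching loaded list files keyed by path (one
#'   is created on the fly when omitted).
#' @param base_dir Directory against which relative list-file paths are
#'   resolved.
#' @return The literal, the stored statistic, or a subpattern list
#'   (data frame, see [load_list_file()]).
#' @examples
#' vars <- var_store()
#' bind_variables("b", list(length = 8L, pattern_idx = 3L,
#'                          pattern_name = "BC04", edits = 1L), vars)
#' resolve_value(value_expr("variable_ref", "b.length"), vars)
#' @export
resolve_value <- function(expr, vars = NULL, lists = NULL, base_dir = ".") {
  if (!is_value_expr(expr)) return(expr)
  switch(expr$kind,
    literal = expr$payload,
    variable_ref = {
      parts <- strsplit(expr$payload, ".", fixed = TRUE)[[1]]
      var_get(vars, parts[1], parts[2])
    },
    file_ref = load_list_file_cached(expr$payload, lists, base_dir),
    file_ref_selected = {
      lst <- load_list_file_cached(expr$payload, lists, base_dir)
      sel <- resolve_value(expr$selector, vars, lists, base_dir)
      sel <- as.integer(sel)
      if (is.na(sel) || sel < 0L || sel >= nrow(lst)) {
        stop("selector ", sel, " out of range for list file '", expr$payload,
             "' (", nrow(lst), " entries)", call. = FALSE)
      }
      lst[sel + 1L, , drop = FALSE]
    })
}

# Serialize a value expression back to DSL syntax.
format_value <- function(x) {
  if (!is_value_expr(x)) {
    if (is.numeric(x)) return(as.character(x))
    return(paste0('"', x, '"'))
  }
  switch(x$kind,
    literal = if (is.numeric(x$payload)) as.character(x$payload)
              else paste0('"', x$payload, '"'),
    variable_ref = paste0("%", x$payload, "%"),
    file_ref = paste0('f"', x$payload, '"'),
    file_ref_selected = paste0('f"', x$payload, '"[',
                               format_value(x$selector), "]"))
}

#' @export
print.value_expr <- function(x, ...) {
  cat("<value_expr ", x$kind, ": ", format_value(x), ">\n", sep = "")
  invisible(x)
}
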