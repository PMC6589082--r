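#' Variable stores
#'
#' Named patterns bind match statistics -- `length`, `pattern_idx`,
#' `pattern_name`, `edits` -- that later patterns (on the same template line
#' or on lines with a later processing order) and output path templates can
#' reference as `%name.field%`.  A store lives for one record; a name is
#' bound at most once per record.
#'
#' @return `var_store()` returns an empty store (class `var_store`).
#' @examples
#' vars <- var_store()
#' bind_variables("b", list(length = 8L, pattern_idx = 3L,
#'                          pattern_name = "BC04", edits = 1L), vars)
#' var_get(vars, "b", "pattern_name")
#' @export
var_store <- function() {
  structure(new.env(parent = emptyenv()), class = "var_store")
}

VAR_FIELDS <- c("length", "pattern_idx", "pattern_name", "edits")

#' @rdname var_store
#' @param name Variable name (the pattern's `name` parameter).
#' @param match A list with any of the fields `length`, `pattern_idx`,
#'   `pattern_name`, `edits`; missing fields are stored as `NA`.  A match row
#'   as returned by the searchers (with columns of the same names) is also
#'   accepted.
#' @param vars The store to bind into.
#' @return `bind_variables()` returns the store, invisibly.  Rebinding an
#'   existing name is an error.
#' @export
bind_variables <- function(name, match, vars) {
  stopifnot(inherits(vars, "var_store"), is.character(name), nzchar(name))
  if (exists(name, envir = vars, inherits = FALSE)) {
    stop("variable '", name, "' is already bound in this record",
         call. = FALSE)
  }
  match <- as.list(match)
  stats <- lapply(VAR_FIELDS, function(f) {
    if (is.null(match[[f]])) NA else match[[f]][[1]]
  })
  names(stats) <- VAR_FIELDS
  assign(name, stats, envir = vars)
  invisible(vars)
}

#' @rdname var_store
#' @param field One of `"length"`, `"pattern_idx"`, `"pattern_name"`,
#'   `"edits"`.
#' @param overlay Optional named list of not-yet-committed bindings searched
#'   before the store (used while a line is being matched).
#' @return `var_get()` returns the stored statistic; unknown variables or
#'   fields are errors.
#' @export
var_get <- function(vars, name, field, overlay = NULL) {
  if (!field %in% VAR_FIELDS) {
    stop("unknown variable field '", field, "' (available: ",
         paste(VAR_FIELDS, collapse = ", "), ")", call. = FALSE)
  }
  if (!is.null(overlay) && !is.null(overlay[[name]])) {
    return(overlay[[name]][[field]])
  }
  if (!is.null(vars) && exists(name, envir = vars, inherits = FALSE)) {
    return(get(name, envir = vars, inherits = FALSE)[[field]])
  }
  avail <- c(names(overlay), if (!is.null(vars)) ls(vars))
  stop("unknown variable '", name, "'",
       if (length(avail)) paste0(" (available: ",
                                 paste(sort(unique(avail)), collapse = ", "),
                                 ")") else " (no variables bound)",
       call. = FALSE)
}

#' @rdname var_store
#' @export
var_names <- function(vars) sort(ls(vars))

#' @export
print.var_store <- function(x, ...) {
  nm <- var_names(x)
  cat("<var_store: ", length(nm), " binding(s)>\n", sep = "")
  for (n in nm) {
    s <- get(n, envir = x, inherits = FALSE)
    cat("  ", n, ": length=", s$length, " pattern_idx=", s$pattern_idx,
        " pattern_name=", s$pattern_name, " edits=", s$edits, "\n", sep = "")
  }
  invisible(x)
}
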