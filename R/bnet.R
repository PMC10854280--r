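#' Read a Boolean network from a rule file
#'
#' The text format has one line per variable, `"target, expression"`, with
#' the operators `!`, `&`, `|`, parentheses and the constants `0`/`1`.
#' Lines starting with `#` (and a `targets, factors` header line, if
#' present) are ignored.  Names that appear only on the right-hand side are
#' collected as external parameters.
#'
#' @param path path to a rule file, or a character vector of lines via
#'   `text`.
#' @param text optional character vector of rule lines (used instead of
#'   `path`).
#' @return a `BooleanNetwork`.
#' @seealso [write_bnet()]
#' @export
read_bnet <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("either 'path' or 'text' must be given", call. = FALSE)
    if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
    text <- readLines(path, warn = FALSE)
  }
  targets <- character(0)
  exprs <- character(0)
  for (i in seq_along(text)) {
    line <- sub("#.*$", "", text[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^targets[[:space:]]*,[[:space:]]*factors$", line, ignore.case = TRUE)) next
    comma <- regexpr(",", line, fixed = TRUE)
    if (comma < 0L) {
      stop(sprintf("line %d: expected 'target, expression'", i), call. = FALSE)
    }
    target <- trimws(substr(line, 1L, comma - 1L))
    rhs <- trimws(substr(line, comma + 1L, nchar(line)))
    if (!grepl("^[A-Za-z_.][A-Za-z0-9_.]*$", target)) {
      stop(sprintf("line %d: invalid target name '%s'", i, target), call. = FALSE)
    }
    if (target %in% targets) {
      stop(sprintf("line %d: duplicate target '%s'", i, target), call. = FALSE)
    }
    if (!nzchar(rhs)) {
      stop(sprintf("line %d: empty expression", i), call. = FALSE)
    }
    ok <- tryCatch({ parse_rule_expression(rhs); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok)) {
      stop(sprintf("line %d: %s", i, conditionMessage(ok)), call. = FALSE)
    }
    targets <- c(targets, target)
    exprs <- c(exprs, rhs)
  }
  if (!length(targets)) stop("no rules found", call. = FALSE)
  network_from_rules(stats::setNames(exprs, targets))
}

#' Write a Boolean network as a rule file
#'
#' Each update function is serialised as a disjunction of the input
#' assignments with output 1 (or the constant `0`/`1`), so that reading
#' the file back reproduces the network truth-table exactly.
#'
#' @param network a `BooleanNetwork`.
#' @param path output file path; if `NULL` the lines are returned invisibly
#'   without writing.
#' @return invisibly, the character vector of lines.
#' @export
write_bnet <- function(network, path = NULL) {
  lines <- c("targets, factors",
             vapply(network$variables, function(v) {
               sprintf("%s, %s", v, bf_to_rule(network$functions[[v]]))
             }, character(1)))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# render a truth table as a DNF rule string (constants for constant tables)
bf_to_rule <- function(f) {
  if (is_constant_bf(f) || !length(f$inputs)) {
    return(as.character(f$table[1L]))
  }
  rows <- tt_rows(length(f$inputs))
  on <- which(f$table == 1L)
  terms <- vapply(on, function(k) {
    lits <- ifelse(rows[k, ] == 1L, f$inputs, paste0("!", f$inputs))
    paste0("(", paste(lits, collapse = " & "), ")")
  }, character(1))
  paste(terms, collapse = " | ")
}
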