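#' Construct a Boolean function from a truth table
#'
#' A `BooleanFunction` is an update rule over an ordered list of named
#' inputs, stored as a complete truth table with `2^m` entries (`m` = arity).
#' Row `k` of the table is the output for the assignment whose bits are the
#' binary digits of `k - 1`, first input most significant, so rows follow
#' the counting order `00..0, 00..1, ..., 11..1`.
#'
#' @param inputs character vector of input names (may be empty for a
#'   constant function).
#' @param table integer vector of `2^length(inputs)` outputs, each 0 or 1.
#' @return an object of class `BooleanFunction`.
#' @seealso [bf_from_expression()] to build one from a rule string.
#' @export
#' @examples
#' f <- boolean_function(c("x1", "x2"), c(0, 0, 0, 1)) # AND
#' eval_bf(f, c(x1 = 1, x2 = 1))
boolean_function <- function(inputs, table) {
  inputs <- as.character(inputs)
  if (anyDuplicated(inputs)) {
    stop("duplicate input names in Boolean function", call. = FALSE)
  }
  table <- check_binary(table, "truth table")
  if (length(table) != 2L^length(inputs)) {
    stop(sprintf("truth table has %d entries; expected %d for arity %d",
                 length(table), 2L^length(inputs), length(inputs)),
         call. = FALSE)
  }
  structure(list(inputs = inputs, table = table), class = "BooleanFunction")
}

#' Build a Boolean function from a rule expression
#'
#' Parses an expression in the rule grammar used by the package's text
#' format: variable names, the constants `0` and `1`, the operators `!`
#' (not), `&` (and), `|` (or), and parentheses.
#'
#' @param text a single rule string, e.g. `"x2 & !x3"`.
#' @param inputs optional character vector fixing the input order; defaults
#'   to the order of first appearance in `text`.  May list extra names,
#'   which become non-essential inputs.
#' @return a `BooleanFunction`.
#' @export
#' @examples
#' bf_from_expression("Ceramide | (Fas & !FLIP)")
bf_from_expression <- function(text, inputs = NULL) {
  expr <- parse_rule_expression(text)
  seen <- all.vars(expr)
  if (is.null(inputs)) {
    inputs <- seen
  } else {
    inputs <- as.character(inputs)
    missing <- setdiff(seen, inputs)
    if (length(missing)) {
      stop(sprintf("expression uses inputs not listed: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  m <- length(inputs)
  rows <- tt_rows(m)
  env <- new.env(parent = baseenv())
  for (j in seq_len(m)) assign(inputs[j], rows[, j], envir = env)
  val <- eval(expr, env)
  val <- as.integer(as.logical(val))
  if (length(val) == 1L) val <- rep(val, nrow(rows))
  boolean_function(inputs, val)
}

# validate + parse a rule string into an R expression; only the !, &, |
# operators, parentheses, names and the 0/1 constants are admitted
parse_rule_expression <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("rule must be a single character string", call. = FALSE)
  }
  leftover <- gsub("[A-Za-z_.][A-Za-z0-9_.]*", "", text)
  leftover <- gsub("[01!&|()[:space:]]", "", leftover)
  if (nzchar(leftover)) {
    stop(sprintf("invalid characters in rule: '%s'", leftover), call. = FALSE)
  }
  expr <- tryCatch(str2lang(text),
                   error = function(e) stop(sprintf("cannot parse rule '%s'", text),
                                            call. = FALSE))
  expr
}

#' Evaluate a Boolean function on one assignment
#'
#' @param f a `BooleanFunction`.
#' @param values named vector or list of 0/1 values covering all inputs of
#'   `f`; extra names are ignored.
#' @return 0 or 1.
#' @export
eval_bf <- function(f, values) {
  values <- unlist(values)
  missing <- setdiff(f$inputs, names(values))
  if (length(missing)) {
    stop(sprintf("no value bound for input(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bits <- check_binary(values[f$inputs], "input values")
  f$table[tt_index(bits)]
}

# evaluate f on a 0/1 matrix whose columns are (a superset of) f's inputs
eval_bf_matrix <- function(f, mat) {
  cols <- mat[, f$inputs, drop = FALSE]
  f$table[tt_index_mat(cols)]
}

#' Test whether a Boolean function depends essentially on a variable
#'
#' An input is essential when toggling it changes the output for at least
#' one assignment of the remaining inputs.
#'
#' @param f a `BooleanFunction`.
#' @param variable an input name of `f`.
#' @return `TRUE` or `FALSE`.
#' @export
is_essential <- function(f, variable) {
  j <- match(variable, f$inputs)
  if (is.na(j)) {
    stop(sprintf("'%s' is not an input of the function", variable), call. = FALSE)
  }
  m <- length(f$inputs)
  rows <- tt_rows(m)
  low <- rows[, j] == 0L
  flipped <- rows[low, , drop = FALSE]
  flipped[, j] <- 1L
  any(f$table[low] != f$table[tt_index_mat(flipped)])
}

#' List the essential inputs of a Boolean function
#' @param f a `BooleanFunction`.
#' @return character vector (possibly empty) in input order.
#' @export
essential_inputs <- function(f) {
  f$inputs[vapply(f$inputs, function(v) is_essential(f, v), logical(1))]
}

#' Drop non-essential inputs from a Boolean function
#'
#' Returns a semantically identical function whose input list contains only
#' essential variables.  The names of any removed inputs are recorded in the
#' `"dropped_inputs"` attribute for auditability.
#'
#' @param f a `BooleanFunction`.
#' @return a `BooleanFunction` whose inputs are all essential.
#' @export
normalize_function <- function(f) {
  keep <- essential_inputs(f)
  dropped <- setdiff(f$inputs, keep)
  if (!length(dropped)) {
    attr(f, "dropped_inputs") <- character(0)
    return(f)
  }
  rows <- tt_rows(length(keep))
  colnames(rows) <- keep
  full <- matrix(0L, nrow(rows), length(f$inputs))
  colnames(full) <- f$inputs
  full[, keep] <- rows
  out <- boolean_function(keep, f$table[tt_index_mat(full)])
  attr(out, "dropped_inputs") <- dropped
  out
}

# pin one input to a constant; the input list is unchanged (the pinned
# variable simply becomes non-essential)
pin_input <- function(f, variable, value) {
  j <- match(variable, f$inputs)
  if (is.na(j)) {
    stop(sprintf("'%s' is not an input of the function", variable), call. = FALSE)
  }
  value <- check_binary(value, "pinned value")
  rows <- tt_rows(length(f$inputs))
  rows[, j] <- value
  boolean_function(f$inputs, f$table[tt_index_mat(rows)])
}

# partially evaluate: fix an input to a constant and remove it
restrict_input <- function(f, variable, value) {
  j <- match(variable, f$inputs)
  if (is.na(j)) {
    stop(sprintf("'%s' is not an input of the function", variable), call. = FALSE)
  }
  value <- check_binary(value, "restricted value")
  rows <- tt_rows(length(f$inputs))
  keep <- rows[, j] == value
  boolean_function(f$inputs[-j], f$table[keep])
}

constant_bf <- function(inputs, value) {
  value <- check_binary(value, "constant value")
  boolean_function(inputs, rep(value, 2L^length(inputs)))
}

is_constant_bf <- function(f) {
  length(unique(f$table)) == 1L
}

# semantic equality over the union of input sets
bf_equal <- function(f, g) {
  vars <- union(f$inputs, g$inputs)
  rows <- tt_rows(length(vars))
  colnames(rows) <- vars
  all(eval_bf_matrix(f, rows) == eval_bf_matrix(g, rows))
}

#' @export
print.BooleanFunction <- function(x, ...) {
  m <- length(x$inputs)
  cat(sprintf("BooleanFunction on %d input(s)%s\n", m,
              if (m) paste0(": ", paste(x$inputs, collapse = ", ")) else ""))
  cat("  table:", paste(x$table, collapse = ""), "\n")
  invisible(x)
}
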