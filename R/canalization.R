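#' Canalizing variables of a Boolean function
#'
#' A variable `x` canalizes `f` (to `b`) when there is an input value `a`
#' such that fixing `x = a` forces `f = b` regardless of all other
#' inputs.  Non-essential inputs are never canalizing for a non-constant
#' function.
#'
#' @param f a non-constant `BooleanFunction`.
#' @return a data frame with columns `variable`, `input` (the canalizing
#'   input `a`) and `output` (the canalized output `b`); zero rows when
#'   `f` is not canalizing.  An arity-one function is reported with both
#'   of its canalizing (input, output) pairs.
#' @export
canalizing_variables <- function(f) {
  if (is_constant_bf(f)) {
    stop("canalization is undefined for constant functions", call. = FALSE)
  }
  m <- length(f$inputs)
  rows <- tt_rows(m)
  variable <- character(0); input <- integer(0); output <- integer(0)
  for (j in seq_len(m)) {
    for (a in 0:1) {
      vals <- f$table[rows[, j] == a]
      if (length(unique(vals)) == 1L) {
        variable <- c(variable, f$inputs[j])
        input <- c(input, a)
        output <- c(output, vals[1L])
      }
    }
  }
  data.frame(variable = variable, input = input, output = output,
             stringsAsFactors = FALSE)
}

#' Canalizing-layer decomposition of a Boolean function
#'
#' Every non-constant Boolean function can be written uniquely as
#' `f = M1 (M2 (... (M_{r-1} (M_r pC + 1) + 1) ...) + 1) + q` over GF(2),
#' where each layer `Mi` is an extended monomial -- a product of factors
#' `(x + a)` over the variables of the layer, vanishing exactly when some
#' variable receives its canalizing input -- and `pC` is the core
#' polynomial on the variables that never become canalizing.  The layers
#' are found by stripping: all canalizing variables of `f` form layer 1;
#' the variables that become canalizing after the first layer's variables
#' are excluded form layer 2; and so on.  Variables within a layer share a
#' canalized output, and the outputs of consecutive layers alternate,
#' starting with `q` for layer 1.
#'
#' Non-essential inputs are dropped (recorded in the result) before the
#' layers are computed, so the decomposition is taken on the function's
#' essential variables.  Arity is capped because layer extraction scans
#' whole truth tables; biological rules are far below the cap.
#'
#' @param f a non-constant `BooleanFunction` of arity at most `max_arity`.
#' @param max_arity refuse truth tables larger than `2^max_arity`.
#' @return an object of class `CanalizingLayers`: a list with `layers`
#'   (list of data frames `variable`, `input`), `outputs` (canalized
#'   output per layer), `structure` (the vector `k1, ..., kr` of layer
#'   sizes), `depth` (their sum), `core` (a `BooleanFunction` on the
#'   residual variables, or `NULL` when the core polynomial is the
#'   constant 1), `offset` (`q`), `inputs` (the essential inputs, in
#'   original order) and `nested_canalizing` (depth equals arity).
#' @seealso [reconstruct()] for the inverse, [layer_structure()],
#'   [canalizing_depth()], [is_nested_canalizing()] for projections.
#' @export
#' @examples
#' f <- bf_from_expression("x1 & (!x2 | (x3 & x4))")
#' layer_decomposition(f)$structure  # (1, 1, 2)
layer_decomposition <- function(f, max_arity = 16L) {
  if (length(f$inputs) > max_arity) {
    stop(sprintf("arity %d exceeds the layer-decomposition cap of %d",
                 length(f$inputs), max_arity), call. = FALSE)
  }
  if (is_constant_bf(f)) {
    stop("constant functions have no layer decomposition", call. = FALSE)
  }
  nf <- normalize_function(f)
  dropped <- attr(nf, "dropped_inputs")
  g <- nf
  layers <- list()
  outputs <- integer(0)
  repeat {
    if (is_constant_bf(g)) {
      # all variables stripped: nested canalizing, core polynomial == 1
      r <- length(layers)
      stopifnot((g$table[1L] + outputs[r]) %% 2L == 1L)
      core <- NULL
      break
    }
    cv <- canalizing_variables(g)
    if (!nrow(cv)) {
      core <- g
      break
    }
    # pick the canalized output of this layer; an arity-one remainder is
    # canalizing in both directions, so fix the ambiguity: alternation
    # forces the output after the first layer, and q = 0 by convention
    # for a first layer consisting of a single lonely variable
    outs <- unique(cv$output)
    if (length(outs) > 1L) {
      b <- if (length(layers)) 1L - outputs[length(outputs)] else 0L
      cv <- cv[cv$output == b, , drop = FALSE]
    } else {
      b <- outs
    }
    if (length(outputs) && b == outputs[length(outputs)]) {
      stop("consecutive layers share an output (internal error)", call. = FALSE)
    }
    layer_vars <- unique(cv$variable)
    cv <- cv[match(layer_vars, cv$variable), , drop = FALSE]
    # keep within-layer order by original input position
    cv <- cv[order(match(cv$variable, nf$inputs)), , drop = FALSE]
    rownames(cv) <- NULL
    layers[[length(layers) + 1L]] <- cv[, c("variable", "input")]
    outputs <- c(outputs, b)
    for (i in seq_len(nrow(cv))) {
      g <- restrict_input(g, cv$variable[i], 1L - cv$input[i])
    }
  }
  r <- length(layers)
  structure_vec <- vapply(layers, nrow, integer(1))
  q <- if (r) outputs[1L] else 0L
  # core polynomial: pC = residual XOR b_r (pC = f itself when r = 0)
  if (is.null(core)) {
    core_fn <- NULL  # pC == 1
  } else if (r == 0L) {
    core_fn <- core
  } else {
    core_fn <- boolean_function(core$inputs, (core$table + outputs[r]) %% 2L)
  }
  out <- structure(list(layers = layers,
                        outputs = outputs,
                        structure = structure_vec,
                        depth = sum(structure_vec),
                        core = core_fn,
                        offset = q,
                        inputs = nf$inputs,
                        nested_canalizing = sum(structure_vec) == length(nf$inputs)),
                   class = "CanalizingLayers")
  attr(out, "dropped_inputs") <- dropped
  out
}

#' @export
print.CanalizingLayers <- function(x, ...) {
  cat(sprintf("CanalizingLayers: depth %d of arity %d%s\n", x$depth,
              length(x$inputs),
              if (x$nested_canalizing) " (nested canalizing)" else ""))
  for (i in seq_along(x$layers)) {
    lay <- x$layers[[i]]
    cat(sprintf("  layer %d (output %d): %s\n", i, x$outputs[i],
                paste(sprintf("%s:%d", lay$variable, lay$input), collapse = ", ")))
  }
  if (!is.null(x$core)) {
    cat("  core polynomial on:", paste(x$core$inputs, collapse = ", "), "\n")
  } else if (x$depth > 0L) {
    cat("  core polynomial: 1\n")
  }
  invisible(x)
}

#' Layer structure, canalizing depth, and NCF status
#'
#' Thin projections of [layer_decomposition()]: the vector of layer sizes
#' `(k1, ..., kr)`, their sum (the canalizing depth), and whether the
#' function is nested canalizing (depth equals arity).
#'
#' @inheritParams layer_decomposition
#' @return `layer_structure()` an integer vector (length 0 for a
#'   non-canalizing function); `canalizing_depth()` an integer;
#'   `is_nested_canalizing()` a logical.
#' @export
layer_structure <- function(f, max_arity = 16L) {
  layer_decomposition(f, max_arity)$structure
}

#' @rdname layer_structure
#' @export
canalizing_depth <- function(f, max_arity = 16L) {
  layer_decomposition(f, max_arity)$depth
}

#' @rdname layer_structure
#' @export
is_nested_canalizing <- function(f, max_arity = 16L) {
  layer_decomposition(f, max_arity)$nested_canalizing
}

#' Rebuild a Boolean function from its canalizing layers
#'
#' Evaluates the extended monomial form
#' `M1 (M2 (... (M_r pC + 1) ...) + 1) + q` over GF(2), giving back the
#' truth table of the decomposed function; with
#' [layer_decomposition()] this is an exact round trip.
#'
#' @param cl a `CanalizingLayers` object.
#' @param inputs optional variable order for the result; defaults to the
#'   decomposition's recorded input order.
#' @return a `BooleanFunction`.
#' @export
reconstruct <- function(cl, inputs = NULL) {
  if (is.null(inputs)) inputs <- cl$inputs
  covered <- c(unlist(lapply(cl$layers, `[[`, "variable")),
               if (!is.null(cl$core)) cl$core$inputs)
  if (!setequal(covered, inputs) || anyDuplicated(covered)) {
    stop("layer and core variables must partition the input list", call. = FALSE)
  }
  m <- length(inputs)
  rows <- tt_rows(m)
  colnames(rows) <- inputs
  r <- length(cl$layers)
  # innermost term: M_r * pC (pC == 1 when core is NULL)
  pc_vals <- if (is.null(cl$core)) rep(1L, nrow(rows))
             else eval_bf_matrix(cl$core, rows)
  h <- pc_vals
  for (i in rev(seq_len(r))) {
    lay <- cl$layers[[i]]
    M <- rep(1L, nrow(rows))
    for (j in seq_len(nrow(lay))) {
      M <- M * ((rows[, lay$variable[j]] + lay$input[j]) %% 2L)
    }
    h <- if (i == r) M * h else M * ((h + 1L) %% 2L)
  }
  # with no layers f = pC + q
  table <- (h + cl$offset) %% 2L
  boolean_function(inputs, table)
}

#' Random nested canalizing function with a prescribed layer structure
#'
#' Draws an NCF by sampling, for each variable, a layer assignment
#' following `structure`, a canalizing input, and an offset bit, then
#' building the extended monomial form.  The layer decomposition of the
#' result recovers `structure` exactly (uniqueness of the form).  Uses the
#' R random number generator; call `set.seed()` for reproducibility.
#'
#' @param arity number of variables.
#' @param structure integer vector summing to `arity`; when the function
#'   has more than one layer the last layer must have at least two
#'   variables (a trailing singleton layer would merge into the previous
#'   one).  Default: a valid structure drawn at random.
#' @param inputs variable names; default `x1..x<arity>`.
#' @return a `BooleanFunction` that is nested canalizing with the
#'   requested layer structure.
#' @export
random_ncf <- function(arity, structure = NULL, inputs = NULL) {
  arity <- as.integer(arity)
  if (arity < 1L) stop("arity must be at least 1", call. = FALSE)
  if (is.null(structure)) {
    structure <- random_layer_structure(arity)
  }
  structure <- as.integer(structure)
  if (sum(structure) != arity) {
    stop("layer structure must sum to the arity", call. = FALSE)
  }
  if (any(structure < 1L)) stop("layer sizes must be positive", call. = FALSE)
  r <- length(structure)
  if (r > 1L && structure[r] < 2L) {
    stop(paste("the last layer of a nested canalizing function with more",
               "than one layer must contain at least two variables"),
         call. = FALSE)
  }
  if (is.null(inputs)) inputs <- paste0("x", seq_len(arity))
  perm <- sample.int(arity)
  a <- sample(0:1, arity, replace = TRUE)
  q <- if (r == 1L && structure[1L] == 1L) 0L else sample(0:1, 1L)
  offsets <- c(0L, cumsum(structure))
  layers <- lapply(seq_len(r), function(i) {
    idx <- perm[(offsets[i] + 1L):offsets[i + 1L]]
    idx <- sort(idx)  # within-layer order by original index
    data.frame(variable = inputs[idx], input = a[idx],
               stringsAsFactors = FALSE)
  })
  cl <- structure(list(layers = layers,
                       outputs = (q + (seq_len(r) - 1L)) %% 2L,
                       structure = structure,
                       depth = arity,
                       core = NULL,
                       offset = q,
                       inputs = inputs,
                       nested_canalizing = TRUE),
                  class = "CanalizingLayers")
  reconstruct(cl)
}

# a uniformly random composition of n whose last part is >= 2 unless it is
# the only part
random_layer_structure <- function(n) {
  repeat {
    parts <- integer(0)
    left <- n
    while (left > 0L) {
      k <- sample.int(left, 1L)
      parts <- c(parts, k)
      left <- left - k
    }
    if (length(parts) == 1L || parts[length(parts)] >= 2L) return(parts)
  }
}

#' Random Boolean function, optionally with all inputs essential
#'
#' @param arity number of inputs.
#' @param inputs variable names; default `x1..x<arity>`.
#' @param essential resample until every input is essential.
#' @return a `BooleanFunction`.
#' @export
random_boolean_function <- function(arity, inputs = NULL, essential = TRUE) {
  arity <- as.integer(arity)
  if (is.null(inputs)) inputs <- paste0("x", seq_len(arity))
  repeat {
    f <- boolean_function(inputs, sample(0:1, 2L^arity, replace = TRUE))
    if (!essential || length(essential_inputs(f)) == arity) return(f)
  }
}
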