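#' Construct a synchronous Boolean network
#'
#' A `BooleanNetwork` is an ordered list of variables, one update function
#' per variable, and an (optionally empty) ordered list of external
#' parameters.  Every input of every update function must be either a
#' network variable or an external parameter.  When the external list is
#' empty the network is autonomous: a map from n-bit states to n-bit
#' states, updated synchronously.
#'
#' @param functions named list of [boolean_function()] objects; the names
#'   give the variable order.
#' @param externals optional character vector of external parameter names.
#'   By default all function inputs that are not variables are collected as
#'   externals, in order of first appearance.
#' @return an object of class `BooleanNetwork`.
#' @export
#' @examples
#' net <- network_from_rules(c(
#'   x1 = "x2 & !x3",
#'   x2 = "x3",
#'   x3 = "!x1 & x2"
#' ))
#' attractors(net)
boolean_network <- function(functions, externals = NULL) {
  if (!length(functions) || is.null(names(functions)) ||
      any(!nzchar(names(functions)))) {
    stop("'functions' must be a non-empty named list", call. = FALSE)
  }
  variables <- names(functions)
  if (anyDuplicated(variables)) {
    stop("duplicate variable names", call. = FALSE)
  }
  for (f in functions) {
    if (!inherits(f, "BooleanFunction")) {
      stop("every element of 'functions' must be a BooleanFunction", call. = FALSE)
    }
  }
  used <- unique(unlist(lapply(functions, function(f) f$inputs), use.names = FALSE))
  free <- setdiff(used, variables)
  if (is.null(externals)) {
    externals <- free
  } else {
    externals <- as.character(externals)
    missing <- setdiff(free, externals)
    if (length(missing)) {
      stop(sprintf("inputs neither variables nor declared externals: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  if (length(intersect(externals, variables))) {
    stop("external parameters must be disjoint from variables", call. = FALSE)
  }
  structure(list(variables = variables,
                 functions = functions,
                 externals = externals),
            class = "BooleanNetwork")
}

#' Build a network from rule strings
#'
#' @param rules named character vector; names are the target variables and
#'   values are expressions in the rule grammar (`!`, `&`, `|`,
#'   parentheses, `0`/`1`).  Names appearing only on the right-hand side
#'   become external parameters.
#' @return a `BooleanNetwork`.
#' @export
network_from_rules <- function(rules) {
  if (is.null(names(rules))) stop("'rules' must be named", call. = FALSE)
  funs <- lapply(rules, bf_from_expression)
  boolean_network(funs)
}

is_autonomous <- function(network) length(network$externals) == 0L

n_vars <- function(network) length(network$variables)

#' @export
print.BooleanNetwork <- function(x, ...) {
  cat(sprintf("BooleanNetwork with %d variable(s)%s\n", n_vars(x),
              if (length(x$externals))
                sprintf(" and %d external parameter(s)", length(x$externals))
              else ""))
  for (v in x$variables) {
    f <- x$functions[[v]]
    cat(sprintf("  %s <- f(%s)\n", v, paste(f$inputs, collapse = ", ")))
  }
  if (length(x$externals)) {
    cat("  externals:", paste(x$externals, collapse = ", "), "\n")
  }
  invisible(x)
}

## ---- states -------------------------------------------------------------

#' Convert between states and bit strings
#'
#' States are 0/1 vectors in network variable order; `x1` is the leftmost
#' character of the printed string.
#'
#' @param state integer 0/1 vector.
#' @return `state_to_string` returns a character scalar such as `"010"`;
#'   `string_to_state` returns an integer vector.
#' @export
state_to_string <- function(state) paste(as.integer(state), collapse = "")

#' @rdname state_to_string
#' @param string a bit string such as `"010"`.
#' @export
string_to_state <- function(string) {
  bits <- as.integer(strsplit(string, "")[[1]])
  check_binary(bits, "state string")
}

check_state <- function(network, state) {
  state <- check_binary(unlist(state), "state")
  if (length(state) != n_vars(network)) {
    stop(sprintf("state has length %d; network has %d variables",
                 length(state), n_vars(network)), call. = FALSE)
  }
  state
}

check_bindings <- function(network, bindings) {
  if (!length(network$externals)) return(integer(0))
  bindings <- unlist(bindings)
  missing <- setdiff(network$externals, names(bindings))
  if (length(missing)) {
    stop(sprintf("unbound external parameter(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  check_binary(bindings[network$externals], "external bindings")
}

## ---- dynamics -----------------------------------------------------------

#' Synchronous update of a Boolean network
#'
#' Applies every update function to the current state simultaneously and
#' returns the successor state F(x).
#'
#' @param network a `BooleanNetwork`.
#' @param state 0/1 vector in variable order (or a bit string).
#' @param bindings named 0/1 values for all external parameters (omit for
#'   autonomous networks).
#' @return the successor state as an integer vector.
#' @export
evaluate <- function(network, state, bindings = NULL) {
  if (is.character(state)) state <- string_to_state(state)
  state <- check_state(network, state)
  bound <- check_bindings(network, bindings)
  values <- c(stats::setNames(state, network$variables),
              stats::setNames(bound, network$externals))
  vapply(network$functions, eval_bf, integer(1), values = values,
         USE.NAMES = FALSE)
}

#' Trajectory of a Boolean network from an initial state
#'
#' Iterates the synchronous update until a state repeats.  Termination is
#' guaranteed because the state space is finite.
#'
#' @inheritParams evaluate
#' @param initial the initial state (0/1 vector or bit string).
#' @return an object of class `Trajectory`: a list with `states` (matrix,
#'   one row per time step up to and including the first revisited state's
#'   last new step), `transient_length` (steps before the periodic part)
#'   and `period`.
#' @export
trajectory <- function(network, initial, bindings = NULL) {
  if (is.character(initial)) initial <- string_to_state(initial)
  state <- check_state(network, initial)
  seen <- character(0)
  states <- list()
  repeat {
    key <- state_to_string(state)
    hit <- match(key, seen)
    if (!is.na(hit)) {
      transient <- hit - 1L
      period <- length(seen) - transient
      break
    }
    seen <- c(seen, key)
    states[[length(states) + 1L]] <- state
    state <- evaluate(network, state, bindings)
  }
  mat <- do.call(rbind, states)
  colnames(mat) <- network$variables
  structure(list(states = mat,
                 transient_length = transient,
                 period = period),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  strs <- apply(x$states, 1L, paste, collapse = "")
  cat(sprintf("Trajectory: %s ... (transient %d, period %d)\n",
              paste(strs, collapse = " -> "), x$transient_length, x$period))
  invisible(x)
}

cap_check <- function(n, cap) {
  if (n > cap) {
    stop(sprintf(paste0("exhaustive enumeration over %d variables exceeds the ",
                        "cap of %d; raise the cap or use the modular route ",
                        "(decompose/modular_attractors)"), n, cap),
         call. = FALSE)
  }
}

default_cap <- function() getOption("bncontrol.cap", 24L)

# successor index (1-based over all 2^n states) for every state
transition_table <- function(network, bindings = NULL, cap = default_cap()) {
  n <- n_vars(network)
  cap_check(n, cap)
  bound <- check_bindings(network, bindings)
  rows <- tt_rows(n)
  colnames(rows) <- network$variables
  if (length(bound)) {
    ext <- matrix(rep(bound, each = nrow(rows)), nrow = nrow(rows))
    colnames(ext) <- network$externals
    rows <- cbind(rows, ext)
  }
  nxt <- matrix(0L, nrow(rows), n)
  for (j in seq_len(n)) {
    nxt[, j] <- eval_bf_matrix(network$functions[[j]], rows)
  }
  tt_index_mat(nxt)
}

#' State space of a Boolean network
#'
#' The functional digraph on all `2^n` states: every state has exactly one
#' outgoing edge, to its synchronous image.
#'
#' @inheritParams evaluate
#' @param cap refuse enumeration above this number of variables (default
#'   24, settable via `options(bncontrol.cap = )`).
#' @return an [igraph::graph] whose vertex names are the state bit strings.
#' @export
state_space <- function(network, bindings = NULL, cap = default_cap()) {
  n <- n_vars(network)
  succ <- transition_table(network, bindings, cap)
  labels <- apply(tt_rows(n), 1L, paste, collapse = "")
  g <- igraph::make_empty_graph(n = length(succ), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = labels)
  igraph::add_edges(g, rbind(seq_along(succ), succ))
}

# cycles (as lists of 1-based state indices, in orbit order) and the basin
# id of every state, from a successor table
find_cycles <- function(succ) {
  N <- length(succ)
  basin <- integer(N)
  walk_pos <- integer(N)
  cycles <- list()
  for (s in seq_len(N)) {
    if (basin[s]) next
    path <- integer(0)
    v <- s
    while (!basin[v] && !walk_pos[v]) {
      walk_pos[v] <- length(path) + 1L
      path[length(path) + 1L] <- v
      v <- succ[v]
    }
    if (basin[v]) {
      id <- basin[v]
    } else {
      cyc <- path[walk_pos[v]:length(path)]
      cycles[[length(cycles) + 1L]] <- cyc
      id <- length(cycles)
    }
    basin[path] <- id
    walk_pos[path] <- 0L
  }
  list(cycles = cycles, basin = basin)
}

#' Attractors of a Boolean network
#'
#' Enumerates all minimal sets of states mapped onto themselves by the
#' synchronous update: steady states (length 1) and limit cycles.  Every
#' state's trajectory ends in exactly one of the returned attractors.
#'
#' @inheritParams state_space
#' @return a list of `Attractor` objects, sorted by (length, first state).
#'   Each attractor's states are rotated so the lexicographically smallest
#'   state comes first.
#' @export
attractors <- function(network, bindings = NULL, cap = default_cap()) {
  attractor_basins(network, bindings, cap)$attractors
}

#' @describeIn attractors also return the basin id of every state (in
#'   state-index order; basin `k` drains into the `k`-th listed attractor).
#' @export
attractor_basins <- function(network, bindings = NULL, cap = default_cap()) {
  n <- n_vars(network)
  succ <- transition_table(network, bindings, cap)
  res <- find_cycles(succ)
  rows <- tt_rows(n)
  colnames(rows) <- network$variables
  atts <- lapply(res$cycles, function(cyc) {
    as_attractor(rows[cyc, , drop = FALSE])
  })
  ord <- attractor_order(atts)
  basin <- match(res$basin, ord)
  list(attractors = atts[ord], basin = basin)
}

## ---- attractor objects --------------------------------------------------

#' Construct an attractor
#'
#' An `Attractor` is an ordered cyclic sequence of distinct states, each
#' mapped to the next by the network.  The canonical rotation puts the
#' lexicographically smallest state first.
#'
#' @param states a 0/1 matrix (one row per state, columns in variable
#'   order) or a character vector of bit strings.
#' @param variables optional column names.
#' @return an object of class `Attractor` with fields `states` and
#'   `length`.
#' @export
as_attractor <- function(states, variables = NULL) {
  if (is.character(states)) {
    states <- do.call(rbind, lapply(states, string_to_state))
  }
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  storage.mode(states) <- "integer"
  if (!is.null(variables)) colnames(states) <- variables
  keys <- apply(states, 1L, paste, collapse = "")
  if (anyDuplicated(keys)) {
    stop("attractor states must be distinct", call. = FALSE)
  }
  start <- order(keys)[1L]
  idx <- c(seq(start, nrow(states)), seq_len(start - 1L))
  structure(list(states = states[idx, , drop = FALSE],
                 length = nrow(states)),
            class = "Attractor")
}

attractor_strings <- function(a) apply(a$states, 1L, paste, collapse = "")

attractor_key <- function(a) paste(attractor_strings(a), collapse = ">")

#' Compare two attractors for equality
#'
#' Equal when they contain the same states in the same cyclic order.
#' @param a,b `Attractor` objects.
#' @return `TRUE` or `FALSE`.
#' @export
attractor_equal <- function(a, b) {
  identical(attractor_key(a), attractor_key(b))
}

attractor_order <- function(atts) {
  lens <- vapply(atts, function(a) a$length, integer(1))
  keys <- vapply(atts, attractor_key, character(1))
  order(lens, keys)
}

sort_attractors <- function(atts) atts[attractor_order(atts)]

# set equality of two attractor lists
attractor_sets_equal <- function(a, b) {
  ka <- sort(vapply(a, attractor_key, character(1)))
  kb <- sort(vapply(b, attractor_key, character(1)))
  identical(ka, kb)
}

#' @export
print.Attractor <- function(x, ...) {
  cat(sprintf("Attractor of length %d: {%s}\n", x$length,
              paste(attractor_strings(x), collapse = ", ")))
  invisible(x)
}

#' @export
format.Attractor <- function(x, ...) {
  paste0("{", paste(attractor_strings(x), collapse = ","), "}")
}

## ---- wiring diagram -----------------------------------------------------

#' Wiring diagram of a Boolean network
#'
#' The directed graph with an edge `xi -> xj` exactly when the update
#' function of `xj` depends essentially on `xi`.  External parameters that
#' regulate some variable appear as extra source nodes.
#'
#' @param network a `BooleanNetwork`.
#' @return an object of class `WiringDiagram`: a list with `nodes`
#'   (variables first, then externals) and `edges` (two-column data frame
#'   `from`, `to`).
#' @export
wiring_diagram <- function(network) {
  from <- character(0)
  to <- character(0)
  for (v in network$variables) {
    for (src in essential_inputs(network$functions[[v]])) {
      from <- c(from, src)
      to <- c(to, v)
    }
  }
  structure(list(nodes = c(network$variables, network$externals),
                 edges = data.frame(from = from, to = to,
                                    stringsAsFactors = FALSE)),
            class = "WiringDiagram")
}

#' @export
print.WiringDiagram <- function(x, ...) {
  cat(sprintf("WiringDiagram: %d node(s), %d edge(s)\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    cat(paste(sprintf("  %s -> %s", x$edges$from, x$edges$to), collapse = "\n"),
        "\n")
  }
  invisible(x)
}

wiring_igraph <- function(wd, nodes = wd$nodes) {
  g <- igraph::make_empty_graph(n = length(nodes), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  keep <- wd$edges$from %in% nodes & wd$edges$to %in% nodes
  edges <- wd$edges[keep, , drop = FALSE]
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(match(edges$from, nodes),
                                    match(edges$to, nodes)))
  }
  g
}

has_edge <- function(wd, from, to) {
  any(wd$edges$from == from & wd$edges$to == to)
}
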