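#' Edge and node controls
#'
#' An edge control pins one input of one target function to a constant:
#' the controlled function is `f_j(x)` with `x_i` replaced by `a` wherever
#' it feeds `f_j` (and nowhere else).  `a = 0` models deletion of the edge
#' `x_i -> x_j`, `a = 1` its constant expression; the notation is
#' `xi ->a xj`.
#'
#' A node control rewires a variable's own update: `(mu_minus, mu_plus) =
#' (1,0)` knocks the node out (constant 0), `(0,1)` expresses it
#' constitutively (constant 1), `(0,0)` is inactive, and `(1,1)` negates
#' the function.  Negation is rejected by default as biologically
#' impractical; pass `allow_negation = TRUE` to permit it.
#'
#' @param source,target variable names (the edge `source -> target`, or
#'   the controlled node `target`).
#' @param value the pinned constant `a` for an edge control.
#' @param mu_minus,mu_plus the two node-control bits.
#' @param allow_negation permit `(1,1)`.
#' @return an `EdgeControl` or `NodeControl` object.
#' @export
#' @examples
#' edge_control("x1", "x2", 1)   # x1 ->1 x2
#' node_control("x4", 0, 1)      # constant expression of x4
edge_control <- function(source, target, value) {
  structure(list(source = as.character(source),
                 target = as.character(target),
                 value = check_binary(value, "edge control value")),
            class = "EdgeControl")
}

#' @rdname edge_control
#' @export
node_control <- function(target, mu_minus, mu_plus, allow_negation = FALSE) {
  mu_minus <- check_binary(mu_minus, "mu_minus")
  mu_plus <- check_binary(mu_plus, "mu_plus")
  if (mu_minus == 1L && mu_plus == 1L && !allow_negation) {
    stop(paste("node control (1,1) negates the update function and is",
               "disabled by default; set allow_negation = TRUE to permit it"),
         call. = FALSE)
  }
  structure(list(target = as.character(target),
                 mu_minus = mu_minus, mu_plus = mu_plus),
            class = "NodeControl")
}

#' @export
print.EdgeControl <- function(x, ...) {
  cat(sprintf("EdgeControl: %s ->%d %s\n", x$source, x$value, x$target))
  invisible(x)
}

#' @export
print.NodeControl <- function(x, ...) {
  action <- if (x$mu_minus == 1L && x$mu_plus == 0L) "knock-out"
            else if (x$mu_minus == 0L && x$mu_plus == 1L) "constant expression"
            else if (x$mu_minus == 0L && x$mu_plus == 0L) "inactive"
            else "negation"
  cat(sprintf("NodeControl: %s (%s)\n", x$target, action))
  invisible(x)
}

control_label <- function(ctrl) {
  if (inherits(ctrl, "EdgeControl")) {
    sprintf("%s ->%d %s", ctrl$source, ctrl$value, ctrl$target)
  } else {
    sprintf("%s := %s", ctrl$target,
            if (ctrl$mu_plus == 1L && ctrl$mu_minus == 0L) "1"
            else if (ctrl$mu_minus == 1L && ctrl$mu_plus == 0L) "0"
            else if (ctrl$mu_minus == 0L) "(inactive)" else "NOT")
  }
}

#' Bundle edge and node controls into a control set
#'
#' At most one node control per variable and one edge control per ordered
#' edge are admitted; the empty set is the identity control.
#'
#' @param ... `EdgeControl` and `NodeControl` objects (or lists of them).
#' @return an object of class `ControlSet` with fields `edges` and
#'   `nodes`.
#' @export
control_set <- function(...) {
  items <- list(...)
  if (length(items) == 1L && is.list(items[[1]]) &&
      !inherits(items[[1]], c("EdgeControl", "NodeControl"))) {
    items <- items[[1]]
  }
  edges <- Filter(function(x) inherits(x, "EdgeControl"), items)
  nodes <- Filter(function(x) inherits(x, "NodeControl"), items)
  if (length(edges) + length(nodes) != length(items)) {
    stop("control_set() accepts only EdgeControl and NodeControl objects",
         call. = FALSE)
  }
  ekeys <- vapply(edges, function(e) paste(e$source, e$target), character(1))
  if (anyDuplicated(ekeys)) {
    stop("at most one edge control per ordered edge", call. = FALSE)
  }
  nkeys <- vapply(nodes, function(n) n$target, character(1))
  if (anyDuplicated(nkeys)) {
    stop("at most one node control per variable", call. = FALSE)
  }
  structure(list(edges = edges, nodes = nodes), class = "ControlSet")
}

control_set_size <- function(cs) length(cs$edges) + length(cs$nodes)

#' @export
print.ControlSet <- function(x, ...) {
  k <- control_set_size(x)
  if (!k) {
    cat("ControlSet: (empty / identity)\n")
    return(invisible(x))
  }
  cat(sprintf("ControlSet with %d control(s):\n", k))
  for (ctrl in c(x$edges, x$nodes)) cat("  ", control_label(ctrl), "\n")
  invisible(x)
}

#' Apply an edge control to a single update function
#'
#' With the control active, the `source` input of `f` is pinned to the
#' constant `a` inside `f` only; the controlled function is no longer
#' essential in `source`.  Inactive controls leave `f` unchanged.
#'
#' @param f a `BooleanFunction` (the target's update rule).
#' @param source an input of `f`.
#' @param a the pinned constant.
#' @param active logical; the control's activity bit.
#' @return a `BooleanFunction`.
#' @export
apply_edge_control <- function(f, source, a, active = TRUE) {
  if (!active) return(f)
  pin_input(f, source, a)
}

#' Apply a node control to an update function
#'
#' Implements the four settings of the two-bit node control:
#' `(0,0)` identity, `(1,0)` constant 0 (knock-out), `(0,1)` constant 1
#' (constant expression), `(1,1)` negation (only with
#' `allow_negation = TRUE`).
#'
#' @param f a `BooleanFunction`.
#' @param mu_minus,mu_plus the control bits.
#' @param allow_negation permit the `(1,1)` setting.
#' @return a `BooleanFunction` over the same inputs.
#' @export
apply_node_control <- function(f, mu_minus, mu_plus, allow_negation = FALSE) {
  mu_minus <- check_binary(mu_minus, "mu_minus")
  mu_plus <- check_binary(mu_plus, "mu_plus")
  if (mu_minus == 1L && mu_plus == 1L && !allow_negation) {
    stop("node control (1,1) (negation) is disabled; set allow_negation = TRUE",
         call. = FALSE)
  }
  # (mu_minus + mu_plus + 1) f(x) + mu_plus over GF(2)
  table <- ((mu_minus + mu_plus + 1L) * f$table + mu_plus) %% 2L
  boolean_function(f$inputs, table)
}

#' Apply a control set to a network
#'
#' Edge controls are applied first (each pinning one input of one target
#' function), then node controls (which replace the whole function and
#' therefore dominate).  Every referenced edge must exist in the wiring
#' diagram and every referenced node must be a network variable.
#'
#' @param network a `BooleanNetwork`.
#' @param cs a `ControlSet`.
#' @param allow_negation permit `(1,1)` node controls.
#' @return the controlled `BooleanNetwork`.
#' @export
controlled_network <- function(network, cs, allow_negation = FALSE) {
  funs <- network$functions
  for (e in cs$edges) {
    if (!e$target %in% network$variables) {
      stop(sprintf("unknown control target '%s'", e$target), call. = FALSE)
    }
    f <- funs[[e$target]]
    if (!e$source %in% f$inputs) {
      stop(sprintf("no edge %s -> %s in the wiring diagram",
                   e$source, e$target), call. = FALSE)
    }
    funs[[e$target]] <- apply_edge_control(f, e$source, e$value)
  }
  for (ctl in cs$nodes) {
    if (!ctl$target %in% network$variables) {
      stop(sprintf("unknown control target '%s'", ctl$target), call. = FALSE)
    }
    funs[[ctl$target]] <- apply_node_control(funs[[ctl$target]],
                                             ctl$mu_minus, ctl$mu_plus,
                                             allow_negation = allow_negation)
  }
  boolean_network(funs, externals = network$externals)
}

#' Does a control stabilize a network at a target attractor?
#'
#' True exactly when the controlled network has the target as its only
#' attractor.  The target may be a new attractor created by the control;
#' it is checked against the controlled network only.
#'
#' @param network a `BooleanNetwork`.
#' @param cs a `ControlSet`.
#' @param target an `Attractor` over the network's variables.
#' @param bindings external bindings, for non-autonomous networks.
#' @param allow_negation permit `(1,1)` node controls.
#' @param cap enumeration cap.
#' @return `TRUE` or `FALSE`.
#' @export
stabilizes <- function(network, cs, target, bindings = NULL,
                       allow_negation = FALSE, cap = default_cap()) {
  ctrl <- controlled_network(network, cs, allow_negation = allow_negation)
  atts <- attractors(ctrl, bindings = bindings, cap = cap)
  length(atts) == 1L && attractor_equal(atts[[1]], target)
}

## ---- exhaustive control search ------------------------------------------

# deterministic candidate list: node controls first (variable order,
# knock-out before constant expression), then edge controls (target in
# variable order, then source, deletion before constant expression)
control_candidates <- function(network, kinds = c("node", "edge"),
                               allow_negation = FALSE) {
  out <- list()
  if ("node" %in% kinds) {
    for (v in network$variables) {
      out <- c(out, list(node_control(v, 1, 0), node_control(v, 0, 1)))
      if (allow_negation) out <- c(out, list(node_control(v, 1, 1, TRUE)))
    }
  }
  if ("edge" %in% kinds) {
    wd <- wiring_diagram(network)
    for (tgt in network$variables) {
      srcs <- wd$edges$from[wd$edges$to == tgt]
      srcs <- network$variables[network$variables %in% srcs]
      for (src in srcs) {
        out <- c(out, list(edge_control(src, tgt, 0), edge_control(src, tgt, 1)))
      }
    }
  }
  out
}

controls_compatible <- function(ctrls) {
  keys <- vapply(ctrls, function(x) {
    if (inherits(x, "EdgeControl")) paste("e", x$source, x$target)
    else paste("n", x$target)
  }, character(1))
  !anyDuplicated(keys)
}

#' Exhaustive search for minimal stabilizing controls of a module
#'
#' Breadth-first search by cardinality over all admissible edge and node
#' controls: returns every control set of the smallest cardinality (up to
#' `max_size`) that stabilizes the network at the target.  The target may
#' be a new attractor created by the control.  The enumeration order is
#' deterministic (node controls before edge controls, variables by index),
#' so results are reproducible.
#'
#' @param network an autonomous `BooleanNetwork` (bind module externals
#'   first, e.g. via [substitute_steady_state()]).
#' @param target an `Attractor` over the network's variables.
#' @param max_size largest control-set cardinality to try.
#' @param kinds which control kinds to use: `"node"`, `"edge"` or both.
#' @param allow_negation permit `(1,1)` node controls.
#' @param cap enumeration cap.
#' @return a list of `ControlSet` objects, all of the same minimal
#'   cardinality (the empty control set alone when the target is already
#'   the unique attractor).  Empty, with a `"diagnostic"` attribute, when
#'   nothing within `max_size` works.
#' @export
search_module_control <- function(network, target, max_size = 2L,
                                  kinds = c("node", "edge"),
                                  allow_negation = FALSE,
                                  cap = default_cap()) {
  kinds <- match.arg(kinds, c("node", "edge"), several.ok = TRUE)
  if (!is_autonomous(network)) {
    stop("search works on autonomous networks; bind externals first",
         call. = FALSE)
  }
  cands <- control_candidates(network, kinds, allow_negation)
  for (size in 0:max_size) {
    found <- list()
    if (size == 0L) {
      combos <- list(integer(0))
    } else if (size > length(cands)) {
      break
    } else {
      combos <- utils::combn(length(cands), size, simplify = FALSE)
    }
    for (idx in combos) {
      ctrls <- cands[idx]
      if (!controls_compatible(ctrls)) next
      cs <- control_set(ctrls)
      ok <- tryCatch(stabilizes(network, cs, target,
                                allow_negation = allow_negation, cap = cap),
                     error = function(e) FALSE)
      if (ok) found[[length(found) + 1L]] <- cs
    }
    if (length(found)) return(found)
  }
  out <- list()
  attr(out, "diagnostic") <- sprintf(
    "no control of size <= %d stabilizes the network at %s",
    max_size, format(target))
  out
}

## ---- modular assembly ----------------------------------------------------

# lift a module-level control to the full network: edge-control sources
# that are external parameters are replaced by the upstream variables they
# stand for
lift_control <- function(ctrl, external_map) {
  if (inherits(ctrl, "EdgeControl") && ctrl$source %in% names(external_map)) {
    edge_control(external_map[[ctrl$source]], ctrl$target, ctrl$value)
  } else {
    ctrl
  }
}

#' Assemble module-level controls into a global control
#'
#' Given a modular decomposition, one control set per module and one
#' target attractor per module (each over that module's variables), this
#' verifies module by module -- in topological order, under the drive
#' induced by the upstream targets -- that each control stabilizes its
#' module, combines the targets by direct sum, and returns the union
#' control together with the global target attractor.  At every
#' composition step the driven module must have a unique periodic orbit;
#' this holds automatically whenever the accumulated target or the
#' module's target is a steady state, and is verified explicitly on the
#' product space otherwise.  When the full network is small enough the
#' assembled claim is re-checked by whole-network enumeration; a failure
#' raises an error rather than returning silently.
#'
#' @param decomp a `ModularDecomposition`.
#' @param module_controls list of `ControlSet` objects, one per module
#'   (in module order); controls may pin module-internal edges, edges
#'   from external parameters, or nodes.
#' @param module_targets list of `Attractor` objects, one per module,
#'   over the module's own variables.
#' @param allow_negation permit `(1,1)` node controls.
#' @param cap enumeration cap for the final whole-network verification.
#' @return a list with `control` (the union `ControlSet` on the full
#'   network), `attractor` (the global target, in original variable
#'   order) and `verified` (logical; whole-network check performed).
#' @export
assemble_modular_control <- function(decomp, module_controls, module_targets,
                                     allow_negation = FALSE,
                                     cap = default_cap()) {
  n_mod <- length(decomp$modules)
  stopifnot(length(module_controls) == n_mod,
            length(module_targets) == n_mod)
  vars_so_far <- character(0)
  partial <- as_attractor(matrix(integer(0), nrow = 1L, ncol = 0L))
  all_controls <- list()
  for (k in seq_len(n_mod)) {
    mod <- decomp$modules[[k]]
    emap <- attr(mod, "external_map")
    ctrl_mod <- controlled_network(mod, module_controls[[k]],
                                   allow_negation = allow_negation)
    if (length(emap)) {
      drive <- partial$states[, emap, drop = FALSE]
      colnames(drive) <- names(emap)
    } else {
      drive <- matrix(integer(0), nrow = partial$length, ncol = 0L)
    }
    orbits <- driven_attractors(ctrl_mod, drive, cap = cap)
    if (length(orbits) != 1L) {
      stop(sprintf(paste0(
        "module %d: the controlled module has %d periodic orbits under the ",
        "upstream drive; the modular assembly requires a unique orbit, which ",
        "is guaranteed when the upstream target or the module target is a ",
        "steady state"), k, length(orbits)), call. = FALSE)
    }
    orbit <- orbits[[1L]]
    target_k <- module_targets[[k]]
    # the orbit must realise the module target as a cyclic state sequence
    realised <- unique(apply(orbit$states, 1L, paste, collapse = ""))
    wanted <- attractor_strings(target_k)
    if (!setequal(realised, wanted)) {
      stop(sprintf(paste0(
        "module %d: control does not stabilize the module at the requested ",
        "target %s under the upstream drive"), k, format(target_k)),
        call. = FALSE)
    }
    partial <- compose_attractors(partial, list(orbit))[[1L]]
    vars_so_far <- c(vars_so_far, decomp$variable_sets[[k]])
    all_controls <- c(all_controls,
                      lapply(c(module_controls[[k]]$edges,
                               module_controls[[k]]$nodes),
                             lift_control, external_map = emap))
  }
  perm <- match(decomp$network$variables, vars_so_far)
  global_target <- as_attractor(partial$states[, perm, drop = FALSE],
                                variables = decomp$network$variables)
  global_cs <- control_set(all_controls)
  verified <- FALSE
  if (n_vars(decomp$network) <= cap) {
    ok <- stabilizes(decomp$network, global_cs, global_target,
                     allow_negation = allow_negation, cap = cap)
    if (!ok) {
      stop(paste("assembled control fails whole-network verification;",
                 "this indicates a violated side condition"), call. = FALSE)
    }
    verified <- TRUE
  }
  list(control = global_cs, attractor = global_target, verified = verified)
}
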