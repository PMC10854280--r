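#' Restrict a Boolean network to a subset of its variables
#'
#' The restriction keeps the original update functions of the subset;
#' every input from outside the subset becomes an external parameter named
#' `e_<input>`.  Restrictions to the strongly connected components of the
#' wiring diagram are the network's modules.
#'
#' @param network a `BooleanNetwork`.
#' @param variable_subset non-empty character vector of network variables.
#' @return a `BooleanNetwork` over the subset (in network variable order),
#'   with an `"external_map"` attribute mapping each external parameter
#'   name back to the original variable it stands for.
#' @export
restriction <- function(network, variable_subset) {
  variable_subset <- as.character(variable_subset)
  unknown <- setdiff(variable_subset, network$variables)
  if (length(unknown)) {
    stop(sprintf("unknown variable(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (!length(variable_subset)) stop("empty variable subset", call. = FALSE)
  keep <- network$variables[network$variables %in% variable_subset]
  funs <- list()
  ext_map <- character(0)
  for (v in keep) {
    f <- network$functions[[v]]
    ins <- f$inputs
    outside <- setdiff(ins, keep)
    renamed <- ins
    for (u in outside) {
      e <- paste0("e_", u)
      if (e %in% network$variables || e %in% keep) {
        stop(sprintf("external name '%s' collides with a variable", e),
             call. = FALSE)
      }
      renamed[renamed == u] <- e
      ext_map[e] <- u
    }
    funs[[v]] <- boolean_function(renamed, f$table)
  }
  out <- boolean_network(funs)
  attr(out, "external_map") <- ext_map[out$externals]
  out
}

#' Decompose a network into strongly connected modules
#'
#' Computes the strongly connected components of the wiring diagram,
#' restricts the network to each component (cross-component inputs become
#' external parameters), and records the acyclic quotient graph obtained
#' by contracting each component to a single node.  Modules are numbered
#' in a topological order of the quotient graph; ties between incomparable
#' modules are broken by smallest original variable index.
#'
#' @param network an autonomous `BooleanNetwork`.
#' @return an object of class `ModularDecomposition`: a list with
#'   `network`, `variable_sets`, `modules` (restrictions, with external
#'   maps), `quotient_dag` (data frame of module-index edges `from`,
#'   `to`), `order` (the topological module order, identical to the
#'   numbering) and `couplings` (per DAG edge, the named map from upstream
#'   variables to the downstream module's external parameters).
#' @export
decompose <- function(network) {
  if (!is_autonomous(network)) {
    stop("decompose() expects an autonomous network; bind its externals first",
         call. = FALSE)
  }
  wd <- wiring_diagram(network)
  g <- wiring_igraph(wd, nodes = network$variables)
  comp <- igraph::components(g, mode = "strong")$membership
  n_mod <- max(comp)
  sets <- split(network$variables, comp)
  # quotient edges between distinct components
  q_from <- integer(0)
  q_to <- integer(0)
  if (nrow(wd$edges)) {
    cf <- comp[match(wd$edges$from, network$variables)]
    ct <- comp[match(wd$edges$to, network$variables)]
    cross <- which(!is.na(cf) & cf != ct)
    pairs <- unique(cbind(cf[cross], ct[cross]))
    if (length(pairs)) {
      q_from <- pairs[, 1L]
      q_to <- pairs[, 2L]
    }
  }
  # topological order; tie-break by smallest original variable index
  min_idx <- vapply(seq_len(n_mod), function(k) {
    min(match(sets[[as.character(k)]], network$variables))
  }, integer(1))
  indeg <- tabulate(q_to, nbins = n_mod)
  remaining <- seq_len(n_mod)
  topo <- integer(0)
  while (length(remaining)) {
    ready <- remaining[indeg[remaining] == 0L]
    if (!length(ready)) stop("quotient graph is cyclic (internal error)", call. = FALSE)
    pick <- ready[which.min(min_idx[ready])]
    topo <- c(topo, pick)
    remaining <- setdiff(remaining, pick)
    out_edges <- which(q_from == pick)
    indeg[q_to[out_edges]] <- indeg[q_to[out_edges]] - 1L
  }
  renum <- match(seq_len(n_mod), topo)  # old component id -> new module index
  variable_sets <- lapply(topo, function(k) sets[[as.character(k)]])
  modules <- lapply(variable_sets, function(s) restriction(network, s))
  dag <- data.frame(from = renum[q_from], to = renum[q_to])
  dag <- dag[order(dag$from, dag$to), , drop = FALSE]
  rownames(dag) <- NULL
  couplings <- lapply(seq_len(nrow(dag)), function(e) {
    mod <- modules[[dag$to[e]]]
    emap <- attr(mod, "external_map")
    src <- variable_sets[[dag$from[e]]]
    keep <- emap %in% src
    stats::setNames(names(emap)[keep], emap[keep])  # upstream var -> external
  })
  structure(list(network = network,
                 variable_sets = variable_sets,
                 modules = modules,
                 quotient_dag = dag,
                 order = seq_len(n_mod),
                 couplings = couplings),
            class = "ModularDecomposition")
}

#' @export
print.ModularDecomposition <- function(x, ...) {
  cat(sprintf("ModularDecomposition: %d module(s)\n", length(x$modules)))
  for (k in seq_along(x$variable_sets)) {
    cat(sprintf("  M%d: {%s}\n", k, paste(x$variable_sets[[k]], collapse = ", ")))
  }
  if (nrow(x$quotient_dag)) {
    cat("  DAG:", paste(sprintf("M%d->M%d", x$quotient_dag$from,
                                x$quotient_dag$to), collapse = ", "), "\n")
  }
  invisible(x)
}

quotient_igraph <- function(decomp) {
  n <- length(decomp$modules)
  g <- igraph::make_empty_graph(n = n, directed = TRUE)
  if (nrow(decomp$quotient_dag)) {
    g <- igraph::add_edges(g, rbind(decomp$quotient_dag$from,
                                    decomp$quotient_dag$to))
  }
  g
}

#' Semidirect product of two coupled networks
#'
#' Recombines an upstream network and a downstream network with external
#' parameters into one network, substituting each coupled upstream
#' variable for the corresponding external parameter.  This is the inverse
#' of [decompose()] on two-module networks.
#'
#' @param upper upstream `BooleanNetwork`.
#' @param lower downstream `BooleanNetwork`; all its external parameters
#'   must be covered by the coupling.
#' @param coupling named character vector mapping upstream variable names
#'   to external parameter names of `lower` (e.g.
#'   `c(x1 = "e_x1", x2 = "e_x2")`).  May be empty when `lower` is
#'   autonomous, giving the disjoint union.
#' @return a `BooleanNetwork` over the concatenated variables.
#' @export
semidirect_product <- function(upper, lower, coupling = character(0)) {
  coupling <- unlist(coupling)
  if (length(coupling)) {
    bad <- setdiff(names(coupling), upper$variables)
    if (length(bad)) {
      stop(sprintf("coupling sources not in upstream network: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    if (anyDuplicated(coupling)) {
      stop("coupling must be injective into the lower externals", call. = FALSE)
    }
  }
  unmapped <- setdiff(lower$externals, coupling)
  if (length(unmapped)) {
    stop(sprintf("unmapped external parameter(s) of the lower network: %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  clash <- intersect(upper$variables, lower$variables)
  if (length(clash)) {
    stop(sprintf("variable name clash: %s", paste(clash, collapse = ", ")),
         call. = FALSE)
  }
  rev_map <- if (length(coupling)) {
    stats::setNames(names(coupling), coupling)  # external -> upstream var
  } else character(0)
  funs <- upper$functions
  for (v in lower$variables) {
    f <- lower$functions[[v]]
    ins <- f$inputs
    hit <- ins %in% names(rev_map)
    ins[hit] <- rev_map[ins[hit]]
    funs[[v]] <- boolean_function(ins, f$table)
  }
  boolean_network(funs)
}

#' Bind the external parameters of a module to constants
#'
#' Substitutes a steady upstream state into a module: every external
#' parameter is replaced by the given constant and the update functions
#' are re-tabulated without those inputs, yielding an autonomous network.
#'
#' @param module a `BooleanNetwork` with external parameters.
#' @param values named 0/1 vector covering all externals.
#' @return an autonomous `BooleanNetwork`.
#' @export
substitute_steady_state <- function(module, values) {
  bound <- check_bindings(module, values)
  funs <- lapply(module$variables, function(v) {
    f <- module$functions[[v]]
    for (e in intersect(module$externals, f$inputs)) {
      f <- restrict_input(f, e, bound[match(e, module$externals)])
    }
    f
  })
  names(funs) <- module$variables
  boolean_network(funs, externals = character(0))
}

# semantic equality of two networks: same variables (order), same update
# map on every state (requires bindings when not autonomous)
networks_equal <- function(a, b, cap = default_cap()) {
  if (!identical(a$variables, b$variables)) return(FALSE)
  if (!identical(sort(a$externals), sort(b$externals))) return(FALSE)
  if (!is_autonomous(a)) {
    # compare functionwise over variables and externals
    return(all(vapply(a$variables, function(v) {
      bf_equal(a$functions[[v]], b$functions[[v]])
    }, logical(1))))
  }
  identical(transition_table(a, cap = cap), transition_table(b, cap = cap))
}

## ---- non-autonomous dynamics -------------------------------------------

#' Attractors of a module under a periodic external drive
#'
#' A module with external parameters driven by a periodic sequence
#' `g(t)` of external values is a non-autonomous network
#' `y(t+1) = H(g(t), y(t))`.  Its attractors are computed exactly on the
#' product space (drive phase, module state): every periodic orbit of the
#' pair `(g(t), y(t))` is returned, with the phase of each state recorded.
#' For a drive of period 1 this coincides with [attractors()] applied
#' after [substitute_steady_state()].
#'
#' @param module a `BooleanNetwork` (externals allowed).
#' @param drive a 0/1 matrix with one row per drive phase (period =
#'   number of rows) and one named column per external parameter.  A
#'   one-row matrix is a constant drive.
#' @param cap enumeration cap applied to period x 2^m product states.
#' @return a list of `DrivenAttractor` objects: each has `states` (matrix
#'   of module states along the orbit), `phases` (drive phase of each
#'   step, starting at phase 0) and `period`.
#' @export
driven_attractors <- function(module, drive, cap = default_cap()) {
  if (is.null(dim(drive))) drive <- matrix(drive, nrow = 1L,
                                           dimnames = list(NULL, names(drive)))
  p <- nrow(drive)
  if (p < 1L) stop("drive must have at least one phase", call. = FALSE)
  missing <- setdiff(module$externals, colnames(drive))
  if (length(missing)) {
    stop(sprintf("drive does not cover external(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  m <- n_vars(module)
  cap_check(m + ceiling(log2(max(p, 1L))), cap)
  n_states <- 2L^m
  # per-phase successor tables
  succ <- integer(p * n_states)
  for (ph in seq_len(p)) {
    bindings <- drive[ph, , drop = TRUE]
    if (length(module$externals)) {
      bindings <- stats::setNames(as.integer(drive[ph, module$externals]),
                                  module$externals)
    } else {
      bindings <- NULL
    }
    tt <- transition_table(module, bindings, cap = cap)
    nxt_ph <- ph %% p  # 0-based index of the next phase
    succ[(ph - 1L) * n_states + seq_len(n_states)] <- nxt_ph * n_states + tt
  }
  cycles <- find_cycles(succ)$cycles
  rows <- tt_rows(m)
  colnames(rows) <- module$variables
  lapply(cycles, function(cyc) {
    phases <- (cyc - 1L) %/% n_states
    ystates <- (cyc - 1L) %% n_states + 1L
    # rotate so the orbit starts at phase 0, smallest state among phase-0 steps
    zero <- which(phases == 0L)
    keys <- apply(rows[ystates[zero], , drop = FALSE], 1L, paste, collapse = "")
    start <- zero[order(keys)[1L]]
    idx <- c(seq(start, length(cyc)), seq_len(start - 1L))
    structure(list(states = rows[ystates[idx], , drop = FALSE],
                   phases = phases[idx],
                   period = length(cyc)),
              class = "DrivenAttractor")
  })
}

#' @export
print.DrivenAttractor <- function(x, ...) {
  strs <- apply(x$states, 1L, paste, collapse = "")
  cat(sprintf("DrivenAttractor (period %d): %s at phases %s\n", x$period,
              paste(strs, collapse = " -> "),
              paste(x$phases, collapse = ",")))
  invisible(x)
}

# a driven attractor under a period-1 drive is an ordinary attractor
as_attractor_from_driven <- function(d) {
  as_attractor(d$states)
}

#' Compose upstream and downstream attractors into full-network attractors
#'
#' Concatenates (direct sum) the states of an upstream attractor with the
#' states of each downstream orbit computed under the drive that the
#' upstream attractor induces.  When both sides have length greater than
#' one, the distinct phase alignments appear as distinct downstream orbits
#' and therefore as distinct composed attractors.
#'
#' @param upper_attractor an `Attractor` of the upstream (partial) network.
#' @param lower_attractors list of `DrivenAttractor` objects obtained from
#'   [driven_attractors()] with the drive read off `upper_attractor`.
#' @return a sorted list of `Attractor` objects over the concatenated
#'   variables.
#' @export
compose_attractors <- function(upper_attractor, lower_attractors) {
  out <- lapply(lower_attractors, function(d) {
    upper_rows <- upper_attractor$states[(d$phases %% upper_attractor$length) + 1L,
                                         , drop = FALSE]
    as_attractor(cbind(upper_rows, d$states))
  })
  sort_attractors(out)
}

#' Attractors via modular decomposition
#'
#' Computes the attractor set of an autonomous network compositionally:
#' modules are processed in topological order; each module is driven by
#' every attractor of the already-processed upstream part, its periodic
#' orbits are found on the product space, and the direct sums are
#' accumulated.  The result equals whole-network enumeration, but only
#' ever enumerates one module (times the drive period) at a time.
#'
#' @param network an autonomous `BooleanNetwork`.
#' @param cap per-module enumeration cap.
#' @return a sorted list of `Attractor` objects in original variable order.
#' @export
modular_attractors <- function(network, cap = default_cap()) {
  decomp <- decompose(network)
  vars_so_far <- character(0)
  # start from a single empty attractor over zero variables
  partial <- list(as_attractor(matrix(integer(0), nrow = 1L, ncol = 0L)))
  for (k in seq_along(decomp$modules)) {
    mod <- decomp$modules[[k]]
    emap <- attr(mod, "external_map")  # external name -> original variable
    nxt <- list()
    for (a in partial) {
      if (length(emap)) {
        drive <- a$states[, emap, drop = FALSE]
        colnames(drive) <- names(emap)
      } else {
        drive <- matrix(integer(0), nrow = a$length, ncol = 0L)
      }
      orbits <- driven_attractors(mod, drive, cap = cap)
      nxt <- c(nxt, compose_attractors(a, orbits))
    }
    partial <- nxt
    vars_so_far <- c(vars_so_far, decomp$variable_sets[[k]])
  }
  perm <- match(network$variables, vars_so_far)
  sort_attractors(lapply(partial, function(a) {
    as_attractor(a$states[, perm, drop = FALSE], variables = network$variables)
  }))
}
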