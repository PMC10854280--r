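#' Define a phenotype by marker variables
#'
#' A phenotype is an equivalence class of attractors that agree, in every
#' state, on a non-empty subset of marker variables.
#'
#' @param markers named 0/1 vector: names are the marker variables, values
#'   the required marker states (e.g. `c(Apoptosis = 1)`).
#' @return an object of class `Phenotype`.
#' @export
phenotype <- function(markers) {
  markers <- unlist(markers)
  if (!length(markers) || is.null(names(markers)) || any(!nzchar(names(markers)))) {
    stop("a phenotype needs at least one named marker", call. = FALSE)
  }
  structure(list(markers = names(markers),
                 values = check_binary(markers, "marker values")),
            class = "Phenotype")
}

#' @export
print.Phenotype <- function(x, ...) {
  cat("Phenotype:", paste(sprintf("%s=%d", x$markers, x$values), collapse = ", "),
      "\n")
  invisible(x)
}

#' Does an attractor display a phenotype?
#'
#' True when every state of the attractor matches the marker values; an
#' attractor whose markers oscillate matches no phenotype.
#'
#' @param attractor an `Attractor` whose state columns are named and cover
#'   the markers.
#' @param ph a [phenotype()].
#' @return `TRUE` or `FALSE`.
#' @export
phenotype_match <- function(attractor, ph) {
  missing <- setdiff(ph$markers, colnames(attractor$states))
  if (length(missing)) {
    stop(sprintf("attractor states do not cover marker(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  sub <- attractor$states[, ph$markers, drop = FALSE]
  all(sub == matrix(ph$values, nrow = nrow(sub), ncol = length(ph$values),
                    byrow = TRUE))
}

# module indices containing at least one marker
marker_modules <- function(decomp, ph) {
  unknown <- setdiff(ph$markers, decomp$network$variables)
  if (length(unknown)) {
    stop(sprintf("marker(s) not in the network: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  which(vapply(decomp$variable_sets, function(s) any(ph$markers %in% s),
               logical(1)))
}

#' Chain condition for module exclusion
#'
#' For candidate modules `i` (to be excluded) and `j` (holding the
#' decoupled bridge), the condition requires that the phenotype's markers
#' lie only in `j` or in modules `k` such that every directed path from
#' `i` to `k` in the quotient DAG passes through `j`; markers inside `i`
#' itself fail the condition.
#'
#' @param decomp a `ModularDecomposition`.
#' @param i,j module indices with `i` preceding `j`.
#' @param ph a [phenotype()].
#' @return `TRUE` or `FALSE`.
#' @export
chain_condition <- function(decomp, i, j, ph) {
  mm <- marker_modules(decomp, ph)
  if (i %in% mm) return(FALSE)
  g <- quotient_igraph(decomp)
  reach_full <- reachable_from(g, i)
  g_minus_j <- igraph::delete_vertices(g, j)
  # vertex ids shift after deletion; map old -> new
  old_ids <- setdiff(seq_len(length(decomp$modules)), j)
  reach_minus <- if (i == j) integer(0) else {
    old_ids[reachable_from(g_minus_j, match(i, old_ids))]
  }
  for (k in setdiff(mm, j)) {
    if (!(k %in% reach_full)) next       # untouched by module i
    if (k %in% reach_minus) return(FALSE)  # a path i -> k bypasses j
  }
  TRUE
}

reachable_from <- function(g, v) {
  as.integer(igraph::subcomponent(g, v, mode = "out"))
}

#' Canalizing-layer analysis of the nodes bridging two modules
#'
#' A bridging node of the DAG edge `i -> j` is a variable of module `j`
#' whose update function depends essentially on variables of module `i`.
#' For each bridging node the update function's layer decomposition is
#' computed and every regulator is tagged with its source module and layer
#' index (`Inf`-like convention: regulators in the core polynomial get
#' layer `r + 1`).  `ell` is the most dominant (smallest) layer index
#' holding a module-`i` regulator.
#'
#' @param decomp a `ModularDecomposition`.
#' @param i,j module indices joined by a quotient-DAG edge `i -> j`.
#' @return a list, one element per bridging node: `node`, `layers` (the
#'   `CanalizingLayers` of its update function), `regulators` (data frame
#'   with `variable`, `module`, `layer`), and `ell`.
#' @export
bridging_analysis <- function(decomp, i, j) {
  if (!any(decomp$quotient_dag$from == i & decomp$quotient_dag$to == j)) {
    stop(sprintf("no quotient-DAG edge M%d -> M%d", i, j), call. = FALSE)
  }
  si <- decomp$variable_sets[[i]]
  sj <- decomp$variable_sets[[j]]
  net <- decomp$network
  var_module <- function(v) {
    for (k in seq_along(decomp$variable_sets)) {
      if (v %in% decomp$variable_sets[[k]]) return(k)
    }
    NA_integer_
  }
  out <- list()
  for (x in sj) {
    f <- normalize_function(net$functions[[x]])
    regs_i <- intersect(f$inputs, si)
    if (!length(regs_i)) next
    cl <- layer_decomposition(f)
    r <- length(cl$layers)
    layer_of <- stats::setNames(rep(r + 1L, length(cl$inputs)), cl$inputs)
    for (d in seq_len(r)) {
      layer_of[cl$layers[[d]]$variable] <- d
    }
    regs <- data.frame(variable = cl$inputs,
                       module = vapply(cl$inputs, var_module, integer(1)),
                       layer = unname(layer_of[cl$inputs]),
                       stringsAsFactors = FALSE)
    ell <- min(regs$layer[regs$variable %in% regs_i])
    out[[length(out) + 1L]] <- list(node = x, layers = cl,
                                    regulators = regs, ell = ell)
  }
  out
}

#' Controls that decouple one module from a downstream module
#'
#' Proposes, for each bridging node `x` of the DAG edge `i -> j`,
#' controls that make the update function of `x` independent of all
#' module-`i` regulators:
#' * when module-`i` regulators sit in the most dominant layer of `f_x`,
#'   an edge control pinning such a regulator's edge into `x` to its
#'   canalizing input (which also fixes `f_x` to the layer's output);
#' * when some variable `y` outside module `i` sits in a layer more
#'   dominant than every module-`i` regulator, a node control fixing `y`
#'   to its canalizing input.
#'
#' Every proposal is verified exhaustively on the truth table of `f_x`:
#' with the control applied, `f_x` must be non-essential in all
#' module-`i` regulators.  Edge proposals are listed before node
#' proposals.
#'
#' @inheritParams bridging_analysis
#' @return a list of proposals, each a list with `control` (an
#'   `EdgeControl` or `NodeControl`), `bridging_node`, `route`
#'   (`"edge"` or `"node"`), `pins_to` (the value `f_x` is forced to, or
#'   `NA`) and `verified` (always `TRUE` for returned proposals).  Empty,
#'   with a `"diagnostic"` attribute, when no decoupling is possible.
#' @export
decoupling_controls <- function(decomp, i, j) {
  bridges <- bridging_analysis(decomp, i, j)
  si <- decomp$variable_sets[[i]]
  net <- decomp$network
  edge_props <- list()
  node_props <- list()
  for (br in bridges) {
    f <- normalize_function(net$functions[[br$node]])
    regs_i <- intersect(f$inputs, si)
    cl <- br$layers
    r <- length(cl$layers)
    verify <- function(pin_var, pin_val) {
      g <- pin_input(f, pin_var, pin_val)
      !any(vapply(regs_i, function(v) is_essential(g, v), logical(1)))
    }
    if (br$ell <= r && br$ell == 1L) {
      lay <- cl$layers[[1L]]
      for (idx in which(lay$variable %in% si)) {
        y <- lay$variable[idx]; a <- lay$input[idx]
        if (verify(y, a)) {
          edge_props[[length(edge_props) + 1L]] <-
            list(control = edge_control(y, br$node, a),
                 bridging_node = br$node, route = "edge",
                 pins_to = cl$outputs[1L], verified = TRUE)
        }
      }
    }
    if (br$ell > 1L) {
      for (d in seq_len(min(br$ell - 1L, r))) {
        lay <- cl$layers[[d]]
        for (idx in which(!(lay$variable %in% si))) {
          y <- lay$variable[idx]; a <- lay$input[idx]
          if (verify(y, a)) {
            node_props[[length(node_props) + 1L]] <-
              list(control = node_control(y, as.integer(a == 0L),
                                          as.integer(a == 1L)),
                   bridging_node = br$node, route = "node",
                   pins_to = if (d == 1L) cl$outputs[1L] else NA_integer_,
                   verified = TRUE)
          }
        }
      }
    }
  }
  out <- c(edge_props, node_props)
  if (!length(out)) {
    attr(out, "diagnostic") <- sprintf(
      "no canalizing decoupling of M%d from M%d: module-%d regulators sit in the core (or no dominant canalizing variable exists)",
      i, j, i)
  }
  out
}

#' Modules excludable from a phenotype control search
#'
#' Combines two exclusion routes:
#' * reachability: a module with no directed path to any marker module
#'   (and holding no marker itself) cannot affect the phenotype and is
#'   excluded outright;
#' * canalizing decoupling: a module `i` feeding a single downstream
#'   module `j` such that (1) bridging nodes exist, (2) every bridging
#'   node admits a verified decoupling control, and (3) after removing
#'   the edge `i -> j` the quotient DAG has no remaining path from `i`
#'   to any marker module (so the markers' dependence on `i` runs
#'   entirely through the decoupled bridge).
#'
#' @param decomp a `ModularDecomposition`.
#' @param ph a [phenotype()].
#' @param strict require a single bridging node per excluded module
#'   (the unrelaxed condition); by default multiple bridging nodes are
#'   handled by decoupling each one.
#' @return a list of `ExclusionReport` objects: lists with `module`,
#'   `route` (`"reachability"` or `"decoupling"`), and for the decoupling
#'   route `via_module`, `bridging_nodes`, `controls` (one verified
#'   proposal per bridging node, edge controls preferred) and
#'   `conditions` (flags for the three theorem conditions).
#' @export
excludable_modules <- function(decomp, ph, strict = FALSE) {
  mm <- marker_modules(decomp, ph)
  g <- quotient_igraph(decomp)
  n_mod <- length(decomp$modules)
  reports <- list()
  for (i in seq_len(n_mod)) {
    if (i %in% mm) next
    reach <- reachable_from(g, i)
    if (!any(mm %in% reach)) {
      reports[[length(reports) + 1L]] <-
        structure(list(module = i, route = "reachability"),
                  class = "ExclusionReport")
      next
    }
    succs <- decomp$quotient_dag$to[decomp$quotient_dag$from == i]
    for (j in succs) {
      # markers must be cut off from i once the i -> j edge is decoupled
      g_cut <- igraph::delete_edges(
        g, igraph::get_edge_ids(g, c(i, j)))
      still <- reachable_from(g_cut, i)
      cond_iii <- !any(mm %in% still)
      if (!cond_iii) next
      bridges <- bridging_analysis(decomp, i, j)
      cond_i <- length(bridges) >= 1L && (!strict || length(bridges) == 1L)
      if (!cond_i) next
      props <- decoupling_controls(decomp, i, j)
      nodes_covered <- unique(vapply(props, `[[`, character(1), "bridging_node"))
      bridge_nodes <- vapply(bridges, `[[`, character(1), "node")
      cond_ii <- all(bridge_nodes %in% nodes_covered)
      if (!cond_ii) next
      picks <- lapply(bridge_nodes, function(x) {
        cand <- Filter(function(p) p$bridging_node == x, props)
        cand[[1L]]  # edge proposals are listed first
      })
      reports[[length(reports) + 1L]] <-
        structure(list(module = i, route = "decoupling", via_module = j,
                       bridging_nodes = bridge_nodes,
                       controls = picks,
                       conditions = c(single_or_relaxed_bridge = cond_i,
                                      decoupling_verified = cond_ii,
                                      chain = cond_iii)),
                  class = "ExclusionReport")
      break
    }
  }
  reports
}

#' @export
print.ExclusionReport <- function(x, ...) {
  if (x$route == "reachability") {
    cat(sprintf("Module M%d excluded: no path to any marker module\n", x$module))
  } else {
    cat(sprintf("Module M%d excluded via decoupling from M%d\n",
                x$module, x$via_module))
    for (p in x$controls) {
      cat(sprintf("  bridge %s: %s%s\n", p$bridging_node,
                  control_label(p$control),
                  if (!is.na(p$pins_to))
                    sprintf(" (pins %s to %d)", p$bridging_node, p$pins_to)
                  else ""))
    }
  }
  invisible(x)
}
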