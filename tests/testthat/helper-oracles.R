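# Shared fixtures and independent oracles for the test suite.

# the three-variable demonstration network (two steady states, one 2-cycle)
toy3 <- function() {
  network_from_rules(c(x1 = "x2 & !x3", x2 = "x3", x3 = "!x1 & x2"))
}

# four variables, two strongly connected modules {x1,x2} -> {x3,x4}
modular4 <- function() {
  network_from_rules(c(x1 = "x2 & x1", x2 = "!x1",
                       x3 = "x1 | !x4", x4 = "(x1 & !x2) | (x3 & x4)"))
}

# two coupled feedback loops, the standard control example
twoloop4 <- function() {
  network_from_rules(c(x1 = "x2", x2 = "x1", x3 = "x2 & x4", x4 = "x3"))
}

disc_rule <- function() {
  bf_from_expression("Ceramide | (Fas & !FLIP)")
}

# random autonomous network: every variable gets 1..max_arity random
# regulators and a random function essential in all of them
random_network <- function(n, max_arity = 3L) {
  vars <- paste0("x", seq_len(n))
  funs <- lapply(seq_len(n), function(j) {
    k <- sample.int(min(max_arity, n), 1L)
    random_boolean_function(k, inputs = sort(sample(vars, k)))
  })
  names(funs) <- vars
  boolean_network(funs)
}

# Brute-force attractor oracle: build the successor map state by state with
# evaluate(), push every state forward 2^n steps (so it must land on its
# cycle), and read the cycles off the periodic points.  Independent of
# find_cycles()/transition_table() vectorisation.
oracle_attractors <- function(net) {
  n <- length(net$variables)
  N <- 2L^n
  states <- lapply(seq_len(N) - 1L, function(i) {
    bits <- as.integer(intToBits(i))[seq_len(n)]
    rev(bits)
  })
  succ <- vapply(states, function(s) {
    img <- evaluate(net, s)
    as.integer(sum(img * 2L^(n - seq_len(n)))) + 1L
  }, integer(1))
  pos <- seq_len(N)
  for (step in seq_len(N)) pos <- succ[pos]
  periodic <- sort(unique(pos))
  seen <- logical(N)
  cycles <- list()
  for (s in periodic) {
    if (seen[s]) next
    cyc <- s
    v <- succ[s]
    while (v != s) { cyc <- c(cyc, v); v <- succ[v] }
    seen[cyc] <- TRUE
    cycles[[length(cycles) + 1L]] <- cyc
  }
  lapply(cycles, function(cyc) {
    mat <- do.call(rbind, states[cyc])
    colnames(mat) <- net$variables
    as_attractor(mat)
  })
}

attractor_keyset <- function(atts) {
  sort(vapply(atts, function(a)
    paste(apply(a$states, 1L, paste, collapse = ""), collapse = ">"),
    character(1)))
}

expect_same_attractors <- function(a, b) {
  expect_identical(attractor_keyset(a), attractor_keyset(b))
}

# reduce a cyclic sequence to its primitive period and canonical rotation
canonical_cycle <- function(v) {
  n <- length(v)
  for (p in seq_len(n)) {
    if (n %% p == 0L && all(v == rep(v[seq_len(p)], n %/% p))) {
      v <- v[seq_len(p)]
      break
    }
  }
  rots <- vapply(seq_along(v), function(s) {
    paste(c(v[s:length(v)], v[seq_len(s - 1L)]), collapse = ">")
  }, character(1))
  min(rots)
}

# marker projections (as a set of primitive marker cycles) of an attractor
# list; projections are compared up to period replication and rotation
marker_projections <- function(atts, markers) {
  sort(unique(vapply(atts, function(a) {
    canonical_cycle(apply(a$states[, markers, drop = FALSE], 1L,
                          paste, collapse = ""))
  }, character(1))))
}
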