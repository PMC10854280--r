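# three-module chain used throughout: a two-variable oscillator feeding a
# death-receptor-style module, which feeds a self-sustaining marker node
chain_net <- function() {
  network_from_rules(c(
    Ceramide = "Fas2",
    Fas2 = "Ceramide",
    DISC = "Ceramide | (Fas & !FLIP)",
    Fas = "DISC",
    FLIP = "!DISC & FLIP",
    Apoptosis = "DISC | Apoptosis"
  ))
}

test_that("phenotype matching requires constant agreement on the markers", {
  ph <- phenotype(c(x4 = 1))
  a <- as_attractor(matrix(c(1L, 1L, 1L, 1L), 1L, 4L,
                           dimnames = list(NULL, paste0("x", 1:4))))
  expect_true(phenotype_match(a, ph))
  osc <- as_attractor(matrix(c(0L, 1L, 0L, 1L, 1L, 0L), 2L, 3L, byrow = TRUE,
                             dimnames = list(NULL, paste0("x", 1:3))))
  expect_false(phenotype_match(osc, phenotype(c(x1 = 1))))  # x1 oscillates
  expect_true(phenotype_match(osc, phenotype(c(x2 = 1))))   # x2 constant
  expect_error(phenotype(c()), "at least one")
  expect_error(phenotype_match(a, phenotype(c(zz = 1))), "cover")
})

test_that("the chain condition tracks paths through the bridge module", {
  d <- decompose(chain_net())
  ph <- phenotype(c(Apoptosis = 1))
  # markers downstream of the bridge: every path from M1 passes M2
  expect_true(chain_condition(d, 1, 2, ph))
  # markers inside the candidate module itself fail
  expect_false(chain_condition(d, 3, 3, phenotype(c(Apoptosis = 1))))
  expect_false(chain_condition(d, 1, 2, phenotype(c(Ceramide = 1))))

  # a bypass edge around the bridge violates the condition
  bypass <- network_from_rules(c(
    a = "b", b = "a",                 # M1
    c = "a | c2", c2 = "c",           # M2 (bridge)
    m = "c | a | m"                   # M3, also regulated directly by M1
  ))
  db <- decompose(bypass)
  expect_false(chain_condition(db, 1, 2, phenotype(c(m = 1))))
})

test_that("bridging analysis tags regulators with module and layer", {
  d <- decompose(chain_net())
  ba <- bridging_analysis(d, 1, 2)
  expect_length(ba, 1L)
  expect_equal(ba[[1]]$node, "DISC")
  expect_equal(ba[[1]]$ell, 1L)  # Ceramide leads the most dominant layer
  regs <- ba[[1]]$regulators
  expect_equal(regs$module[regs$variable == "Ceramide"], 1L)
  expect_equal(regs$layer[regs$variable == "Ceramide"], 1L)
  expect_equal(regs$layer[regs$variable == "Fas"], 2L)
  expect_error(bridging_analysis(d, 2, 1), "no quotient-DAG edge")
})

test_that("a second-layer upstream input yields ell = 2 and a node control", {
  # f_x = y & (e | z): upstream input e sits in the second layer under y
  net <- network_from_rules(c(
    e = "e2", e2 = "e",
    x = "y & (e | z)", y = "x", z = "!x & z"
  ))
  d <- decompose(net)
  ba <- bridging_analysis(d, 1, 2)
  expect_equal(ba[[1]]$node, "x")
  expect_equal(ba[[1]]$ell, 2L)
  props <- decoupling_controls(d, 1, 2)
  expect_gt(length(props), 0L)
  expect_true(all(vapply(props, function(p) p$route, character(1)) == "node"))
  # the proposed control fixes y to its canalizing input 0, forcing f_x == 0
  ctl <- props[[1]]$control
  expect_s3_class(ctl, "NodeControl")
  expect_equal(ctl$target, "y")
  expect_equal(ctl$mu_minus, 1L)  # y := 0
  f <- normalize_function(net$functions$x)
  pinned <- bncontrol:::pin_input(f, "y", 0L)
  expect_false(is_essential(pinned, "e"))
})

test_that("core-bound upstream regulators admit no decoupling", {
  net <- network_from_rules(c(
    e = "e2", e2 = "e",
    x = "(e & !y) | (!e & y)", y = "x"  # e enters x through an XOR core
  ))
  d <- decompose(net)
  props <- decoupling_controls(d, 1, 2)
  expect_length(props, 0L)
  expect_match(attr(props, "diagnostic"), "core")
})

test_that("decoupling proposals are sound on random modular networks", {
  set.seed(71)
  checked <- 0L
  for (rep in 1:30) {
    net <- generate_modular_network(c(2L, sample(2:3, 1L)), rbind(c(1L, 2L)),
                                    family = "ncf")
    d <- decompose(net)
    props <- decoupling_controls(d, 1, 2)
    si <- d$variable_sets[[1]]
    for (p in props) {
      f <- normalize_function(net$functions[[p$bridging_node]])
      pin_var <- if (inherits(p$control, "EdgeControl")) p$control$source
                 else p$control$target
      pin_val <- if (inherits(p$control, "EdgeControl")) p$control$value
                 else p$control$mu_plus
      g <- bncontrol:::pin_input(f, pin_var, pin_val)
      for (v in intersect(g$inputs, si)) {
        expect_false(is_essential(g, v))
      }
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 10L)
})

test_that("exclusion reports cover both routes on the chain network", {
  d <- decompose(chain_net())
  ph <- phenotype(c(Apoptosis = 1))
  reports <- excludable_modules(d, ph)
  mods <- vapply(reports, `[[`, integer(1), "module")
  routes <- vapply(reports, `[[`, character(1), "route")
  expect_true(1L %in% mods)
  r1 <- reports[[which(mods == 1L)]]
  expect_equal(r1$route, "decoupling")
  expect_equal(r1$via_module, 2L)
  expect_equal(r1$bridging_nodes, "DISC")
  ctl <- r1$controls[[1]]$control
  expect_s3_class(ctl, "EdgeControl")
  expect_equal(ctl$source, "Ceramide")
  expect_equal(ctl$target, "DISC")
  expect_equal(ctl$value, 1L)
  expect_equal(r1$controls[[1]]$pins_to, 1L)

  # a module downstream of the markers is excluded by reachability
  withtail <- network_from_rules(c(
    Ceramide = "Fas2", Fas2 = "Ceramide",
    DISC = "Ceramide | (Fas & !FLIP)", Fas = "DISC", FLIP = "!DISC & FLIP",
    Apoptosis = "DISC | Apoptosis",
    tail1 = "Apoptosis | tail2", tail2 = "tail1"
  ))
  dt <- decompose(withtail)
  rep_t <- excludable_modules(dt, ph)
  tail_mod <- which(vapply(dt$variable_sets, function(s) "tail1" %in% s,
                           logical(1)))
  rt <- Filter(function(r) r$module == tail_mod, rep_t)
  expect_length(rt, 1L)
  expect_equal(rt[[1]]$route, "reachability")
})

test_that("a single-module network has nothing to exclude", {
  d <- decompose(toy3())
  expect_length(excludable_modules(d, phenotype(c(x1 = 0))), 0L)
})

test_that("applying the decoupling control preserves the reachable phenotypes", {
  # with Ceramide ->1 DISC applied, the markers' attractor projections of
  # the full network equal those of the subnetwork without the upstream
  # module (externals of the cut bridge bound arbitrarily: DISC is pinned)
  net <- chain_net()
  d <- decompose(net)
  ph <- phenotype(c(Apoptosis = 1))
  r1 <- Filter(function(r) r$route == "decoupling",
               excludable_modules(d, ph))[[1]]
  cs <- control_set(r1$controls[[1]]$control)
  full_ctrl <- controlled_network(net, cs)
  proj_full <- marker_projections(attractors(full_ctrl), "Apoptosis")

  sub_vars <- unlist(d$variable_sets[-r1$module])
  sub <- restriction(net, sub_vars)
  # pin the bridge inside the subnetwork exactly as the edge control does
  sub_ctrl <- controlled_network(sub, control_set(
    edge_control("e_Ceramide", "DISC", 1L)))
  # the upstream external no longer matters; bind it to either constant
  for (b in 0:1) {
    proj_sub <- marker_projections(attractors(sub_ctrl,
                                              bindings = c(e_Ceramide = b)),
                                   "Apoptosis")
    expect_equal(proj_sub, proj_full)
  }
})

test_that("ancestor-closed subnetworks preserve the marker projections", {
  # dropping modules with no path to the markers never changes the set of
  # reachable marker patterns
  set.seed(72)
  for (rep in 1:15) {
    net <- generate_modular_network(c(2L, 2L, 2L), rbind(c(1L, 2L), c(1L, 3L)),
                                    family = sample(c("ncf", "uniform"), 1L))
    d <- decompose(net)
    marker <- d$variable_sets[[2]][1L]   # marker in module 2; module 3 is off-path
    keep <- unlist(d$variable_sets[1:2])
    sub <- restriction(net, keep)
    expect_length(sub$externals, 0L)
    expect_equal(marker_projections(attractors(sub), marker),
                 marker_projections(attractors(net), marker))
  }
})
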