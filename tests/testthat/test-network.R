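test_that("rule parsing tabulates LUTs and derives wiring", {
  net <- parse_rules("x* = x1 or x2\nx1* = x1\nx2* = x2")
  x <- net$nodes[["x"]]
  expect_equal(x$inputs, c("x1", "x2"))
  expect_equal(x$lut, c(0L, 1L, 1L, 1L))
  x1 <- net$nodes[["x1"]]
  expect_equal(x1$inputs, "x1")
  expect_equal(x1$lut, c(0L, 1L))
  expect_equal(nrow(net$edges), 4)

  expect_equal(n_nodes(grn), 6)
  expect_equal(nrow(grn$edges), 8)
  p1 <- grn$nodes[["P1"]]
  expect_equal(p1$inputs, c("g1", "P2"))
  expect_equal(p1$lut, c(0L, 0L, 1L, 0L))  # g1 and not P2
})

test_that("parser rejects bad input and prunes fictitious variables", {
  expect_error(parse_rules("a* = b"), "undefined")
  expect_error(parse_rules("a* = a\na* = not a"), "duplicate")
  expect_error(parse_rules("a* = a ~ a"), "unparseable")
  # y is fictitious in (x and y) or (x and not y)
  net <- parse_rules("x* = (x and y) or (x and not y)\ny* = y")
  expect_equal(net$nodes[["x"]]$inputs, "x")
  # constants
  net2 <- parse_rules("c* = 0\nd* = 1")
  expect_equal(length(net2$nodes[["c"]]$inputs), 0)
  expect_equal(net2$nodes[["c"]]$lut, 0L)
  expect_equal(net2$nodes[["d"]]$lut, 1L)
})

test_that("synchronous update follows the LUTs simultaneously", {
  cfg <- c(x = 0L, x1 = 1L, x2 = 0L)
  nxt <- synchronous_step(or_net, cfg)
  expect_equal(nxt[["x"]], 1L)
  expect_equal(nxt[["x1"]], 1L)

  zero <- stats::setNames(rep(0L, 6), node_names(grn))
  expect_equal(synchronous_step(grn, zero), zero)  # all-zero fixed point

  expect_error(synchronous_step(grn, zero[-1]), "missing")
  bad <- zero; bad[1] <- NA_integer_
  expect_error(synchronous_step(grn, bad), "full")
})

test_that("rule files round-trip through write_rules and the LUT table", {
  for (fixture in c("or_gate", "example_grn", "example_grn_lattice4")) {
    net <- load_fixture(fixture)
    back <- parse_rules(write_rules(net))
    expect_equal(node_names(back), node_names(net))
    for (v in node_names(net)) {
      expect_equal(back$nodes[[v]]$inputs, net$nodes[[v]]$inputs, info = v)
      expect_equal(back$nodes[[v]]$lut, net$nodes[[v]]$lut, info = v)
    }
    tab <- read_lut_table(strsplit(write_lut_table(net), "\n")[[1]])
    for (v in node_names(net)) {
      expect_equal(tab$nodes[[v]]$lut, net$nodes[[v]]$lut, info = v)
    }
  }
})

test_that("exhaustive stabilization oracle matches hand-derived cases", {
  # pinning the i1 input OFF drags the whole cascade OFF
  st <- brute_force_stabilization(grn, c(i1 = 0L))
  expect_mapequal(as.list(st),
                  list(g1 = 0L, g2 = 0L, i1 = 0L, P1 = 0L, P2 = 0L))
  # synergy case: P1 ON plus i2 ON locks g2 and P2 ON
  st2 <- brute_force_stabilization(grn, c(P1 = 1L, i2 = 1L))
  expect_equal(st2[["g2"]], 1L)
  expect_equal(st2[["P2"]], 1L)
  # a free self-copy input reaches both of its states: nothing stabilizes
  free <- parse_rules("a* = a\nb* = a")
  expect_length(brute_force_stabilization(free), 0)
  expect_error(brute_force_stabilization(generate_random_bn(8, 2, seed = 1),
                                         cap = 5), "cap")
})

test_that("stabilization output never contains both states of a variable", {
  for (seed in 1:20) {
    net <- generate_random_bn(8, 2, bias = 0.5, seed = seed)
    pin <- stats::setNames(seed %% 2L, sample(node_names(net), 1))
    st <- brute_force_stabilization(net, pin)
    expect_false(anyDuplicated(names(st)) > 0)
  }
})

test_that("attractor enumeration finds fixed points and cycles", {
  # two self-activators: four fixed points
  net <- parse_rules("a* = a\nb* = b")
  att <- enumerate_attractors(net)
  expect_length(att, 4)
  expect_true(all(vapply(att, nrow, integer(1)) == 1))
  # a negation loop: one 2-cycle
  net2 <- parse_rules("a* = not a")
  att2 <- enumerate_attractors(net2)
  expect_length(att2, 1)
  expect_equal(nrow(att2[[1]]), 2)
})

test_that("lattice composition replicates cells and rewires coupling", {
  # no coupling: disjoint union
  tmpl <- parse_rules("a* = b\nb* = a")
  lat <- compose_lattice(lattice_spec(tmpl, 4))
  expect_equal(n_nodes(lat), 8)
  expect_equal(lat$nodes[["a_3"]]$inputs, "b_3")

  # copy ring of 3 cells: attractors are the two constant states plus the
  # two rotation 3-cycles
  ring_t <- parse_rules("x* = xin\nxin* = xin")
  ring <- compose_lattice(lattice_spec(ring_t, 3,
                                       coupling = list(xin = "x[-1]"),
                                       boundary = "periodic"))
  expect_equal(n_nodes(ring), 3)
  att <- enumerate_attractors(ring)
  expect_equal(sort(vapply(att, nrow, integer(1))), c(1L, 1L, 3L, 3L))

  # open boundary rejects escaping offsets
  expect_error(compose_lattice(lattice_spec(ring_t, 3,
                                            coupling = list(xin = "x[-1]"),
                                            boundary = "open")),
               "boundary")
  expect_error(lattice_spec(ring_t, 3, coupling = list(zz = "x[-1]")),
               "missing")

  # the bundled 4-cell composition of the example network
  lat4 <- load_fixture("example_grn_lattice4")
  expect_equal(n_nodes(lat4), 20)
  expect_true(all(c("g1_1", "P2_4") %in% node_names(lat4)))
  # cell 1's g1 now reads the left neighbour's P2
  expect_equal(lat4$nodes[["g1_1"]]$inputs, "P2_4")
})

test_that("random network generation is seeded and well-formed", {
  a <- generate_random_bn(5, 2, bias = 0.5, seed = 42)
  b <- generate_random_bn(5, 2, bias = 0.5, seed = 42)
  expect_identical(write_rules(a), write_rules(b))
  expect_true(all(vapply(a$nodes, function(nd) length(nd$lut), integer(1)) == 4))
  c <- generate_random_bn(5, 2, bias = 0.5, seed = 43)
  expect_false(identical(write_rules(a), write_rules(c)))
  expect_error(generate_random_bn(5, 7), "k must")
  expect_error(generate_random_bn(5, 2, bias = 2), "bias")
  # generator must not disturb the global RNG stream
  set.seed(99); x1 <- stats::runif(1)
  set.seed(99); invisible(generate_random_bn(5, 2, seed = 7))
  x2 <- stats::runif(1)
  expect_identical(x1, x2)
})

test_that("bias-1 networks unfold every reachable ON state from any seed", {
  net <- generate_random_bn(6, 2, bias = 1, seed = 3)
  dcm <- build_dcm(net)
  pm <- unfold(dcm, "x1-1")
  on_units <- paste0(node_names(net), "-1")
  expect_true(all(on_units %in% pm$module_set))
})
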