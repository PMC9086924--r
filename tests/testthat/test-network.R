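# Graph representation, cycle basis, Kirchhoff solver and the
# series-parallel reduction oracle.

simple_series_net <- function() {
  net <- mf_network(fluid(5, interfacial_tension = 0.05))
  net <- add_node(net, "a", role = "inlet")
  net <- add_node(net, "b")
  net <- add_node(net, "c", role = "outlet")
  net <- add_channel(net, "c1", "a", "b", 1000, 100, 50)
  net <- add_channel(net, "c2", "b", "c", 2000, 100, 50)
  net <- add_pressure_source(net, "src", "c", "a", 50)
  set_reference(net, "c")
}

test_that("cycle basis has the cyclomatic number of cycles", {
  # a pure series path + source forms a single loop
  net <- simple_series_net()
  cb <- cycle_basis(net)
  expect_length(cb, 1L)
  expect_setequal(cb[[1]]$edge, c("c1", "c2", "src"))
  # two parallel branches: |E| - |V| + 1 = 3 - 2 + 1 = 2
  expect_length(cycle_basis(two_branch_net()), 2L)
  # random connected graph: 20 edges, 12 nodes -> 9 independent cycles
  doc <- generate_test_network("random", 20, seed = 11)
  net_r <- realize_network_document(doc)$network
  expect_identical(nrow(net_r$edges) - nrow(net_r$nodes) + 1L, 9L)
  expect_length(cycle_basis(net_r), 9L)
  # every fundamental cycle closes: signed pressure drops cancel on solve
  fs <- solve_flow(net_r)
  expect_lt(fs$residuals$cycle, 1e-9)
})

test_that("a single channel with a pressure source reproduces Q = dP / R", {
  net <- mf_network(fluid(5, interfacial_tension = 0.05))
  net <- add_node(net, "a", role = "inlet")
  net <- add_node(net, "b", role = "outlet")
  net <- add_channel(net, "c1", "a", "b", 1000, 100, 50)
  net <- add_pressure_source(net, "p1", "b", "a", 50)
  net <- set_reference(net, "b")
  fs <- solve_flow(net)
  R <- rect_channel_resistance(channel_geometry(1000, 100, 50), 5)
  expect_identical(fs$si$Q[1], to_si(50, "pressure") / R)
  expect_equal(fs$edges$dP[fs$edges$id == "c1"], 50)
  expect_equal(fs$nodes$P[fs$nodes$id == "a"], 50)
})

test_that("parallel branches split by conductance", {
  fs <- solve_flow(two_branch_net(c(1, 1)))
  q <- fs$si$Q[1:2]
  expect_equal(q[1], q[2], tolerance = 1e-12)
  # resistances R and 2R -> flows 2:1
  fs2 <- solve_flow(two_branch_net(c(1, 2)))
  q2 <- fs2$si$Q[1:2]
  expect_equal(q2[1] / q2[2], 2, tolerance = 1e-12)
})

test_that("raising one branch resistance strictly lowers its flow and the
total delivered flow", {
  fs_before <- solve_flow(two_branch_net(c(1, 1)))
  fs_after <- solve_flow(two_branch_net(c(1, 1.7)))
  expect_lt(abs(fs_after$si$Q[2]), abs(fs_before$si$Q[2]))
  i_src <- 3L
  expect_lt(abs(fs_after$si$Q[i_src]), abs(fs_before$si$Q[i_src]))
})

test_that("flows on ladder networks match the recursive series-parallel
reduction and the nodal-analysis oracle", {
  for (seed in 1:8) {
    k <- 2 + (seed %% 5)
    net <- random_ladder_net(k, seed)
    fs <- solve_flow(net)
    expect_lt(fs$residuals$node, 1e-9)
    expect_lt(fs$residuals$cycle, 1e-9)
    # equivalent resistance from the solver vs recursive reduction
    Req <- reduce_series_parallel(net, "n0", "g")
    src_q <- fs$si$Q[net$edges$kind == "pressure_source"]
    expect_equal(to_si(50, "pressure") / src_q, Req, tolerance = 1e-9)
    # full flow vector against the independent nodal formulation
    nod <- oracle_nodal_flow(net)
    expect_equal(fs$si$Q, nod$Q, tolerance = 1e-9)
    expect_equal(fs$si$P, nod$P, tolerance = 1e-9)
  }
})

test_that("random connected networks solve with tight conservation and cycle
residuals and agree with the nodal oracle", {
  for (seed in 1:25) {
    doc <- generate_test_network("random", 10 + (seed * 7) %% 40, seed = seed)
    net <- realize_network_document(doc)$network
    fs <- solve_flow(net)
    expect_lt(fs$residuals$node, 1e-9)
    expect_lt(fs$residuals$cycle, 1e-9)
    nod <- oracle_nodal_flow(net)
    expect_equal(fs$si$Q, nod$Q, tolerance = 1e-8)
  }
})

test_that("the physical flow state is invariant under node and edge
relabelling", {
  set.seed(1)
  doc <- generate_test_network("random", 18, seed = 3)
  net <- realize_network_document(doc)$network
  fs1 <- solve_flow(net)
  net2 <- net
  perm_nodes <- paste0("x_", rev(net$nodes$id))
  names(perm_nodes) <- net$nodes$id
  net2$nodes$id <- unname(perm_nodes[net$nodes$id])
  net2$edges$from <- unname(perm_nodes[net$edges$from])
  net2$edges$to <- unname(perm_nodes[net$edges$to])
  net2$reference <- unname(perm_nodes[net$reference])
  sh <- sample(nrow(net2$edges))
  net2$edges <- net2$edges[sh, ]
  net2$edges$id <- paste0("y_", net2$edges$id)
  fs2 <- solve_flow(net2)
  m <- match(paste0("y_", net$edges$id), fs2$edges$id)
  expect_equal(fs2$si$Q[m], fs1$si$Q, tolerance = 1e-9)
})

test_that("flow sources fix their edge flow and the rest follows Kirchhoff",
{
  net <- mf_network(fluid(5, interfacial_tension = 0.05))
  net <- add_node(net, "a", role = "inlet")
  net <- add_node(net, "b")
  net <- add_node(net, "c", role = "outlet")
  net <- add_channel(net, "c1", "a", "b", 1000, 100, 50)
  net <- add_channel(net, "c2", "b", "c", 1500, 100, 50)
  net <- add_channel(net, "c3", "b", "c", 1500, 100, 50)
  net <- add_flow_source(net, "pump", "c", "a", 3)
  net <- set_reference(net, "c")
  fs <- solve_flow(net)
  expect_equal(fs$edges$Q[fs$edges$id == "pump"], 3, tolerance = 1e-12)
  expect_equal(fs$edges$Q[fs$edges$id == "c1"], 3, tolerance = 1e-9)
  expect_equal(fs$edges$Q[fs$edges$id == "c2"], 1.5, tolerance = 1e-9)
  nod <- oracle_nodal_flow(net)
  expect_equal(fs$si$Q, nod$Q, tolerance = 1e-9)
})

test_that("structural defects raise diagnostic errors", {
  net <- mf_network(fluid(5, interfacial_tension = 0.05))
  net <- add_node(net, c("a", "b", "c", "d"))
  net <- add_channel(net, "c1", "a", "b", 1000, 100, 50)
  net <- add_channel(net, "c2", "c", "d", 1000, 100, 50)
  net <- add_pressure_source(net, "p", "b", "a", 10)
  net <- set_reference(net, "b")
  expect_error(solve_flow(net), "disconnected")
  net3 <- mf_network(fluid(5, interfacial_tension = 0.05))
  net3 <- add_node(net3, c("a", "b"))
  net3 <- add_channel(net3, "c1", "a", "b", 1000, 100, 50)
  expect_error(solve_flow(net3), "source")
  net4 <- add_pressure_source(net3, "p", "b", "a", 10)
  expect_error(solve_flow(net4), "reference")
  expect_error(add_channel(net3, "c1", "a", "b", 1000, 100, 50), "duplicate")
  expect_error(add_node(net3, "a"), "duplicate")
})

test_that("series-parallel reduction handles the base cases and flags
irreducible topologies", {
  net <- simple_series_net()
  R1 <- rect_channel_resistance(channel_geometry(1000, 100, 50), 5)
  R2 <- rect_channel_resistance(channel_geometry(2000, 100, 50), 5)
  expect_equal(reduce_series_parallel(net, "a", "c"), R1 + R2,
               tolerance = 1e-12)
  netp <- two_branch_net(c(1, 1))
  expect_equal(reduce_series_parallel(netp, "s", "t"), R1 / 2,
               tolerance = 1e-12)
  # Wheatstone bridge is not series-parallel
  wb <- mf_network(fluid(5, interfacial_tension = 0.05))
  wb <- add_node(wb, c("s", "a", "b", "t"))
  wb <- add_channel(wb, "e1", "s", "a", 1000, 100, 50)
  wb <- add_channel(wb, "e2", "s", "b", 1200, 100, 50)
  wb <- add_channel(wb, "e3", "a", "t", 1400, 100, 50)
  wb <- add_channel(wb, "e4", "b", "t", 1600, 100, 50)
  wb <- add_channel(wb, "e5", "a", "b", 1800, 100, 50)
  wb <- add_pressure_source(wb, "p", "t", "s", 50)
  wb <- set_reference(wb, "t")
  expect_error(reduce_series_parallel(wb, "s", "t"),
               class = "dropnet_not_reducible")
  # ... but the main solver handles it fine and matches the nodal oracle
  fs <- solve_flow(wb)
  expect_lt(fs$residuals$node, 1e-9)
  expect_equal(fs$si$Q, oracle_nodal_flow(wb)$Q, tolerance = 1e-9)
})
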