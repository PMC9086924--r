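# Event-driven engine: kinematics, routing, bookkeeping, caching,
# determinism and the dense fixed-step integration oracle.

series_path_net <- function(pressure = 50) {
  net <- mf_network(fluid(5, interfacial_tension = 0.05))
  net <- add_node(net, "in", role = "inlet")
  net <- add_node(net, "m")
  net <- add_node(net, "out", role = "outlet")
  net <- add_channel(net, "c1", "in", "m", 2000, 100, 50)
  net <- add_channel(net, "c2", "m", "out", 3000, 100, 50)
  net <- add_pressure_source(net, "src", "out", "in", pressure)
  set_reference(net, "out")
}

fork_net <- function(L2 = 1500, L3 = 3000) {
  net <- mf_network(fluid(5, interfacial_tension = 0.05))
  net <- add_node(net, "in", role = "inlet")
  net <- add_node(net, "m")
  net <- add_node(net, "out", role = "outlet")
  net <- add_channel(net, "stem", "in", "m", 1000, 100, 50)
  net <- add_channel(net, "armA", "m", "out", L2, 100, 50)
  net <- add_channel(net, "armB", "m", "out", L3, 100, 50)
  net <- add_pressure_source(net, "src", "out", "in", 50)
  set_reference(net, "out")
}

test_that("an empty schedule leaves the flow state constant with no events",
{
  net <- series_path_net()
  sim <- simulate_droplets(net, NULL)
  expect_identical(sim$stats$n_events, 0L)
  expect_identical(sim$stats$n_solves, 1L)
  expect_identical(sim$stats$injected, 0L)
  expect_identical(sim$stats$stop_reason, "end_of_events")
  bare <- solve_flow(net)
  expect_equal(as.vector(sim$flow_states$Q[1, ]), bare$edges$Q,
               tolerance = 1e-12)
})

test_that("droplet-free flow equals the bare network and one droplet on one
of two equal branches strictly reduces that branch's flow", {
  net <- fork_net(1500, 1500)
  st <- init_simulation(net, injection_schedule(0, "in", 250, 90))
  f0 <- compute_flow_state(st)
  expect_equal(f0$Q, solve_flow(net)$si$Q, tolerance = 1e-12)
  qA0 <- f0$Q[match("armA", net$edges$id)]
  ev <- next_event_time(st, f0)
  advance_state(st, ev, f0)                    # inject onto the stem
  repeat {                                     # march until it sits on an arm
    fl <- compute_flow_state(st)
    if (!is.na(st$drop$edge[1]) &&
        net$edges$id[st$drop$edge[1]] %in% c("armA", "armB")) break
    ev <- next_event_time(st, fl)
    advance_state(st, ev, fl)
  }
  arm <- net$edges$id[st$drop$edge[1]]
  fl <- compute_flow_state(st)
  expect_lt(abs(fl$Q[match(arm, net$edges$id)]), abs(qA0))
})

test_that("single-droplet residence times follow the slip kinematics
t = L / (slip * Q / (w h))", {
  net <- series_path_net()
  sim <- simulate_droplets(net, injection_schedule(0, "in", 250, 90))
  expect_identical(sim$droplets$status[1], "exited")
  res <- sim$residence
  # flow while the droplet sat on each channel, from the recorded states
  for (ce in c("c1", "c2")) {
    row <- res[res$edge == ce, ]
    i <- max(which(sim$flow_states$time <= row$enter + 1e-12))
    Q <- to_si(unname(sim$flow_states$Q[i, ce]), "flow")
    L <- net$edges$length[net$edges$id == ce]
    v <- 1.28 * Q / (100e-6 * 50e-6)
    expect_equal(row$residence, unname(L / v), tolerance = 1e-9)
  }
})

test_that("next_event_time returns the boundary-hit minimum and injections
compete with transitions", {
  net <- series_path_net()
  st <- init_simulation(net, injection_schedule(c(0, 10), "in", 250, 90))
  fl <- compute_flow_state(st)
  ev <- next_event_time(st, fl)
  expect_identical(ev$kind, "injection")
  expect_equal(ev$time, 0)
  advance_state(st, ev, fl)
  fl <- compute_flow_state(st)
  # droplet mid-channel: time to boundary = remaining length / droplet speed
  st$drop$pos[1] <- 0.5
  ev2 <- next_event_time(st, fl)
  e <- st$drop$edge[1]
  v <- 1.28 * fl$Q[e] / (100e-6 * 50e-6)
  expect_identical(ev2$kind, "transition")
  expect_equal(ev2$time - st$time, 0.5 * net$edges$length[e] / v,
               tolerance = 1e-12)
  # a transition occurring before the next injection wins
  expect_lt(ev2$time, 10)
})

test_that("routing picks the highest outgoing flow, breaks exact ties by
edge order, and follows the only channel when there is one", {
  net <- fork_net(1500, 3000)   # armA carries more flow
  st <- init_simulation(net, injection_schedule(0, "in", 250, 90))
  fl <- compute_flow_state(st)
  expect_identical(route_droplet(st, "m", fl, exclude = "stem"), "armA")
  expect_identical(route_droplet(st, "in", fl), "stem")
  tie <- fork_net(2000, 2000)   # identical arms
  st2 <- init_simulation(tie, injection_schedule(0, "in", 250, 90))
  fl2 <- compute_flow_state(st2)
  iA <- match("armA", tie$edges$id); iB <- match("armB", tie$edges$id)
  expect_equal(fl2$Q[iA], fl2$Q[iB], tolerance = 1e-12)
  # force a bitwise-exact tie and check the deterministic break
  fl2$Q[iB] <- fl2$Q[iA]
  expect_identical(route_droplet(st2, "m", fl2, exclude = "stem"), "armA")
})

test_that("droplets are conserved across statuses and the flow state is
solved exactly once per event", {
  tw <- build_trapwell_network(trapwell_params(n_pairs = 2))
  sch <- alternating_schedule(c("in1", "in2"), 6)
  sim <- simulate_droplets(tw, sch)
  s <- sim$stats
  expect_identical(s$injected,
                   s$flowing + s$trapped + s$merged + s$exited + s$stalled)
  expect_identical(s$injected, 6L)
  expect_identical(s$n_solves, s$n_events + 1L)
  # cached state is reused without a re-solve
  st <- init_simulation(tw, sch)
  f1 <- compute_flow_state(st)
  f2 <- compute_flow_state(st)
  expect_identical(st$n_solves, 1L)
  expect_identical(f1, f2)
})

test_that("identical inputs give identical event logs and flow records", {
  tw <- build_trapwell_network(trapwell_params(n_pairs = 2))
  sch <- alternating_schedule(c("in1", "in2"), 4)
  s1 <- simulate_droplets(tw, sch)
  s2 <- simulate_droplets(tw, sch)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$objective_log, s2$objective_log)
  expect_identical(s1$flow_states, s2$flow_states)
})

test_that("event-driven exit times match a dense fixed-step integrator within
0.1 percent", {
  # network 1: series path, two droplets
  net <- series_path_net()
  sch <- injection_schedule(c(0, 0.05), "in", 250, 90)
  sim <- simulate_droplets(net, sch)
  t_exit <- sim$events$time[sim$events$kind == "exit"]
  # shortest single-channel transit sets the oracle step
  transit <- min(sim$residence$residence, na.rm = TRUE)
  orc <- oracle_fixed_step(net, sch, dt = transit * 1e-4, t_max = 5)
  expect_identical(sim$droplets$status, c("exited", "exited"))
  expect_equal(sort(t_exit), sort(orc$exit_time), tolerance = 1e-3)

  # network 2: fork with unequal arms, three droplets (8 edges incl. source)
  net2 <- fork_net(1500, 2600)
  sch2 <- injection_schedule(c(0, 0.04, 0.08), "in", 250, 90)
  sim2 <- simulate_droplets(net2, sch2)
  transit2 <- min(sim2$residence$residence, na.rm = TRUE)
  orc2 <- oracle_fixed_step(net2, sch2, dt = transit2 * 1e-4, t_max = 5)
  t2 <- sim2$events$time[sim2$events$kind == "exit"]
  expect_length(t2, 3L)
  expect_equal(sort(t2), sort(orc2$exit_time), tolerance = 1e-3)
})

test_that("exits decrement edge counts and stalls are signalled", {
  net <- series_path_net()
  sim <- simulate_droplets(net, injection_schedule(0, "in", 250, 90))
  expect_true(all(sim$final_state$count == 0L))
  ev <- sim$events
  expect_identical(ev$kind[nrow(ev)], "exit")
  expect_identical(ev$node[nrow(ev)], "out")
})
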