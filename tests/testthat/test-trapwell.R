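# Trap-well case study: fixture construction, working principle and the
# design-exploration drivers.

test_that("the cascade template has the closed-form node and edge counts", {
  for (n in c(1L, 3L, 5L)) {
    net <- build_trapwell_network(trapwell_params(n_pairs = n))
    expect_identical(nrow(net$nodes), 8L * n + 4L)
    expect_identical(nrow(net$edges), 13L * n + 5L)
    # one flow-ratio and one downstream objective per well, one inter-trap
    # objective per pair
    expect_length(net$objectives, 5L * n)
  }
  # shared-manifold topology adds one link per pair
  net_sh <- build_trapwell_network(
    trapwell_params(n_pairs = 2, bypass_topology = "shared"))
  expect_identical(nrow(net_sh$edges), 13L * 2L + 5L + 2L)
  expect_lt(solve_flow(net_sh)$residuals$node, 1e-9)
})

test_that("the two streams are constructively symmetric", {
  net <- build_trapwell_network(trapwell_params(n_pairs = 3))
  fs <- solve_flow(net)
  for (k in 1:3) {
    for (base in c("ent", "byp", "gapA")) {
      q1 <- fs$edges$Q[fs$edges$id == sprintf("%s_%d_1", base, k)]
      q2 <- fs$edges$Q[fs$edges$id == sprintf("%s_%d_2", base, k)]
      expect_equal(q1, q2, tolerance = 1e-9)
    }
  }
  # the intersection carries essentially no flow in the symmetric state
  qix <- fs$edges$Q[fs$edges$id == "ix_1"]
  expect_lt(abs(qix), 1e-6 * abs(fs$edges$Q[fs$edges$id == "ent_1_1"]))
})

test_that("parameter validation rejects broken specifications", {
  expect_error(trapwell_params(gap_width = 120), "gap_width")
  expect_error(trapwell_params(channel_height = 120), "section ratio")
  expect_error(trapwell_params(n_pairs = 0), "n_pairs")
  expect_error(trapwell_params(inlet_pressure = -5), "positive")
  expect_warning(trapwell_params(droplet_radius = 150), "trap radius")
})

test_that("the trap-pair working principle plays out: capture, ratio flip,
bypass of the follower, pairwise merge", {
  p <- trapwell_params(n_pairs = 1)
  net <- build_trapwell_network(p)
  # two droplets on the same stream: the first is trapped, the second must
  # take the bypass once the trap is occupied, and exits
  sim <- simulate_droplets(net, injection_schedule(c(0, 0.3), "in1", 250, 90))
  expect_identical(sim$droplets$status, c("trapped", "exited"))
  expect_identical(sim$droplets$trap[1], "t1_s1")
  rl <- sim$objective_log
  r1 <- rl[rl$id == "ratio_t1_s1", ]
  t_capture <- sim$events$time[sim$events$kind == "trap_capture"][1]
  expect_gt(min(r1$measured[r1$time < t_capture]), 1)    # trap favoured
  expect_lt(max(r1$measured[r1$time >= t_capture]), 1)   # flipped after
  expect_true(all(rl$pass))
  d2 <- sim$events[sim$events$droplet == 2 & !is.na(sim$events$droplet), ]
  expect_true("byp_1_1" %in% d2$edge_to)
  # alternating streams: both wells fill and the pair merges
  sim2 <- simulate_droplets(net, alternating_schedule(c("in1", "in2"), 2))
  expect_identical(sim2$droplets$status, c("merged", "merged"))
  expect_identical(unname(sim2$stats$merged), 2L)
})

test_that("a generously long bypass keeps every squeeze check clean while a
tiny interfacial tension fails the inter-trap condition under asymmetric
pressure", {
  # large interfacial tension: thresholds dwarf any finite pressure here
  p_hi <- trapwell_params(n_pairs = 1,
                          fluid = fluid(5, 1, interfacial_tension = 10))
  st <- init_simulation(build_trapwell_network(p_hi))
  rep_hi <- check_objectives(st)
  expect_true(all(rep_hi$pass))
  # near-zero tension + strongly asymmetric inlet pressures: the inter-trap
  # pressure difference exceeds the Laplace threshold
  p_lo <- trapwell_params(n_pairs = 1, inlet_pressure = c(300, 5),
                          fluid = fluid(5, 1, interfacial_tension = 1e-4))
  st2 <- init_simulation(build_trapwell_network(p_lo))
  rep_lo <- check_objectives(st2)
  inter <- rep_lo[rep_lo$type == "squeeze_intertrap", ]
  expect_false(any(inter$pass))
  expect_gt(inter$measured[1], inter$threshold[1])
})

test_that("objectives referencing absent network elements are configuration
errors", {
  net <- build_trapwell_network(trapwell_params(n_pairs = 1))
  net$objectives <- list(list(id = "bad", type = "flow_ratio",
                              trap_edge = "nope", bypass_edge = "byp_1_1",
                              trap = "t1_s1"))
  expect_error(init_simulation(net), "absent")
  net$objectives <- list(list(id = "bad2", type = "squeeze_downstream",
                              node_a = "missing", node_b = "D_1_1",
                              gap_width = 15, radius = 100))
  expect_error(init_simulation(net), "absent")
})

test_that("the minimal bypass length brackets, orders with gap width and is
stable under step halving", {
  p15 <- trapwell_params(gap_width = 15, n_pairs = 2)
  p25 <- trapwell_params(gap_width = 25, n_pairs = 2)
  mb15 <- min_bypass_length(p15, range = c(500, 4000), step = 200)
  mb25 <- min_bypass_length(p25, range = c(300, 4000), step = 200)
  expect_lt(as.numeric(mb25), as.numeric(mb15))
  # boundary definition: one step below the result the droplet bypasses
  scan <- attr(mb15, "scan")
  below <- scan[scan$bypass_length < as.numeric(mb15), , drop = FALSE]
  expect_true(nrow(below) >= 1 && !any(below$trapped))
  expect_true(all(scan$trapped[scan$bypass_length >= as.numeric(mb15)]))
  # halving the step moves the estimate by at most one (coarse) step
  mb15b <- min_bypass_length(p15, range = c(500, 4000), step = 100)
  expect_lte(abs(as.numeric(mb15b) - as.numeric(mb15)), 200)
  # a range that does not bracket the transition errors out
  expect_error(min_bypass_length(p15, range = c(3500, 4000), step = 100),
               "bracket")
})

test_that("the maximal pressure boundary is self-consistent and limited by a
squeeze objective", {
  p <- trapwell_params(n_pairs = 2)
  mp <- max_pressure(p, range = c(50, 800), step = 50)
  expect_true(attr(mp, "limiting") %in%
                c("squeeze_downstream", "squeeze_intertrap"))
  scan <- attr(mp, "scan")
  expect_true(all(scan$clean[scan$pressure <= as.numeric(mp)]))
  expect_false(scan$clean[nrow(scan)])  # one step beyond violates
  expect_error(max_pressure(p, range = c(50, 6000), step = 50), "5 bar")
  expect_error(max_pressure(p, range = c(50, 100), step = 50), "bracket")
})

test_that("a single immediate pair load matches hand kinematics from the
solved flow states", {
  p <- trapwell_params(n_pairs = 1)
  sch <- injection_schedule(c(0, 1), c("in1", "in2"), 250, 90)
  net <- build_trapwell_network(p)
  sim <- simulate_droplets(net, sch)      # full flow-state record
  lt <- loading_time(p, schedule = sch)
  # droplet 2 transits inlet2 and ent_1_2 in the stationary post-capture
  # configuration; hand-sum its two residence times
  res2 <- sim$residence[sim$residence$droplet == 2, ]
  expect_identical(res2$edge[1:2], c("inlet2", "ent_1_2"))
  res2 <- res2[1:2, ]                     # the chamber stay is open-ended
  t_hand <- 1 + sum(res2$residence)
  t_merge <- sim$events$time[sim$events$kind == "merge"]
  expect_equal(lt$loading_time, t_merge - 0, tolerance = 1e-12)
  expect_equal(t_merge, t_hand, tolerance = 1e-9)
  # and each residence is L / (slip * Q / (w h)) under the then-valid flow
  for (i in seq_len(nrow(res2))) {
    row <- res2[i, ]
    k <- max(which(sim$flow_states$time <= row$enter + 1e-12))
    Q <- to_si(unname(sim$flow_states$Q[k, row$edge]), "flow")
    L <- unname(net$edges$length[net$edges$id == row$edge])
    expect_equal(row$residence, L / (1.28 * Q / (100e-6 * 50e-6)),
                 tolerance = 1e-9)
  }
})

test_that("loading time grows with cascade depth and shrinks with pressure",
{
  p <- trapwell_params()
  lt_a <- loading_time(p, n_pairs = 2, pressure = 100)
  lt_b <- loading_time(p, n_pairs = 4, pressure = 100)
  expect_gt(lt_b$loading_time, lt_a$loading_time)
  lt_c <- loading_time(p, n_pairs = 2, pressure = 200)
  expect_lt(lt_c$loading_time, lt_a$loading_time)
})

test_that("incomplete loading raises the timeout diagnostic with partial
occupancy", {
  # a bypass far below its minimal length: the first droplets skip the traps
  p_bad <- trapwell_params(n_pairs = 2, bypass_length = 600)
  expect_error(loading_time(p_bad, t_cap = 5), class = "dropnet_timeout")
  cond <- tryCatch(loading_time(p_bad, t_cap = 5),
                   dropnet_timeout = function(e) e)
  expect_true(!is.null(cond$occupancy))
})

test_that("sequential filling: wells fill upstream to downstream and every
pair ends merged", {
  p <- trapwell_params(n_pairs = 3)
  lt <- loading_time(p, pressure = 100)
  sim <- lt$sim
  expect_identical(unname(sim$stats$merged), 6L)
  caps <- sim$events[sim$events$kind == "trap_capture", , drop = FALSE]
  pair_of <- as.integer(sub("^t(\\d+)_s\\d$", "\\1",
                            sim$droplets$trap[caps$droplet]))
  for (s in 1:2) {
    tr_s <- caps[grepl(sprintf("_s%d$", s), sim$droplets$trap[caps$droplet]), ]
    ord <- pair_of[match(tr_s$droplet, caps$droplet)]
    expect_true(!is.unsorted(ord))
  }
  expect_identical(sim$stats$violations, 0L)
})

test_that("the robustness report mirrors the qualitative grid assessment", {
  specs <- list(
    trapwell_params(bypass_length = 3000, gap_width = 15, n_pairs = 2),
    trapwell_params(bypass_length = 4000, gap_width = 15, n_pairs = 2),
    trapwell_params(bypass_length = 5000, gap_width = 25, n_pairs = 2)
  )
  rep <- robustness_report(specs, ratio_margin = 2, pressure_margin = 150,
                           bypass_threshold = 5000,
                           pressure_range = c(25, 800),
                           pressure_step = 25,
                           bypass_range = c(400, 6000), bypass_step = 250)
  expect_identical(nrow(rep), 3L)
  expect_true(all(c("flow_ratio", "max_pressure", "min_bypass",
                    "problems") %in% names(rep)))
  # wider gaps trap more easily: higher flow ratio, but less pressure headroom
  expect_gt(rep$flow_ratio[3], rep$flow_ratio[1])
  expect_lt(rep$max_pressure[3], rep$max_pressure[2])
  expect_match(rep$problems[3], "throughput")
  expect_match(rep$problems[3], "pressures")
  # an artificially high ratio margin flags every spec as non-robust
  rep2 <- robustness_report(specs[2], ratio_margin = 50,
                            pressure_range = c(25, 400),
                            pressure_step = 50,
                            bypass_range = c(400, 6000), bypass_step = 500)
  expect_match(rep2$problems[1], "no robust flow rate ratio")
})
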