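# Independent oracles used across the suite. Each is coded from first
# principles, separately from the package internals it checks.

# one-term rectangular-duct resistance by direct hand substitution (SI)
oracle_rect_resistance <- function(L_um, w_um, h_um, mu_mPas) {
  L <- L_um * 1e-6; w <- w_um * 1e-6; h <- h_um * 1e-6; mu <- mu_mPas * 1e-3
  a <- 12 / (1 - (192 * h / (pi^5 * w)) * tanh(pi * w / (2 * h)))
  a * mu * L / (w * h^3)
}

# truncated exact Fourier-series rectangular-duct resistance (SI)
oracle_rect_resistance_series <- function(L_um, w_um, h_um, mu_mPas,
                                          n_terms = 200) {
  L <- L_um * 1e-6; w <- w_um * 1e-6; h <- h_um * 1e-6; mu <- mu_mPas * 1e-3
  n <- seq(1, 2 * n_terms - 1, by = 2)
  s <- sum((192 * h / (pi^5 * w)) * (1 / n^5) * tanh(n * pi * w / (2 * h)))
  12 * mu * L / (w * h^3) / (1 - s)
}

# independent flow solver by nodal analysis (node potentials + source
# currents), a different formulation from the package's cycle-basis system
oracle_nodal_flow <- function(net, resistances = NULL) {
  ed <- net$edges
  nd <- net$nodes
  V <- nrow(nd); E <- nrow(ed)
  nid <- seq_len(V); names(nid) <- nd$id
  ref <- if (!is.na(net$reference)) nid[[net$reference]] else
    nid[[nd$id[nd$role == "outlet"][1]]]
  R <- numeric(E)
  for (e in seq_len(E)) {
    if (ed$kind[e] == "channel") {
      # resistance symmetric in w and h; orient so the formula domain holds
      wm <- max(ed$width[e], ed$height[e]) * 1e6
      hm <- min(ed$width[e], ed$height[e]) * 1e6
      R[e] <- oracle_rect_resistance(ed$length[e] * 1e6, wm, hm,
                                     net$fluid$mu_c * 1e3)
    }
  }
  if (!is.null(resistances)) {
    m <- match(names(resistances), ed$id)
    R[m] <- unname(resistances)
  }
  ps <- which(ed$kind == "pressure_source")
  fs <- which(ed$kind == "flow_source")
  n_unk <- V + length(ps)            # node potentials + pressure-source flows
  A <- matrix(0, n_unk, n_unk); b <- numeric(n_unk)
  for (e in which(ed$kind == "channel")) {
    f <- nid[[ed$from[e]]]; t <- nid[[ed$to[e]]]
    g <- 1 / R[e]
    A[f, f] <- A[f, f] + g; A[t, t] <- A[t, t] + g
    A[f, t] <- A[f, t] - g; A[t, f] <- A[t, f] - g
  }
  for (e in fs) {
    f <- nid[[ed$from[e]]]; t <- nid[[ed$to[e]]]
    b[f] <- b[f] - ed$value[e]; b[t] <- b[t] + ed$value[e]
  }
  for (j in seq_along(ps)) {
    e <- ps[j]
    f <- nid[[ed$from[e]]]; t <- nid[[ed$to[e]]]
    col <- V + j
    A[f, col] <- A[f, col] - 1; A[t, col] <- A[t, col] + 1
    A[col, t] <- 1; A[col, f] <- -1
    b[col] <- ed$value[e]             # P_to - P_from = source value
  }
  A[ref, ] <- 0; A[ref, ref] <- 1; b[ref] <- net$ambient
  sc <- pmax(apply(abs(A), 1, max), 1e-300)
  x <- solve(A / sc, b / sc)
  P <- x[seq_len(V)]
  Q <- numeric(E)
  for (e in seq_len(E)) {
    f <- nid[[ed$from[e]]]; t <- nid[[ed$to[e]]]
    Q[e] <- switch(ed$kind[e],
      channel = (P[f] - P[t]) / R[e],
      pressure_source = -x[V + match(e, ps)],
      flow_source = ed$value[e])
  }
  list(P = P, Q = Q, edge_id = ed$id, node_id = nd$id)
}

# dense fixed-step time integrator for droplet transport; shares only the
# steady-state flow solver with the package, none of the event machinery
oracle_fixed_step <- function(net, schedule, dt, t_max = 60,
                              slip = 1.28, plug = 3) {
  ed <- net$edges
  E <- nrow(ed)
  eid <- ed$id
  base_R <- rep(NA_real_, E)
  for (e in seq_len(E)) {
    if (ed$kind[e] == "channel") {
      wm <- max(ed$width[e], ed$height[e]) * 1e6
      hm <- min(ed$width[e], ed$height[e]) * 1e6
      base_R[e] <- oracle_rect_resistance(ed$length[e] * 1e6, wm, hm,
                                          net$fluid$mu_c * 1e3)
    }
  }
  nD <- nrow(schedule)
  d_edge <- rep(NA_integer_, nD); d_pos <- numeric(nD)
  d_state <- rep("pending", nD)
  d_L <- schedule$length * 1e-6
  exit_time <- rep(NA_real_, nD)
  outlets <- net$nodes$id[net$nodes$role == "outlet"]
  t <- 0
  flow <- NULL; dirty <- TRUE
  droplet_R <- function(d, e) {
    if (d_L[d] <= ed$width[e]) return(0)
    wm <- max(ed$width[e], ed$height[e]) * 1e6
    hm <- min(ed$width[e], ed$height[e]) * 1e6
    plug * oracle_rect_resistance(d_L[d] * 1e6, wm, hm, net$fluid$mu_c * 1e3)
  }
  route <- function(node, flow) {
    cand <- which(ed$kind == "channel" &
                    ((ed$from == node & flow$Q > 0) |
                       (ed$to == node & flow$Q < 0)))
    if (!length(cand)) return(NA_integer_)
    cand[order(-abs(flow$Q[cand]), cand)][1]
  }
  while (t <= t_max) {
    if (dirty) {
      Rstar <- base_R
      for (d in which(d_state == "flowing")) {
        e <- d_edge[d]
        Rstar[e] <- Rstar[e] + droplet_R(d, e)
      }
      names(Rstar) <- eid
      flow <- oracle_nodal_flow(net, Rstar[!is.na(Rstar)])
      dirty <- FALSE
    }
    # inject
    for (d in which(d_state == "pending")) {
      if (schedule$time[d] <= t) {
        e <- route(schedule$inlet[d], flow)
        stopifnot(!is.na(e))
        d_edge[d] <- e
        d_pos[d] <- 0
        d_state[d] <- "flowing"
        dirty <- TRUE
      }
    }
    if (dirty) next
    for (d in which(d_state == "flowing")) {
      e <- d_edge[d]
      v <- slip * flow$Q[e] / (ed$width[e] * ed$height[e])
      d_pos[d] <- d_pos[d] + v * dt / ed$length[e]
      if ((v > 0 && d_pos[d] >= 1) || (v < 0 && d_pos[d] <= 0)) {
        node <- if (v > 0) ed$to[e] else ed$from[e]
        if (node %in% outlets) {
          d_state[d] <- "exited"; exit_time[d] <- t
        } else {
          en <- route(node, flow)
          if (is.na(en)) { d_state[d] <- "stalled" } else {
            d_edge[d] <- en
            d_pos[d] <- if (ed$to[en] == node) 1 else 0
          }
        }
        dirty <- TRUE
      }
    }
    if (all(d_state %in% c("exited", "stalled")) &&
        !any(d_state == "pending")) break
    t <- t + dt
  }
  list(exit_time = exit_time, state = d_state)
}

# quick builders ---------------------------------------------------------------

two_branch_net <- function(R_scale = c(1, 1), pressure = 50) {
  net <- mf_network(fluid(5, interfacial_tension = 0.05))
  net <- add_node(net, "s", role = "inlet")
  net <- add_node(net, "t", role = "outlet")
  net <- add_channel(net, "b1", "s", "t", 1000 * R_scale[1], 100, 50)
  net <- add_channel(net, "b2", "s", "t", 1000 * R_scale[2], 100, 50)
  net <- add_pressure_source(net, "src", "t", "s", pressure)
  set_reference(net, "t")
}

random_ladder_net <- function(k, seed) {
  doc <- generate_test_network("ladder", k, seed = seed)
  realize_network_document(doc)$network
}
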