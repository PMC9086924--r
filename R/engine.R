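# Event-driven simulation loop: flow-state recomputation, objective checking,
# next-event scheduling, state advancement and droplet routing.
#
# Between events the flow state is constant, so droplets move at constant
# speed; the engine jumps from event to event (injection, channel transition,
# trap capture, merge, exit) and re-solves the Kirchhoff system only when the
# old flow state becomes invalid.

.STATUS <- c(pending = 0L, flowing = 1L, trapped = 2L, merged = 3L,
             exited = 4L, stalled = 5L)
.STATUS_NAMES <- names(.STATUS)

.EVENT_KINDS <- c("injection", "transition", "exit", "trap_capture", "merge",
                  "stall", "misroute", "end")

#' Droplet injection schedule
#'
#' One row per droplet: when and at which inlet it enters the network, and its
#' size. Times must be non-decreasing per inlet.
#'
#' @param time injection times, s.
#' @param inlet inlet node ids (recycled).
#' @param length plug lengths, um (recycled).
#' @param radius droplet radii, um (recycled).
#' @return a data.frame of class `mf_schedule`.
#' @examples
#' injection_schedule(c(0, 0.2), c("in1", "in2"), 250, 90)
#' @export
injection_schedule <- function(time, inlet, length = 250, radius = 90) {
  n <- max(length(time), length(inlet))
  sch <- data.frame(
    time = rep_len(as.numeric(time), n),
    inlet = rep_len(as.character(inlet), n),
    length = rep_len(as.numeric(length), n),
    radius = rep_len(as.numeric(radius), n),
    stringsAsFactors = FALSE
  )
  if (any(sch$time < 0) || any(!is.finite(sch$time))) {
    stop("injection times must be finite and >= 0", call. = FALSE)
  }
  if (any(sch$length <= 0) || any(sch$radius <= 0)) {
    stop("droplet length and radius must be positive (um)", call. = FALSE)
  }
  for (inl in unique(sch$inlet)) {
    tt <- sch$time[sch$inlet == inl]
    if (is.unsorted(tt)) {
      stop(sprintf("injection times at inlet '%s' must be non-decreasing", inl),
           call. = FALSE)
    }
  }
  sch <- sch[order(sch$time), , drop = FALSE]
  rownames(sch) <- NULL
  class(sch) <- c("mf_schedule", "data.frame")
  sch
}

#' Alternating two-stream injection schedule
#'
#' Droplets alternate between the given inlets with a fixed period, the usual
#' loading pattern for a trap-pair cascade.
#'
#' @param inlets character vector of inlet node ids to cycle through.
#' @param n total number of droplets.
#' @param period time between consecutive injections, s.
#' @param length,radius droplet size, um.
#' @param start time of the first injection, s.
#' @export
alternating_schedule <- function(inlets, n, period = 0.2, length = 250,
                                 radius = 90, start = 0) {
  injection_schedule(start + (seq_len(n) - 1) * period,
                     rep_len(inlets, n), length, radius)
}

# ---- simulation state --------------------------------------------------------

#' Initialise a simulation state
#'
#' Compiles the network, assembles the Kirchhoff system once (only channel
#' coefficients change between events), registers droplets and objectives and
#' returns a mutable simulation state. Normally called through
#' [simulate_droplets()]; exposed so the four loop steps
#' ([compute_flow_state()], [check_objectives()], [next_event_time()],
#' [advance_state()]) can be driven and inspected directly.
#'
#' @param net an [mf_network()].
#' @param schedule an [injection_schedule()] (or `NULL` for a droplet-free
#'   network).
#' @param objectives list of objective descriptors (defaults to those
#'   registered on the network, e.g. by [build_trapwell_network()]).
#' @param t_end simulation horizon, s.
#' @param clog_factor multiplier applied to the exit-gap resistances of an
#'   occupied trap (a trapped droplet clogs its gaps and drastically reduces
#'   the flow into the trap). A large finite factor keeps the system regular.
#' @param slip_factor constant droplet slip factor.
#' @param plug_factor plug-to-slug resistance ratio of a confined droplet.
#' @param fail_fast stop at the first objective violation instead of logging
#'   it and continuing.
#' @param record `"full"` keeps every per-event flow state, `"light"` keeps
#'   only logs and summaries, `"auto"` (default) keeps full states for
#'   networks up to 200 edges.
#' @param spacing_widths droplets on one edge closer than this many channel
#'   widths violate the non-interacting-perturbation assumption and are
#'   counted as warnings.
#' @param max_events hard cap on the number of processed events.
#' @return an environment of class `mf_sim_state`.
#' @export
init_simulation <- function(net, schedule = NULL, objectives = net$objectives,
                            t_end = Inf, clog_factor = 1e4, slip_factor = 1.28,
                            plug_factor = 3, fail_fast = FALSE,
                            record = c("auto", "full", "light"),
                            spacing_widths = 3, max_events = 1e6) {
  stopifnot(inherits(net, "mf_network"))
  record <- match.arg(record)
  idx <- .net_index(net)
  if (record == "auto") record <- if (idx$n_edges <= 200L) "full" else "light"
  sys <- assemble_flow_system(idx)

  st <- new.env(parent = emptyenv())
  st$net <- net
  st$idx <- idx
  st$sys <- sys
  st$opts <- list(t_end = t_end, clog_factor = clog_factor,
                  slip = slip_factor, plug = plug_factor,
                  fail_fast = fail_fast, record = record,
                  spacing_widths = spacing_widths, max_events = max_events)
  st$time <- 0
  st$flow <- NULL          # cached raw solve (SI)
  st$flow_valid <- FALSE
  st$n_solves <- 0L
  st$n_events <- 0L
  st$stop_reason <- NA_character_

  if (is.null(schedule)) {
    schedule <- injection_schedule(numeric(0), character(0))
  }
  stopifnot(inherits(schedule, "mf_schedule"))
  m <- match(schedule$inlet, idx$node_id)
  if (anyNA(m)) {
    stop(sprintf("schedule references unknown inlet(s): %s",
                 paste(unique(schedule$inlet[is.na(m)]), collapse = ", ")),
         call. = FALSE)
  }
  nD <- nrow(schedule)
  st$schedule <- schedule
  st$next_inj <- if (nD) 1L else NA_integer_
  st$drop <- list(
    t_inject = schedule$time,
    inlet = m,
    L_d = to_si(schedule$length, "length"),
    r_d = to_si(schedule$radius, "length"),
    status = rep(.STATUS[["pending"]], nD),
    edge = rep(NA_integer_, nD),
    pos = rep(NA_real_, nD),       # fractional position along the edge
    R_d = rep(0, nD),              # resistance contribution on current edge
    trap = rep(NA_character_, nD)
  )
  st$count <- integer(idx$n_edges)  # flowing droplets per edge (feeds R*)

  st$traps <- .trap_registry(idx)
  st$occupant <- stats::setNames(rep(NA_integer_, length(st$traps)),
                                 names(st$traps))
  st$misroute <- FALSE
  st$spacing_warnings <- 0L
  st$violations <- 0L

  st$obj <- .compile_objectives(objectives, idx, net$fluid)
  st$log_events <- .buf_new()
  st$log_obj <- .buf_new()
  st$log_flow <- if (record == "full") list() else NULL
  st$log_flow_times <- numeric(0)
  class(st) <- "mf_sim_state"
  st
}

# trap registry: chamber/gap edge indices, chamber (C) and downstream (D)
# nodes, and the partner trap across the pair intersection
.trap_registry <- function(idx) {
  trap_ids <- unique(idx$trap[!is.na(idx$trap)])
  traps <- lapply(trap_ids, function(tr) {
    mine <- which(!is.na(idx$trap) & idx$trap == tr)
    chamber <- mine[idx$label[mine] %in% "chamber"]
    gaps <- mine[idx$label[mine] %in% "gap"]
    if (!length(chamber)) chamber <- mine[1L]
    C_node <- idx$to[chamber[1L]]
    D_node <- if (length(gaps)) idx$to[gaps[1L]] else NA_integer_
    pair <- idx$pair[chamber[1L]]
    stream <- idx$stream[chamber[1L]]
    partner <- NA_character_
    if (!is.na(pair) && !is.na(stream)) {
      others <- which(!is.na(idx$trap) & idx$pair %in% pair &
                        !idx$stream %in% stream)
      if (length(others)) partner <- idx$trap[others[1L]]
    }
    list(id = tr, chamber = chamber, gaps = gaps, C = C_node, D = D_node,
         pair = pair, stream = stream, partner = partner)
  })
  stats::setNames(traps, trap_ids)
}

# objective descriptors -> integer-indexed table (thresholds precomputed, SI)
.compile_objectives <- function(objectives, idx, fluid) {
  if (is.null(objectives) || !length(objectives)) {
    return(list(n = 0L))
  }
  n <- length(objectives)
  type <- integer(n); e1 <- integer(n); e2 <- integer(n)
  n1 <- integer(n); n2 <- integer(n); thr <- numeric(n)
  trap <- character(n); oid <- character(n)
  for (i in seq_len(n)) {
    ob <- objectives[[i]]
    oid[i] <- if (!is.null(ob$id)) ob$id else sprintf("obj%02d", i)
    ty <- match(ob$type, c("flow_ratio", "squeeze_intertrap",
                           "squeeze_downstream"))
    if (is.na(ty)) {
      stop(sprintf("unknown objective type '%s'", ob$type), call. = FALSE)
    }
    type[i] <- ty
    if (ty == 1L) {
      e1[i] <- match(ob$trap_edge, idx$edge_id)
      e2[i] <- match(ob$bypass_edge, idx$edge_id)
      if (is.na(e1[i]) || is.na(e2[i])) {
        stop(sprintf("objective '%s' references absent edges", oid[i]),
             call. = FALSE)
      }
      trap[i] <- ob$trap
      thr[i] <- 1
    } else {
      n1[i] <- match(ob$node_a, idx$node_id)
      n2[i] <- match(ob$node_b, idx$node_id)
      if (is.na(n1[i]) || is.na(n2[i])) {
        stop(sprintf("objective '%s' references absent nodes", oid[i]),
             call. = FALSE)
      }
      trap[i] <- if (!is.null(ob$trap)) ob$trap else NA_character_
      thr[i] <- laplace_pressure(fluid$gamma, ob$gap_width, ob$radius)
    }
  }
  list(n = n, id = oid, type = type, e1 = e1, e2 = e2, n1 = n1, n2 = n2,
       thr = thr, trap = trap)
}

# growable column buffers (records are appended once per event)
.buf_new <- function() new.env(parent = emptyenv())
.buf_add <- function(buf, row) {
  k <- length(buf$.n)
  if (is.null(buf$rows)) {
    buf$rows <- vector("list", 256L)
    buf$n <- 0L
  }
  if (buf$n == length(buf$rows)) {
    buf$rows <- c(buf$rows, vector("list", length(buf$rows)))
  }
  buf$n <- buf$n + 1L
  buf$rows[[buf$n]] <- row
  invisible(buf)
}
.buf_collect <- function(buf) {
  if (is.null(buf$rows) || buf$n == 0L) return(NULL)
  rows <- buf$rows[seq_len(buf$n)]
  cols <- names(rows[[1L]])
  out <- lapply(cols, function(cn) unlist(lapply(rows, `[[`, cn),
                                          use.names = FALSE))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

# ---- loop step 1: flow state -------------------------------------------------

#' Compute (or fetch) the flow state of the current droplet configuration
#'
#' Effective resistances are `R* = R + n R_d` per channel, with the exit gaps
#' of occupied traps multiplied by the clog factor; the Kirchhoff system is
#' then re-solved by LU decomposition. The result is cached and reused until
#' the next event invalidates it, so the system is solved exactly once per
#' event.
#'
#' @param state an [init_simulation()] state.
#' @return the raw flow solution (SI): `Q`, `dP` per edge, `P` per node,
#'   residuals.
#' @export
compute_flow_state <- function(state) {
  stopifnot(inherits(state, "mf_sim_state"))
  if (state$flow_valid) return(state$flow)
  idx <- state$idx
  Rstar <- idx$R_base
  fl <- which(state$drop$status == .STATUS[["flowing"]])
  for (d in fl) {
    e <- state$drop$edge[d]
    Rstar[e] <- Rstar[e] + state$drop$R_d[d]
  }
  occ <- names(state$occupant)[!is.na(state$occupant)]
  for (tr in occ) {
    g <- state$traps[[tr]]$gaps
    Rstar[g] <- Rstar[g] * state$opts$clog_factor
  }
  state$sys <- .update_system(state$sys, Rstar)
  state$flow <- .solve_fast(state$sys)
  state$flow_valid <- TRUE
  state$n_solves <- state$n_solves + 1L
  state$flow
}

# droplet resistance contribution on entry to an edge; zero when the edge is
# not a channel the droplet confines in
.droplet_R_on_edge <- function(state, d, e) {
  idx <- state$idx
  if (idx$kind[e] != 1L) return(0)
  L_d <- state$drop$L_d[d]
  if (L_d <= idx$w[e]) return(0)  # unconfined here: no plug resistance
  state$opts$plug * .oriented_resistance(L_d, idx$w[e], idx$h[e], idx$mu)
}

# ---- loop step 2: objectives -------------------------------------------------

#' Check the registered objectives against a flow state
#'
#' Evaluates, for every registered objective: the trap/bypass flow-rate ratio
#' (must favour the trap while it is empty and the bypass once it is
#' occupied), the inter-trap pressure difference against the Laplace pressure
#' of the pair intersection, and the trap-to-downstream pressure difference
#' against the Laplace pressure of the exit gaps. Every configured objective
#' appears in every report.
#'
#' @param state an [init_simulation()] state.
#' @param flow a flow solution from [compute_flow_state()] (defaults to the
#'   state's cached one).
#' @return data.frame: objective id, type, measured value, threshold, pass.
#'   Pressures in mbar, ratios dimensionless.
#' @export
check_objectives <- function(state, flow = compute_flow_state(state)) {
  stopifnot(inherits(state, "mf_sim_state"))
  ob <- state$obj
  if (ob$n == 0L) {
    return(data.frame(id = character(), type = character(),
                      measured = numeric(), threshold = numeric(),
                      pass = logical(), stringsAsFactors = FALSE))
  }
  measured <- numeric(ob$n); thr_out <- numeric(ob$n); pass <- logical(ob$n)
  typ <- character(ob$n)
  for (i in seq_len(ob$n)) {
    if (ob$type[i] == 1L) {
      qt <- flow$Q[ob$e1[i]]; qb <- flow$Q[ob$e2[i]]
      occupied <- !is.na(state$occupant[[ob$trap[i]]])
      measured[i] <- qt / qb
      thr_out[i] <- 1
      pass[i] <- if (occupied) qt < qb else qt > qb
      typ[i] <- "flow_ratio"
    } else if (ob$type[i] == 2L) {
      dp <- abs(flow$P[ob$n1[i]] - flow$P[ob$n2[i]])
      measured[i] <- from_si(dp, "pressure")
      thr_out[i] <- from_si(ob$thr[i], "pressure")
      pass[i] <- dp < ob$thr[i]
      typ[i] <- "squeeze_intertrap"
    } else {
      dp <- flow$P[ob$n1[i]] - flow$P[ob$n2[i]]
      measured[i] <- from_si(dp, "pressure")
      thr_out[i] <- from_si(ob$thr[i], "pressure")
      pass[i] <- dp < ob$thr[i]
      typ[i] <- "squeeze_downstream"
    }
  }
  data.frame(id = ob$id, type = typ, measured = measured,
             threshold = thr_out, pass = pass, stringsAsFactors = FALSE)
}

# ---- loop step 3: next event -------------------------------------------------

#' Time and identity of the next event
#'
#' The next event is the earliest of: the next scheduled injection, and for
#' each flowing droplet the time at which it reaches the end of its channel
#' (remaining length over droplet speed). Droplets with zero speed contribute
#' no event. Simultaneous events are processed in droplet-id order.
#'
#' @inheritParams check_objectives
#' @return list with `time`, `kind` (`"injection"`, `"transition"` or
#'   `"end"`), and `droplet` (id) when applicable.
#' @export
next_event_time <- function(state, flow = compute_flow_state(state)) {
  stopifnot(inherits(state, "mf_sim_state"))
  idx <- state$idx
  best_t <- Inf; best_kind <- "end"; best_d <- NA_integer_
  fl <- which(state$drop$status == .STATUS[["flowing"]])
  for (d in fl) {
    e <- state$drop$edge[d]
    v <- state$opts$slip * flow$Q[e] / (idx$w[e] * idx$h[e])
    if (!is.finite(v) || v == 0) next
    rem <- if (v > 0) (1 - state$drop$pos[d]) else state$drop$pos[d]
    dt <- rem * idx$L[e] / abs(v)
    t_ev <- state$time + max(dt, 0)
    if (t_ev < best_t - 1e-12 ||
        (abs(t_ev - best_t) <= 1e-12 && d < best_d)) {
      best_t <- t_ev; best_kind <- "transition"; best_d <- d
    }
  }
  if (!is.na(state$next_inj) && state$next_inj <= nrow(state$schedule)) {
    t_inj <- state$schedule$time[state$next_inj]
    d_inj <- state$next_inj
    if (t_inj < best_t - 1e-12 ||
        (abs(t_inj - best_t) <= 1e-12 &&
         (is.na(best_d) || d_inj < best_d))) {
      best_t <- t_inj; best_kind <- "injection"; best_d <- d_inj
    }
  }
  list(time = best_t, kind = best_kind, droplet = best_d)
}

# ---- routing -----------------------------------------------------------------

#' Route a droplet at a node
#'
#' Among the channels carrying flow out of the node, the droplet enters the
#' one with the highest volumetric flow rate; exact ties break to the lowest
#' edge id, deterministically. Returns `NA` (a stall) when no channel carries
#' flow out of the node.
#'
#' @inheritParams check_objectives
#' @param node node id (or internal index) at which the droplet head sits.
#' @param exclude optional edge (id or index) the droplet arrived on.
#' @return the chosen edge id, or `NA_character_` on a stall.
#' @export
route_droplet <- function(state, node, flow = compute_flow_state(state),
                          exclude = NULL) {
  stopifnot(inherits(state, "mf_sim_state"))
  idx <- state$idx
  v <- if (is.character(node)) match(node, idx$node_id) else node
  if (is.na(v)) stop("unknown node", call. = FALSE)
  ex <- if (is.null(exclude)) NA_integer_ else
    if (is.character(exclude)) match(exclude, idx$edge_id) else exclude
  e <- .route_idx(state, v, flow, ex)
  if (is.na(e)) NA_character_ else idx$edge_id[e]
}

.route_idx <- function(state, v, flow, exclude = NA_integer_) {
  idx <- state$idx
  ch <- idx$kind == 1L
  out_fwd <- which(ch & idx$from == v & flow$Q > 0)
  out_bwd <- which(ch & idx$to == v & flow$Q < 0)
  cand <- c(out_fwd, out_bwd)
  cand <- cand[!cand %in% exclude]
  if (!length(cand)) return(NA_integer_)
  qout <- abs(flow$Q[cand])
  # highest outgoing flow; exact tie -> lowest edge index (stable order)
  cand <- cand[order(-qout, cand)]
  cand[[1L]]
}

# ---- loop step 4: advance ----------------------------------------------------

#' Advance the simulation to an event and process it
#'
#' Moves every flowing droplet by its speed times the elapsed time, sets the
#' clock to the event time, then processes the triggering event: an injection
#' places the droplet at its inlet and routes it; a transition routes the
#' droplet at the node it reached (capture when the chosen edge is an empty
#' trap chamber, merge when its partner trap is already occupied, exit when
#' the node is an outlet). Per-edge droplet counts, trap occupancy and the
#' flow-state cache are updated.
#'
#' @inheritParams check_objectives
#' @param event an event from [next_event_time()].
#' @return the state, invisibly.
#' @export
advance_state <- function(state, event, flow = compute_flow_state(state)) {
  stopifnot(inherits(state, "mf_sim_state"))
  idx <- state$idx
  dt <- event$time - state$time
  if (dt < -1e-9) stop("event lies in the past", call. = FALSE)
  dt <- max(dt, 0)
  fl <- which(state$drop$status == .STATUS[["flowing"]])
  for (d in fl) {
    e <- state$drop$edge[d]
    v <- state$opts$slip * flow$Q[e] / (idx$w[e] * idx$h[e])
    state$drop$pos[d] <- min(max(state$drop$pos[d] + v * dt / idx$L[e], 0), 1)
  }
  state$time <- event$time

  if (event$kind == "end") {
    state$stop_reason <- "end_of_events"
    return(invisible(state))
  }

  if (event$kind == "injection") {
    d <- event$droplet
    state$next_inj <- state$next_inj + 1L
    v_node <- state$drop$inlet[d]
    e <- .route_idx(state, v_node, flow)
    if (is.na(e)) {
      state$drop$status[d] <- .STATUS[["stalled"]]
      .log_event(state, "stall", d, NA_integer_, NA_integer_, v_node)
      state$flow_valid <- FALSE
      return(invisible(state))
    }
    state$drop$status[d] <- .STATUS[["flowing"]]
    .place_on_edge(state, d, e)
    .log_event(state, "injection", d, NA_integer_, e, v_node)
    .maybe_capture(state, d, e)
    state$flow_valid <- FALSE
    return(invisible(state))
  }

  # channel transition of droplet d at the end of its edge
  d <- event$droplet
  e_old <- state$drop$edge[d]
  q <- flow$Q[e_old]
  at_node <- if (q >= 0) idx$to[e_old] else idx$from[e_old]
  pos <- state$drop$pos[d]
  if ((q >= 0 && pos < 1 - 1e-6) || (q < 0 && pos > 1e-6)) {
    stop("internal inconsistency: transition event for a droplet not at its
 channel boundary", call. = FALSE)
  }
  state$count[e_old] <- state$count[e_old] - 1L
  if (idx$node_role[at_node] == "outlet") {
    state$drop$status[d] <- .STATUS[["exited"]]
    state$drop$edge[d] <- NA_integer_
    .log_event(state, "exit", d, e_old, NA_integer_, at_node)
    state$flow_valid <- FALSE
    return(invisible(state))
  }
  e_new <- .route_idx(state, at_node, flow, exclude = e_old)
  if (is.na(e_new)) {
    state$drop$status[d] <- .STATUS[["stalled"]]
    state$drop$edge[d] <- NA_integer_
    .log_event(state, "stall", d, e_old, NA_integer_, at_node)
    state$flow_valid <- FALSE
    return(invisible(state))
  }
  .place_on_edge(state, d, e_new, enter_at = at_node)
  .log_event(state, "transition", d, e_old, e_new, at_node)
  .maybe_capture(state, d, e_new)
  state$flow_valid <- FALSE
  invisible(state)
}

.place_on_edge <- function(state, d, e, enter_at = NULL) {
  idx <- state$idx
  state$drop$edge[d] <- e
  state$drop$pos[d] <-
    if (!is.null(enter_at) && idx$to[e] == enter_at) 1 else 0
  state$drop$R_d[d] <- .droplet_R_on_edge(state, d, e)
  state$count[e] <- state$count[e] + 1L
  # droplet-spacing assumption: warn (count) when two droplets share an edge
  # closer than a few channel widths
  same <- which(state$drop$status == .STATUS[["flowing"]] &
                  state$drop$edge == e)
  same <- same[same != d]
  if (length(same)) {
    gap <- min(abs(state$drop$pos[same] - state$drop$pos[d])) * idx$L[e]
    if (gap < state$opts$spacing_widths * idx$w[e]) {
      state$spacing_warnings <- state$spacing_warnings + 1L
    }
  }
  invisible(state)
}

# capture / merge / misroute handling when a droplet enters a trap chamber
.maybe_capture <- function(state, d, e) {
  tr <- state$idx$trap[e]
  if (is.na(tr) || !identical(state$idx$label[e], "chamber")) {
    return(invisible(state))
  }
  reg <- state$traps[[tr]]
  if (!is.na(state$occupant[[tr]])) {
    # a droplet was routed into an occupied trap: flagged as a mis-route
    state$misroute <- TRUE
    .log_event(state, "misroute", d, NA_integer_, e, reg$C)
  }
  state$occupant[[tr]] <- d
  state$drop$status[d] <- .STATUS[["trapped"]]
  state$drop$trap[d] <- tr
  state$drop$pos[d] <- 1
  state$count[e] <- state$count[e] - 1L  # trapped: no plug resistance
  .log_event(state, "trap_capture", d, NA_integer_, e, reg$C)
  partner <- reg$partner
  if (!is.na(partner) && !is.na(state$occupant[[partner]])) {
    other <- state$occupant[[partner]]
    state$drop$status[d] <- .STATUS[["merged"]]
    state$drop$status[other] <- .STATUS[["merged"]]
    .log_event(state, "merge", d, NA_integer_, e, reg$C)
  }
  invisible(state)
}

.log_event <- function(state, kind, droplet, edge_from, edge_to, node) {
  idx <- state$idx
  .buf_add(state$log_events, list(
    time = state$time,
    kind = kind,
    droplet = if (is.na(droplet)) NA_integer_ else as.integer(droplet),
    edge_from = if (is.na(edge_from)) NA_character_ else idx$edge_id[edge_from],
    edge_to = if (is.na(edge_to)) NA_character_ else idx$edge_id[edge_to],
    node = if (is.na(node)) NA_character_ else idx$node_id[node]
  ))
}

# ---- main loop ---------------------------------------------------------------

#' Simulate droplets through a microfluidic network
#'
#' The event-driven loop: (1) compute the flow state for the current droplet
#' configuration, (2) check the registered objectives, (3) find the next
#' event, (4) advance the state to it — repeated until the schedule and all
#' droplets are exhausted or `t_end` is reached. Deterministic: identical
#' inputs give identical logs.
#'
#' @inheritParams init_simulation
#' @param ... passed to [init_simulation()].
#' @return an object of class `droplet_simulation`: `$events` (event log),
#'   `$objective_log` (one report row per objective per event),
#'   `$flow_states` (per-event edge flows, when recorded), `$residence`
#'   (per-droplet per-channel residence times), `$droplets` (final droplet
#'   table), `$stats` (counters incl. number of solves and violations).
#' @examples
#' \donttest{
#' tw <- build_trapwell_network(trapwell_params(n_pairs = 1))
#' sim <- simulate_droplets(tw, alternating_schedule(c("in1", "in2"), 2))
#' summary(sim)
#' }
#' @export
simulate_droplets <- function(net, schedule = NULL,
                              objectives = net$objectives, t_end = Inf, ...) {
  state <- init_simulation(net, schedule, objectives, t_end = t_end, ...)
  run_simulation(state)
}

#' @rdname simulate_droplets
#' @param state an [init_simulation()] state.
#' @export
run_simulation <- function(state) {
  stopifnot(inherits(state, "mf_sim_state"))
  opts <- state$opts
  repeat {
    flow <- compute_flow_state(state)
    rep_df <- check_objectives(state, flow)
    .record_state(state, flow, rep_df)
    if (nrow(rep_df) && any(!rep_df$pass)) {
      state$violations <- state$violations + sum(!rep_df$pass)
      if (opts$fail_fast) {
        state$stop_reason <- "objective_violation"
        break
      }
    }
    ev <- next_event_time(state, flow)
    if (ev$kind == "end") {
      state$stop_reason <- "end_of_events"
      break
    }
    if (ev$time > opts$t_end) {
      advance_state(state, list(time = opts$t_end, kind = "end"), flow)
      state$stop_reason <- "t_end"
      break
    }
    advance_state(state, ev, flow)
    state$n_events <- state$n_events + 1L
    if (state$n_events >= opts$max_events) {
      state$stop_reason <- "max_events"
      break
    }
  }
  .finalize_simulation(state)
}

.record_state <- function(state, flow, rep_df) {
  k <- state$n_events + 1L
  if (nrow(rep_df)) {
    .buf_add(state$log_obj, list(
      event = rep(k, nrow(rep_df)), time = rep(state$time, nrow(rep_df)),
      id = rep_df$id, type = rep_df$type, measured = rep_df$measured,
      threshold = rep_df$threshold, pass = rep_df$pass
    ))
  }
  if (!is.null(state$log_flow)) {
    state$log_flow[[k]] <- flow$Q
    state$log_flow_times[k] <- state$time
  }
}

.finalize_simulation <- function(state) {
  idx <- state$idx
  events <- .buf_collect(state$log_events)
  if (is.null(events)) {
    events <- data.frame(time = numeric(), kind = character(),
                         droplet = integer(), edge_from = character(),
                         edge_to = character(), node = character(),
                         stringsAsFactors = FALSE)
  }
  obj_log <- .buf_collect(state$log_obj)
  if (is.null(obj_log)) {
    obj_log <- data.frame(event = integer(), time = numeric(),
                          id = character(), type = character(),
                          measured = numeric(), threshold = numeric(),
                          pass = logical(), stringsAsFactors = FALSE)
  }
  flow_states <- NULL
  if (!is.null(state$log_flow) && length(state$log_flow)) {
    Qm <- do.call(rbind, state$log_flow)
    colnames(Qm) <- idx$edge_id
    flow_states <- list(time = state$log_flow_times,
                        Q = from_si(Qm, "flow"))
  }
  nD <- length(state$drop$t_inject)
  droplets <- data.frame(
    droplet = seq_len(nD),
    t_inject = state$drop$t_inject,
    status = .STATUS_NAMES[state$drop$status + 1L],
    edge = ifelse(is.na(state$drop$edge), NA_character_,
                  idx$edge_id[state$drop$edge]),
    position = state$drop$pos,
    trap = state$drop$trap,
    stringsAsFactors = FALSE
  )
  res <- .residence_times(events, state)
  stats <- list(
    n_events = state$n_events,
    n_solves = state$n_solves,
    injected = sum(state$drop$status != .STATUS[["pending"]]),
    flowing = sum(state$drop$status == .STATUS[["flowing"]]),
    trapped = sum(state$drop$status == .STATUS[["trapped"]]),
    merged = sum(state$drop$status == .STATUS[["merged"]]),
    exited = sum(state$drop$status == .STATUS[["exited"]]),
    stalled = sum(state$drop$status == .STATUS[["stalled"]]),
    violations = state$violations,
    misroute = state$misroute,
    spacing_warnings = state$spacing_warnings,
    stop_reason = state$stop_reason,
    time = state$time
  )
  structure(
    list(events = events, objective_log = obj_log, flow_states = flow_states,
         residence = res, droplets = droplets, stats = stats,
         occupancy = state$occupant, options = state$opts,
         network = state$net, schedule = state$schedule,
         final_state = state),
    class = "droplet_simulation"
  )
}

# per-droplet, per-channel residence times from the event log
.residence_times <- function(events, state) {
  out <- list()
  if (!nrow(events)) {
    return(data.frame(droplet = integer(), edge = character(),
                      enter = numeric(), leave = numeric(),
                      residence = numeric(), stringsAsFactors = FALSE))
  }
  for (d in sort(unique(events$droplet[!is.na(events$droplet)]))) {
    ev <- events[!is.na(events$droplet) & events$droplet == d, , drop = FALSE]
    ev <- ev[order(ev$time), , drop = FALSE]
    cur_edge <- NA_character_; t_enter <- NA_real_
    for (i in seq_len(nrow(ev))) {
      row <- ev[i, ]
      leaves <- row$kind %in% c("transition", "exit", "stall")
      if (leaves && !is.na(cur_edge)) {
        out[[length(out) + 1L]] <- list(droplet = d, edge = cur_edge,
                                        enter = t_enter, leave = row$time,
                                        residence = row$time - t_enter)
        cur_edge <- NA_character_
      }
      if (!is.na(row$edge_to) && row$kind %in% c("injection", "transition")) {
        cur_edge <- row$edge_to; t_enter <- row$time
      }
    }
    if (!is.na(cur_edge)) {
      out[[length(out) + 1L]] <- list(droplet = d, edge = cur_edge,
                                      enter = t_enter, leave = NA_real_,
                                      residence = NA_real_)
    }
  }
  if (!length(out)) {
    return(data.frame(droplet = integer(), edge = character(),
                      enter = numeric(), leave = numeric(),
                      residence = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(out, function(r) {
    data.frame(droplet = r$droplet, edge = r$edge, enter = r$enter,
               leave = r$leave, residence = r$residence,
               stringsAsFactors = FALSE)
  }))
}

# ---- methods -----------------------------------------------------------------

#' @export
print.droplet_simulation <- function(x, ...) {
  s <- x$stats
  cat("<droplet_simulation>\n")
  cat(sprintf("  simulated time : %.4g s (%s)\n", s$time, s$stop_reason))
  cat(sprintf("  events/solves  : %d / %d\n", s$n_events, s$n_solves))
  cat(sprintf(paste0("  droplets       : %d injected | %d flowing | ",
                     "%d trapped | %d merged | %d exited | %d stalled\n"),
              s$injected, s$flowing, s$trapped, s$merged, s$exited, s$stalled))
  if (s$violations > 0) {
    cat(sprintf("  objective violations: %d report rows\n", s$violations))
  }
  if (s$misroute) cat("  WARNING: droplet mis-routed into an occupied trap\n")
  invisible(x)
}

#' @export
summary.droplet_simulation <- function(object, ...) {
  print(object)
  if (nrow(object$objective_log)) {
    bad <- object$objective_log[!object$objective_log$pass, , drop = FALSE]
    cat(sprintf("  objective reports: %d rows, %d failing\n",
                nrow(object$objective_log), nrow(bad)))
    if (nrow(bad)) print(utils::head(bad, 5L))
  }
  if (nrow(object$residence)) {
    cat("  residence times (s) by edge, first rows:\n")
    print(utils::head(object$residence, 5L))
  }
  invisible(object)
}

#' Plot droplet trajectories of a simulation
#'
#' Draws, for every droplet, the index of the channel it occupies against
#' time — a compact view of routing decisions, captures and exits.
#'
#' @param x a [simulate_droplets()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.droplet_simulation <- function(x, ...) {
  ev <- x$events
  ev <- ev[!is.na(ev$droplet) & !is.na(ev$edge_to), , drop = FALSE]
  if (!nrow(ev)) {
    warning("nothing to plot: no droplet movements recorded", call. = FALSE)
    return(invisible(x))
  }
  eidx <- match(ev$edge_to, x$network$edges$id)
  cols <- grDevices::hcl.colors(max(ev$droplet), "Dark 3")
  graphics::plot(ev$time, eidx, type = "n",
                 xlab = "time [s]", ylab = "channel index", ...)
  for (d in unique(ev$droplet)) {
    sel <- ev$droplet == d
    graphics::lines(ev$time[sel], eidx[sel], type = "s", col = cols[d])
    graphics::points(ev$time[sel], eidx[sel], pch = 16, cex = 0.5,
                     col = cols[d])
  }
  invisible(x)
}
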