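# Directed-graph representation of a microfluidic network and the
# Kirchhoff-analogue steady-state flow solver.
#
# Edges are channels (resistors), pressure sources (pumps: fixed pressure gain
# from tail to head) or flow sources (fixed volumetric flow in the counting
# direction). The edge direction is the counting direction of the flow; a
# negative solved Q means flow against it. One node is the reference and sits
# at the ambient pressure.

#' Create an empty microfluidic network
#'
#' @param fluid an [fluid()] object (carrier viscosity sets channel
#'   resistances).
#' @param ambient_pressure pressure of the reference node, mbar (default 0).
#' @return an object of class `mf_network`; grow it with [add_node()],
#'   [add_channel()], [add_pressure_source()], [add_flow_source()].
#' @examples
#' net <- mf_network(fluid(5, interfacial_tension = 0.05))
#' net <- add_node(net, "a", role = "inlet")
#' net <- add_node(net, "b", role = "outlet")
#' net <- add_channel(net, "c1", "a", "b", length = 1000, width = 100, height = 50)
#' net <- add_pressure_source(net, "p1", "b", "a", pressure = 50)
#' net <- set_reference(net, "b")
#' solve_flow(net)
#' @export
mf_network <- function(fluid, ambient_pressure = 0) {
  stopifnot(inherits(fluid, "mf_fluid"))
  structure(
    list(
      nodes = data.frame(id = character(), role = character(),
                         stringsAsFactors = FALSE),
      edges = data.frame(id = character(), kind = character(),
                         from = character(), to = character(),
                         length = numeric(), width = numeric(),
                         height = numeric(), value = numeric(),
                         label = character(), trap = character(),
                         pair = integer(), stream = integer(),
                         stringsAsFactors = FALSE),
      fluid = fluid,
      reference = NA_character_,
      ambient = to_si(ambient_pressure, "pressure"),
      objectives = list(),
      meta = list()
    ),
    class = "mf_network"
  )
}

#' Add a node to a network
#'
#' @param net an [mf_network()].
#' @param id unique node identifier.
#' @param role `"junction"`, `"inlet"` or `"outlet"`. Droplets reaching an
#'   outlet node leave the network.
#' @return the modified network.
#' @export
add_node <- function(net, id, role = c("junction", "inlet", "outlet")) {
  stopifnot(inherits(net, "mf_network"), is.character(id))
  role <- match.arg(role)
  if (any(id %in% net$nodes$id)) {
    stop(sprintf("duplicate node id: %s",
                 paste(intersect(id, net$nodes$id), collapse = ", ")),
         call. = FALSE)
  }
  net$nodes <- rbind(net$nodes,
                     data.frame(id = id, role = role, stringsAsFactors = FALSE))
  net
}

.add_edge <- function(net, id, kind, from, to, length = NA_real_,
                      width = NA_real_, height = NA_real_, value = NA_real_,
                      label = NA_character_, trap = NA_character_,
                      pair = NA_integer_, stream = NA_integer_) {
  if (id %in% net$edges$id) {
    stop(sprintf("duplicate edge id: %s", id), call. = FALSE)
  }
  for (nd in c(from, to)) {
    if (!nd %in% net$nodes$id) {
      stop(sprintf("edge '%s' references unknown node '%s'", id, nd),
           call. = FALSE)
    }
  }
  if (from == to) {
    stop(sprintf("edge '%s' is a self-loop", id), call. = FALSE)
  }
  net$edges <- rbind(net$edges, data.frame(
    id = id, kind = kind, from = from, to = to,
    length = length, width = width, height = height, value = value,
    label = label, trap = trap, pair = as.integer(pair),
    stream = as.integer(stream), stringsAsFactors = FALSE
  ))
  net
}

#' Add a channel edge
#'
#' @inheritParams add_node
#' @param from,to endpoint node ids; the direction `from -> to` is the
#'   counting direction of the flow.
#' @param length,width,height channel dimensions, um. The cross-section is
#'   oriented internally so the wider dimension plays the role of `w` in the
#'   rectangular-duct formula (the physical resistance is symmetric in w and
#'   h), so narrow tall gaps are handled exactly.
#' @param label free-form structural tag (e.g. `"bypass"`, `"gap"`).
#' @param trap trap identifier when the edge is a trap chamber or trap gap.
#' @param pair,stream cascade bookkeeping for the trap fixture.
#' @return the modified network.
#' @export
add_channel <- function(net, id, from, to, length, width, height,
                        label = NA_character_, trap = NA_character_,
                        pair = NA_integer_, stream = NA_integer_) {
  stopifnot(inherits(net, "mf_network"))
  geom <- channel_geometry(length, width, height)  # validates positivity
  .add_edge(net, id, "channel", from, to,
            length = geom$L, width = geom$w, height = geom$h,
            label = label, trap = trap, pair = pair, stream = stream)
}

#' Add a pressure source edge (pump)
#'
#' The source raises the pressure by `pressure` from `from` to `to`
#' (`P_to = P_from + pressure` when no other element intervenes). A zero-value
#' pressure source is an ideal wire tying two nodes to the same pressure.
#'
#' @inheritParams add_channel
#' @param pressure pressure gain, mbar.
#' @export
add_pressure_source <- function(net, id, from, to, pressure,
                                label = NA_character_) {
  stopifnot(inherits(net, "mf_network"), is.numeric(pressure))
  .add_edge(net, id, "pressure_source", from, to,
            value = to_si(pressure, "pressure"), label = label)
}

#' Add a flow source edge (volumetric pump)
#'
#' Fixes the volumetric flow rate on the edge to `flow` in the counting
#' direction; the pressure gain across the source becomes an unknown.
#'
#' @inheritParams add_channel
#' @param flow volumetric flow rate, ul/min.
#' @export
add_flow_source <- function(net, id, from, to, flow, label = NA_character_) {
  stopifnot(inherits(net, "mf_network"), is.numeric(flow))
  .add_edge(net, id, "flow_source", from, to,
            value = to_si(flow, "flow"), label = label)
}

#' Set the reference (ambient-pressure) node
#'
#' @inheritParams add_node
#' @param id node id to use as the pressure reference.
#' @export
set_reference <- function(net, id) {
  stopifnot(inherits(net, "mf_network"))
  if (!id %in% net$nodes$id) {
    stop(sprintf("unknown reference node '%s'", id), call. = FALSE)
  }
  net$reference <- id
  net
}

#' @export
print.mf_network <- function(x, ...) {
  cat(sprintf("<mf_network> %d nodes, %d edges (%d channels, %d sources)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$kind == "channel"),
              sum(x$edges$kind != "channel")))
  if (!is.na(x$reference)) {
    cat(sprintf("  reference: %s at %g mbar\n", x$reference,
                from_si(x$ambient, "pressure")))
  }
  if (length(x$objectives)) {
    cat(sprintf("  objectives: %d registered\n", length(x$objectives)))
  }
  invisible(x)
}

#' @export
summary.mf_network <- function(object, ...) {
  print(object)
  kinds <- table(object$edges$kind)
  for (k in names(kinds)) cat(sprintf("  %-16s %d\n", k, kinds[[k]]))
  invisible(object)
}

# ---- internal compiled index -------------------------------------------------

# Compile a network into integer-indexed vectors for the solver and engine.
.net_index <- function(net) {
  stopifnot(inherits(net, "mf_network"))
  nodes <- net$nodes
  edges <- net$edges
  if (nrow(nodes) < 2L) stop("network needs at least two nodes", call. = FALSE)
  if (nrow(edges) < 1L) stop("network has no edges", call. = FALSE)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  if (anyDuplicated(edges$id)) stop("duplicate edge ids", call. = FALSE)
  if (!any(edges$kind != "channel")) {
    stop("network needs at least one pressure or flow source", call. = FALSE)
  }
  ref <- net$reference
  if (is.na(ref)) {
    out <- nodes$id[nodes$role == "outlet"]
    if (length(out) == 0L) {
      stop(paste0("no reference node: call set_reference() or mark an ",
                  "outlet node"), call. = FALSE)
    }
    ref <- out[[1L]]
  }
  nid <- seq_len(nrow(nodes))
  names(nid) <- nodes$id
  from <- unname(nid[edges$from])
  to <- unname(nid[edges$to])
  kind <- match(edges$kind, c("channel", "pressure_source", "flow_source"))
  is_ch <- kind == 1L
  mu <- net$fluid$mu_c
  R_base <- rep(NA_real_, nrow(edges))
  R_base[is_ch] <- .oriented_resistance(edges$length[is_ch],
                                        edges$width[is_ch],
                                        edges$height[is_ch], mu)
  idx <- list(
    n_nodes = nrow(nodes), n_edges = nrow(edges),
    node_id = nodes$id, node_role = nodes$role,
    edge_id = edges$id, kind = kind, from = from, to = to,
    L = edges$length, w = edges$width, h = edges$height,
    value = edges$value, R_base = R_base,
    label = edges$label, trap = edges$trap,
    pair = edges$pair, stream = edges$stream,
    ref = unname(nid[ref]), ambient = net$ambient,
    mu = mu
  )
  comp <- .components(idx)
  if (max(comp) > 1L) {
    parts <- split(nodes$id, comp)
    stop(sprintf("network is disconnected: components {%s}",
                 paste(vapply(parts, paste, "", collapse = ","),
                       collapse = "} {")), call. = FALSE)
  }
  idx
}

# connected components over the undirected support of the graph
.components <- function(idx) {
  n <- idx$n_nodes
  adj <- vector("list", n)
  for (e in seq_len(idx$n_edges)) {
    adj[[idx$from[e]]] <- c(adj[[idx$from[e]]], idx$to[e])
    adj[[idx$to[e]]] <- c(adj[[idx$to[e]]], idx$from[e])
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

# BFS spanning tree rooted at the reference node.
# Returns parent node/edge arrays and the BFS visit order.
.spanning_tree <- function(idx) {
  n <- idx$n_nodes
  heads <- vector("list", n)  # incident edges per node
  for (e in seq_len(idx$n_edges)) {
    heads[[idx$from[e]]] <- c(heads[[idx$from[e]]], e)
    heads[[idx$to[e]]] <- c(heads[[idx$to[e]]], e)
  }
  parent <- integer(n); parent_edge <- integer(n); depth <- integer(n)
  visited <- logical(n)
  root <- idx$ref
  visited[root] <- TRUE
  order <- integer(n); order[1L] <- root; head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- order[head]; head <- head + 1L
    for (e in heads[[v]]) {
      u <- if (idx$from[e] == v) idx$to[e] else idx$from[e]
      if (!visited[u]) {
        visited[u] <- TRUE
        parent[u] <- v; parent_edge[u] <- e; depth[u] <- depth[v] + 1L
        tail <- tail + 1L; order[tail] <- u
      }
    }
  }
  list(parent = parent, parent_edge = parent_edge, depth = depth,
       order = order, in_tree = seq_len(idx$n_edges) %in%
         parent_edge[parent_edge > 0L])
}

#' Fundamental cycle basis of a network
#'
#' Builds a spanning tree and closes one cycle per chord (non-tree edge), a
#' variant of the classic tree-based cycle-finding algorithm. For a connected
#' graph the basis has exactly `|E| - |V| + 1` cycles; a tree network yields an
#' empty basis. The choice of basis does not affect the solved flow state.
#'
#' @param net an [mf_network()].
#' @return a list of data.frames, one per cycle, with columns `edge` (edge id)
#'   and `sign` (+1 when the cycle traverses the edge in its counting
#'   direction, -1 against it).
#' @examples
#' # a triangle of channels has exactly one independent cycle
#' @export
cycle_basis <- function(net) {
  idx <- if (inherits(net, "mf_network")) .net_index(net) else net
  cyc <- .cycle_basis_idx(idx)
  lapply(cyc, function(cc) {
    data.frame(edge = idx$edge_id[cc$edge], sign = cc$sign,
               stringsAsFactors = FALSE)
  })
}

.cycle_basis_idx <- function(idx, tree = NULL) {
  if (is.null(tree)) tree <- .spanning_tree(idx)
  chords <- which(!tree$in_tree)
  lapply(chords, function(e) {
    u <- idx$from[e]; v <- idx$to[e]
    # traverse the cycle: u -> v along e, then tree path v .. u
    up_u <- integer(0); su <- numeric(0)
    up_v <- integer(0); sv <- numeric(0)
    a <- u; b <- v
    while (tree$depth[a] > tree$depth[b]) {
      pe <- tree$parent_edge[a]
      # cycle traverses parent[a] -> a (downward on u's side)
      up_u <- c(up_u, pe); su <- c(su, if (idx$to[pe] == a) 1 else -1)
      a <- tree$parent[a]
    }
    while (tree$depth[b] > tree$depth[a]) {
      pe <- tree$parent_edge[b]
      # cycle traverses b -> parent[b] (upward on v's side)
      up_v <- c(up_v, pe); sv <- c(sv, if (idx$from[pe] == b) 1 else -1)
      b <- tree$parent[b]
    }
    while (a != b) {
      pe <- tree$parent_edge[a]
      up_u <- c(up_u, pe); su <- c(su, if (idx$to[pe] == a) 1 else -1)
      a <- tree$parent[a]
      pe <- tree$parent_edge[b]
      up_v <- c(up_v, pe); sv <- c(sv, if (idx$from[pe] == b) 1 else -1)
      b <- tree$parent[b]
    }
    list(edge = c(e, up_v, rev(up_u)), sign = c(1, sv, rev(su)))
  })
}

# ---- equation assembly -------------------------------------------------------

#' Assemble the Kirchhoff-analogue linear system
#'
#' One flow-balance equation per node (sum of flows in equals sum of flows
#' out; the reference node is omitted) and one pressure equation per
#' fundamental cycle (the directed sum of pressure gradients around a closed
#' cycle is zero, with `dP = Q R*` substituted on channel edges and the fixed
#' gains on pressure sources). The unknown on a channel or pressure-source
#' edge is its flow rate; on a flow-source edge it is the pressure gain. The
#' system is square (`|E|` unknowns).
#'
#' @param net an [mf_network()].
#' @param resistances optional vector of effective channel resistances `R*`
#'   (SI, Pa s m^-3) named by edge id or ordered as `net$edges`; defaults to
#'   the bare channel resistances.
#' @return an object of class `mf_flow_system` (matrix, right-hand side and
#'   bookkeeping), to be solved with [solve_flow_state()].
#' @export
assemble_flow_system <- function(net, resistances = NULL) {
  idx <- if (inherits(net, "mf_network")) .net_index(net) else net
  tree <- .spanning_tree(idx)
  cycles <- .cycle_basis_idx(idx, tree)
  E <- idx$n_edges
  V <- idx$n_nodes
  if (length(cycles) != E - V + 1L) {
    stop(sprintf("inconsistent cycle count (%d, expected %d)",
                 length(cycles), E - V + 1L), call. = FALSE)
  }
  Rstar <- .resolve_resistances(idx, resistances)

  A <- matrix(0, nrow = E, ncol = E)
  b <- numeric(E)
  node_rows <- setdiff(seq_len(V), idx$ref)
  row_of_node <- integer(V)
  row_of_node[node_rows] <- seq_along(node_rows)
  q_unknown <- idx$kind != 3L  # channels and pressure sources
  for (e in seq_len(E)) {
    f <- idx$from[e]; t <- idx$to[e]
    if (q_unknown[e]) {
      if (row_of_node[f] > 0L) A[row_of_node[f], e] <- A[row_of_node[f], e] + 1
      if (row_of_node[t] > 0L) A[row_of_node[t], e] <- A[row_of_node[t], e] - 1
    } else {
      qf <- idx$value[e]
      if (row_of_node[f] > 0L) b[row_of_node[f]] <- b[row_of_node[f]] - qf
      if (row_of_node[t] > 0L) b[row_of_node[t]] <- b[row_of_node[t]] + qf
    }
  }
  # cycle rows: channel coefficients depend on R*; record their positions for
  # cheap updates when droplet configurations change
  cyc_row <- integer(0); cyc_col <- integer(0); cyc_sign <- numeric(0)
  nr0 <- length(node_rows)
  for (ci in seq_along(cycles)) {
    row <- nr0 + ci
    cc <- cycles[[ci]]
    for (j in seq_along(cc$edge)) {
      e <- cc$edge[j]; s <- cc$sign[j]
      if (idx$kind[e] == 1L) {
        cyc_row <- c(cyc_row, row); cyc_col <- c(cyc_col, e)
        cyc_sign <- c(cyc_sign, s)
      } else if (idx$kind[e] == 2L) {
        b[row] <- b[row] + s * idx$value[e]   # dP = -P_source
      } else {
        A[row, e] <- A[row, e] + s            # unknown pressure gain drop
      }
    }
  }
  lin <- (cyc_col - 1L) * E + cyc_row
  A[lin] <- A[lin] + cyc_sign * Rstar[cyc_col]

  structure(
    list(A = A, b = b, Rstar = Rstar, idx = idx, tree = tree,
         cycles = cycles, node_rows = node_rows,
         cyc_lin = lin, cyc_sign = cyc_sign, cyc_col = cyc_col,
         A0 = NULL),
    class = "mf_flow_system"
  )
}

.resolve_resistances <- function(idx, resistances) {
  Rstar <- idx$R_base
  if (!is.null(resistances)) {
    if (!is.null(names(resistances))) {
      m <- match(names(resistances), idx$edge_id)
      if (anyNA(m)) stop("unknown edge id in `resistances`", call. = FALSE)
      Rstar[m] <- unname(resistances)
    } else {
      if (length(resistances) != idx$n_edges) {
        stop("`resistances` must be named or of length |E|", call. = FALSE)
      }
      keep <- !is.na(resistances)
      Rstar[keep] <- resistances[keep]
    }
  }
  bad <- idx$kind == 1L & (!is.finite(Rstar) | Rstar <= 0)
  if (any(bad)) {
    stop(sprintf("non-positive or non-finite resistance on channel(s): %s",
                 paste(idx$edge_id[bad], collapse = ", ")), call. = FALSE)
  }
  Rstar
}

# refresh channel coefficients of an assembled system for new R* values
.update_system <- function(sys, Rstar) {
  A <- sys$A
  A[sys$cyc_lin] <- 0
  A[sys$cyc_lin] <- A[sys$cyc_lin] + sys$cyc_sign * Rstar[sys$cyc_col]
  sys$A <- A
  sys$Rstar <- Rstar
  sys
}

# ---- solving -----------------------------------------------------------------

#' Solve the flow state of a network
#'
#' Row-equilibrates the assembled system and solves it by dense LU
#' decomposition. Node pressures are then propagated from the reference node
#' along a spanning tree. Node-balance and cycle-pressure residuals are
#' reported and must be below 1e-9 relative for a healthy solve.
#'
#' @param system an [assemble_flow_system()] result.
#' @param net the network the system was assembled from (used for labels; may
#'   be omitted).
#' @return an object of class `mf_flow_state`: `$edges` (id, kind, `Q` in
#'   ul/min, `dP` in mbar), `$nodes` (id, `P` in mbar), `$residuals`, and the
#'   raw SI solution in `$si`.
#' @export
solve_flow_state <- function(system, net = NULL) {
  stopifnot(inherits(system, "mf_flow_system"))
  raw <- .solve_fast(system)
  idx <- system$idx
  structure(
    list(
      edges = data.frame(
        id = idx$edge_id,
        kind = c("channel", "pressure_source", "flow_source")[idx$kind],
        Q = from_si(raw$Q, "flow"),
        dP = from_si(raw$dP, "pressure"),
        stringsAsFactors = FALSE
      ),
      nodes = data.frame(id = idx$node_id, P = from_si(raw$P, "pressure"),
                         stringsAsFactors = FALSE),
      residuals = raw$residuals,
      si = raw
    ),
    class = "mf_flow_state"
  )
}

#' @rdname solve_flow_state
#' @param resistances optional effective channel resistances, as in
#'   [assemble_flow_system()].
#' @export
solve_flow <- function(net, resistances = NULL) {
  solve_flow_state(assemble_flow_system(net, resistances), net)
}

# core solver on an assembled system; returns SI vectors
.solve_fast <- function(sys) {
  A <- sys$A; b <- sys$b
  sc <- pmax(apply(abs(A), 1L, max), 1e-300)
  As <- A / sc; bs <- b / sc
  x <- tryCatch(
    {
      x0 <- solve(As, bs)
      r <- bs - As %*% x0
      if (max(abs(r)) > 1e-12 * max(abs(bs), 1e-300)) {
        x0 <- x0 + solve(As, r)       # one step of iterative refinement
      }
      drop(x0)
    },
    error = function(e) {
      stop(paste0("flow system is singular or inconsistent (", conditionMessage(e),
                  "); check that the network has a reference/outlet path and ",
                  "that flow sources do not form an inconsistent cut"),
           call. = FALSE)
    }
  )
  idx <- sys$idx
  E <- idx$n_edges
  Q <- numeric(E); dP <- numeric(E)
  ch <- idx$kind == 1L; ps <- idx$kind == 2L; fs <- idx$kind == 3L
  Q[ch] <- x[ch]; dP[ch] <- x[ch] * sys$Rstar[ch]
  Q[ps] <- x[ps]; dP[ps] <- -idx$value[ps]
  Q[fs] <- idx$value[fs]; dP[fs] <- x[fs]
  P <- .propagate_pressure(idx, sys$tree, dP)
  res <- .residuals(idx, sys, Q, dP)
  list(Q = Q, dP = dP, P = P, x = x, residuals = res)
}

# node pressures from the reference along the spanning tree;
# dP is the drop tail -> head
.propagate_pressure <- function(idx, tree, dP) {
  P <- numeric(idx$n_nodes)
  P[idx$ref] <- idx$ambient
  ord <- tree$order
  for (i in seq_along(ord)[-1L]) {
    v <- ord[i]
    e <- tree$parent_edge[v]
    p <- tree$parent[v]
    P[v] <- if (idx$to[e] == v) P[p] - dP[e] else P[p] + dP[e]
  }
  P
}

.residuals <- function(idx, sys, Q, dP) {
  # node balance: sum of signed flows at every non-reference node,
  # relative to the total throughflow of that node
  net_flow <- numeric(idx$n_nodes)
  mag_flow <- numeric(idx$n_nodes)
  nf <- rowsum(c(-Q, Q), c(idx$from, idx$to))
  net_flow[as.integer(rownames(nf))] <- nf[, 1L]
  mf <- rowsum(c(abs(Q), abs(Q)), c(idx$from, idx$to))
  mag_flow[as.integer(rownames(mf))] <- mf[, 1L]
  nn <- setdiff(seq_len(idx$n_nodes), idx$ref)
  # relative to the node throughflow, floored at 1e-3 of the network's flow
  # scale so that stagnant branches (throughflow at round-off level) measure
  # their absolute noise against the problem scale instead of against itself
  scale_q <- pmax(mag_flow[nn], max(abs(Q), 1e-300) * 1e-3)
  node_rel <- if (length(nn)) max(abs(net_flow[nn]) / scale_q) else 0
  # cycle pressure sums relative to the gradient magnitudes around the cycle,
  # floored at 1e-3 of the network's pressure scale for the same reason
  cycle_rel <- 0
  for (cc in sys$cycles) {
    s <- sum(cc$sign * dP[cc$edge])
    m <- sum(abs(cc$sign * dP[cc$edge]))
    cycle_rel <- max(cycle_rel, abs(s) / max(m, max(abs(dP), 1e-300) * 1e-3))
  }
  list(node = node_rel, cycle = cycle_rel)
}

#' @export
print.mf_flow_state <- function(x, ...) {
  cat(sprintf("<mf_flow_state> %d edges, %d nodes\n",
              nrow(x$edges), nrow(x$nodes)))
  cat(sprintf("  residuals: node %.2e, cycle %.2e (relative)\n",
              x$residuals$node, x$residuals$cycle))
  print(utils::head(x$edges, 10L))
  if (nrow(x$edges) > 10L) cat(sprintf("  ... %d more edges\n",
                                       nrow(x$edges) - 10L))
  invisible(x)
}

# ---- series-parallel reduction (analytic oracle) ----------------------------

#' Equivalent resistance by recursive series-parallel reduction
#'
#' Reduces the channel subnetwork between two terminal nodes by repeatedly
#' merging parallel edges and eliminating interior degree-2 nodes. Exact for
#' series-parallel topologies; used as an independent analytic oracle for the
#' Kirchhoff solver. Dangling branches (which carry no flow) are pruned.
#'
#' @param net an [mf_network()] (only channel edges are used).
#' @param from,to terminal node ids.
#' @param resistances optional named vector of channel resistances (SI)
#'   overriding the geometric ones.
#' @return the equivalent resistance in SI Pa s m^-3. Signals an error of
#'   class `dropnet_not_reducible` when the topology is not series-parallel.
#' @export
reduce_series_parallel <- function(net, from, to, resistances = NULL) {
  stopifnot(inherits(net, "mf_network"))
  ed <- net$edges[net$edges$kind == "channel", , drop = FALSE]
  if (nrow(ed) == 0L) stop("no channel edges to reduce", call. = FALSE)
  idx <- .net_index(net)
  ch <- idx$kind == 1L
  R <- .resolve_resistances(idx, resistances)[ch]
  a <- net$edges$from[net$edges$kind == "channel"]
  b <- net$edges$to[net$edges$kind == "channel"]
  if (!from %in% c(a, b) && !from %in% net$nodes$id) {
    stop("unknown terminal node", call. = FALSE)
  }
  repeat {
    changed <- FALSE
    # prune dangling interior branches
    repeat {
      degs <- table(c(a, b))
      dang <- setdiff(names(degs)[degs == 1L], c(from, to))
      if (!length(dang)) break
      keep <- !(a %in% dang | b %in% dang)
      a <- a[keep]; b <- b[keep]; R <- R[keep]
      changed <- TRUE
    }
    if (length(R) == 0L) {
      stop(errorCondition("network reduced to nothing between the terminals",
                          class = "dropnet_not_reducible"))
    }
    # merge parallel edges
    key <- paste(pmin(a, b), pmax(a, b))
    if (anyDuplicated(key)) {
      g <- split(seq_along(key), key)
      keep <- logical(length(key))
      for (ii in g) {
        keep[ii[1L]] <- TRUE
        if (length(ii) > 1L) {
          R[ii[1L]] <- 1 / sum(1 / R[ii])
          changed <- TRUE
        }
      }
      a <- a[keep]; b <- b[keep]; R <- R[keep]
    }
    if (length(R) == 1L && setequal(c(a, b), c(from, to))) return(R)
    # series-eliminate one interior degree-2 node
    degs <- table(c(a, b))
    cand <- setdiff(names(degs)[degs == 2L], c(from, to))
    done_series <- FALSE
    for (v in cand) {
      ii <- which(a == v | b == v)
      if (length(ii) != 2L) next
      e1 <- ii[1L]; e2 <- ii[2L]
      o1 <- if (a[e1] == v) b[e1] else a[e1]
      o2 <- if (a[e2] == v) b[e2] else a[e2]
      if (o1 == o2 && !v %in% c(from, to)) {
        # two edges between the same pair: handled by the parallel pass
        next
      }
      a[e1] <- o1; b[e1] <- o2; R[e1] <- R[e1] + R[e2]
      a <- a[-e2]; b <- b[-e2]; R <- R[-e2]
      changed <- TRUE; done_series <- TRUE
      break
    }
    if (length(R) == 1L && setequal(c(a, b), c(from, to))) return(R)
    if (!changed && !done_series) {
      stop(errorCondition(
        "network between the terminals is not series-parallel reducible",
        class = "dropnet_not_reducible"))
    }
  }
}
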