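# The trap-and-merge case study: a cascade of trapping-well pairs fed by two
# droplet streams, plus the three design-exploration drivers (minimal bypass
# length, maximal operating pressure, cascade loading time) and a qualitative
# robustness report.
#
# Each pair holds two facing wells connected by a narrow intersection. A
# droplet arriving at the entrance junction of an empty well must prefer the
# well over the bypass (Q_trap > Q_bypass); once the well is occupied the
# clogged exit gaps flip the ratio and later droplets take the bypass. A
# trapped droplet must not be squeezed into the facing well nor through its
# exit gaps: the corresponding pressure differences must stay below the
# Laplace pressures of the intersection and of the gaps.

#' Parameters of the cascaded trap-well network
#'
#' All lengths in um, pressures in mbar. The defaults are a single documented
#' reference geometry chosen to satisfy the model's validity constraints
#' (section ratios below one after orientation, confined droplets, capillary
#' number within the slip-factor window, trap-favouring flow split at the
#' default bypass length and gap width); the gap-width and bypass-length grid
#' explored in the studies is {15, 25} um x {3000, 4000, 5000} um.
#'
#' @param trap_radius trap well radius r; the chamber is modelled as a short
#'   wide channel of length and width `2 r`.
#' @param entrance_length L1, entrance channel from the junction to the well.
#' @param gap_length L2, length of the two exit gaps.
#' @param gap_width w_gap, width of the two exit gaps.
#' @param intersection_width w_i, width of the inter-trap intersection.
#' @param intersection_length length of the inter-trap intersection channel.
#' @param bypass_length L_bypass.
#' @param channel_width,channel_height cross-section of the ordinary
#'   connecting channels.
#' @param n_pairs number of cascaded trap pairs.
#' @param inlet_pressure applied pressure at both inlets, mbar (length 1 or 2).
#' @param fluid an [fluid()] object.
#' @param droplet_length,droplet_radius droplet plug length and radius, um.
#' @param inlet_channel_length,connector_length,outlet_channel_length plumbing
#'   lengths.
#' @param bypass_topology `"per_stream"` keeps each stream's bypass rejoining
#'   its own downstream node; `"shared"` additionally links the two downstream
#'   nodes of a pair into a manifold.
#' @return a validated list of class `trapwell_params`.
#' @export
trapwell_params <- function(trap_radius = 100, entrance_length = 200,
                            gap_length = 50, gap_width = 15,
                            intersection_width = 15,
                            intersection_length = 200,
                            bypass_length = 4000,
                            channel_width = 100, channel_height = 50,
                            n_pairs = 5, inlet_pressure = 50,
                            fluid = dropnet_default_fluid(),
                            droplet_length = 250, droplet_radius = 90,
                            inlet_channel_length = 1000,
                            connector_length = 400,
                            outlet_channel_length = 1000,
                            bypass_topology = c("per_stream", "shared")) {
  bypass_topology <- match.arg(bypass_topology)
  p <- list(trap_radius = trap_radius, entrance_length = entrance_length,
            gap_length = gap_length, gap_width = gap_width,
            intersection_width = intersection_width,
            intersection_length = intersection_length,
            bypass_length = bypass_length, channel_width = channel_width,
            channel_height = channel_height, n_pairs = as.integer(n_pairs),
            inlet_pressure = rep_len(inlet_pressure, 2L), fluid = fluid,
            droplet_length = droplet_length, droplet_radius = droplet_radius,
            inlet_channel_length = inlet_channel_length,
            connector_length = connector_length,
            outlet_channel_length = outlet_channel_length,
            bypass_topology = bypass_topology)
  num <- p[c("trap_radius", "entrance_length", "gap_length", "gap_width",
             "intersection_width", "intersection_length", "bypass_length",
             "channel_width", "channel_height", "droplet_length",
             "droplet_radius", "inlet_channel_length", "connector_length",
             "outlet_channel_length")]
  if (any(!vapply(num, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x) && x > 0, TRUE))) {
    stop("all trap-well dimensions must be single positive numbers (um)",
         call. = FALSE)
  }
  if (p$n_pairs < 1L) stop("`n_pairs` must be >= 1", call. = FALSE)
  if (any(p$inlet_pressure <= 0)) {
    stop("inlet pressures must be positive (mbar)", call. = FALSE)
  }
  if (p$gap_width >= p$channel_width) {
    stop("`gap_width` must be smaller than `channel_width`", call. = FALSE)
  }
  if (p$channel_height >= p$channel_width) {
    stop("`channel_height` must be below `channel_width` (section ratio < 1)",
         call. = FALSE)
  }
  if (p$droplet_radius > p$trap_radius) {
    warning("droplet radius exceeds the trap radius; squeeze thresholds use ",
            "the trap radius", call. = FALSE)
  }
  stopifnot(inherits(p$fluid, "mf_fluid"))
  class(p) <- "trapwell_params"
  p
}

#' Default two-phase system of the trap-well fixture
#'
#' Silicone-oil-like carrier (5 mPa s) with aqueous droplets (1 mPa s) and a
#' surfactant-free interfacial tension of 0.05 N/m.
#' @export
dropnet_default_fluid <- function() {
  fluid(viscosity_continuous = 5, viscosity_dispersed = 1,
        interfacial_tension = 0.05)
}

#' @export
print.trapwell_params <- function(x, ...) {
  cat("<trapwell_params>\n")
  cat(sprintf("  %d pair(s); L_bypass = %g um, w_gap = %g um, r = %g um\n",
              x$n_pairs, x$bypass_length, x$gap_width, x$trap_radius))
  cat(sprintf("  inlet pressures %g / %g mbar; topology %s\n",
              x$inlet_pressure[1], x$inlet_pressure[2], x$bypass_topology))
  invisible(x)
}

#' Build the cascaded trap-well network
#'
#' Constructs the two-stream network: each stream passes `n_pairs` trap
#' sections in series; a section is an entrance channel into the well chamber,
#' two parallel narrow exit gaps out of it, and a bypass from the entrance
#' junction to the downstream node. Facing wells of a pair are connected by a
#' narrow intersection channel. Objectives are registered on the network: one
#' flow-ratio objective per entrance junction, one inter-trap squeeze
#' objective per pair, one downstream squeeze objective per well.
#'
#' Node/edge counts are closed-form in the pair count: `8 n + 4` nodes and
#' `13 n + 5` edges (plus `n` manifold links for the shared topology).
#'
#' @param params a [trapwell_params()] object.
#' @return an [mf_network()] with objectives registered and the fixture
#'   parameters stored in `$meta$params`.
#' @export
build_trapwell_network <- function(params = trapwell_params()) {
  stopifnot(inherits(params, "trapwell_params"))
  p <- params
  w <- p$channel_width; h <- p$channel_height
  net <- mf_network(p$fluid)
  net <- add_node(net, "amb")
  net <- add_node(net, c("in1", "in2"), role = "inlet")
  net <- add_node(net, "out", role = "outlet")
  net <- set_reference(net, "amb")
  for (s in 1:2) {
    net <- add_pressure_source(net, sprintf("src%d", s), "amb",
                               sprintf("in%d", s), p$inlet_pressure[s])
  }
  for (s in 1:2) {
    for (k in seq_len(p$n_pairs)) {
      for (nd in c("J", "E", "C", "D")) {
        net <- add_node(net, sprintf("%s_%d_%d", nd, k, s))
      }
    }
  }
  nm <- function(base, k, s) sprintf("%s_%d_%d", base, k, s)
  for (s in 1:2) {
    net <- add_channel(net, sprintf("inlet%d", s), sprintf("in%d", s),
                       nm("J", 1, s), p$inlet_channel_length, w, h,
                       label = "inlet")
    for (k in seq_len(p$n_pairs)) {
      tr <- sprintf("t%d_s%d", k, s)
      net <- add_channel(net, nm("ent", k, s), nm("J", k, s), nm("E", k, s),
                         p$entrance_length, w, h, label = "entrance",
                         trap = tr, pair = k, stream = s)
      net <- add_channel(net, nm("ch", k, s), nm("E", k, s), nm("C", k, s),
                         2 * p$trap_radius, 2 * p$trap_radius, h,
                         label = "chamber", trap = tr, pair = k, stream = s)
      net <- add_channel(net, nm("gapA", k, s), nm("C", k, s), nm("D", k, s),
                         p$gap_length, p$gap_width, h, label = "gap",
                         trap = tr, pair = k, stream = s)
      net <- add_channel(net, nm("gapB", k, s), nm("C", k, s), nm("D", k, s),
                         p$gap_length, p$gap_width, h, label = "gap",
                         trap = tr, pair = k, stream = s)
      net <- add_channel(net, nm("byp", k, s), nm("J", k, s), nm("D", k, s),
                         p$bypass_length, w, h, label = "bypass",
                         pair = k, stream = s)
      if (k < p$n_pairs) {
        net <- add_channel(net, nm("conn", k, s), nm("D", k, s),
                           nm("J", k + 1, s), p$connector_length, w, h,
                           label = "connector", pair = k, stream = s)
      }
    }
    net <- add_channel(net, sprintf("outch%d", s),
                       nm("D", p$n_pairs, s), "out",
                       p$outlet_channel_length, w, h, label = "outlet")
  }
  for (k in seq_len(p$n_pairs)) {
    net <- add_channel(net, sprintf("ix_%d", k), nm("C", k, 1), nm("C", k, 2),
                       p$intersection_length, p$intersection_width, h,
                       label = "intersection", pair = k)
    if (p$bypass_topology == "shared") {
      net <- add_channel(net, sprintf("man_%d", k), nm("D", k, 1),
                         nm("D", k, 2), 2 * w, w, h, label = "manifold",
                         pair = k)
    }
  }
  net <- add_pressure_source(net, "wire_out", "out", "amb", 0,
                             label = "outlet_tie")

  obj <- list()
  for (k in seq_len(p$n_pairs)) {
    for (s in 1:2) {
      tr <- sprintf("t%d_s%d", k, s)
      obj[[length(obj) + 1L]] <- list(
        id = sprintf("ratio_%s", tr), type = "flow_ratio",
        trap_edge = nm("ent", k, s), bypass_edge = nm("byp", k, s), trap = tr)
      obj[[length(obj) + 1L]] <- list(
        id = sprintf("down_%s", tr), type = "squeeze_downstream",
        node_a = nm("C", k, s), node_b = nm("D", k, s),
        gap_width = p$gap_width, radius = p$trap_radius, trap = tr)
    }
    obj[[length(obj) + 1L]] <- list(
      id = sprintf("inter_p%d", k), type = "squeeze_intertrap",
      node_a = nm("C", k, 1), node_b = nm("C", k, 2),
      gap_width = p$intersection_width, radius = p$trap_radius)
  }
  net$objectives <- obj
  net$meta$params <- p
  net
}

#' Default loading schedule for a trap-well cascade
#'
#' Alternates droplets between the two inlets, two droplets per pair.
#'
#' @param params a [trapwell_params()].
#' @param n_droplets total droplets (default `2 * n_pairs`).
#' @param period time between consecutive injections, s.
#' @export
trapwell_schedule <- function(params, n_droplets = 2L * params$n_pairs,
                              period = 0.2) {
  alternating_schedule(c("in1", "in2"), n_droplets, period,
                       length = params$droplet_length,
                       radius = params$droplet_radius)
}

# does the first injected droplet enter the (empty) first trap of its stream?
.first_droplet_trapped <- function(params) {
  net <- build_trapwell_network(params)
  sch <- injection_schedule(0, "in1", params$droplet_length,
                            params$droplet_radius)
  sim <- simulate_droplets(net, sch, record = "light")
  identical(sim$droplets$trap[1L], "t1_s1")
}

#' Minimal bypass length that still traps the first droplet
#'
#' Stepwise reduces the bypass length and stops as soon as the first injected
#' droplet no longer enters the empty first trapping well (the trap-favouring
#' flow split `Q_trap > Q_bypass` breaks down); returns the smallest tested
#' length for which the droplet is still trapped. The search range must
#' bracket the transition: trapping must hold at the upper end and fail at the
#' lower end.
#'
#' @param params a [trapwell_params()] (its `bypass_length` is overridden by
#'   the scan).
#' @param range numeric length-2, bypass lengths in um bracketing the
#'   transition.
#' @param step scan step, um.
#' @param refine logical; bisect below the last passing step to tighten the
#'   boundary to `tol`.
#' @param tol bisection tolerance, um.
#' @return the minimal bypass length (um) with attributes `limiting` (always
#'   the flow-ratio objective) and `scan` (tested lengths and outcomes).
#' @export
min_bypass_length <- function(params = trapwell_params(),
                              range = c(500, 4000), step = 100,
                              refine = FALSE, tol = 10) {
  stopifnot(inherits(params, "trapwell_params"), length(range) == 2L,
            range[1] < range[2], step > 0)
  set_L <- function(L) { params$bypass_length <- L; params }
  hi_ok <- .first_droplet_trapped(set_L(range[2]))
  lo_ok <- .first_droplet_trapped(set_L(range[1]))
  if (!hi_ok || lo_ok) {
    stop(sprintf(paste0("search range [%g, %g] um does not bracket the ",
                        "trapping transition (trapped at upper end: %s, ",
                        "at lower end: %s)"),
                 range[1], range[2], hi_ok, lo_ok), call. = FALSE)
  }
  Ls <- seq(range[2], range[1], by = -step)
  trapped <- logical(length(Ls))
  best <- range[2]
  for (i in seq_along(Ls)) {
    trapped[i] <- .first_droplet_trapped(set_L(Ls[i]))
    if (!trapped[i]) break
    best <- Ls[i]
  }
  scan <- data.frame(bypass_length = Ls[seq_len(i)],
                     trapped = trapped[seq_len(i)])
  if (refine) {
    lo <- best - step; hi <- best
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (.first_droplet_trapped(set_L(mid))) hi <- mid else lo <- mid
    }
    best <- hi
  }
  structure(best, limiting = "flow_ratio", scan = scan)
}

# one loading run; returns the simulation (fail-fast on objective violations
# when requested)
.loading_run <- function(params, pressure = NULL, n_pairs = NULL,
                         period = 0.2, fail_fast = FALSE, t_end = Inf) {
  if (!is.null(n_pairs)) params$n_pairs <- as.integer(n_pairs)
  if (!is.null(pressure)) params$inlet_pressure <- rep_len(pressure, 2L)
  net <- build_trapwell_network(params)
  sch <- trapwell_schedule(params, period = period)
  simulate_droplets(net, sch, record = "light", fail_fast = fail_fast,
                    t_end = t_end)
}

#' Maximal inlet pressure before a squeeze objective is violated
#'
#' Increments the inlet pressure and runs a full loading of the cascade at
#' each level until any objective is violated at any evaluated flow state;
#' returns the largest tested pressure with a clean loading, together with the
#' objective that limits it (found to be the squeeze conditions: the pressure
#' across an occupied well and its narrow gaps exceeds the Laplace pressure).
#' Pressures above the 5 bar PDMS operating ceiling are refused.
#'
#' @param params a [trapwell_params()] (its `inlet_pressure` is overridden).
#' @param range numeric length-2, inlet pressures in mbar bracketing the first
#'   violation.
#' @param step increment, mbar.
#' @param period injection period of the loading schedule, s.
#' @return the maximal pressure (mbar) with attributes `limiting` (objective
#'   type of the first violated objective beyond the boundary) and `scan`.
#' @export
max_pressure <- function(params = trapwell_params(), range = c(25, 1000),
                         step = 25, period = 0.2) {
  stopifnot(inherits(params, "trapwell_params"), length(range) == 2L,
            range[1] < range[2], step > 0)
  if (range[2] > 5000) {
    stop("pressures above the 5 bar PDMS operating ceiling are not explored",
         call. = FALSE)
  }
  ps <- seq(range[1], range[2], by = step)
  ok <- logical(length(ps))
  limiting <- NA_character_
  last_ok <- NA_real_
  for (i in seq_along(ps)) {
    sim <- .loading_run(params, pressure = ps[i], period = period,
                        fail_fast = TRUE)
    ok[i] <- sim$stats$violations == 0L
    if (!ok[i]) {
      bad <- sim$objective_log[!sim$objective_log$pass, , drop = FALSE]
      limiting <- bad$type[1L]
      break
    }
    last_ok <- ps[i]
  }
  scan <- data.frame(pressure = ps[seq_len(i)], clean = ok[seq_len(i)])
  if (is.na(last_ok)) {
    stop(sprintf("already violated at the lower end of the range (%g mbar)",
                 range[1]), call. = FALSE)
  }
  if (all(ok[seq_len(i)])) {
    stop(sprintf("no objective violation up to %g mbar: range does not
 bracket the limit", range[2]), call. = FALSE)
  }
  structure(last_ok, limiting = limiting, scan = scan)
}

#' Loading time of a cascade
#'
#' Simulates the loading of `n_pairs` cascaded trap pairs from an alternating
#' two-stream schedule and measures the time from the first injection until
#' every pair is occupied and merged.
#'
#' @param params a [trapwell_params()].
#' @param n_pairs number of cascaded pairs (overrides `params`).
#' @param pressure inlet pressure, mbar (overrides `params`).
#' @param schedule optional [injection_schedule()]; defaults to the
#'   alternating loading schedule with `period`.
#' @param period injection period of the default schedule, s.
#' @param t_cap wall time cap of the simulated loading, s; exceeding it raises
#'   a timeout diagnostic (class `dropnet_timeout`) reporting the partial
#'   occupancy.
#' @return list of class `mf_loading`: `loading_time` (s), `n_pairs`,
#'   `pressure`, and the full `sim` trace.
#' @export
loading_time <- function(params = trapwell_params(),
                         n_pairs = params$n_pairs, pressure = NULL,
                         schedule = NULL, period = 0.2, t_cap = Inf) {
  params$n_pairs <- as.integer(n_pairs)
  if (!is.null(pressure)) params$inlet_pressure <- rep_len(pressure, 2L)
  net <- build_trapwell_network(params)
  if (is.null(schedule)) schedule <- trapwell_schedule(params, period = period)
  if (nrow(schedule) < 2L * params$n_pairs) {
    stop("schedule must supply at least two droplets per pair", call. = FALSE)
  }
  sim <- simulate_droplets(net, schedule, record = "light", t_end = t_cap)
  if (sim$stats$misroute) {
    stop("a droplet was routed into an occupied trap during loading; the
 configuration does not load correctly", call. = FALSE)
  }
  loaded <- all(!is.na(sim$occupancy)) && sim$stats$merged ==
    2L * params$n_pairs
  if (!loaded) {
    filled <- sum(!is.na(sim$occupancy))
    stop(errorCondition(
      sprintf("loading incomplete at t = %g s: %d of %d wells occupied",
              sim$stats$time, filled, 2L * params$n_pairs),
      class = "dropnet_timeout", occupancy = sim$occupancy))
  }
  merges <- sim$events[sim$events$kind == "merge", , drop = FALSE]
  t0 <- min(schedule$time)
  structure(list(loading_time = max(merges$time) - t0,
                 n_pairs = params$n_pairs,
                 pressure = params$inlet_pressure[1L], sim = sim),
            class = "mf_loading")
}

#' @export
print.mf_loading <- function(x, ...) {
  cat(sprintf(
    "<mf_loading> %d pairs at %g mbar: loading time %.3f s (%d events)\n",
    x$n_pairs, x$pressure, x$loading_time, x$sim$stats$n_events))
  invisible(x)
}

#' Qualitative robustness report over a set of specifications
#'
#' For each specification: the empty-trap flow-rate ratio `Q_trap/Q_bypass`
#' at the first junction, the maximal clean-loading pressure, the margin of
#' the bypass length over its minimal trapping value, and qualitative flags —
#' a ratio below `ratio_margin` means the trap/bypass decision is not robust
#' (a small obstruction could flip it), a maximal pressure below
#' `pressure_margin` makes the design sensitive to high input pressures, and
#' a bypass at or beyond `bypass_threshold` lengthens transit and cuts
#' throughput.
#'
#' @param specs list of [trapwell_params()] objects (one report row each).
#' @param ratio_margin minimal robust `Q_trap/Q_bypass` ratio.
#' @param pressure_margin minimal comfortable maximal pressure, mbar.
#' @param bypass_threshold bypass length flagged as throughput-limiting, um.
#' @param pressure_range,pressure_step passed to [max_pressure()].
#' @param bypass_range,bypass_step passed to [min_bypass_length()].
#' @return data.frame with one row per spec and a `problems` column.
#' @export
robustness_report <- function(specs, ratio_margin = 2,
                              pressure_margin = 100,
                              bypass_threshold = 5000,
                              pressure_range = c(25, 1000),
                              pressure_step = 25,
                              bypass_range = c(500, 6000),
                              bypass_step = 100) {
  if (inherits(specs, "trapwell_params")) specs <- list(specs)
  stopifnot(length(specs) >= 1L)
  rows <- lapply(seq_along(specs), function(i) {
    p <- specs[[i]]
    stopifnot(inherits(p, "trapwell_params"))
    net <- build_trapwell_network(p)
    fs <- solve_flow(net)
    qt <- fs$edges$Q[fs$edges$id == "ent_1_1"]
    qb <- fs$edges$Q[fs$edges$id == "byp_1_1"]
    ratio <- qt / qb
    pmax_v <- tryCatch(as.numeric(max_pressure(p, pressure_range,
                                               pressure_step)),
                       error = function(e) NA_real_)
    lmin <- tryCatch(as.numeric(min_bypass_length(p, bypass_range,
                                                  bypass_step)),
                     error = function(e) NA_real_)
    problems <- character(0)
    if (ratio < ratio_margin) {
      problems <- c(problems, "no robust flow rate ratio")
    }
    if (!is.na(pmax_v) && pmax_v < pressure_margin) {
      problems <- c(problems, "sensitive to high input pressures")
    }
    if (p$bypass_length >= bypass_threshold) {
      problems <- c(problems, "bypass length decreases throughput")
    }
    data.frame(
      id = i, bypass_length = p$bypass_length, gap_width = p$gap_width,
      flow_ratio = ratio, max_pressure = pmax_v, min_bypass = lmin,
      bypass_margin = p$bypass_length - lmin,
      problems = if (length(problems)) paste(problems, collapse = "; ")
                 else "-",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mf_robustness", "data.frame")
  out
}
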