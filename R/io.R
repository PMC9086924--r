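# Structured-text network documents (YAML), CSV/JSON result writing and
# seeded synthetic test-network generators.
#
# The document is a plain YAML/JSON-compatible data model with a version tag
# and a fixed unit declaration: lengths um, pressures mbar, flows ul/min,
# viscosities mPa s, interfacial tension N/m, time s. Unknown keys are
# rejected so typos fail loudly rather than being silently ignored.

.DOC_UNITS <- list(length = "um", pressure = "mbar", flow = "ul_min",
                   viscosity = "mPa_s", interfacial_tension = "N_m",
                   time = "s")

.check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop(sprintf("unknown key(s) at %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Read a network specification document
#'
#' Loads a YAML network document (channel dimensions, network structure,
#' applied pressures or flow rates, fluid properties, injection schedule,
#' objectives, simulation options), validates it against the schema and
#' builds the simulation inputs. Units are fixed per field group and declared
#' in the document's `units` block; values are converted to SI on entry.
#'
#' @param path path to a YAML file (as written by [write_network_spec()]).
#' @return a list with `network` (an [mf_network()] with objectives
#'   registered), `schedule` (an [injection_schedule()] or NULL), `options`
#'   (simulation options list) and `document` (the raw validated document).
#' @export
read_network_spec <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("no such network spec: %s", path), call. = FALSE)
  }
  doc <- yaml::read_yaml(path)
  realize_network_document(doc)
}

#' @rdname read_network_spec
#' @param doc a network document list (the parsed YAML).
#' @export
realize_network_document <- function(doc) {
  .check_keys(doc, c("version", "units", "fluid", "nodes", "edges",
                     "reference", "ambient_pressure", "injections",
                     "objectives", "options"), "document root")
  if (is.null(doc$version)) {
    stop("network document lacks a `version` tag", call. = FALSE)
  }
  if (!identical(as.integer(doc$version), 1L)) {
    stop(sprintf("unsupported document version %s", doc$version),
         call. = FALSE)
  }
  if (!is.null(doc$units)) {
    .check_keys(doc$units, names(.DOC_UNITS), "units")
    for (k in names(doc$units)) {
      if (!identical(doc$units[[k]], .DOC_UNITS[[k]])) {
        stop(sprintf("inconsistent unit for %s: '%s' (this format fixes '%s')",
                     k, doc$units[[k]], .DOC_UNITS[[k]]), call. = FALSE)
      }
    }
  }
  if (is.null(doc$fluid)) stop("document lacks a `fluid` block", call. = FALSE)
  .check_keys(doc$fluid, c("viscosity_continuous", "viscosity_dispersed",
                           "interfacial_tension", "density"), "fluid")
  fl <- fluid(
    viscosity_continuous = doc$fluid$viscosity_continuous,
    viscosity_dispersed = doc$fluid$viscosity_dispersed %||% NA_real_,
    interfacial_tension = doc$fluid$interfacial_tension %||% 0,
    density = doc$fluid$density %||% NA_real_
  )
  net <- mf_network(fl, ambient_pressure = doc$ambient_pressure %||% 0)
  if (is.null(doc$nodes) || !length(doc$nodes)) {
    stop("document lacks `nodes`", call. = FALSE)
  }
  for (nd in doc$nodes) {
    .check_keys(nd, c("id", "role"), sprintf("node '%s'", nd$id %||% "?"))
    if (is.null(nd$id)) stop("node without id", call. = FALSE)
    net <- add_node(net, nd$id, role = nd$role %||% "junction")
  }
  if (!any(vapply(doc$nodes, function(nd)
    identical(nd$role, "outlet"), TRUE)) && is.null(doc$reference)) {
    stop("document has no outlet node and no reference", call. = FALSE)
  }
  if (is.null(doc$edges) || !length(doc$edges)) {
    stop("document lacks `edges`", call. = FALSE)
  }
  for (ed in doc$edges) {
    id <- ed$id %||% stop("edge without id", call. = FALSE)
    kind <- ed$kind %||% "channel"
    if (kind == "channel") {
      .check_keys(ed, c("id", "kind", "from", "to", "length", "width",
                        "height", "label", "trap", "pair", "stream"),
                  sprintf("edge '%s'", id))
      net <- add_channel(net, id, ed$from, ed$to, ed$length, ed$width,
                         ed$height, label = ed$label %||% NA_character_,
                         trap = ed$trap %||% NA_character_,
                         pair = ed$pair %||% NA_integer_,
                         stream = ed$stream %||% NA_integer_)
    } else if (kind == "pressure_source") {
      .check_keys(ed, c("id", "kind", "from", "to", "value", "label"),
                  sprintf("edge '%s'", id))
      net <- add_pressure_source(net, id, ed$from, ed$to, ed$value,
                                 label = ed$label %||% NA_character_)
    } else if (kind == "flow_source") {
      .check_keys(ed, c("id", "kind", "from", "to", "value", "label"),
                  sprintf("edge '%s'", id))
      net <- add_flow_source(net, id, ed$from, ed$to, ed$value,
                             label = ed$label %||% NA_character_)
    } else {
      stop(sprintf("edge '%s': unknown kind '%s'", id, kind), call. = FALSE)
    }
  }
  if (!is.null(doc$reference)) net <- set_reference(net, doc$reference)
  schedule <- NULL
  if (!is.null(doc$injections) && length(doc$injections)) {
    for (inj in doc$injections) {
      .check_keys(inj, c("time", "inlet", "length", "radius"), "injections")
    }
    schedule <- injection_schedule(
      vapply(doc$injections, `[[`, 0, "time"),
      vapply(doc$injections, `[[`, "", "inlet"),
      vapply(doc$injections, function(x) x$length %||% 250, 0),
      vapply(doc$injections, function(x) x$radius %||% 90, 0)
    )
  }
  if (!is.null(doc$objectives)) {
    for (ob in doc$objectives) {
      .check_keys(ob, c("id", "type", "trap_edge", "bypass_edge", "trap",
                        "node_a", "node_b", "gap_width", "radius"),
                  sprintf("objective '%s'", ob$id %||% "?"))
    }
    net$objectives <- doc$objectives
  }
  opts <- doc$options %||% list()
  .check_keys(opts, c("t_end", "fail_fast", "clog_factor", "slip_factor",
                      "plug_factor", "record"), "options")
  # validate the network is solvable-shaped early (structure errors surface
  # at read time, not mid-simulation)
  invisible(.net_index(net))
  list(network = net, schedule = schedule, options = opts, document = doc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a network specification document
#'
#' Serialises a network (plus optional schedule and options) to the YAML
#' document format of [read_network_spec()]; writing and re-reading is an
#' identity on the document.
#'
#' @param net an [mf_network()].
#' @param path output file path.
#' @param schedule optional [injection_schedule()].
#' @param options optional simulation option list.
#' @return `path`, invisibly.
#' @export
write_network_spec <- function(net, path, schedule = NULL, options = NULL) {
  doc <- as_network_document(net, schedule, options)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
as_network_document <- function(net, schedule = NULL, options = NULL) {
  stopifnot(inherits(net, "mf_network"))
  drop_na <- function(x) x[!vapply(x, function(v)
    is.null(v) || (length(v) == 1L && is.na(v)), TRUE)]
  nodes <- lapply(seq_len(nrow(net$nodes)), function(i) {
    list(id = net$nodes$id[i], role = net$nodes$role[i])
  })
  edges <- lapply(seq_len(nrow(net$edges)), function(i) {
    e <- net$edges[i, ]
    if (e$kind == "channel") {
      drop_na(list(id = e$id, kind = "channel", from = e$from, to = e$to,
                   length = from_si(e$length, "length"),
                   width = from_si(e$width, "length"),
                   height = from_si(e$height, "length"),
                   label = e$label, trap = e$trap,
                   pair = e$pair, stream = e$stream))
    } else {
      drop_na(list(id = e$id, kind = e$kind, from = e$from, to = e$to,
                   value = if (e$kind == "pressure_source")
                     from_si(e$value, "pressure") else
                     from_si(e$value, "flow"),
                   label = e$label))
    }
  })
  doc <- list(
    version = 1L,
    units = .DOC_UNITS,
    fluid = drop_na(list(
      viscosity_continuous = from_si(net$fluid$mu_c, "viscosity"),
      viscosity_dispersed = if (is.na(net$fluid$mu_d)) NULL else
        from_si(net$fluid$mu_d, "viscosity"),
      interfacial_tension = net$fluid$gamma,
      density = if (is.na(net$fluid$density)) NULL else net$fluid$density
    )),
    nodes = nodes,
    edges = edges,
    reference = if (is.na(net$reference)) NULL else net$reference,
    ambient_pressure = from_si(net$ambient, "pressure")
  )
  if (!is.null(schedule) && nrow(schedule)) {
    doc$injections <- lapply(seq_len(nrow(schedule)), function(i) {
      list(time = schedule$time[i], inlet = schedule$inlet[i],
           length = schedule$length[i], radius = schedule$radius[i])
    })
  }
  if (length(net$objectives)) doc$objectives <- net$objectives
  if (!is.null(options) && length(options)) doc$options <- options
  doc[!vapply(doc, is.null, TRUE)]
}

# ---- result writing ----------------------------------------------------------

#' Write simulation results to CSV tables and a JSON manifest
#'
#' Writes, with a stable locale-independent column order:
#' `events.csv` (the event log), `trajectories.csv` (droplet channel entries:
#' time, droplet, edge, fractional position, status),
#' `residence_times.csv` (per droplet per channel), `objective_reports.csv`,
#' `flow_states.csv` (per recorded event: edge, Q in ul/min, dP in mbar; only
#' when flow states were recorded) and `manifest.json` (library version,
#' options, droplet/objective counters, MD5 of each table).
#'
#' @param sim a [simulate_droplets()] result.
#' @param out_dir output directory (created if missing).
#' @return the vector of written file paths, invisibly.
#' @export
write_results <- function(sim, out_dir) {
  stopifnot(inherits(sim, "droplet_simulation"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir),
                  call. = FALSE)
  }
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE, na = "")
    p
  }
  paths <- character(0)
  paths <- c(paths, wcsv(sim$events, "events.csv"))
  traj <- sim$events[!is.na(sim$events$droplet) & !is.na(sim$events$edge_to),
                     c("time", "droplet", "edge_to", "kind"), drop = FALSE]
  names(traj) <- c("time", "droplet", "edge", "kind")
  traj$position <- ifelse(traj$kind == "trap_capture", 1, 0)
  traj$status <- ifelse(traj$kind == "trap_capture", "trapped", "flowing")
  paths <- c(paths, wcsv(traj[, c("time", "droplet", "edge", "position",
                                  "status")], "trajectories.csv"))
  paths <- c(paths, wcsv(sim$residence, "residence_times.csv"))
  paths <- c(paths, wcsv(sim$objective_log, "objective_reports.csv"))
  if (!is.null(sim$flow_states)) {
    fsq <- sim$flow_states$Q
    long <- data.frame(
      event = rep(seq_len(nrow(fsq)), each = ncol(fsq)),
      time = rep(sim$flow_states$time, each = ncol(fsq)),
      edge = rep(colnames(fsq), times = nrow(fsq)),
      Q_ul_min = as.vector(t(fsq)),
      stringsAsFactors = FALSE
    )
    paths <- c(paths, wcsv(long, "flow_states.csv"))
  }
  manifest <- list(
    library = "dropnet",
    version = as.character(utils::packageVersion("dropnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    options = sim$options[c("t_end", "clog_factor", "slip", "plug",
                            "fail_fast", "record")],
    stats = sim$stats,
    tables = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                     basename(paths)))
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(c(paths, mp))
}

# ---- synthetic network generators -------------------------------------------

#' Generate a synthetic test network document
#'
#' Reproducible fixtures for solver testing: `"ladder"` (a series rail with
#' rungs to ground — series-parallel reducible, `2 k + 1` channel edges for
#' `k` rungs), `"loop"` (a single cycle of `k` channels), and
#' `"random"` (a random connected graph: spanning tree plus random chords).
#' Every generated network has one pressure source, one outlet at the
#' reference, positive channel resistances, and is solvable.
#'
#' @param kind `"ladder"`, `"loop"` or `"random"`.
#' @param size rung count (ladder), cycle length (loop) or target edge count
#'   (random), >= 1.
#' @param seed RNG seed; the same seed yields the identical document.
#' @param pressure source pressure, mbar.
#' @return a network document list (see [read_network_spec()]); realize with
#'   [realize_network_document()].
#' @export
generate_test_network <- function(kind = c("ladder", "loop", "random"),
                                  size, seed = 1L, pressure = 50) {
  kind <- match.arg(kind)
  stopifnot(size >= 1L)
  rng <- .seeded_rng(seed)
  geom <- function() list(length = round(rng(1, 500, 5000)),
                          width = round(rng(1, 60, 200)),
                          height = round(rng(1, 20, 50)))
  nodes <- list(); edges <- list()
  add_n <- function(id, role = "junction") {
    nodes[[length(nodes) + 1L]] <<- list(id = id, role = role)
  }
  add_ch <- function(id, from, to) {
    g <- geom()
    edges[[length(edges) + 1L]] <<- c(list(id = id, kind = "channel",
                                           from = from, to = to), g)
  }
  if (kind == "ladder") {
    add_n("g", role = "outlet")
    add_n("n0", role = "inlet")
    for (i in seq_len(size)) add_n(sprintf("n%d", i))
    for (i in seq_len(size)) {
      add_ch(sprintf("rail%d", i), sprintf("n%d", i - 1L), sprintf("n%d", i))
      add_ch(sprintf("rung%d", i), sprintf("n%d", i), "g")
    }
    add_ch("rail0", "n0", "g")
    edges[[length(edges) + 1L]] <- list(id = "src", kind = "pressure_source",
                                        from = "g", to = "n0",
                                        value = pressure)
  } else if (kind == "loop") {
    k <- max(size, 2L)
    add_n("n1", role = "inlet")
    for (i in 2:k) add_n(sprintf("n%d", i))
    add_n("g", role = "outlet")
    for (i in seq_len(k)) {
      add_ch(sprintf("c%d", i), sprintf("n%d", i),
             if (i < k) sprintf("n%d", i + 1L) else "g")
    }
    add_ch("back", "n1", "g")
    edges[[length(edges) + 1L]] <- list(id = "src", kind = "pressure_source",
                                        from = "g", to = "n1",
                                        value = pressure)
  } else {
    n_edges <- max(size, 2L)
    n_nodes <- max(3L, ceiling(n_edges * 0.6))
    ref <- sprintf("n%d", n_nodes)
    add_n("n1", role = "inlet")
    for (i in 2:(n_nodes - 1L)) add_n(sprintf("n%d", i))
    add_n(sprintf("n%d", n_nodes), role = "outlet")
    eid <- 0L
    for (i in 2:n_nodes) {   # random spanning tree
      j <- if (i == 2L) 1L else floor(rng(1, 1, i - 1L + 0.999))
      eid <- eid + 1L
      add_ch(sprintf("e%d", eid), sprintf("n%d", j), sprintf("n%d", i))
    }
    while (eid < n_edges - 1L) {  # chords
      a <- floor(rng(1, 1, n_nodes + 0.999))
      b <- floor(rng(1, 1, n_nodes + 0.999))
      if (a == b) next
      eid <- eid + 1L
      add_ch(sprintf("e%d", eid), sprintf("n%d", a), sprintf("n%d", b))
    }
    edges[[length(edges) + 1L]] <- list(id = "src", kind = "pressure_source",
                                        from = sprintf("n%d", n_nodes),
                                        to = "n1", value = pressure)
  }
  list(
    version = 1L,
    units = .DOC_UNITS,
    fluid = list(viscosity_continuous = 5, interfacial_tension = 0.05),
    nodes = nodes,
    edges = edges,
    reference = if (kind == "random") ref else "g",
    ambient_pressure = 0
  )
}

# small self-contained uniform RNG (linear congruential), so generated
# fixtures never disturb or depend on the session RNG state
.seeded_rng <- function(seed) {
  state <- as.double((as.integer(seed) %% 2147483647L) + 1L)
  function(n, lo = 0, hi = 1) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (state * 16807) %% 2147483647
      out[i] <- lo + (hi - lo) * (state - 1) / 2147483645
    }
    out
  }
}
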