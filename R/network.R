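# 0D surrogate of the aortic domain: chains of lumped resistive (optionally
# inertial) lumen segments for the trunk, true lumen and false lumen,
# tear elements connecting the lumina through the septum, Windkessel
# outlets at the branch vessels, and a single inlet source.

#' Effective circular diameter of a tear
#'
#' Diameter of the circle with the same area: `d = 2 * sqrt(A / pi)`.
#'
#' @param area tear area, mm^2, > 0.
#' @return Effective diameter, mm.
#' @examples
#' effective_diameter(135)  # ~13.1 mm (primary entry tear)
#' effective_diameter(68)   # ~9.3 mm (exit tear)
#' @export
effective_diameter <- function(area) {
  if (any(area <= 0)) stop("tear area must be positive")
  2 * sqrt(area / pi)
}

#' Poiseuille resistance of a cylindrical conduit
#'
#' `R = 8 * mu * length / (pi * radius^4)` for fully developed laminar flow.
#'
#' @param radius lumen radius, mm, > 0.
#' @param length conduit length, mm, > 0.
#' @param blood a [blood_properties()].
#' @return Resistance, g/(mm^4 s).
#' @export
poiseuille_resistance <- function(radius, length, blood = blood_properties()) {
  if (any(radius <= 0) || any(length <= 0))
    stop("radius and length must be positive")
  8 * blood$mu * length / (pi * radius^4)
}

#' Hydraulic resistance of a septal tear
#'
#' Models the tear as a short cylindrical channel through the septum with
#' the tear's effective diameter: Poiseuille resistance of a conduit of
#' radius `effective_diameter(area)/2` and length `channel_length`. An
#' optional quadratic orifice loss (coefficient `rho / (2 Cd^2 A^2)`) can
#' be switched on in the network configuration.
#'
#' @param area tear area, mm^2.
#' @param channel_length septum thickness, mm.
#' @param blood a [blood_properties()].
#' @return Linear resistance, g/(mm^4 s).
#' @export
tear_resistance <- function(area, channel_length, blood = blood_properties()) {
  poiseuille_resistance(effective_diameter(area) / 2, channel_length, blood)
}

# quadratic orifice coefficient K such that dP = K * Q * |Q|
tear_orifice_coeff <- function(area, blood, Cd = 0.61) {
  blood$rho / (2 * Cd^2 * area^2)
}

#' Read or write a network configuration as JSON
#'
#' The configuration is a list with elements `variant`, `segments`
#' (columns `name,from,to,radius,length,lumen`, or an explicit `R`),
#' `tears` (`name,from,to,area,channel_length,role`), `outlets`
#' (`name,node` with names resolving against the outlet registry),
#' `inlet` (node name) and optionally `stations` (matched true/false
#' lumen probes). See [fixture_configs()] for generated examples.
#'
#' @param path file path.
#' @param config a configuration list.
#' @return `read_network_config` returns the configuration list.
#' @export
read_network_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  cfg
}

#' @rdname read_network_config
#' @export
write_network_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

# breadth-first connectivity over an undirected edge list of node indices
bfs_reachable <- function(n_nodes, from, to, start) {
  adj <- vector("list", n_nodes)
  for (k in seq_along(from)) {
    adj[[from[k]]] <- c(adj[[from[k]]], to[k])
    adj[[to[k]]] <- c(adj[[to[k]]], from[k])
  }
  seen <- logical(n_nodes)
  queue <- start
  seen[start] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  seen
}

#' Build a validated network topology from a configuration
#'
#' Resolves segment and tear resistances from geometry, attaches the
#' Windkessel outlets from the registry, checks connectivity (every node
#' reachable from the inlet) and that every tear connects a true-lumen-side
#' node to a false-lumen-side node, and returns the assembled topology
#' ready for [simulate_network()].
#'
#' @param config configuration list (see [read_network_config()] and
#'   [fixture_configs()]).
#' @param registry outlet registry, default [load_table4_registry()].
#' @param blood a [blood_properties()]; overridden by `config$blood`.
#' @return Object of class `network_topology`.
#' @export
build_network <- function(config, registry = load_table4_registry(),
                          blood = blood_properties()) {
  if (!is.null(config$blood))
    blood <- blood_properties(config$blood$rho, config$blood$mu)
  seg <- as.data.frame(config$segments)
  if (nrow(seg) == 0L) stop("configuration has no segments")
  tears <- if (!is.null(config$tears) && NROW(config$tears) > 0)
    as.data.frame(config$tears) else NULL
  out <- as.data.frame(config$outlets)
  if (!all(c("name", "node") %in% names(out)))
    stop("outlets must have columns name,node")
  unknown <- setdiff(out$name, names(registry))
  if (length(unknown))
    stop("unknown outlet name (not in registry): ", unknown[1L])

  if (is.null(seg$R)) seg$R <- NA_real_
  need_geom <- is.na(seg$R)
  if (any(need_geom))
    seg$R[need_geom] <- poiseuille_resistance(seg$radius[need_geom],
                                              seg$length[need_geom], blood)
  if (is.null(seg$L)) seg$L <- 0
  seg$L[is.na(seg$L)] <- 0
  if (is.null(seg$lumen)) seg$lumen <- "trunk"
  if (any(seg$R <= 0)) stop("segment resistance must be positive: ",
                            seg$name[seg$R <= 0][1L])

  elem <- data.frame(name = seg$name, type = "segment",
                     from = seg$from, to = seg$to,
                     R = seg$R, L = seg$L, K = 0,
                     lumen = seg$lumen, stringsAsFactors = FALSE)
  if (!is.null(tears)) {
    use_orifice <- isTRUE(config$tear_orifice)
    tr <- data.frame(name = tears$name, type = "tear",
                     from = tears$from, to = tears$to,
                     R = tear_resistance(tears$area, tears$channel_length,
                                         blood),
                     L = 0,
                     K = if (use_orifice)
                       tear_orifice_coeff(tears$area, blood) else 0,
                     lumen = "tear", stringsAsFactors = FALSE)
    elem <- rbind(elem, tr)
  }

  nodes <- unique(c(elem$from, elem$to, out$node, config$inlet))
  idx <- function(x) match(x, nodes)
  if (anyNA(idx(out$node)))
    stop("outlet attached to unknown node")
  inlet_i <- idx(config$inlet)
  if (is.na(inlet_i)) stop("inlet node not found in network")

  # connectivity: every node reachable from the inlet through segments/tears
  # and outlet attachments
  seen <- bfs_reachable(length(nodes), idx(elem$from), idx(elem$to), inlet_i)
  if (!all(seen))
    stop("network is disconnected: node '", nodes[!seen][1L],
         "' unreachable from the inlet")

  # lumen-side tags per node from incident segments (trunk counts as the
  # true-lumen side: the entry tear communicates the undissected trunk with
  # the false lumen)
  tl_nodes <- unique(c(seg$from[seg$lumen %in% c("true_lumen", "trunk")],
                       seg$to[seg$lumen %in% c("true_lumen", "trunk")]))
  fl_nodes <- unique(c(seg$from[seg$lumen == "false_lumen"],
                       seg$to[seg$lumen == "false_lumen"]))
  if (!is.null(tears)) {
    for (k in seq_len(nrow(tears))) {
      a <- tears$from[k]
      b <- tears$to[k]
      ok <- (a %in% tl_nodes && b %in% fl_nodes) ||
            (a %in% fl_nodes && b %in% tl_nodes)
      if (!ok)
        stop("tear '", tears$name[k],
             "' does not connect a true-lumen node to a false-lumen node")
    }
  }

  node_C <- stats::setNames(rep(0, length(nodes)), nodes)
  if (!is.null(config$node_compliance)) {
    nc <- config$node_compliance
    node_C[names(nc)] <- as.numeric(nc)
  }

  structure(list(nodes = nodes,
                 elements = elem,
                 from_i = idx(elem$from), to_i = idx(elem$to),
                 outlets = data.frame(name = out$name, node = out$node,
                                      node_i = idx(out$node),
                                      stringsAsFactors = FALSE),
                 outlet_params = lapply(out$name, function(nm) registry[[nm]]),
                 node_C = node_C,
                 inlet_i = inlet_i,
                 inlet = config$inlet,
                 stations = if (!is.null(config$stations))
                   as.data.frame(config$stations) else NULL,
                 blood = blood,
                 variant = config$variant %||% "custom"),
            class = "network_topology")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf("<network_topology> '%s': %d nodes, %d segments, %d tears, %d outlets\n",
              x$variant, length(x$nodes),
              sum(x$elements$type == "segment"),
              sum(x$elements$type == "tear"), nrow(x$outlets)))
  invisible(x)
}

#' Count tear elements in a topology or configuration
#'
#' @param x a `network_topology` or configuration list.
#' @return Integer number of tear connections.
#' @export
n_tears <- function(x) {
  if (inherits(x, "network_topology")) sum(x$elements$type == "tear")
  else NROW(x$tears)
}
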