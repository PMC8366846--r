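#' Construct a dendritic river network
#'
#' A river network is a directed tree of stream segments draining to a
#' single outlet. Each segment (edge) runs from an upstream node to a
#' downstream node; positions along a segment are measured as fractions
#' from the upstream end (0) to the downstream end (1). Dams and sampling
#' sites are placed on segments.
#'
#' @param edges data.frame with columns `edge`, `from`, `to`, `length`
#'   (`length` optional, default 1)
#' @param dams optional data.frame with columns `edge`, `pos`
#' @param sites optional data.frame with columns `site`, `edge`, `pos`
#' @return object of class `river_network`
#' @export
river_network <- function(edges, dams = NULL, sites = NULL) {
  edges <- as.data.frame(edges)
  need <- c("edge", "from", "to")
  if (!all(need %in% names(edges)))
    stop("edge table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"length" %in% names(edges)) edges$length <- 1
  edges$edge <- as.character(edges$edge)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (anyDuplicated(edges$edge))
    stop("duplicate edge identifiers", call. = FALSE)
  if (any(edges$length <= 0))
    stop("edge lengths must be positive", call. = FALSE)
  nodes <- unique(c(edges$from, edges$to))
  out_deg <- table(factor(edges$from, levels = nodes))
  if (any(out_deg > 1))
    stop("node '", names(out_deg)[out_deg > 1][1],
         "' has multiple downstream edges: not dendritic", call. = FALSE)
  outlets <- nodes[out_deg == 0]
  if (length(outlets) != 1)
    stop("network must have exactly one outlet, found ", length(outlets),
         call. = FALSE)
  # acyclicity: follow the unique downstream pointer from every node
  down_edge <- setNames(edges$edge, edges$from) # node -> its downstream edge
  to_of <- setNames(edges$to, edges$edge)
  for (n in nodes) {
    seen <- character(0)
    cur <- n
    while (!is.na(down_edge[cur])) {
      if (cur %in% seen) stop("cycle detected at node '", cur, "'",
                              call. = FALSE)
      seen <- c(seen, cur)
      cur <- unname(to_of[down_edge[cur]])
    }
  }
  check_placement <- function(df, what, id_col = NULL) {
    if (is.null(df)) return(NULL)
    df <- as.data.frame(df)
    if (!"pos" %in% names(df)) df$pos <- 0.5
    df$edge <- as.character(df$edge)
    bad <- setdiff(df$edge, edges$edge)
    if (length(bad))
      stop(what, " on unknown edge '", bad[1], "'", call. = FALSE)
    if (any(df$pos < 0 | df$pos > 1))
      stop(what, " position outside [0, 1]", call. = FALSE)
    if (!is.null(id_col)) df[[id_col]] <- as.character(df[[id_col]])
    df
  }
  dams <- check_placement(dams, "dam")
  sites <- check_placement(sites, "site", "site")
  if (!is.null(sites) && anyDuplicated(sites$site))
    stop("duplicate site identifiers in placements", call. = FALSE)
  structure(list(edges = edges, dams = dams, sites = sites,
                 outlet = outlets),
            class = "river_network")
}

#' @export
print.river_network <- function(x, ...) {
  cat(sprintf("river_network: %d segments, %d dams, %d sites, outlet '%s'\n",
              nrow(x$edges),
              if (is.null(x$dams)) 0L else nrow(x$dams),
              if (is.null(x$sites)) 0L else nrow(x$sites), x$outlet))
  invisible(x)
}

#' Read a river network from delimited text files
#'
#' @param edge_path file with columns `edge`, `from`, `to` and optional
#'   `length`
#' @param dam_path optional file with columns `edge`, `pos`
#' @param placement_path optional file with columns `site`, `edge`, `pos`
#' @param sep optional delimiter override
#' @return a [river_network()]
#' @export
read_network <- function(edge_path, dam_path = NULL, placement_path = NULL,
                         sep = NULL) {
  rd <- function(p) {
    if (is.null(sep)) sep <- detect_sep(p)
    read.table(p, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  }
  river_network(rd(edge_path),
                dams = if (!is.null(dam_path)) rd(dam_path),
                sites = if (!is.null(placement_path)) rd(placement_path))
}

# --- internal graph helpers -------------------------------------------------

# edges immediately upstream of a given edge (those draining into its
# upstream node)
upstream_edges_of <- function(net, edge_id) {
  e <- net$edges
  e$edge[e$to == e$from[e$edge == edge_id]]
}

# all edges strictly or weakly upstream of `edge_id` (including itself)
upstream_closure <- function(net, edge_id) {
  acc <- character(0)
  stack <- edge_id
  while (length(stack)) {
    cur <- stack[[1]]
    stack <- stack[-1]
    acc <- c(acc, cur)
    stack <- c(stack, upstream_edges_of(net, cur))
  }
  acc
}

# downstream chain of edges from an edge to the outlet (excluding itself)
downstream_chain <- function(net, edge_id) {
  e <- net$edges
  chain <- character(0)
  cur <- e$to[e$edge == edge_id]
  down <- setNames(e$edge, e$from)
  while (!is.na(down[cur])) {
    chain <- c(chain, unname(down[cur]))
    cur <- e$to[e$edge == unname(down[cur])]
  }
  chain
}

is_source_edge <- function(net, edge_id) {
  length(upstream_edges_of(net, edge_id)) == 0
}

site_row <- function(net, site) {
  if (is.null(net$sites)) stop("network has no site placements", call. = FALSE)
  i <- match(site, net$sites$site)
  if (is.na(i)) stop("unknown site '", site, "'", call. = FALSE)
  net$sites[i, ]
}

# --- connectivity metrics ---------------------------------------------------

#' Strahler order of every stream segment
#'
#' Source ("finger-tip") segments have order 1. Where tributaries meet, the
#' downstream segment takes order max + 1 when two or more tributaries tie
#' at the maximal order, and the maximum otherwise.
#'
#' @param net a `river_network`
#' @return named integer vector over edges
#' @export
strahler_orders <- function(net) {
  e <- net$edges
  ord <- setNames(rep(NA_integer_, nrow(e)), e$edge)
  compute <- function(edge_id) {
    if (!is.na(ord[edge_id])) return(ord[edge_id])
    ups <- upstream_edges_of(net, edge_id)
    o <- if (length(ups) == 0) 1L else {
      uo <- vapply(ups, compute, integer(1))
      m <- max(uo)
      if (sum(uo == m) >= 2) m + 1L else m
    }
    ord[edge_id] <<- o
    o
  }
  for (id in e$edge) compute(id)
  ord
}

#' Strahler order at a sampling site
#'
#' A site inherits the order of the segment it lies on.
#'
#' @param net a `river_network`
#' @param site site identifier
#' @return integer Strahler order
#' @export
strahler_order <- function(net, site) {
  unname(strahler_orders(net)[site_row(net, site)$edge])
}

# magnitude of a link: number of first-order source segments upstream
link_magnitude <- function(net, edge_id) {
  sum(vapply(upstream_closure(net, edge_id), is_source_edge,
             logical(1), net = net))
}

#' Downstream-link magnitude and its log2 category for a site
#'
#' The downstream link (Dlink) of a point is the magnitude (number of
#' first-order source segments upstream) of the link below the next
#' confluence downstream of that point. Sites on the outlet link, with no
#' confluence downstream, take the outlet link's own magnitude. The log2 of
#' the magnitude is binned into the unit-interval categories
#' `"1-2"`, `"2-3"`, `"3-4"` (values above 4 get `"4+"` with a warning).
#'
#' @param net a `river_network`
#' @param site site identifier
#' @param verbose log fallback decisions to stderr
#' @return list with `magnitude` (integer) and `log2_category` (character)
#' @export
downstream_link <- function(net, site, verbose = FALSE) {
  sr <- site_row(net, site)
  chain <- downstream_chain(net, sr$edge)
  # next downstream confluence = first downstream node with >= 2 tributaries;
  # the link "below" it is the first chain edge whose upstream node is a
  # confluence
  below <- NA_character_
  for (eid in chain) {
    if (length(upstream_edges_of(net, eid)) >= 2) {
      below <- eid
      break
    }
  }
  if (is.na(below)) {
    # site is on or below the last confluence: use the outlet link
    below <- if (length(chain)) chain[length(chain)] else sr$edge
    log_msg("site '", site, "' has no confluence downstream; ",
            "using outlet link magnitude", verbose = verbose)
  }
  mag <- link_magnitude(net, below)
  l2 <- log2(mag)
  cat_l2 <- if (l2 < 2) "1-2" else if (l2 < 3) "2-3" else {
    if (l2 <= 4) "3-4" else "4+"
  }
  if (cat_l2 == "4+")
    warning("log2(Dlink) = ", round(l2, 2), " exceeds category 3-4 at site ",
            site, call. = FALSE)
  list(magnitude = mag, log2_category = cat_l2)
}

#' Dam category of a site
#'
#' `"Up"`: at least one dam upstream but none downstream; `"Down"`: dam(s)
#' downstream only; `"Up&Down"`: dams on both sides; `"None"`: no dam on any
#' upstream path or on the path to the outlet.
#'
#' @param net a `river_network`
#' @param site site identifier
#' @return one of `"Up"`, `"Down"`, `"Up&Down"`, `"None"`
#' @export
dam_category <- function(net, site) {
  sr <- site_row(net, site)
  dams <- net$dams
  if (is.null(dams) || nrow(dams) == 0) return("None")
  up_edges <- setdiff(upstream_closure(net, sr$edge), sr$edge)
  down_edges <- downstream_chain(net, sr$edge)
  up <- any(dams$edge %in% up_edges) ||
    any(dams$edge == sr$edge & dams$pos < sr$pos)
  down <- any(dams$edge %in% down_edges) ||
    any(dams$edge == sr$edge & dams$pos >= sr$pos)
  if (up && down) "Up&Down" else if (up) "Up" else {
    if (down) "Down" else "None"
  }
}

#' Distance from a site to the outlet along the channel
#'
#' @param net a `river_network`
#' @param site site identifier
#' @return numeric channel distance in edge-length units
#' @export
distance_to_outlet <- function(net, site) {
  sr <- site_row(net, site)
  e <- net$edges
  own <- e$length[e$edge == sr$edge] * (1 - sr$pos)
  own + sum(e$length[match(downstream_chain(net, sr$edge), e$edge)])
}

#' Site attribute table derived from a river network
#'
#' Computes, for every placed site, the Strahler order, downstream-link
#' magnitude with its log2 category, and the dam category.
#'
#' @param net a `river_network` with site placements
#' @param coords optional data.frame of `x`, `y` per site to include
#' @return data.frame with one row per site
#' @export
network_site_attributes <- function(net, coords = NULL) {
  if (is.null(net$sites)) stop("network has no site placements", call. = FALSE)
  ids <- net$sites$site
  dl <- lapply(ids, function(s) downstream_link(net, s))
  out <- data.frame(
    row.names = ids,
    order_category = vapply(ids, function(s) strahler_order(net, s),
                            integer(1)),
    dlink_magnitude = vapply(dl, function(z) z$magnitude, integer(1)),
    dlink_category = vapply(dl, function(z) z$log2_category, character(1)),
    dam_category = vapply(ids, function(s) dam_category(net, s),
                          character(1)),
    dist_outlet = vapply(ids, function(s) distance_to_outlet(net, s),
                         numeric(1))
  )
  if (!is.null(coords)) out <- cbind(coords[rownames(out), c("x", "y")], out)
  out
}
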