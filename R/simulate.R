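#' Scenario configuration for the synthetic metacommunity generator
#'
#' Bundles every knob of the generator with defaults emulating a
#' dam-fragmented subtropical river survey: 24 sites on a dendritic
#' network, 82 species with phylogenetically structured mixed traits,
#' low-prevalence-dominated occupancy, and multiplicative occupancy
#' filtering of rheophilic/benthic guilds below upstream dams.
#'
#' @param n_species species-pool size (default 82)
#' @param n_sites number of sampling sites (default 24)
#' @param seed master seed; the same config is bit-identical across runs
#' @param regime `"mixed"` (default), `"turnover"` or `"nestedness"`
#' @param lambda exponential rate for tree branch lengths (mean 1/lambda)
#' @param sigma2 Brownian-motion variance per unit branch for traits
#' @param n_sources number of source (order-1) segments in the network
#' @param n_dams number of dams placed on random segments
#' @param tau niche breadth on the [0, 1] upstream-downstream gradient
#' @param mu_abund,sigma_abund lognormal abundance parameters (counts are
#'   rounded up to at least 1 individual)
#' @param dam_filter multiplicative occupancy penalty (< 1) applied to
#'   rheophilic or benthic species at sites with an upstream dam
#' @param base_occupancy ceiling occupancy probability of a species at
#'   its niche optimum
#' @param max_retries resampling attempts for empty sites/species
#' @return a list of class `scenario_config`
#' @export
scenario_config <- function(n_species = 82, n_sites = 24, seed = 1,
                            regime = c("mixed", "turnover", "nestedness"),
                            lambda = 1, sigma2 = 0.1, n_sources = 13,
                            n_dams = 5, tau = 0.12, mu_abund = 1,
                            sigma_abund = 1, dam_filter = 0.3,
                            base_occupancy = 0.9, max_retries = 200) {
  regime <- match.arg(regime)
  stopifnot(lambda > 0, sigma2 >= 0, tau > 0, sigma_abund > 0,
            dam_filter > 0, dam_filter <= 1, n_species >= 2, n_sites >= 2,
            n_sources >= 2)
  structure(list(n_species = n_species, n_sites = n_sites, seed = seed,
                 regime = regime, lambda = lambda, sigma2 = sigma2,
                 n_sources = n_sources, n_dams = n_dams, tau = tau,
                 mu_abund = mu_abund, sigma_abund = sigma_abund,
                 dam_filter = dam_filter, base_occupancy = base_occupancy,
                 max_retries = max_retries),
            class = "scenario_config")
}

#' Simulate a pure-birth phylogeny
#'
#' Sequential random tip splitting (each split picks a uniform random
#' extant tip) with i.i.d. exponential branch lengths. Deterministic
#' under `seed`.
#'
#' @param n_species number of tips
#' @param lambda exponential rate for branch lengths
#' @param seed integer seed
#' @return rooted binary `phylo` with tips `sp01, sp02, ...`
#' @export
generate_tree <- function(n_species, lambda = 1, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # grow a nested-list topology by splitting random tips
  n_tips <- 1L
  topo <- 1L
  split_tip <- function(node, target, counter) {
    if (is.integer(node) && length(node) == 1) {
      if (node == target)
        list(node = list(node, counter), hit = TRUE)
      else list(node = node, hit = FALSE)
    } else {
      l <- split_tip(node[[1]], target, counter)
      if (l$hit) return(list(node = list(l$node, node[[2]]), hit = TRUE))
      r <- split_tip(node[[2]], target, counter)
      list(node = list(node[[1]], r$node), hit = r$hit)
    }
  }
  while (n_tips < n_species) {
    target <- sample.int(n_tips, 1)
    n_tips <- n_tips + 1L
    topo <- split_tip(topo, target, n_tips)$node
  }
  # convert to Newick with exponential branch lengths
  bl <- function() rexp(1, lambda)
  to_newick <- function(node) {
    if (is.integer(node) && length(node) == 1)
      sprintf("sp%02d:%.10f", node, bl())
    else
      sprintf("(%s,%s):%.10f", to_newick(node[[1]]), to_newick(node[[2]]),
              bl())
  }
  txt <- if (n_species == 1) sprintf("(sp01:%.10f);", bl()) else
    paste0(to_newick(topo), ";")
  tree <- ape::read.tree(text = txt)
  validate_tree(tree)
}

#' Simulate phylogenetically structured traits
#'
#' Continuous traits evolve by Brownian motion on the tree (root values at
#' realistic fish morphometric ratios) and are exponentiated to enforce
#' positivity; the three categorical traits threshold hidden Brownian
#' traits at the 1/3 and 2/3 population quantiles, so closely related
#' species tend to share guilds.
#'
#' @param tree a `phylo` from [generate_tree()]
#' @param sigma2 Brownian variance per unit branch length
#' @param seed integer seed
#' @return a [trait_table()] with the default ten-trait schema
#' @export
generate_traits <- function(tree, sigma2 = 0.1, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  schema <- default_trait_schema()
  root_log <- log(c(Hl.Sl = 0.25, Ed.Hd = 0.30, Snl.Hl = 0.30,
                    Hd.Bd = 0.70, PecFl.Sl = 0.20, CPd.CFd = 0.45,
                    Bd.Sl = 0.25))
  n_hidden <- length(schema$categorical)
  bm <- simulate_bm(tree, n_traits = length(root_log) + n_hidden,
                    sigma2 = sigma2)
  cont <- exp(sweep(bm[, seq_along(root_log), drop = FALSE], 2, root_log,
                    "+"))
  colnames(cont) <- names(root_log)
  df <- as.data.frame(cont)
  for (k in seq_len(n_hidden)) {
    hid <- bm[, length(root_log) + k]
    lev <- schema$categorical[[k]]
    cutpts <- quantile(hid, c(1 / 3, 2 / 3))
    df[[names(schema$categorical)[k]]] <-
      lev[1 + (hid > cutpts[1]) + (hid > cutpts[2])]
  }
  rownames(df) <- tree$tip.label
  trait_table(df, schema)
}

# Brownian motion on a tree: root value 0, each branch adds
# N(0, sigma2 * length); returns tips x traits matrix
simulate_bm <- function(tree, n_traits, sigma2) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  vals <- matrix(0, nnode, n_traits)
  ord <- ape::reorder.phylo(tree, "postorder")
  # preorder = reversed postorder edge sequence
  edges <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]
  lens <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  for (k in seq_len(nrow(edges))) {
    parent <- edges[k, 1]; child <- edges[k, 2]
    vals[child, ] <- vals[parent, ] +
      rnorm(n_traits, 0, sqrt(sigma2 * lens[k]))
  }
  out <- vals[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Simulate a dendritic river network with dams and site placements
#'
#' Builds a random binary confluence tree over `n_sources` source
#' segments (so 2 * n_sources - 1 segments in total), assigns exponential
#' segment lengths, places one site per sampled segment and dams on
#' random distinct segments. Each site receives planar coordinates (for
#' spatial weights) and a gradient position: its channel distance to the
#' outlet, normalised to [0, 1] (1 = headwater).
#'
#' @param n_sources number of order-1 source segments
#' @param n_dams number of dams
#' @param n_sites number of sites (must be <= 2 * n_sources - 1)
#' @param seed integer seed
#' @return list with `network` (a [river_network()]), `gradient` (named
#'   per-site vector) and `coordinates` (per-site x/y data.frame)
#' @export
generate_network <- function(n_sources, n_dams, n_sites, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_edges <- 2 * n_sources - 1
  if (n_sites > n_edges)
    stop("n_sites exceeds number of segments (", n_edges, ")",
         call. = FALSE)
  # each open segment is identified by its upstream node; coalescing two
  # segments terminates both at a new confluence node, which starts the
  # next segment downstream. Edge count: n_sources + (n_sources - 2)
  # internal + 1 outlet = 2 * n_sources - 1.
  open_ends <- paste0("hw", seq_len(n_sources))
  node_id <- 0L
  eid <- 0L
  e_edge <- e_from <- e_to <- character(0)
  add_edge <- function(from, to) {
    eid <<- eid + 1L
    e_edge <<- c(e_edge, paste0("e", eid))
    e_from <<- c(e_from, from)
    e_to <<- c(e_to, to)
  }
  while (length(open_ends) > 1) {
    pick <- sample.int(length(open_ends), 2)
    node_id <- node_id + 1L
    conf <- paste0("c", node_id)
    add_edge(open_ends[pick[1]], conf)
    add_edge(open_ends[pick[2]], conf)
    open_ends <- c(open_ends[-pick], conf)
  }
  add_edge(open_ends[1], "outlet")
  edges <- data.frame(edge = e_edge, from = e_from, to = e_to,
                      length = rexp(n_edges, 1) + 0.2,
                      stringsAsFactors = FALSE)
  site_edges <- sample(edges$edge, n_sites)
  sites <- data.frame(site = sprintf("site%02d", seq_len(n_sites)),
                      edge = site_edges,
                      pos = runif(n_sites, 0.2, 0.8),
                      stringsAsFactors = FALSE)
  dam_edges <- sample(edges$edge, min(n_dams, n_edges))
  dams <- data.frame(edge = dam_edges,
                     pos = runif(length(dam_edges), 0.1, 0.9),
                     stringsAsFactors = FALSE)
  net <- river_network(edges, dams = dams, sites = sites)
  d_out <- vapply(sites$site, function(s) distance_to_outlet(net, s),
                  numeric(1))
  gradient <- d_out / max(d_out)
  # planar coordinates: jittered embedding along the gradient so that
  # spatial distance loosely tracks channel distance
  coords <- data.frame(row.names = sites$site,
                       x = d_out + rnorm(n_sites, 0, 0.3),
                       y = runif(n_sites, 0, 3))
  list(network = net, gradient = gradient, coordinates = coords)
}

#' Simulate site-by-species communities on a river network
#'
#' Occurrence probability of species i at site s combines, depending on
#' the regime: a Gaussian niche on the upstream-downstream gradient
#' (turnover), a species rarity x site capacity product whose draws share
#' one uniform deviate per species so that poorer sites hold nested
#' subsets of richer ones (nestedness), or the product of both (mixed).
#' Sites with an upstream dam multiply the occupancy of rheophilic or
#' benthic species by `dam_filter`. Abundances given occurrence are
#' lognormal, rounded up so every occurrence has at least one individual.
#' Empty sites or globally absent species are resampled up to
#' `max_retries` times; any species (or site) still empty is then placed
#' deterministically at its highest-probability site (species), the
#' limiting conditional draw given at least one occurrence.
#'
#' @param scenario a [scenario_config()]
#' @param tree phylogeny over the species pool (names the species)
#' @param traits a [trait_table()] (supplies the filtered guilds)
#' @param network_info a [generate_network()] result
#' @return a [community_matrix()]
#' @export
generate_communities <- function(scenario, tree, traits, network_info) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(scenario$seed + 3L)
  species <- tree$tip.label
  n_sp <- length(species)
  g <- network_info$gradient
  sites <- names(g)
  n_si <- length(sites)
  net <- network_info$network
  dam_cat <- vapply(sites, function(s) dam_category(net, s), "")
  has_up_dam <- dam_cat %in% c("Up", "Up&Down")
  filtered_guild <- traits[species, "rheophily"] == "rheophilic" |
    traits[species, "water_column"] == "benthic"
  # niche optima spread across the realized gradient positions of the
  # sites, so every species has at least one reachable site
  optima <- runif(n_sp, min(g), max(g))
  # right-skewed rarity with a floor: the pool emulates an *observed*
  # species list, so every species must remain drawable at >= 1 site
  rarity <- runif(n_sp, 0.15, 1)^1.5
  capacity <- 1 - 0.5 * g # downstream sites hold more species
  p_occ <- matrix(0, n_si, n_sp, dimnames = list(sites, species))
  for (s in seq_len(n_si)) {
    niche <- exp(-(g[s] - optima)^2 / (2 * scenario$tau^2))
    p <- switch(scenario$regime,
      turnover = scenario$base_occupancy * niche,
      nestedness = rarity * capacity[s],
      mixed = scenario$base_occupancy * niche * rarity * capacity[s])
    if (has_up_dam[s]) p[filtered_guild] <- p[filtered_guild] *
        scenario$dam_filter
    p_occ[s, ] <- pmin(p, 1)
  }
  nested <- scenario$regime == "nestedness"
  draw_col <- function(i) {
    if (nested) {
      # one uniform per species couples the draws across sites: a species
      # present at a low-probability site is automatically present at
      # every higher-probability site, yielding nested subsets while
      # keeping the stated marginal occupancy probabilities
      runif(1) <= p_occ[, i]
    } else {
      runif(n_si) <= p_occ[, i]
    }
  }
  occ <- vapply(seq_len(n_sp), draw_col, logical(n_si))
  dimnames(occ) <- list(sites, species)
  # resample empty species (columns) and empty sites (rows) only
  for (attempt in seq_len(scenario$max_retries)) {
    empty_sp <- which(colSums(occ) == 0)
    for (i in empty_sp) occ[, i] <- draw_col(i)
    empty_si <- which(rowSums(occ) == 0)
    for (s in empty_si) occ[s, ] <- runif(n_sp) <= p_occ[s, ]
    if (all(rowSums(occ) > 0) && all(colSums(occ) > 0)) break
  }
  # conditioning fallback: for a species whose total occupancy
  # probability is so small that rejection cannot land a presence, the
  # conditional law of its occupancy given >= 1 occurrence concentrates
  # on the site where it is most likely -- place it there. Likewise an
  # empty site receives its single most likely species.
  for (i in which(colSums(occ) == 0)) occ[which.max(p_occ[, i]), i] <- TRUE
  for (s in which(rowSums(occ) == 0)) occ[s, which.max(p_occ[s, ])] <- TRUE
  counts <- matrix(0L, n_si, n_sp, dimnames = list(sites, species))
  n_occ <- sum(occ)
  counts[occ] <- pmax(1L, as.integer(ceiling(
    rlnorm(n_occ, scenario$mu_abund, scenario$sigma_abund))))
  community_matrix(counts)
}

#' Generate a complete synthetic input bundle
#'
#' Runs the tree, trait, network and community generators with seeds
#' derived deterministically from the scenario seed, and derives the site
#' attribute table.
#'
#' @param scenario a [scenario_config()]
#' @return list with `tree`, `traits`, `network`, `gradient`,
#'   `coordinates`, `community`, `site_attributes`, `scenario`
#' @export
simulate_scenario <- function(scenario = scenario_config()) {
  tree <- generate_tree(scenario$n_species, scenario$lambda,
                        seed = scenario$seed)
  traits <- generate_traits(tree, scenario$sigma2,
                            seed = scenario$seed + 1L)
  nw <- generate_network(scenario$n_sources, scenario$n_dams,
                         scenario$n_sites, seed = scenario$seed + 2L)
  community <- generate_communities(scenario, tree, traits, nw)
  attrs <- network_site_attributes(nw$network, coords = nw$coordinates)
  list(tree = tree, traits = traits, network = nw$network,
       gradient = nw$gradient, coordinates = nw$coordinates,
       community = community, site_attributes = attrs,
       scenario = scenario)
}

#' Write a synthetic bundle to a directory in the standard input formats
#'
#' @param bundle a [simulate_scenario()] result
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    community = file.path(dir, "community.tsv"),
    traits = file.path(dir, "traits.tsv"),
    tree = file.path(dir, "tree.nwk"),
    site_attributes = file.path(dir, "site_attributes.tsv"),
    edges = file.path(dir, "network_edges.tsv"),
    dams = file.path(dir, "network_dams.tsv"),
    placements = file.path(dir, "network_sites.tsv"))
  write_results(as.data.frame(unclass(bundle$community)),
                paths["community"])
  tr <- as.data.frame(bundle$traits)
  tr[] <- lapply(tr, function(x) if (is.factor(x)) as.character(x) else x)
  write_results(tr, paths["traits"])
  ape::write.tree(bundle$tree, paths["tree"])
  write_results(bundle$site_attributes, paths["site_attributes"])
  write_results(bundle$network$edges, paths["edges"], row_names = FALSE)
  write_results(bundle$network$dams, paths["dams"], row_names = FALSE)
  write_results(bundle$network$sites, paths["placements"],
                row_names = FALSE)
  invisible(paths)
}
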