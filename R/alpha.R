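#' Shannon diversity (natural log)
#'
#' `H = -sum(p_i log p_i)` with `p_i` the relative abundances.
#'
#' @param abundances vector of non-negative counts with at least one
#'   positive entry
#' @return H in nats
#' @export
shannon <- function(abundances) {
  x <- abundances[abundances > 0]
  if (length(x) == 0) stop("no positive abundances", call. = FALSE)
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Shannon evenness
#'
#' `H / log(S)`; undefined (NA) for a single-species community.
#'
#' @inheritParams shannon
#' @return value in [0, 1], or NA when S = 1
#' @export
shannon_evenness <- function(abundances) {
  s <- sum(abundances > 0)
  if (s < 2) return(NA_real_)
  shannon(abundances) / log(s)
}

#' Rao's quadratic entropy
#'
#' `Q = sum_ij d_ij p_i p_j`: the abundance-weighted mean pairwise
#' functional distance of a community.
#'
#' @param abundances named vector of counts for the species present
#' @param distances symmetric zero-diagonal distance matrix whose
#'   dimnames cover the names of `abundances` (or an unnamed matrix in
#'   matching order)
#' @return Q >= 0 (0 for a single species)
#' @export
rao_q <- function(abundances, distances) {
  x <- abundances[abundances > 0]
  if (length(x) == 1) return(0)
  d <- as.matrix(distances)
  if (!is.null(names(x)) && !is.null(rownames(d))) {
    miss <- setdiff(names(x), rownames(d))
    if (length(miss))
      stop("distance matrix missing species: ",
           paste(miss, collapse = ", "), call. = FALSE)
    d <- d[names(x), names(x)]
  } else if (nrow(d) != length(x)) {
    stop("distances not aligned with abundances", call. = FALSE)
  }
  p <- x / sum(x)
  drop(p %*% d %*% p)
}

# Prim's algorithm on a dense symmetric distance matrix; returns an edge
# list (i, j, w)
mst_edges <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  parent <- rep(1L, n)
  edges <- matrix(0, n - 1, 3)
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    edges[k, ] <- c(parent[j], j, best[j])
    in_tree[j] <- TRUE
    upd <- which(!in_tree & d[j, ] < best)
    parent[upd] <- j
    best[upd] <- d[j, upd]
  }
  edges
}

#' Functional evenness (FEve)
#'
#' Regularity of the abundance distribution along the minimum spanning
#' tree of the community's species in functional-trait space. Each MST
#' edge between species i and j gets weight `EW = dist / (p_i + p_j)`;
#' after normalising to `PEW`, FEve contrasts the observed partial
#' weights with the perfectly even value `1/(S-1)`.
#'
#' @param abundances named counts of the species present (S >= 3 for a
#'   defined value)
#' @param coordinates species x axes matrix of functional coordinates,
#'   rows covering the names of `abundances`
#' @return FEve in [0, 1]; NA when S < 3 or the species are functionally
#'   coincident
#' @export
functional_evenness <- function(abundances, coordinates) {
  x <- abundances[abundances > 0]
  s <- length(x)
  if (s < 3) return(NA_real_)
  co <- coordinates[names(x), , drop = FALSE]
  d <- as.matrix(stats::dist(co))
  if (sum(d) == 0) return(NA_real_)
  p <- x / sum(x)
  ed <- mst_edges(d)
  if (sum(ed[, 3]) == 0) return(NA_real_)
  ew <- ed[, 3] / (p[ed[, 1]] + p[ed[, 2]])
  pew <- ew / sum(ew)
  thr <- 1 / (s - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

# --- phylogenetic machinery -------------------------------------------------

# tips x edges incidence: B[t, e] is TRUE when tip t lies below edge e.
# All phylogenetic indices are linear functionals of this table.
tree_edge_table <- function(tree) {
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  nnode <- ntip + tree$Nnode
  below <- vector("list", nnode)
  for (t in seq_len(ntip)) below[[t]] <- t
  # postorder guarantees children are resolved before their parent edge
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  b <- matrix(FALSE, ntip, nedge,
              dimnames = list(tree$tip.label, NULL))
  for (k in seq_len(nrow(ord))) {
    parent <- ord[k, 1]; child <- ord[k, 2]
    tips <- below[[child]]
    below[[parent]] <- c(below[[parent]], tips)
    e <- which(tree$edge[, 1] == parent & tree$edge[, 2] == child)
    b[tips, e] <- TRUE
  }
  list(incidence = b, lengths = tree$edge.length)
}

# edge indices of the spanning subtree of a species set
branch_set <- function(edge_table, species, include_root = TRUE) {
  b <- edge_table$incidence[species, , drop = FALSE]
  k <- colSums(b)
  if (include_root) which(k >= 1) else which(k >= 1 & k < length(species))
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree connecting a set of tips;
#' with `include_root = TRUE` (default) the subtree is anchored at the
#' root, so a single species contributes its root-to-tip depth.
#'
#' @param present_species character vector of tip labels
#' @param tree a rooted `phylo` with branch lengths
#' @param include_root include the path from the set's most recent common
#'   ancestor up to the root
#' @return PD in branch-length units
#' @export
faith_pd <- function(present_species, tree, include_root = TRUE) {
  et <- tree_edge_table(tree)
  unknown <- setdiff(present_species, rownames(et$incidence))
  if (length(unknown))
    stop("unknown tip(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(present_species) == 0)
    stop("present_species is empty", call. = FALSE)
  sum(et$lengths[branch_set(et, present_species, include_root)])
}

# phylogenetic correlation matrix over a species subset: covariance
# V_ij = shared root path length, standardised by root-to-tip depths
# (exact correlation for non-ultrametric trees, identity scaling when
# ultrametric)
phylo_correlation <- function(tree, species = tree$tip.label) {
  et <- tree_edge_table(tree)
  b <- et$incidence[species, , drop = FALSE] * 1
  v <- b %*% (et$lengths * t(b))
  dep <- sqrt(diag(v))
  if (any(dep == 0))
    stop("species with zero root-to-tip depth: ",
         paste(species[dep == 0], collapse = ", "), call. = FALSE)
  v / tcrossprod(dep)
}

#' Phylogenetic species variability (PSV)
#'
#' `PSV = (n tr(C) - sum(C)) / (n (n - 1))` for the phylogenetic
#' correlation matrix C of the species present: 1 on a star phylogeny,
#' smaller the more related the community is.
#'
#' @param present_species tip labels (>= 2)
#' @param tree rooted `phylo`
#' @return PSV in (0, 1], NA for fewer than 2 species
#' @export
phylo_species_variability <- function(present_species, tree) {
  n <- length(present_species)
  if (n < 2) return(NA_real_)
  c_mat <- phylo_correlation(tree, present_species)
  (n * sum(diag(c_mat)) - sum(c_mat)) / (n * (n - 1))
}

#' Phylogenetic species evenness (PSE)
#'
#' Abundance-weighted PSV: with abundances m, total M and phylogenetic
#' correlation matrix C,
#' `PSE = (M sum(m_i C_ii) - m' C m) / (M^2 - sum(m_i^2))`.
#' Reduces to PSV when all abundances are equal and to 1 on a star
#' phylogeny.
#'
#' @param abundances named counts of the species present
#' @param tree rooted `phylo`
#' @return PSE in (0, 1], NA for a single species
#' @export
phylo_species_evenness <- function(abundances, tree) {
  m <- abundances[abundances > 0]
  if (length(m) < 2) return(NA_real_)
  c_mat <- phylo_correlation(tree, names(m))
  big_m <- sum(m)
  (big_m * sum(m * diag(c_mat)) - drop(m %*% c_mat %*% m)) /
    (big_m^2 - sum(m^2))
}

#' Per-site alpha diversity table
#'
#' Computes the six alpha indices (richness-type: Shannon, Rao's Q,
#' Faith's PD; evenness-type: Shannon evenness, FEve, PSE) for every site,
#' plus richness and mean individuals per species. Functional distances
#' are Euclidean in the retained trait-space axes and, by default, scaled
#' by the global maximum pairwise distance so Rao's Q is comparable
#' across runs.
#'
#' Missing-value policy: SEve and PSE are NA at single-species sites;
#' FEve is NA below 3 species; RaoQ is 0 for a single species.
#'
#' @param community a [community_matrix()]
#' @param trait_space a [build_trait_space()] result
#' @param tree rooted `phylo` covering the community species
#' @param include_root passed to [faith_pd()]
#' @param scale_distances divide functional distances by their global
#'   maximum before Rao's Q (default TRUE)
#' @return data.frame (class `alpha_table`) with one row per site
#' @export
alpha_table <- function(community, trait_space, tree, include_root = TRUE,
                        scale_distances = TRUE) {
  check_tree_coverage(tree, community)
  d <- trait_space$distance_matrix
  if (is.null(d)) stop("trait_space carries no distance matrix; use ",
                       "build_trait_space()", call. = FALSE)
  if (scale_distances && max(d) > 0) d <- d / max(d)
  sites <- rownames(community)
  rows <- lapply(sites, function(s) {
    ab <- unclass(community)[s, ]
    ab <- ab[ab > 0]
    data.frame(
      richness = length(ab),
      individuals_per_species = sum(ab) / length(ab),
      Shannon = shannon(ab),
      SEve = shannon_evenness(ab),
      RaoQ = rao_q(ab, d),
      FEve = functional_evenness(ab, trait_space$coordinates),
      PDfaith = faith_pd(names(ab), tree, include_root),
      PSEve = phylo_species_evenness(ab, tree)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- sites
  class(out) <- c("alpha_table", "data.frame")
  out
}
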