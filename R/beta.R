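#' Sorensen-family beta components from shared/unique quantities
#'
#' Given the shared quantity `a` and the quantities `b`, `c` unique to each
#' of two communities (species counts for the taxonomic facet, hull
#' volumes for the functional facet, branch lengths for the phylogenetic
#' facet), computes total dissimilarity `beta_sor = (b + c) / (2a + b + c)`
#' and its partition into turnover
#' `beta_sim = min(b, c) / (a + min(b, c))` and nestedness
#' `beta_nes = beta_sor - beta_sim`.
#'
#' @param a,b,c non-negative reals, not all zero
#' @return list with `a`, `b`, `c`, `beta_sor`, `beta_sim`, `beta_nes`
#' @export
sorensen_components <- function(a, b, c) {
  if (any(c(a, b, c) < 0)) stop("a, b, c must be >= 0", call. = FALSE)
  if (2 * a + b + c == 0) stop("a, b, c are all zero", call. = FALSE)
  beta_sor <- (b + c) / (2 * a + b + c)
  mn <- min(b, c)
  beta_sim <- if (a + mn == 0) 0 else mn / (a + mn)
  list(a = a, b = b, c = c, beta_sor = beta_sor, beta_sim = beta_sim,
       beta_nes = beta_sor - beta_sim)
}

new_beta_matrices <- function(facet, sites, sor, sim, nes, extra = list()) {
  dimnames(sor) <- dimnames(sim) <- dimnames(nes) <- list(sites, sites)
  structure(c(list(facet = facet, sor = sor, sim = sim, nes = nes), extra),
            class = "beta_matrices")
}

#' @export
print.beta_matrices <- function(x, ...) {
  v <- x$sor[upper.tri(x$sor)]
  cat(sprintf(
    "beta_matrices [%s]: %d sites, beta_sor mean %.3f (range %.3f-%.3f)%s\n",
    x$facet, nrow(x$sor), mean(v, na.rm = TRUE), min(v, na.rm = TRUE),
    max(v, na.rm = TRUE),
    if (anyNA(v)) sprintf(", %d missing pair(s)", sum(is.na(v))) else ""))
  invisible(x)
}

pairwise_apply <- function(sites, fun) {
  n <- length(sites)
  sor <- sim <- nes <- matrix(0, n, n)
  extra <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      comp <- fun(i, j)
      if (is.null(comp)) {
        sor[i, j] <- sor[j, i] <- NA
        sim[i, j] <- sim[j, i] <- NA
        nes[i, j] <- nes[j, i] <- NA
      } else {
        sor[i, j] <- sor[j, i] <- comp$beta_sor
        sim[i, j] <- sim[j, i] <- comp$beta_sim
        nes[i, j] <- nes[j, i] <- comp$beta_nes
        if (isTRUE(comp$reduced)) extra[i, j] <- extra[j, i] <- TRUE
      }
    }
  }
  list(sor = sor, sim = sim, nes = nes, reduced = extra)
}

#' Taxonomic beta diversity (presence/absence Sorensen partition)
#'
#' @param community a [community_matrix()]
#' @return `beta_matrices` for the taxonomic facet
#' @export
taxonomic_beta <- function(community) {
  pa <- presence_absence(community)
  res <- pairwise_apply(rownames(pa), function(i, j) {
    a <- sum(pa[i, ] & pa[j, ])
    b <- sum(pa[i, ] & !pa[j, ])
    c <- sum(!pa[i, ] & pa[j, ])
    sorensen_components(a, b, c)
  })
  new_beta_matrices("TD", rownames(pa), res$sor, res$sim, res$nes)
}

#' Phylogenetic beta diversity (branch-length Sorensen partition)
#'
#' For each site pair, `a` is the summed length of branches shared by the
#' two communities' spanning subtrees and `b`, `c` the lengths unique to
#' each, using the same rooting convention as [faith_pd()].
#'
#' @param community a [community_matrix()]
#' @param tree rooted `phylo` covering the community species
#' @param include_root anchor spanning subtrees at the root (default TRUE)
#' @return `beta_matrices` for the phylogenetic facet
#' @export
phylogenetic_beta <- function(community, tree, include_root = TRUE) {
  check_tree_coverage(tree, community)
  et <- tree_edge_table(tree)
  pa <- presence_absence(community)
  sets <- lapply(rownames(pa), function(s)
    branch_set(et, colnames(pa)[pa[s, ]], include_root))
  len <- et$lengths
  res <- pairwise_apply(rownames(pa), function(i, j) {
    shared <- intersect(sets[[i]], sets[[j]])
    sorensen_components(sum(len[shared]),
                        sum(len[setdiff(sets[[i]], shared)]),
                        sum(len[setdiff(sets[[j]], shared)]))
  })
  new_beta_matrices("PD", rownames(pa), res$sor, res$sim, res$nes)
}

#' Functional beta diversity (convex-hull Sorensen partition)
#'
#' For each site pair, the two communities' species are embedded in the
#' first `n_axes_fd` trait-space axes; `a` is the volume of the
#' intersection of their convex hulls, `b` and `c` the volumes unique to
#' each hull. Intersections are computed exactly by half-space vertex
#' enumeration where the combinatorics allow, and otherwise by a seeded
#' Monte Carlo rejection estimator.
#'
#' Pairs where a community has fewer than `n_axes_fd + 1` species are
#' recomputed with the axis count reduced to (min richness - 1), and
#' flagged in the `reduced` matrix; pairs with min richness below 3 (or
#' degenerate hulls after reduction) are missing (NA).
#'
#' @param community a [community_matrix()]
#' @param trait_space a [build_trait_space()] result with at least
#'   `n_axes_fd` axes
#' @param n_axes_fd hull dimension (default 4)
#' @param mc_points Monte Carlo sample size for the fallback estimator
#' @param seed seed for the Monte Carlo fallback
#' @param verbose log reductions/missing pairs to stderr
#' @return `beta_matrices` for the functional facet, with a logical
#'   `reduced` matrix attached
#' @export
functional_beta <- function(community, trait_space, n_axes_fd = 4,
                            mc_points = 200000, seed = 1, verbose = FALSE) {
  co <- trait_space$coordinates
  if (n_axes_fd > ncol(co))
    stop("n_axes_fd = ", n_axes_fd, " but trait space has ", ncol(co),
         " axes", call. = FALSE)
  check_species_alignment <- setdiff(colnames(community), rownames(co))
  if (length(check_species_alignment))
    stop("trait space missing species: ",
         paste(check_species_alignment, collapse = ", "), call. = FALSE)
  pa <- presence_absence(community)
  sites <- rownames(pa)
  splist <- lapply(sites, function(s) colnames(pa)[pa[s, ]])
  vol_cache <- new.env(parent = emptyenv())
  site_volume <- function(i, dd) {
    key <- paste(i, dd)
    if (!is.null(vol_cache[[key]])) return(vol_cache[[key]])
    v <- hull_volume(co[splist[[i]], seq_len(dd), drop = FALSE])
    vol_cache[[key]] <- v
    v
  }
  res <- pairwise_apply(sites, function(i, j) {
    min_rich <- min(length(splist[[i]]), length(splist[[j]]))
    dd <- min(n_axes_fd, min_rich - 1)
    reduced <- dd < n_axes_fd
    repeat {
      if (dd < 2) {
        log_msg("functional beta missing for pair (", sites[i], ", ",
                sites[j], "): hull dimension below 2", verbose = verbose)
        return(NULL)
      }
      p1 <- co[splist[[i]], seq_len(dd), drop = FALSE]
      p2 <- co[splist[[j]], seq_len(dd), drop = FALSE]
      r1 <- affine_rank(p1)
      r2 <- affine_rank(p2)
      if (r1 >= dd && r2 >= dd) break
      dd <- min(r1, r2)
      reduced <- TRUE
    }
    pair_seed <- (seed + 1009L * i + j) %% .Machine$integer.max
    if (dd <= 3) {
      # exact geometry is cheap in 2-3 dimensions
      v1 <- site_volume(i, dd)
      v2 <- site_volume(j, dd)
      if (v1 <= 0 || v2 <= 0) {
        log_msg("functional beta missing for pair (", sites[i], ", ",
                sites[j], "): degenerate hull", verbose = verbose)
        return(NULL)
      }
      a <- hull_intersection_exact(p1, p2)
      if (is.null(a))
        a <- hull_intersection_mc(p1, p2, n_points = mc_points,
                                  seed = pair_seed)$volume
    } else {
      # vertex enumeration explodes combinatorially beyond 3-D: estimate
      # all three volumes from one shared Monte Carlo sample
      est <- hull_pair_mc(p1, p2, n_points = mc_points, seed = pair_seed)
      v1 <- est$v1
      v2 <- est$v2
      a <- est$v12
      if (v1 <= 0 || v2 <= 0) {
        log_msg("functional beta missing for pair (", sites[i], ", ",
                sites[j], "): degenerate hull", verbose = verbose)
        return(NULL)
      }
    }
    a <- min(max(a, 0), v1, v2)
    comp <- sorensen_components(a, v1 - a, v2 - a)
    comp$reduced <- reduced
    comp
  })
  new_beta_matrices("FD", sites, res$sor, res$sim, res$nes,
                    extra = list(reduced = res$reduced))
}

#' Summary statistics of a beta-diversity matrix set
#'
#' Mean, SD, range and extreme pairs over the strict upper triangle
#' (missing entries ignored), plus 20-bin histogram counts on [0, 1] for
#' each component.
#'
#' @param matrices a `beta_matrices` object
#' @return list with one summary per component (`sor`, `sim`, `nes`)
#' @export
beta_summary <- function(matrices) {
  sites <- rownames(matrices$sor)
  comp_summary <- function(m) {
    ut <- upper.tri(m)
    v <- m[ut]
    if (all(is.na(v))) stop("all pairs missing for facet ", matrices$facet,
                            call. = FALSE)
    idx <- which(ut, arr.ind = TRUE)
    ok <- !is.na(v)
    vi <- v[ok]
    ii <- idx[ok, , drop = FALSE]
    br <- seq(0, 1, by = 0.05)
    list(mean = mean(vi), sd = sd(vi), min = min(vi), max = max(vi),
         argmin = sites[ii[which.min(vi), ]],
         argmax = sites[ii[which.max(vi), ]],
         n_pairs = length(vi), n_missing = sum(!ok),
         histogram = hist_counts(vi, br))
  }
  list(facet = matrices$facet,
       sor = comp_summary(matrices$sor),
       sim = comp_summary(matrices$sim),
       nes = comp_summary(matrices$nes))
}

hist_counts <- function(v, breaks) {
  cut_idx <- findInterval(v, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
  tabulate(cut_idx, nbins = length(breaks) - 1)
}

#' Quadratic regressions among beta components
#'
#' For each ordered pair of components (sor ~ sim, sim ~ nes, sor ~ nes),
#' fits `y ~ 1 + x + x^2` by ordinary least squares over the upper
#' triangle and reports coefficients, adjusted R-squared, the overall F
#' p-value, and the sign of the linear association.
#'
#' @param matrices a `beta_matrices` object
#' @return data.frame with one row per component pair
#' @export
beta_component_regression <- function(matrices) {
  ut <- upper.tri(matrices$sor)
  comp <- list(sor = matrices$sor[ut], sim = matrices$sim[ut],
               nes = matrices$nes[ut])
  pairs <- rbind(c("sim", "sor"), c("nes", "sim"), c("nes", "sor"))
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    x <- comp[[pairs[k, 1]]]
    y <- comp[[pairs[k, 2]]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    fit <- stats::lm(y ~ x + I(x^2))
    sm <- suppressWarnings(summary(fit)) # exact fits trip summary.lm
    fp <- if (is.null(sm$fstatistic)) NA_real_ else
      unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                       lower.tail = FALSE))
    data.frame(facet = matrices$facet,
               x = pairs[k, 1], y = pairs[k, 2],
               intercept = unname(coef(fit)[1]),
               linear = unname(coef(fit)[2]),
               quadratic = unname(coef(fit)[3]),
               r2_adj = sm$adj.r.squared,
               p_value = fp,
               direction = sign(stats::cor(x, y)))
  })
  do.call(rbind, rows)
}
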