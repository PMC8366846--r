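#' Leave-one-out species-removal vulnerability
#'
#' Jackknife over species: for every site and every species present
#' there, the facet index is recomputed with that single species removed
#' from the otherwise intact community, and the decrease
#' `delta = D(site) - D(site without species)` is stored. Each removal is
#' independent (the community is restored between removals). Conventions
#' for the reduced community follow the alpha module: an emptied site has
#' index 0 for every facet; a single remaining species has Shannon and
#' Rao's Q of 0 and Faith's PD equal to its root path (when rooted).
#'
#' @param community a [community_matrix()]
#' @param trait_space a [build_trait_space()] result
#' @param tree rooted `phylo`
#' @param include_root passed to [faith_pd()]
#' @param scale_distances scale functional distances by their global
#'   maximum (matching [alpha_table()])
#' @return object of class `vulnerability_result`: list with `deltas`
#'   (per facet, site x species matrices, NA where absent) and `baseline`
#'   (per facet, per-site index values)
#' @export
leave_one_out <- function(community, trait_space, tree,
                          include_root = TRUE, scale_distances = TRUE) {
  check_tree_coverage(tree, community)
  d <- trait_space$distance_matrix
  if (scale_distances && max(d) > 0) d <- d / max(d)
  et <- tree_edge_table(tree)
  pd_of <- function(sp) {
    if (length(sp) == 0) return(0)
    sum(et$lengths[branch_set(et, sp, include_root)])
  }
  sites <- rownames(community)
  species <- colnames(community)
  empty <- matrix(NA_real_, length(sites), length(species),
                  dimnames = list(sites, species))
  deltas <- list(TD = empty, FD = empty, PD = empty)
  baseline <- matrix(0, length(sites), 3,
                     dimnames = list(sites, c("TD", "FD", "PD")))
  for (s in sites) {
    ab <- unclass(community)[s, ]
    ab <- ab[ab > 0]
    present <- names(ab)
    base <- c(TD = shannon(ab), FD = rao_q(ab, d), PD = pd_of(present))
    baseline[s, ] <- base
    for (i in present) {
      ab2 <- ab[setdiff(present, i)]
      after <- c(
        TD = if (length(ab2) == 0) 0 else shannon(ab2),
        FD = if (length(ab2) == 0) 0 else rao_q(ab2, d),
        PD = pd_of(names(ab2)))
      deltas$TD[s, i] <- base["TD"] - after["TD"]
      deltas$FD[s, i] <- base["FD"] - after["FD"]
      deltas$PD[s, i] <- base["PD"] - after["PD"]
    }
  }
  structure(list(deltas = deltas, baseline = baseline,
                 facet_indices = c(TD = "Shannon", FD = "RaoQ",
                                   PD = "PDfaith")),
            class = "vulnerability_result")
}

#' @export
print.vulnerability_result <- function(x, ...) {
  cat(sprintf(
    "vulnerability_result: %d sites x %d species, %d defined deltas\n",
    nrow(x$deltas$TD), ncol(x$deltas$TD), sum(!is.na(x$deltas$TD))))
  invisible(x)
}

#' Species contributions to diversity vulnerability
#'
#' A species' contribution for a facet is its mean delta over the sites
#' it occupies (absent-site deltas are undefined, not zero). The
#' top-decile sets (`k = ceiling(q * n_species)`) per facet and their
#' union, with per-facet membership flags, reproduce the check-mark
#' layout of vulnerability tables.
#'
#' @param result a [leave_one_out()] result
#' @param q quantile fraction (default 0.1)
#' @return list with `contributions` (species x facet data.frame),
#'   `top_sets` (per facet), and `union_table`
#' @export
species_contributions <- function(result, q = 0.1) {
  contr <- vapply(result$deltas, function(m) colMeans(m, na.rm = TRUE),
                  numeric(ncol(result$deltas$TD)))
  contr[is.nan(contr)] <- NA
  contr <- as.data.frame(contr)
  tops <- lapply(names(result$deltas), function(f) {
    v <- setNames(contr[[f]], rownames(contr))
    top_set(v[!is.na(v)], q)
  })
  names(tops) <- names(result$deltas)
  union_sp <- sort(unique(unlist(tops)))
  ut <- data.frame(row.names = union_sp)
  for (f in names(tops)) ut[[paste0("top_", f)]] <- union_sp %in% tops[[f]]
  list(contributions = contr, top_sets = tops, union_table = ut, q = q)
}

#' Site-level vulnerability summaries and cross-facet variance comparison
#'
#' Each site's vulnerability score for a facet is the mean delta over its
#' species; the most vulnerable sites are the top `ceiling(q * n_sites)`
#' per facet. Whether one facet's deltas disperse more across sites than
#' the others' is tested with a rank-based dispersion (Fligner-Killeen)
#' test on the pooled per-site delta lists, with a Levene-type
#' (absolute-deviation ANOVA) alternative.
#'
#' @param result a [leave_one_out()] result
#' @param q quantile fraction (default 0.1)
#' @param dispersion_test `"fligner"` (default) or `"levene"`
#' @param conf_level confidence level for flagging (default 0.99)
#' @return list with `site_summary` (per facet: mean, variance, n),
#'   `top_sites` per facet, `dispersion` test results, and
#'   `density_data` (per facet, per-site delta lists ordered by site
#'   mean)
#' @export
site_vulnerability <- function(result, q = 0.1,
                               dispersion_test = c("fligner", "levene"),
                               conf_level = 0.99) {
  dispersion_test <- match.arg(dispersion_test)
  facets <- names(result$deltas)
  site_mean <- vapply(result$deltas, function(m) rowMeans(m, na.rm = TRUE),
                      numeric(nrow(result$deltas$TD)))
  site_var <- vapply(result$deltas,
                     function(m) apply(m, 1, var, na.rm = TRUE),
                     numeric(nrow(result$deltas$TD)))
  tops <- lapply(facets, function(f)
    top_set(setNames(site_mean[, f], rownames(site_mean)), q))
  names(tops) <- facets
  # pooled dispersion comparison on all defined deltas, grouped by facet
  long_vals <- unlist(lapply(facets, function(f) {
    v <- result$deltas[[f]]
    v[!is.na(v)]
  }))
  long_grp <- factor(rep(facets, vapply(facets, function(f)
    sum(!is.na(result$deltas[[f]])), integer(1))))
  disp <- if (dispersion_test == "fligner") {
    ft <- stats::fligner.test(long_vals, long_grp)
    list(statistic = unname(ft$statistic), p_value = ft$p.value,
         method = "fligner")
  } else {
    dev <- abs(long_vals - stats::ave(long_vals, long_grp,
                                      FUN = stats::median))
    fit <- stats::anova(stats::lm(dev ~ long_grp))
    list(statistic = fit$`F value`[1], p_value = fit$`Pr(>F)`[1],
         method = "levene")
  }
  facet_var <- vapply(facets, function(f)
    var(result$deltas[[f]][!is.na(result$deltas[[f]])]), numeric(1))
  disp$facet_variance <- facet_var
  disp$higher_variance_facet <-
    if (!is.na(disp$p_value) && disp$p_value < 1 - conf_level)
      names(which.max(facet_var)) else NA
  density_data <- lapply(facets, function(f) {
    m <- result$deltas[[f]]
    ord <- order(rowMeans(m, na.rm = TRUE))
    lapply(setNames(rownames(m)[ord], rownames(m)[ord]),
           function(s) m[s, !is.na(m[s, ])])
  })
  names(density_data) <- facets
  list(site_summary = data.frame(site = rownames(site_mean),
                                 mean = site_mean, var = site_var),
       top_sites = tops, dispersion = disp, density_data = density_data,
       q = q)
}

#' Identify distinctive species
#'
#' A species is distinctive when it has at least one continuous (or
#' ordered) trait in the top or bottom `q` quantile of the species pool,
#' or when its prevalence is in the top `q` quantile. Nominal categorical
#' traits are excluded (no order); life span enters through its ordinal
#' ranks.
#'
#' @param community a [community_matrix()]
#' @param traits a [trait_table()]
#' @param metadata optional named logical/character vector of
#'   endemic/exotic status per species (passed through, not computed)
#' @param q quantile fraction (default 0.1)
#' @return list with `species` (per-species flags data.frame),
#'   `distinctive_set`, and `occupancy` (per-site fraction of richness
#'   made up of distinctive species)
#' @export
distinctive_species <- function(community, traits, metadata = NULL,
                                q = 0.1) {
  schema <- attr(traits, "schema")
  pool <- rownames(traits)
  scan_cols <- c(schema$continuous, schema$ordered)
  high <- low <- setNames(vector("list", length(pool)), pool)
  for (tr in scan_cols) {
    v <- traits[[tr]]
    if (is.ordered(v)) v <- as.integer(v)
    hi_thr <- quantile(v, 1 - q)
    lo_thr <- quantile(v, q)
    for (sp in pool[v >= hi_thr]) high[[sp]] <- c(high[[sp]], tr)
    for (sp in pool[v <= lo_thr]) low[[sp]] <- c(low[[sp]], tr)
  }
  prev <- prevalence(community)
  occ_thr <- quantile(prev, 1 - q)
  occ_top <- names(prev)[prev >= occ_thr]
  df <- data.frame(
    row.names = pool,
    trait_high = vapply(high, function(x) paste(x, collapse = ";"), ""),
    trait_low = vapply(low, function(x) paste(x, collapse = ";"), ""),
    occurrence_top = pool %in% occ_top)
  if (!is.null(metadata)) df$status <- metadata[pool]
  distinct <- pool[nzchar(df$trait_high) | nzchar(df$trait_low) |
                     df$occurrence_top]
  pa <- presence_absence(community)
  distinct_present <- intersect(distinct, colnames(pa))
  occupancy <- rowSums(pa[, distinct_present, drop = FALSE]) /
    richness(community)
  list(species = df, distinctive_set = distinct, occupancy = occupancy,
       q = q)
}
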