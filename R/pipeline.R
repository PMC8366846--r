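facet_pairs <- function(facets) {
  cmb <- combn(facets, 2, simplify = FALSE)
  if (length(facets) > 2) cmb <- c(cmb, list(facets))
  cmb
}

#' Run the full multi-facet diversity analysis
#'
#' Orchestrates every stage end-to-end: trait-space construction, alpha
#' indices, Sorensen beta partitions for the three facets with summaries
#' and component regressions, alpha and beta congruence curves, spatial
#' autocorrelation (Moran's I) and bivariate association (Lee's L) tests,
#' per-index connectivity-factor ANOVAs, leave-one-out vulnerability with
#' species contributions and site summaries, and the distinctive-species
#' report. Deterministic given the inputs and `seed`.
#'
#' @param community a [community_matrix()]
#' @param traits a [trait_table()] covering the community species
#' @param tree rooted `phylo` covering the community species
#' @param site_attributes data.frame with `x`, `y` and the connectivity
#'   categories (`order_category`, `dlink_category`, `dam_category`);
#'   from [network_site_attributes()] or [read_site_attributes()]
#' @param n_axes retained PCoA axes (default 5)
#' @param n_axes_fd hull dimension for functional beta (default 4)
#' @param correction PCoA negative-eigenvalue correction
#' @param weights_scheme spatial weights scheme
#' @param n_perm permutations for the permutation-mode tests
#' @param mc_points Monte Carlo budget for hull intersections
#' @param seed master seed for every stochastic element
#' @param sections subset of
#'   `c("alpha", "beta", "congruence", "spatial", "vulnerability")` to run
#' @param out_dir optional directory; when given, all result tables are
#'   written there as delimited text plus a plain-text summary
#' @param verbose log stage progress to stderr
#' @return a list (class `rivdiv_report`) with one element per section
#' @export
run_pipeline <- function(community, traits, tree, site_attributes,
                         n_axes = 5, n_axes_fd = 4,
                         correction = "lingoes",
                         weights_scheme = "inverse-distance",
                         n_perm = 9999, mc_points = 200000, seed = 1,
                         sections = c("alpha", "beta", "congruence",
                                      "spatial", "vulnerability"),
                         out_dir = NULL, verbose = FALSE) {
  stage <- function(name, expr) {
    log_msg("stage: ", name, verbose = verbose)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  check_species_coverage(traits, community)
  check_tree_coverage(tree, community)
  report <- list(header = list(
    n_sites = nrow(community), n_species = ncol(community),
    n_individuals = sum(community), seed = seed, n_perm = n_perm,
    n_axes = n_axes, n_axes_fd = n_axes_fd,
    weights_scheme = weights_scheme, correction = correction))

  ts <- stage("trait_space",
              build_trait_space(traits[colnames(community), ],
                                n_axes = n_axes, correction = correction))
  report$trait_space <- ts

  if ("alpha" %in% sections) {
    report$alpha <- stage("alpha", alpha_table(community, ts, tree))
    report$prevalence <- prevalence(community)
  }
  if (any(c("beta", "congruence") %in% sections)) {
    report$beta <- stage("beta", list(
      TD = taxonomic_beta(community),
      FD = functional_beta(community, ts, n_axes_fd = n_axes_fd,
                           mc_points = mc_points, seed = seed,
                           verbose = verbose),
      PD = phylogenetic_beta(community, tree)))
  }
  if ("beta" %in% sections) {
    report$beta_summary <- stage("beta_summary",
                                 lapply(report$beta, beta_summary))
    report$beta_regression <- stage("beta_regression",
      do.call(rbind, lapply(report$beta, beta_component_regression)))
  }
  if ("congruence" %in% sections) {
    al <- if (!is.null(report$alpha)) report$alpha else
      alpha_table(community, ts, tree)
    rich_vals <- list(TD = setNames(al$Shannon, rownames(al)),
                      FD = setNames(al$RaoQ, rownames(al)),
                      PD = setNames(al$PDfaith, rownames(al)))
    even_vals <- list(TD = setNames(al$SEve, rownames(al)),
                      FD = setNames(al$FEve, rownames(al)),
                      PD = setNames(al$PSEve, rownames(al)))
    curves <- list()
    for (fp in facet_pairs(c("TD", "FD", "PD"))) {
      nm <- paste(fp, collapse = "-")
      curves[[paste0("alpha_richness_", nm)]] <-
        congruence_curve(rich_vals[fp], mode = "alpha-sites")
      ev <- even_vals[fp]
      if (!anyNA(unlist(ev)))
        curves[[paste0("alpha_evenness_", nm)]] <-
          congruence_curve(ev, mode = "alpha-sites")
      for (comp in c("sor", "sim", "nes")) {
        vals <- lapply(report$beta[fp], function(bm)
          beta_pair_values(bm[[comp]]))
        ok <- !Reduce(`|`, lapply(vals, is.na))
        vals <- lapply(vals, function(v) v[ok])
        curves[[paste0("beta_", comp, "_", nm)]] <-
          congruence_curve(vals, mode = "beta-pairs")
      }
    }
    report$congruence <- curves
  }
  if ("spatial" %in% sections) {
    w <- stage("weights", build_weights(site_attributes[rownames(community),
                                                        , drop = FALSE],
                                        scheme = weights_scheme))
    al <- if (!is.null(report$alpha)) report$alpha else
      alpha_table(community, ts, tree)
    idx <- c("Shannon", "RaoQ", "PDfaith")
    report$morans_i <- lapply(setNames(idx, idx), function(i)
      stage(paste0("morans_i_", i),
            morans_i(al[[i]], w, mode = "normal")))
    pr <- combn(idx, 2, simplify = FALSE)
    report$lees_l <- lapply(pr, function(p)
      stage(paste0("lees_l_", paste(p, collapse = "_")),
            lees_l(al[[p[1]]], al[[p[2]]], w, n_perm = n_perm,
                   seed = seed)))
    names(report$lees_l) <- vapply(pr, paste, "", collapse = "-")
    factors <- intersect(c("order_category", "dlink_category",
                           "dam_category"), names(site_attributes))
    anovas <- list()
    skipped <- character(0)
    for (i in idx) for (f in factors) {
      # a factor can lack two usable levels on small or homogeneous
      # networks; such tests are skipped and recorded, not fatal
      res <- tryCatch(suppressWarnings(
        factor_anova(al, site_attributes, i, f)),
        error = function(e) conditionMessage(e))
      if (is.character(res)) {
        skipped <- c(skipped, paste0(i, ".", f, ": ", res))
        log_msg("anova skipped for ", i, " ~ ", f, ": ", res,
                verbose = verbose)
      } else {
        anovas[[paste(i, f, sep = ".")]] <- res
      }
    }
    report$anova <- anovas
    report$anova_skipped <- skipped
    report$weights <- w
  }
  if ("vulnerability" %in% sections) {
    loo <- stage("leave_one_out", leave_one_out(community, ts, tree))
    report$vulnerability <- loo
    report$species_contributions <- stage("species_contributions",
                                          species_contributions(loo))
    report$site_vulnerability <- stage("site_vulnerability",
                                       site_vulnerability(loo))
    report$distinctive <- stage("distinctive_species",
                                distinctive_species(community, traits))
  }
  class(report) <- "rivdiv_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.rivdiv_report <- function(x, ...) {
  h <- x$header
  cat(sprintf("rivdiv report: %d sites, %d species, %d individuals\n",
              h$n_sites, h$n_species, h$n_individuals))
  cat("  sections:", paste(setdiff(names(x), "header"), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a pipeline report to delimited tables and a text summary
#'
#' @param report a [run_pipeline()] result
#' @param dir output directory
#' @return invisibly, the directory
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- report$header
  lines <- c("rivdiv pipeline report",
             sprintf("sites=%d species=%d individuals=%d", h$n_sites,
                     h$n_species, h$n_individuals),
             sprintf("seed=%d n_perm=%d n_axes=%d n_axes_fd=%d", h$seed,
                     h$n_perm, h$n_axes, h$n_axes_fd),
             sprintf("weights=%s pcoa_correction=%s", h$weights_scheme,
                     h$correction))
  if (!is.null(report$trait_space))
    lines <- c(lines, sprintf("cumulative_variance_retained=%.4f",
      report$trait_space$cumulative_variance[report$trait_space$n_axes]))
  if (!is.null(report$alpha))
    write_results(report$alpha, file.path(dir, "alpha.tsv"))
  if (!is.null(report$beta)) {
    for (f in names(report$beta)) for (comp in c("sor", "sim", "nes"))
      write_results(as.data.frame(report$beta[[f]][[comp]]),
                    file.path(dir, sprintf("beta_%s_%s.tsv", f, comp)))
  }
  if (!is.null(report$beta_summary)) {
    for (f in names(report$beta_summary)) {
      s <- report$beta_summary[[f]]
      for (comp in c("sor", "sim", "nes"))
        lines <- c(lines, sprintf(
          "beta_%s_%s: mean=%.4f sd=%.4f min=%.4f max=%.4f argmin=%s|%s argmax=%s|%s",
          f, comp, s[[comp]]$mean, s[[comp]]$sd, s[[comp]]$min,
          s[[comp]]$max, s[[comp]]$argmin[1], s[[comp]]$argmin[2],
          s[[comp]]$argmax[1], s[[comp]]$argmax[2]))
    }
  }
  if (!is.null(report$beta_regression))
    write_results(report$beta_regression,
                  file.path(dir, "beta_regression.tsv"),
                  row_names = FALSE)
  if (!is.null(report$congruence)) {
    cc <- do.call(rbind, lapply(names(report$congruence), function(nm) {
      d <- report$congruence[[nm]]
      data.frame(curve = nm, q = d$q, k = d$k, overlap = d$overlap)
    }))
    write_results(cc, file.path(dir, "congruence.tsv"), row_names = FALSE)
  }
  if (!is.null(report$morans_i)) {
    mi <- do.call(rbind, lapply(names(report$morans_i), function(i) {
      t0 <- report$morans_i[[i]]
      data.frame(index = i, observed = t0$statistic,
                 expected = t0$expected, sd = t0$sd, p_value = t0$p_value)
    }))
    write_results(mi, file.path(dir, "morans_i.tsv"), row_names = FALSE)
  }
  if (!is.null(report$lees_l)) {
    ll <- do.call(rbind, lapply(names(report$lees_l), function(p) {
      t0 <- report$lees_l[[p]]
      data.frame(pair = p, statistic = t0$statistic,
                 expected = t0$expected, p_value = t0$p_value)
    }))
    write_results(ll, file.path(dir, "lees_l.tsv"), row_names = FALSE)
  }
  if (!is.null(report$anova)) {
    av <- do.call(rbind, lapply(names(report$anova), function(k) {
      t0 <- report$anova[[k]]
      data.frame(test = k, f_statistic = t0$f_statistic,
                 df1 = t0$df[1], df2 = t0$df[2], p_value = t0$p_value,
                 letters = paste(sprintf("%s=%s", names(t0$letters),
                                         t0$letters), collapse = ","))
    }))
    write_results(av, file.path(dir, "anova.tsv"), row_names = FALSE)
  }
  if (!is.null(report$vulnerability)) {
    dl <- report$vulnerability$deltas
    long <- do.call(rbind, lapply(names(dl), function(f) {
      idx <- which(!is.na(dl[[f]]), arr.ind = TRUE)
      data.frame(site = rownames(dl[[f]])[idx[, 1]],
                 species = colnames(dl[[f]])[idx[, 2]],
                 facet = f, delta = dl[[f]][idx])
    }))
    write_results(long, file.path(dir, "vulnerability_deltas.tsv"),
                  row_names = FALSE)
    write_results(report$species_contributions$contributions,
                  file.path(dir, "species_contributions.tsv"))
    write_results(report$site_vulnerability$site_summary,
                  file.path(dir, "site_vulnerability.tsv"),
                  row_names = FALSE)
    write_results(report$distinctive$species,
                  file.path(dir, "distinctive_species.tsv"))
    disp <- report$site_vulnerability$dispersion
    lines <- c(lines, sprintf(
      "dispersion_test=%s statistic=%.4f p=%.4g higher_variance=%s",
      disp$method, disp$statistic, disp$p_value,
      as.character(disp$higher_variance_facet)))
  }
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
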