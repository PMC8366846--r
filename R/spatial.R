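#' Build a spatial weights matrix from site coordinates
#'
#' @param coordinates data.frame or matrix with columns `x`, `y` and site
#'   row names
#' @param scheme `"inverse-distance"` (default), `"k-nearest"` or
#'   `"binary-threshold"`
#' @param row_standardize divide each row by its sum (default TRUE)
#' @param k number of neighbours for `"k-nearest"`
#' @param threshold distance cutoff for `"binary-threshold"`
#' @return object of class `spatial_weights`: the weights matrix with
#'   `scheme` and `row_standardized` attributes
#' @export
build_weights <- function(coordinates,
                          scheme = c("inverse-distance", "k-nearest",
                                     "binary-threshold"),
                          row_standardize = TRUE, k = 4, threshold = NULL) {
  scheme <- match.arg(scheme)
  xy <- as.matrix(coordinates[, c("x", "y")])
  d <- as.matrix(stats::dist(xy))
  n <- nrow(d)
  if (n < 2) stop("need at least 2 sites", call. = FALSE)
  off <- d[upper.tri(d)]
  if (any(off == 0))
    stop("coincident sites (zero distance) in coordinates", call. = FALSE)
  w <- switch(scheme,
    "inverse-distance" = 1 / d,
    "k-nearest" = {
      m <- matrix(0, n, n)
      for (i in seq_len(n)) {
        nb <- order(d[i, ])[2:(min(k, n - 1) + 1)]
        m[i, nb] <- 1
      }
      pmax(m, t(m)) # symmetrise before optional row standardisation
    },
    "binary-threshold" = {
      if (is.null(threshold)) threshold <- stats::median(off)
      (d <= threshold) * 1
    })
  diag(w) <- 0
  if (any(rowSums(w) == 0))
    stop("site with no positive weight to any other site", call. = FALSE)
  if (row_standardize) w <- w / rowSums(w)
  dimnames(w) <- dimnames(d)
  structure(w, scheme = scheme, row_standardized = row_standardize,
            class = c("spatial_weights", "matrix", "array"))
}

moran_stat <- function(z, w) {
  n <- length(z)
  (n / sum(w)) * drop(z %*% w %*% z) / sum(z^2)
}

# all permutations of 1..n (n <= 8)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Moran's I spatial autocorrelation test
#'
#' `I = (n / W0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with centred values
#' z and `W0 = sum(w)`. Under the normality assumption the expected value
#' is `-1/(n-1)` and the variance has the classical closed form; the
#' permutation mode uses random relabellings of the sites (exhaustive
#' enumeration when `n! <= n_perm`), with the `(count + 1)/(n_perm + 1)`
#' convention and two-sided extremeness `|I - E| >= |I_obs - E|`.
#'
#' @param values per-site numeric vector
#' @param weights a [build_weights()] matrix (any non-negative
#'   zero-diagonal matrix works)
#' @param mode `"normal"` (analytic) or `"permutation"`
#' @param n_perm number of permutations
#' @param seed permutation seed
#' @return list (class `facet_test`) with `statistic`, `expected`, `sd`,
#'   `p_value`, `method`, and permutation metadata when applicable
#' @export
morans_i <- function(values, weights, mode = c("normal", "permutation"),
                     n_perm = 9999, seed = 1) {
  mode <- match.arg(mode)
  w <- unclass(weights)
  n <- length(values)
  if (n != nrow(w)) stop("values and weights differ in size", call. = FALSE)
  if (sd(values) == 0) stop("values are constant", call. = FALSE)
  z <- values - mean(values)
  obs <- moran_stat(z, w)
  expected <- -1 / (n - 1)
  if (mode == "normal") {
    s0 <- sum(w)
    s1 <- 0.5 * sum((w + t(w))^2)
    s2 <- sum((rowSums(w) + colSums(w))^2)
    var_i <- (n^2 * s1 - n * s2 + 3 * s0^2) / (s0^2 * (n^2 - 1)) -
      expected^2
    sdev <- sqrt(var_i)
    p <- 2 * stats::pnorm(abs(obs - expected) / sdev, lower.tail = FALSE)
    out <- list(statistic = obs, expected = expected, sd = sdev,
                p_value = p, method = "morans_i_normal")
  } else {
    if (factorial(n) <= n_perm) {
      perms <- all_perms(n)
      sims <- apply(perms, 1, function(p) moran_stat(z[p], w))
      p <- mean(abs(sims - expected) >= abs(obs - expected) - 1e-12)
      out <- list(statistic = obs, expected = expected, sd = sd(sims),
                  p_value = p, method = "morans_i_permutation_exhaustive",
                  n_perm = nrow(perms))
    } else {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old))
      set.seed(seed)
      sims <- replicate(n_perm, moran_stat(z[sample.int(n)], w))
      cnt <- sum(abs(sims - expected) >= abs(obs - expected) - 1e-12)
      out <- list(statistic = obs, expected = expected, sd = sd(sims),
                  p_value = (cnt + 1) / (n_perm + 1),
                  method = "morans_i_permutation", n_perm = n_perm,
                  seed = seed)
    }
  }
  structure(out, class = "facet_test")
}

#' @export
print.facet_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.4f, expected %.4f, p = %.4g\n",
              x$method, x$statistic,
              if (is.null(x$expected)) NA else x$expected, x$p_value))
  invisible(x)
}

lee_stat <- function(zx, zy, w) {
  n <- length(zx)
  lx <- drop(w %*% zx)
  ly <- drop(w %*% zy)
  (n / sum(rowSums(w)^2)) * sum(lx * ly) /
    (sqrt(sum(zx^2)) * sqrt(sum(zy^2)))
}

#' Lee's L bivariate spatial association test
#'
#' Combines Pearson correlation with spatial smoothing: with centred
#' vectors and row sums of the weights, L measures how strongly the two
#' spatially lagged variables co-vary. Significance is assessed by joint
#' permutation of site labels (both variables permuted together keeps
#' their aspatial correlation intact), exhaustively when feasible.
#'
#' @param x,y per-site numeric vectors
#' @param weights spatial weights matrix
#' @param n_perm number of permutations
#' @param seed permutation seed
#' @return a `facet_test` list; `expected` is the permutation mean
#' @export
lees_l <- function(x, y, weights, n_perm = 9999, seed = 1) {
  w <- unclass(weights)
  n <- length(x)
  if (length(y) != n || nrow(w) != n)
    stop("x, y and weights differ in size", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector", call. = FALSE)
  zx <- x - mean(x)
  zy <- y - mean(y)
  obs <- lee_stat(zx, zy, w)
  if (factorial(n) <= n_perm) {
    perms <- all_perms(n)
    sims <- apply(perms, 1, function(p) lee_stat(zx[p], zy[p], w))
    expected <- mean(sims)
    p <- mean(abs(sims - expected) >= abs(obs - expected) - 1e-12)
    method <- "lees_l_permutation_exhaustive"
    np <- nrow(perms)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    sims <- replicate(n_perm, {
      p <- sample.int(n)
      lee_stat(zx[p], zy[p], w)
    })
    expected <- mean(sims)
    cnt <- sum(abs(sims - expected) >= abs(obs - expected) - 1e-12)
    p <- (cnt + 1) / (n_perm + 1)
    method <- "lees_l_permutation"
    np <- n_perm
  }
  structure(list(statistic = obs, expected = expected, sd = sd(sims),
                 p_value = p, method = method, n_perm = np, seed = seed),
            class = "facet_test")
}

#' One-way analysis of variance of an alpha index across a connectivity
#' factor
#'
#' F test of a per-site diversity index against one categorical
#' river-connectivity surrogate (Strahler order, log2 downstream-link
#' category, or dam category), with per-level means and pairwise level
#' comparisons (pooled-variance t tests) lettered at a configurable
#' confidence level. Levels with fewer than 2 sites are dropped with a
#' warning. An optional joint multivariate (Pillai trace) test over
#' several indices is available via `joint_indices`.
#'
#' @param alpha an [alpha_table()]
#' @param attributes site attribute data.frame (rows = sites) holding the
#'   factor column
#' @param index column of `alpha` to test (e.g. `"Shannon"`, `"RaoQ"`,
#'   `"PDfaith"`)
#' @param factor_name column of `attributes` to group by (e.g.
#'   `"order_category"`, `"dlink_category"`, `"dam_category"`)
#' @param conf_level confidence level for pairwise letters (default 0.99)
#' @param joint_indices optional character vector of alpha columns for a
#'   joint Pillai-trace MANOVA
#' @return list (class `anova_result`) with `f_statistic`, `df`,
#'   `p_value`, `level_means`, `pairwise` (data.frame) and `letters`
#' @export
factor_anova <- function(alpha, attributes, index, factor_name,
                         conf_level = 0.99, joint_indices = NULL) {
  if (!index %in% names(alpha))
    stop("unknown index '", index, "'", call. = FALSE)
  if (!factor_name %in% names(attributes))
    stop("unknown factor '", factor_name, "'", call. = FALSE)
  common <- intersect(rownames(alpha), rownames(attributes))
  y <- alpha[common, index]
  g <- as.character(attributes[common, factor_name])
  tab <- table(g)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("dropping level(s) with < 2 sites: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(g %in% small)
    y <- y[keep]; g <- g[keep]; common <- common[keep]
  }
  g <- factor(g)
  k <- nlevels(g)
  if (k < 2) stop("need at least 2 usable levels", call. = FALSE)
  n <- length(y)
  means <- tapply(y, g, mean)
  grand <- mean(y)
  ss_between <- sum(tapply(y, g, length) * (means - grand)^2)
  ss_within <- sum((y - means[g])^2)
  df1 <- k - 1
  df2 <- n - k
  ms_within <- ss_within / df2
  f <- (ss_between / df1) / ms_within
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # pairwise pooled-variance t tests and compact letter display
  lev <- levels(g)
  pw <- expand.grid(level1 = lev, level2 = lev,
                    stringsAsFactors = FALSE)
  pw <- pw[match(pw$level1, lev) < match(pw$level2, lev), ]
  pw$p_value <- vapply(seq_len(nrow(pw)), function(i) {
    n1 <- sum(g == pw$level1[i]); n2 <- sum(g == pw$level2[i])
    se <- sqrt(ms_within * (1 / n1 + 1 / n2))
    tstat <- (means[pw$level1[i]] - means[pw$level2[i]]) / se
    2 * stats::pt(abs(tstat), df2, lower.tail = FALSE)
  }, numeric(1))
  rownames(pw) <- NULL
  letters_out <- letter_display(lev, pw, alpha_level = 1 - conf_level)
  joint <- NULL
  if (!is.null(joint_indices)) {
    ym <- as.matrix(alpha[common, joint_indices, drop = FALSE])
    fit <- stats::manova(ym ~ g)
    st <- summary(fit, test = "Pillai")$stats
    joint <- list(pillai = st[1, "Pillai"], f = st[1, "approx F"],
                  p_value = st[1, "Pr(>F)"])
  }
  structure(list(index = index, factor = factor_name,
                 f_statistic = f, df = c(df1, df2), p_value = p,
                 level_means = means,
                 level_n = as.integer(tapply(y, g, length)),
                 pairwise = pw, letters = letters_out,
                 conf_level = conf_level, joint = joint),
            class = "anova_result")
}

# compact letter display by greedy grouping: levels (ordered by mean) share
# a letter when no pairwise difference within the group is significant
letter_display <- function(levels_, pairwise, alpha_level) {
  sig <- function(l1, l2) {
    hit <- (pairwise$level1 == l1 & pairwise$level2 == l2) |
      (pairwise$level1 == l2 & pairwise$level2 == l1)
    any(pairwise$p_value[hit] < alpha_level)
  }
  groups <- list()
  for (l in levels_) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (!any(vapply(groups[[gi]], sig, logical(1), l1 = l))) {
        groups[[gi]] <- c(groups[[gi]], l)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- l
  }
  out <- setNames(rep("", length(levels_)), levels_)
  for (gi in seq_along(groups))
    for (l in groups[[gi]])
      out[l] <- paste0(out[l], letters[gi])
  out
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: %s ~ %s, F(%d, %d) = %.3f, p = %.4g\n",
              x$index, x$factor, x$df[1], x$df[2], x$f_statistic,
              x$p_value))
  lm_ <- x$level_means
  cat("  level means: ",
      paste(sprintf("%s = %.3f (%s)", names(lm_), lm_,
                    x$letters[names(lm_)]), collapse = ", "), "\n")
  invisible(x)
}
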