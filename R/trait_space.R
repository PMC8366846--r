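#' Gower dissimilarity for mixed continuous/categorical traits
#'
#' Range-normalised mixed-type dissimilarity. Continuous traits contribute
#' `|x_i - x_j| / range`; nominal categorical traits contribute a 0/1
#' mismatch; ordered categorical traits (life span) contribute the
#' range-normalised rank difference. Per-trait contributions are combined
#' as a weighted mean, giving values in [0, 1].
#'
#' A continuous trait with zero range carries no information; it
#' contributes 0 with a warning.
#'
#' @param traits a [trait_table()]
#' @param weights non-negative per-trait weights, recycled/named over the
#'   trait columns; default equal weights
#' @return symmetric species x species dissimilarity matrix in [0, 1]
#' @export
gower_dissimilarity <- function(traits, weights = NULL) {
  schema <- attr(traits, "schema")
  cols <- c(schema$continuous, names(schema$categorical))
  n <- nrow(traits)
  if (n < 2) stop("need at least 2 species", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(cols))
  if (!is.null(names(weights))) weights <- weights[cols]
  if (length(weights) != length(cols) || anyNA(weights))
    stop("weights must cover all ", length(cols), " traits", call. = FALSE)
  if (any(weights < 0) || sum(weights) == 0)
    stop("weights must be >= 0 and not all zero", call. = FALSE)

  acc <- matrix(0, n, n, dimnames = list(rownames(traits), rownames(traits)))
  for (k in seq_along(cols)) {
    tr <- cols[k]
    w <- weights[k]
    if (w == 0) next
    v <- traits[[tr]]
    if (is.numeric(v)) {
      rng <- diff(range(v))
      if (rng == 0) {
        warning("continuous trait '", tr, "' has zero range; contributes 0",
                call. = FALSE)
        next
      }
      contrib <- abs(outer(v, v, "-")) / rng
    } else if (is.ordered(v)) {
      r <- as.integer(v)
      rng <- diff(range(r))
      contrib <- if (rng == 0) matrix(0, n, n) else
        abs(outer(r, r, "-")) / rng
    } else {
      contrib <- outer(as.integer(v), as.integer(v), "!=") * 1
    }
    acc <- acc + w * contrib
  }
  d <- acc / sum(weights)
  diag(d) <- 0
  d
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Classical metric scaling: double-centre `-d^2 / 2`, eigendecompose, and
#' scale eigenvectors by the square roots of their eigenvalues. Negative
#' eigenvalues (non-Euclidean input, typical for Gower matrices) can be
#' handled by the Lingoes or Cailliez additive corrections; with
#' `correction = "none"` the variance decomposition uses positive
#' eigenvalues only. Axis signs are fixed deterministically: each axis's
#' largest-magnitude coordinate is made positive.
#'
#' @param d symmetric zero-diagonal dissimilarity matrix
#' @param correction `"lingoes"` (default), `"cailliez"` or `"none"`
#' @return object of class `trait_space` holding all positive axes:
#'   `coordinates` (species x axes), `eigenvalues` (full spectrum of the
#'   matrix actually decomposed), `cumulative_variance`, `correction`, and
#'   the applied correction constant
#' @export
pcoa <- function(d, correction = c("lingoes", "cailliez", "none")) {
  correction <- match.arg(correction)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  if (any(diag(d) != 0))
    stop("dissimilarity matrix must have a zero diagonal", call. = FALSE)
  n <- nrow(d)
  center <- function(dd) {
    a <- -0.5 * dd^2
    sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  }
  ev0 <- eigen(center(d), symmetric = TRUE)
  const <- 0
  if (correction != "none" && min(ev0$values) < -1e-8 * max(abs(ev0$values))) {
    if (correction == "lingoes") {
      # add constant c1 to all squared off-diagonal dissimilarities
      const <- -min(ev0$values)
      d2 <- sqrt(d^2 + 2 * const)
      diag(d2) <- 0
      ev <- eigen(center(d2), symmetric = TRUE)
    } else {
      # Cailliez: add constant c2 to all off-diagonal dissimilarities;
      # smallest c2 is the largest eigenvalue of a 2n x 2n special matrix
      delta <- center(d)
      a1 <- -0.5 * d
      del1 <- sweep(sweep(a1, 1, rowMeans(a1)), 2, colMeans(a1)) + mean(a1)
      big <- rbind(cbind(matrix(0, n, n), 2 * delta),
                   cbind(-diag(n), -4 * del1))
      const <- max(Re(eigen(big, only.values = TRUE)$values))
      d2 <- d + const
      diag(d2) <- 0
      ev <- eigen(center(d2), symmetric = TRUE)
    }
  } else {
    ev <- ev0
  }
  vals <- ev$values
  pos <- which(vals > max(vals) * 1e-9)
  coords <- ev$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(vals[pos]), length(pos))
  # deterministic axis orientation
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("A", seq_len(ncol(coords)))
  cumvar <- cumsum(vals[pos]) / sum(vals[pos])
  structure(list(species = rownames(d), coordinates = coords,
                 eigenvalues = vals, cumulative_variance = cumvar,
                 correction = correction, correction_constant = const,
                 n_axes = ncol(coords), distance_matrix = NULL),
            class = "trait_space")
}

#' Build the retained-axis functional trait space
#'
#' Runs Gower + PCoA on a trait table and keeps the first `n_axes`
#' principal coordinates; all functional-diversity computations
#' (Rao's Q, FEve, convex-hull beta) operate in this reduced space, with
#' inter-species functional distances taken as Euclidean distances on the
#' retained axes.
#'
#' @param traits a [trait_table()]
#' @param n_axes number of axes to retain (default 5)
#' @param correction passed to [pcoa()]
#' @param weights passed to [gower_dissimilarity()]
#' @return a `trait_space` with `coordinates` restricted to `n_axes` axes
#'   and `distance_matrix` filled in
#' @export
build_trait_space <- function(traits, n_axes = 5,
                              correction = c("lingoes", "cailliez", "none"),
                              weights = NULL) {
  d <- gower_dissimilarity(traits, weights)
  ts <- pcoa(d, match.arg(correction))
  navail <- ts$n_axes
  if (n_axes > navail)
    stop("n_axes = ", n_axes, " but only ", navail,
         " positive axes available", call. = FALSE)
  ts$coordinates <- ts$coordinates[, seq_len(n_axes), drop = FALSE]
  ts$n_axes <- n_axes
  ts$distance_matrix <- as.matrix(stats::dist(ts$coordinates))
  ts
}

#' @export
print.trait_space <- function(x, ...) {
  cat(sprintf(
    "trait_space: %d species, %d retained axes (%.1f%% cumulative variance)\n",
    length(x$species), x$n_axes,
    100 * x$cumulative_variance[min(x$n_axes,
                                    length(x$cumulative_variance))]))
  if (x$correction != "none")
    cat(sprintf("  %s correction, constant %.4g\n", x$correction,
                x$correction_constant))
  invisible(x)
}
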