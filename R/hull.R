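# Exact convex-hull geometry in low dimension (2-4 axes of trait space).
#
# All routines work from first principles on small point sets: supporting
# hyperplanes are found by enumerating point subsets, volumes by recursive
# cone decomposition, and intersections by vertex enumeration over the
# combined half-space system. A seeded Monte Carlo rejection estimator
# provides both a fallback where the combinatorics get too large
# (typically 4-D intersections) and an independent cross-check.

GEOM_TOL <- 1e-9

affine_rank <- function(points) {
  if (nrow(points) < 2) return(0L)
  qr(sweep(points, 2, points[1, ]))$rank
}

# supporting half-spaces A x <= b of the convex hull of `points` (n x d,
# full affine rank). Enumerates d-point subsets; a subset spans a facet
# hyperplane when all points lie on one side.
hull_facets <- function(points) {
  n <- nrow(points)
  d <- ncol(points)
  if (d == 1) {
    return(list(a = matrix(c(1, -1), 2, 1),
                b = c(max(points), -min(points))))
  }
  idx <- combn(n, d)
  keys <- character(0)
  a_rows <- list()
  b_vals <- numeric(0)
  scale <- max(1, max(abs(points)))
  for (k in seq_len(ncol(idx))) {
    sub <- points[idx[, k], , drop = FALSE]
    m <- sweep(sub[-1, , drop = FALSE], 2, sub[1, ])
    dec <- qr(t(m))
    if (dec$rank < d - 1) next
    nor <- qr.Q(dec, complete = TRUE)[, d]
    off <- sum(nor * sub[1, ])
    side <- points %*% nor - off
    tol <- GEOM_TOL * scale
    if (all(side <= tol)) {
      # keep as is
    } else if (all(side >= -tol)) {
      nor <- -nor
      off <- -off
    } else next
    key <- paste(round(c(nor, off / scale), 7), collapse = ",")
    if (key %in% keys) next
    keys <- c(keys, key)
    a_rows[[length(a_rows) + 1]] <- nor
    b_vals <- c(b_vals, off)
  }
  if (!length(a_rows)) stop("degenerate point set: no facets", call. = FALSE)
  list(a = do.call(rbind, a_rows), b = b_vals)
}

hull_contains <- function(facets, x, tol = 1e-7) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  rowSums(x %*% t(facets$a) > rep(facets$b + tol, each = nrow(x))) == 0
}

# volume of the convex hull of `points` by recursive cone decomposition:
# sum over facets of (1/d) * height(centroid -> facet) * facet area,
# facet areas computed recursively in an orthonormal basis of the facet
# hyperplane.
hull_volume <- function(points) {
  points <- as.matrix(points)
  d <- ncol(points)
  if (affine_rank(points) < d) return(0)
  if (d == 1) return(diff(range(points)))
  f <- hull_facets(points)
  centroid <- colMeans(points)
  scale <- max(1, max(abs(points)))
  vol <- 0
  for (i in seq_along(f$b)) {
    nor <- f$a[i, ]
    on_plane <- abs(points %*% nor - f$b[i]) <= 1e-7 * scale
    fp <- points[on_plane, , drop = FALSE]
    if (nrow(fp) < d) next
    # orthonormal basis of the hyperplane through fp[1, ]
    basis <- qr.Q(qr(cbind(nor, diag(d))))[, -1, drop = FALSE]
    proj <- sweep(fp, 2, fp[1, ]) %*% basis
    area <- hull_volume(proj)
    height <- abs(sum(nor * centroid) - f$b[i])
    vol <- vol + height * area / d
  }
  vol
}

# vertices of the intersection polytope of two half-space systems, by
# enumerating d-subsets of the combined constraints
intersection_vertices <- function(f1, f2, cap = 3e4) {
  a <- rbind(f1$a, f2$a)
  b <- c(f1$b, f2$b)
  d <- ncol(a)
  m <- nrow(a)
  if (choose(m, d) > cap) return(NULL) # caller falls back to Monte Carlo
  idx <- combn(m, d)
  scale <- max(1, max(abs(b)))
  verts <- list()
  for (k in seq_len(ncol(idx))) {
    rows <- idx[, k]
    aa <- a[rows, , drop = FALSE]
    if (abs(det(aa)) < GEOM_TOL) next
    x <- solve(aa, b[rows])
    if (all(a %*% x <= b + 1e-7 * scale)) verts[[length(verts) + 1]] <- x
  }
  if (!length(verts)) return(matrix(numeric(0), 0, d))
  v <- do.call(rbind, verts)
  v[!duplicated(round(v / scale, 7)), , drop = FALSE]
}

#' Exact intersection volume of two convex hulls
#'
#' Builds the facet (half-space) systems of both hulls, enumerates the
#' vertices of the combined system, and measures the resulting polytope.
#' Returns NULL when the combinatorial budget is exceeded (the caller
#' should then use [hull_intersection_mc()]).
#'
#' @param p1,p2 point matrices (same dimension)
#' @return intersection volume, 0 when the hulls do not overlap in full
#'   dimension, or NULL when too complex for exact enumeration
#' @export
hull_intersection_exact <- function(p1, p2) {
  d <- ncol(p1)
  if (affine_rank(p1) < d || affine_rank(p2) < d) return(0)
  f1 <- hull_facets(p1)
  f2 <- hull_facets(p2)
  v <- intersection_vertices(f1, f2)
  if (is.null(v)) return(NULL)
  if (nrow(v) < d + 1 || affine_rank(v) < d) return(0)
  hull_volume(v)
}

#' Monte Carlo intersection volume of two convex hulls
#'
#' Rejection sampling in the bounding box of the union: the intersection
#' volume is the box volume times the fraction of sampled points inside
#' both hulls. Deterministic under `seed`.
#'
#' @param p1,p2 point matrices (same dimension)
#' @param n_points number of samples (default 200000)
#' @param seed integer seed
#' @return list with `volume` and its binomial `se`
#' @export
hull_intersection_mc <- function(p1, p2, n_points = 200000, seed = 1) {
  d <- ncol(p1)
  if (affine_rank(p1) < d || affine_rank(p2) < d)
    return(list(volume = 0, se = 0))
  f1 <- hull_facets(p1)
  f2 <- hull_facets(p2)
  lo <- pmin(apply(p1, 2, min), apply(p2, 2, min))
  hi <- pmax(apply(p1, 2, max), apply(p2, 2, max))
  vbox <- prod(hi - lo)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  inside <- 0L
  chunk <- 50000L
  left <- n_points
  while (left > 0) {
    m <- min(chunk, left)
    x <- matrix(runif(m * d, rep(lo, each = m), rep(hi, each = m)), m, d)
    in1 <- rowSums(x %*% t(f1$a) > rep(f1$b + GEOM_TOL, each = m)) == 0
    if (any(in1)) {
      x2 <- x[in1, , drop = FALSE]
      in2 <- rowSums(x2 %*% t(f2$a) >
                       rep(f2$b + GEOM_TOL, each = nrow(x2))) == 0
      inside <- inside + sum(in2)
    }
    left <- left - m
  }
  p <- inside / n_points
  list(volume = vbox * p, se = vbox * sqrt(p * (1 - p) / n_points))
}

# joint Monte Carlo estimate of vol(hull1), vol(hull2) and
# vol(intersection) from ONE shared sample in the union bounding box:
# sharing the sample guarantees the estimated intersection never exceeds
# either hull volume, so the derived Sorensen components stay in range.
hull_pair_mc <- function(p1, p2, n_points = 200000, seed = 1) {
  d <- ncol(p1)
  f1 <- hull_facets(p1)
  f2 <- hull_facets(p2)
  lo <- pmin(apply(p1, 2, min), apply(p2, 2, min))
  hi <- pmax(apply(p1, 2, max), apply(p2, 2, max))
  vbox <- prod(hi - lo)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n1 <- n2 <- n12 <- 0L
  chunk <- 50000L
  left <- n_points
  while (left > 0) {
    m <- min(chunk, left)
    x <- matrix(runif(m * d, rep(lo, each = m), rep(hi, each = m)), m, d)
    in1 <- rowSums(x %*% t(f1$a) > rep(f1$b + GEOM_TOL, each = m)) == 0
    in2 <- rowSums(x %*% t(f2$a) > rep(f2$b + GEOM_TOL, each = m)) == 0
    n1 <- n1 + sum(in1)
    n2 <- n2 + sum(in2)
    n12 <- n12 + sum(in1 & in2)
    left <- left - m
  }
  p12 <- n12 / n_points
  list(v1 = vbox * n1 / n_points, v2 = vbox * n2 / n_points,
       v12 = vbox * p12,
       se12 = vbox * sqrt(p12 * (1 - p12) / n_points))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
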