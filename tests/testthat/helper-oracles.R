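# independent brute-force oracles; every routine here recomputes its
# quantity from the definition, not via the package's code paths

oracle_shannon <- function(x) {
  p <- x[x > 0] / sum(x[x > 0])
  h <- 0
  for (pi in p) h <- h - pi * log(pi)
  h
}

oracle_rao <- function(x, d) {
  x <- x[x > 0]
  p <- x / sum(x)
  q <- 0
  for (i in seq_along(p)) for (j in seq_along(p))
    q <- q + d[names(p)[i], names(p)[j]] * p[i] * p[j]
  unname(q)
}

# all labelled trees on n nodes via Pruefer sequences (n <= 7)
pruefer_trees <- function(n) {
  if (n == 2) return(list(matrix(c(1, 2), 1, 2)))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  lapply(seq_len(nrow(seqs)), function(r) {
    s <- seqs[r, ]
    degree <- rep(1L, n)
    for (v in s) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, n - 1, 2)
    ptr <- s
    for (k in seq_along(ptr)) {
      leaf <- min(which(degree == 1L))
      edges[k, ] <- c(leaf, ptr[k])
      degree[leaf] <- 0L
      degree[ptr[k]] <- degree[ptr[k]] - 1L
    }
    edges[n - 1, ] <- which(degree == 1L)
    edges
  })
}

# exact minimum spanning tree by exhaustive enumeration of all trees
oracle_mst <- function(d) {
  n <- nrow(d)
  best <- NULL
  best_w <- Inf
  for (ed in pruefer_trees(n)) {
    w <- sum(d[ed])
    if (w < best_w) {
      best_w <- w
      best <- ed
    }
  }
  list(edges = best, weight = best_w)
}

oracle_feve <- function(x, co) {
  x <- x[x > 0]
  s <- length(x)
  p <- x / sum(x)
  d <- as.matrix(stats::dist(co[names(x), , drop = FALSE]))
  mst <- oracle_mst(d)
  ew <- numeric(nrow(mst$edges))
  for (k in seq_len(nrow(mst$edges))) {
    i <- mst$edges[k, 1]; j <- mst$edges[k, 2]
    ew[k] <- d[i, j] / (p[i] + p[j])
  }
  pew <- ew / sum(ew)
  thr <- 1 / (s - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

# edges (rows of tree$edge) on the path from the root to a tip
root_path_edges <- function(tree, tip) {
  node <- which(tree$tip.label == tip)
  root <- length(tree$tip.label) + 1L
  path <- integer(0)
  while (node != root) {
    e <- which(tree$edge[, 2] == node)
    path <- c(path, e)
    node <- tree$edge[e, 1]
  }
  path
}

oracle_branch_set <- function(tree, species, include_root = TRUE) {
  paths <- lapply(species, root_path_edges, tree = tree)
  un <- sort(unique(unlist(paths)))
  if (!include_root && length(paths) > 0) {
    shared <- Reduce(intersect, paths)
    un <- setdiff(un, shared)
  }
  un
}

oracle_pd <- function(tree, species, include_root = TRUE) {
  sum(tree$edge.length[oracle_branch_set(tree, species, include_root)])
}

oracle_psv <- function(tree, species) {
  c_mat <- stats::cov2cor(ape::vcv(tree)[species, species])
  n <- length(species)
  (n * sum(diag(c_mat)) - sum(c_mat)) / (n * (n - 1))
}

oracle_pse <- function(tree, m) {
  c_mat <- stats::cov2cor(ape::vcv(tree)[names(m), names(m)])
  big_m <- sum(m)
  (big_m * sum(m * diag(c_mat)) - drop(m %*% c_mat %*% m)) /
    (big_m^2 - sum(m^2))
}

# per-trait hand summation for the Gower dissimilarity of two species
oracle_gower_pair <- function(traits, i, j) {
  schema <- attr(traits, "schema")
  total <- 0
  nt <- 0
  for (tr in schema$continuous) {
    v <- traits[[tr]]
    rng <- max(v) - min(v)
    total <- total + if (rng > 0) abs(v[i] - v[j]) / rng else 0
    nt <- nt + 1
  }
  for (tr in names(schema$categorical)) {
    v <- traits[[tr]]
    if (tr %in% schema$ordered) {
      r <- as.integer(v)
      rng <- max(r) - min(r)
      total <- total + if (rng > 0) abs(r[i] - r[j]) / rng else 0
    } else {
      total <- total + as.numeric(v[i] != v[j])
    }
    nt <- nt + 1
  }
  total / nt
}

oracle_sorensen <- function(set1, set2) {
  a <- length(intersect(set1, set2))
  b <- length(setdiff(set1, set2))
  c <- length(setdiff(set2, set1))
  sor <- (b + c) / (2 * a + b + c)
  mn <- min(b, c)
  sim <- if (a + mn == 0) 0 else mn / (a + mn)
  c(sor = sor, sim = sim, nes = sor - sim)
}

# recursive permutations (insert n at every position), independent of the
# package's enumerator
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1L)) for (pos in seq_len(n))
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

oracle_moran <- function(values, w) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

oracle_lee <- function(x, y, w) {
  n <- length(x)
  zx <- x - mean(x)
  zy <- y - mean(y)
  num <- 0
  denom_w <- 0
  for (i in seq_len(n)) {
    lx <- sum(w[i, ] * zx)
    ly <- sum(w[i, ] * zy)
    num <- num + lx * ly
    denom_w <- denom_w + sum(w[i, ])^2
  }
  (n / denom_w) * num / (sqrt(sum(zx^2)) * sqrt(sum(zy^2)))
}

oracle_quadfit <- function(x, y) {
  xm <- cbind(1, x, x^2)
  beta <- solve(t(xm) %*% xm, t(xm) %*% y)
  res <- y - xm %*% beta
  n <- length(y)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(coef = drop(beta), r2_adj = 1 - (1 - r2) * (n - 1) / (n - 3))
}

# Strahler order straight from the recursive definition
oracle_strahler <- function(net, edge_id) {
  ups <- net$edges$edge[net$edges$to ==
                          net$edges$from[net$edges$edge == edge_id]]
  if (length(ups) == 0) return(1L)
  uo <- vapply(ups, function(e) oracle_strahler(net, e), integer(1))
  if (sum(uo == max(uo)) >= 2) max(uo) + 1L else max(uo)
}

# number of source segments upstream of an edge, by repeated expansion
oracle_sources_above <- function(net, edge_id) {
  acc <- 0L
  frontier <- edge_id
  while (length(frontier)) {
    e <- frontier[1]
    frontier <- frontier[-1]
    ups <- net$edges$edge[net$edges$to ==
                            net$edges$from[net$edges$edge == e]]
    if (length(ups) == 0) acc <- acc + 1L else frontier <- c(frontier, ups)
  }
  acc
}
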