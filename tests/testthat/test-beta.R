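test_that("sorensen_components: closed forms and partition additivity", {
  c1 <- sorensen_components(5, 3, 2)
  expect_equal(c1$beta_sor, 5 / 15)
  expect_equal(c1$beta_sim, 2 / 7)
  expect_equal(c1$beta_nes, 5 / 15 - 2 / 7)
  c2 <- sorensen_components(4, 0, 0) # identical communities
  expect_equal(unlist(c2[c("beta_sor", "beta_sim", "beta_nes")]),
               c(beta_sor = 0, beta_sim = 0, beta_nes = 0))
  c3 <- sorensen_components(0, 3, 5) # disjoint
  expect_equal(c3$beta_sor, 1)
  expect_equal(c3$beta_sim, 1)
  expect_equal(c3$beta_nes, 0)
  expect_error(sorensen_components(0, 0, 0), "zero")
  expect_error(sorensen_components(-1, 1, 1), ">= 0")
  # one-sided guard: a = 0, min(b, c) = 0
  expect_equal(sorensen_components(0, 4, 0)$beta_sim, 0)
})

test_that("taxonomic beta equals the exhaustive set-count oracle", {
  set.seed(10)
  m <- matrix(rbinom(5 * 8, 1, 0.6), 5, 8,
              dimnames = list(paste0("s", 1:5), paste0("sp", 1:8)))
  m[rowSums(m) == 0, 1] <- 1
  m <- m[, colSums(m) > 0]
  cm <- community_matrix(m)
  td <- taxonomic_beta(cm)
  pa <- presence_absence(cm)
  for (i in 1:4) for (j in (i + 1):5) {
    o <- oracle_sorensen(colnames(pa)[pa[i, ]], colnames(pa)[pa[j, ]])
    expect_equal(td$sor[i, j], unname(o["sor"]), tolerance = 1e-12)
    expect_equal(td$sim[i, j], unname(o["sim"]), tolerance = 1e-12)
    expect_equal(td$nes[i, j], unname(o["nes"]), tolerance = 1e-12)
  }
  # abundance scaling leaves presence/absence beta unchanged
  cm10 <- community_matrix(unclass(cm) * 10L)
  expect_equal(taxonomic_beta(cm10)$sor, td$sor)

  # nested rows: pure nestedness
  nest <- community_matrix(matrix(c(1, 1, 1, 1, 1, 1, 0, 1, 0, 0, 1, 0),
                                  2, 6, byrow = TRUE,
                                  dimnames = list(c("big", "small"),
                                                  paste0("x", 1:6))))
  tb <- taxonomic_beta(nest)
  expect_equal(tb$sim[1, 2], 0)
  expect_equal(tb$nes[1, 2], tb$sor[1, 2])
})

test_that("phylogenetic beta matches the branch-set oracle", {
  tr <- random_tree(12, seed = 12)
  set.seed(13)
  m <- matrix(rbinom(4 * 12, 1, 0.5), 4, 12,
              dimnames = list(paste0("s", 1:4), tr$tip.label))
  m[rowSums(m) == 0, 1] <- 1
  keep <- colSums(m) > 0
  m <- m[, keep]
  tr2 <- ape::keep.tip(tr, colnames(m))
  cm <- community_matrix(m)
  pb <- phylogenetic_beta(cm, tr2)
  pa <- presence_absence(cm)
  len <- tr2$edge.length
  for (i in 1:3) for (j in (i + 1):4) {
    s1 <- oracle_branch_set(tr2, colnames(pa)[pa[i, ]])
    s2 <- oracle_branch_set(tr2, colnames(pa)[pa[j, ]])
    a <- sum(len[intersect(s1, s2)])
    b <- sum(len[setdiff(s1, s2)])
    c <- sum(len[setdiff(s2, s1)])
    o <- sorensen_components(a, b, c)
    expect_equal(pb$sor[i, j], o$beta_sor, tolerance = 1e-12)
    expect_equal(pb$sim[i, j], o$beta_sim, tolerance = 1e-12)
    expect_equal(pb$nes[i, j], o$beta_nes, tolerance = 1e-12)
  }
  # identical sites dissimilarity 0
  same <- community_matrix(matrix(c(1, 1, 2, 3), 2, 2,
      dimnames = list(c("u", "v"), tr2$tip.label[1:2])))
  tr3 <- ape::keep.tip(tr2, tr2$tip.label[1:2])
  expect_equal(phylogenetic_beta(same, tr3)$sor[1, 2], 0)
})

test_that("two singleton communities on a star tree are maximally distinct", {
  st <- star_tree(3)
  cm <- community_matrix(matrix(c(1, 0, 0, 1), 2, 2,
      dimnames = list(c("s1", "s2"), c("t1", "t2"))))
  st2 <- ape::keep.tip(st, c("t1", "t2"))
  pb <- phylogenetic_beta(cm, st2, include_root = TRUE)
  expect_equal(pb$sor[1, 2], 1)
})

test_that("PD beta on star trees with unit branches reduces to TD beta", {
  st <- star_tree(6)
  set.seed(14)
  # exhaustive over all non-empty subset pairs of <= 6 species
  subsets <- lapply(1:(2^6 - 1), function(k) which(intToBits(k)[1:6] == 1))
  pick <- sample(length(subsets), 40, replace = TRUE)
  pick2 <- sample(length(subsets), 40, replace = TRUE)
  for (r in 1:40) {
    s1 <- subsets[[pick[r]]]
    s2 <- subsets[[pick2[r]]]
    present <- sort(unique(c(s1, s2)))
    m <- matrix(0L, 2, length(present),
                dimnames = list(c("x", "y"), paste0("t", present)))
    m[1, match(s1, present)] <- 1L
    m[2, match(s2, present)] <- 1L
    cm <- community_matrix(m)
    stp <- ape::keep.tip(st, colnames(m))
    pb <- phylogenetic_beta(cm, stp)
    td <- taxonomic_beta(cm)
    expect_equal(pb$sor[1, 2], td$sor[1, 2], tolerance = 1e-12)
    expect_equal(pb$sim[1, 2], td$sim[1, 2], tolerance = 1e-12)
  }
})

fd_toy <- function(points_by_site) {
  # build a community + coordinate space from named point matrices
  all_pts <- do.call(rbind, points_by_site)
  rownames(all_pts) <- paste0("q", seq_len(nrow(all_pts)))
  k <- 0
  m <- matrix(0L, length(points_by_site), nrow(all_pts),
              dimnames = list(names(points_by_site), rownames(all_pts)))
  for (s in seq_along(points_by_site)) {
    n <- nrow(points_by_site[[s]])
    m[s, k + seq_len(n)] <- 1L
    k <- k + n
  }
  list(community = community_matrix(m), space = coord_space(all_pts))
}

test_that("functional beta: analytic square cases", {
  sq <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
  half <- cbind(c(0, 0, 0.5, 0.5), c(0, 1, 0, 1))
  shifted <- cbind(c(2, 2, 3, 3), c(0, 1, 0, 1))

  # identical point sets: dissimilarity 0
  fx <- fd_toy(list(a = sq, b = sq))
  fb <- functional_beta(fx$community, fx$space, n_axes_fd = 2)
  expect_equal(fb$sor[1, 2], 0, tolerance = 1e-9)

  # disjoint unit squares: total dissimilarity 1
  fx2 <- fd_toy(list(a = sq, b = shifted))
  fb2 <- functional_beta(fx2$community, fx2$space, n_axes_fd = 2)
  expect_equal(fb2$sor[1, 2], 1, tolerance = 1e-9)
  expect_equal(fb2$sim[1, 2], 1, tolerance = 1e-9)

  # unit square vs its left half: pure nestedness, sor = 1/3
  fx3 <- fd_toy(list(a = sq, b = half))
  fb3 <- functional_beta(fx3$community, fx3$space, n_axes_fd = 2)
  expect_equal(fb3$sor[1, 2], 1 / 3, tolerance = 1e-9)
  expect_equal(fb3$sim[1, 2], 0, tolerance = 1e-9)
  expect_equal(fb3$nes[1, 2], 1 / 3, tolerance = 1e-9)
})

test_that("functional beta reduces dimensionality for small communities", {
  set.seed(15)
  big <- matrix(rnorm(6 * 3), 6, 3)
  small <- matrix(rnorm(3 * 3), 3, 3) # 3 species < n_axes_fd + 1
  fx <- fd_toy(list(big = big, small = small))
  fb <- functional_beta(fx$community, fx$space, n_axes_fd = 3,
                        mc_points = 10000)
  expect_true(fb$reduced[1, 2])
  expect_false(is.na(fb$sor[1, 2]))
  # min richness < 3: missing
  tiny <- matrix(rnorm(2 * 3), 2, 3)
  fx2 <- fd_toy(list(big = big, tiny = tiny))
  fb2 <- functional_beta(fx2$community, fx2$space, n_axes_fd = 3)
  expect_true(is.na(fb2$sor[1, 2]))
})

test_that("beta additivity holds for every facet on a simulated bundle", {
  b <- simulate_scenario(scenario_config(n_species = 25, n_sites = 8,
                                         n_sources = 5, seed = 16))
  ts <- build_trait_space(b$traits, n_axes = 3)
  for (bm in list(taxonomic_beta(b$community),
                  phylogenetic_beta(b$community, b$tree),
                  functional_beta(b$community, ts, n_axes_fd = 2,
                                  mc_points = 5000))) {
    gap <- abs(bm$sor - bm$sim - bm$nes)
    expect_lt(max(gap, na.rm = TRUE), 1e-12)
    for (m in list(bm$sor, bm$sim, bm$nes)) {
      expect_true(isSymmetric(unname(m)))
      expect_true(all(diag(m) == 0))
      expect_true(all(m[!is.na(m)] >= 0 & m[!is.na(m)] <= 1 + 1e-12))
    }
  }
})

test_that("beta_summary and regression behave on closed cases", {
  m <- matrix(0.4, 3, 3,
              dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  diag(m) <- 0
  bm <- structure(list(facet = "TD", sor = m, sim = m / 2, nes = m / 2),
                  class = "beta_matrices")
  s <- beta_summary(bm)
  expect_equal(s$sor$sd, 0)
  expect_equal(s$sor$mean, 0.4)
  expect_equal(sum(s$sor$histogram), 3)

  # hand-computed mean on an asymmetric toy
  m2 <- m
  m2[1, 2] <- m2[2, 1] <- 0.2
  m2[1, 3] <- m2[3, 1] <- 0.6
  m2[2, 3] <- m2[3, 2] <- 0.7
  bm2 <- structure(list(facet = "TD", sor = m2, sim = m2, nes = m2 * 0),
                   class = "beta_matrices")
  s2 <- beta_summary(bm2)
  expect_equal(s2$sor$mean, mean(c(0.2, 0.6, 0.7)))
  expect_equal(s2$sor$argmax, c("s2", "s3"))

  nas <- m * NA
  bm3 <- structure(list(facet = "FD", sor = nas, sim = nas, nes = nas),
                   class = "beta_matrices")
  expect_error(beta_summary(bm3), "all pairs missing")

  # regression: quadratic fit recovers exact relations and the oracle
  set.seed(17)
  n <- 8
  sor <- matrix(0, n, n, dimnames = list(paste0("s", 1:n),
                                         paste0("s", 1:n)))
  sor[upper.tri(sor)] <- runif(n * (n - 1) / 2)
  sor <- sor + t(sor)
  bm4 <- structure(list(facet = "TD", sor = sor, sim = sor,
                        nes = 1 - sor), class = "beta_matrices")
  reg <- beta_component_regression(bm4)
  row_ss <- reg[reg$x == "sim" & reg$y == "sor", ]
  expect_equal(row_ss$r2_adj, 1, tolerance = 1e-9)
  expect_equal(row_ss$direction, 1)
  row_ns <- reg[reg$x == "nes" & reg$y == "sim", ]
  expect_equal(row_ns$direction, -1)
  x <- sor[upper.tri(sor)]
  o <- oracle_quadfit(x, 1 - x + 0.3 * x^2)
  bm5 <- structure(list(facet = "TD", sor = sor, sim = sor,
                        nes = matrix(0, n, n)), class = "beta_matrices")
  bm5$nes[upper.tri(bm5$nes)] <- 1 - x + 0.3 * x^2
  bm5$nes <- bm5$nes + t(bm5$nes)
  dimnames(bm5$nes) <- dimnames(sor)
  reg5 <- beta_component_regression(bm5)
  r5 <- reg5[reg5$x == "sim" & reg5$y == "sor", ] # y = sor = x here
  r5b <- reg5[reg5$x == "nes" & reg5$y == "sim", ]
  fit_row <- reg5[reg5$x == "sim" & reg5$y == "sor", ]
  expect_equal(unname(unlist(
    reg5[reg5$x == "nes" & reg5$y == "sim",
         c("intercept", "linear", "quadratic")])),
    unname(oracle_quadfit(1 - x + 0.3 * x^2, x)$coef), tolerance = 1e-8)
})
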