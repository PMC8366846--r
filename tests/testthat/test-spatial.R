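coords5 <- function() {
  data.frame(row.names = paste0("s", 1:5),
             x = c(0, 1, 2, 0, 2), y = c(0, 0, 0, 1, 1))
}

test_that("build_weights schemes behave and validate", {
  co <- coords5()
  w <- build_weights(co)
  expect_equal(unname(rowSums(w)), rep(1, 5))
  expect_equal(attr(w, "scheme"), "inverse-distance")
  # hand-built inverse-distance grid before standardisation
  w_raw <- build_weights(co, row_standardize = FALSE)
  d <- as.matrix(dist(co))
  expect_equal(unclass(w_raw)[1, 2], 1 / d[1, 2])
  expect_equal(unclass(w_raw)[2, 5], 1 / d[2, 5])
  expect_true(isSymmetric(unname(unclass(w_raw))))

  two <- data.frame(row.names = c("a", "b"), x = c(0, 3), y = c(0, 4))
  w2 <- build_weights(two, row_standardize = FALSE)
  expect_equal(w2[1, 2], w2[2, 1])
  expect_gt(w2[1, 2], 0)

  wk <- build_weights(co, scheme = "k-nearest", k = 2)
  expect_true(all(rowSums(unclass(wk) > 0) >= 2))
  wb <- build_weights(co, scheme = "binary-threshold", threshold = 1.0)
  expect_true(all(unclass(wb) %in% c(0, 0.5, 1) |
                    abs(unclass(wb) - 1 / 3) < 1e-12))

  expect_error(build_weights(data.frame(x = c(0, 0), y = c(0, 0),
                                        row.names = c("a", "b"))),
               "coincident")
})

test_that("morans_i matches the closed forms and ape's implementation", {
  # expected value at n = 24
  set.seed(30)
  co <- data.frame(row.names = paste0("s", 1:24),
                   x = runif(24, 0, 10), y = runif(24, 0, 10))
  w <- build_weights(co)
  vals <- rnorm(24)
  t1 <- morans_i(vals, w)
  expect_equal(t1$expected, -1 / 23)

  # oracle: direct double-loop statistic
  expect_equal(t1$statistic, oracle_moran(vals, unclass(w)),
               tolerance = 1e-12)
  # oracle: ape's implementation for the statistic and expectation (its
  # SD uses the randomization variance; ours follows the normality
  # formula, so SDs agree only approximately)
  ao <- ape::Moran.I(vals, unclass(w))
  expect_equal(t1$statistic, ao$observed, tolerance = 1e-10)
  expect_equal(t1$expected, ao$expected, tolerance = 1e-12)
  expect_equal(t1$sd, ao$sd, tolerance = 0.05)
  # normality-variance oracle, typed from the textbook formula
  wm <- unclass(w)
  n <- 24
  s0 <- sum(wm)
  s1 <- sum((wm + t(wm))^2) / 2
  s2 <- sum((rowSums(wm) + colSums(wm))^2)
  var_norm <- (n^2 * s1 - n * s2 + 3 * s0^2) / ((n^2 - 1) * s0^2) -
    1 / (n - 1)^2
  expect_equal(t1$sd, sqrt(var_norm), tolerance = 1e-12)
  expect_equal(t1$p_value,
               2 * pnorm(abs(t1$statistic + 1 / 23) / sqrt(var_norm),
                         lower.tail = FALSE), tolerance = 1e-12)

  # spatial gradient with near-neighbour weights: positive autocorrelation
  grad <- co$x
  tg <- morans_i(grad, build_weights(co, scheme = "k-nearest", k = 3))
  expect_gt(tg$statistic, tg$expected)

  expect_error(morans_i(rep(1, 24), w), "constant")

  # affine invariance of the statistic
  t2 <- morans_i(5 * vals + 3, w)
  expect_equal(t2$statistic, t1$statistic, tolerance = 1e-12)
})

test_that("permutation-mode Moran's I is exhaustively exact for small n", {
  set.seed(31)
  co <- data.frame(row.names = paste0("s", 1:6),
                   x = runif(6), y = runif(6))
  w <- build_weights(co)
  vals <- rnorm(6)
  tp <- morans_i(vals, w, mode = "permutation", n_perm = 9999)
  expect_equal(tp$method, "morans_i_permutation_exhaustive")
  # oracle: enumerate all 720 permutations independently
  sims <- vapply(oracle_perms(6), function(p)
    oracle_moran(vals[p], unclass(w)), numeric(1))
  obs <- oracle_moran(vals, unclass(w))
  expected <- -1 / 5
  p_oracle <- mean(abs(sims - expected) >= abs(obs - expected) - 1e-12)
  expect_equal(tp$p_value, p_oracle, tolerance = 1e-12)
})

test_that("lees_l matches the direct-formula oracle and sign conventions", {
  set.seed(32)
  co <- data.frame(row.names = paste0("s", 1:6),
                   x = runif(6), y = runif(6))
  w <- build_weights(co)
  x <- rnorm(6)
  t_same <- lees_l(x, x, w)
  expect_gt(t_same$statistic, 0)
  t_opp <- lees_l(x, -x, w)
  expect_lt(t_opp$statistic, 0)
  expect_equal(t_opp$statistic, -t_same$statistic, tolerance = 1e-12)

  y <- rnorm(6)
  t_xy <- lees_l(x, y, w)
  expect_equal(t_xy$statistic, oracle_lee(x, y, unclass(w)),
               tolerance = 1e-12)
  expect_equal(t_xy$method, "lees_l_permutation_exhaustive")
  # oracle p from exhaustive joint permutations
  sims <- vapply(oracle_perms(6), function(p)
    oracle_lee(x[p], y[p], unclass(w)), numeric(1))
  p_oracle <- mean(abs(sims - mean(sims)) >=
                     abs(t_xy$statistic - mean(sims)) - 1e-12)
  expect_equal(t_xy$p_value, p_oracle, tolerance = 1e-12)
  expect_error(lees_l(rep(1, 6), y, w), "constant")
})

test_that("factor_anova matches hand sums of squares and is shift-invariant", {
  al <- data.frame(row.names = paste0("s", 1:9),
                   Shannon = c(1.0, 1.2, 1.1, 2.0, 2.2, 2.1, 3.0, 3.1,
                               2.9))
  at <- data.frame(row.names = paste0("s", 1:9),
                   dam_category = rep(c("Up", "Down", "None"), each = 3))
  res <- factor_anova(al, at, "Shannon", "dam_category")
  # sum-of-squares oracle via the standard linear model
  fit <- stats::anova(stats::lm(al$Shannon ~ at$dam_category))
  expect_equal(res$f_statistic, fit$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p_value, fit$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(res$df, c(fit$Df[1], fit$Df[2]))

  al2 <- al
  al2$Shannon <- al$Shannon + 100
  res2 <- factor_anova(al2, at, "Shannon", "dam_category")
  expect_equal(res2$f_statistic, res$f_statistic, tolerance = 1e-9)

  # equal group means with within-group spread: F = 0, p = 1
  al3 <- data.frame(row.names = paste0("s", 1:6),
                    Shannon = c(1, 1, 2, 2, 1.5, 1.5))
  at3 <- data.frame(row.names = paste0("s", 1:6),
                    dam_category = c("Up", "Down", "Up", "Down", "Up",
                                     "Down"))
  res3 <- factor_anova(al3, at3, "Shannon", "dam_category")
  expect_lt(res3$f_statistic, 1e-10)
  expect_equal(res3$p_value, 1, tolerance = 1e-9)

  # a level with a single site is dropped with a warning
  at4 <- data.frame(row.names = paste0("s", 1:9),
                    dam_category = c(rep("Up", 4), rep("Down", 4),
                                     "None"))
  expect_warning(res4 <- factor_anova(al, at4, "Shannon",
                                      "dam_category"), "dropping")
  expect_equal(sum(res4$level_n), 8)

  # letters: clearly separated groups get distinct letters at 0.99
  res5 <- factor_anova(al, at, "Shannon", "dam_category")
  expect_equal(length(unique(res5$letters)), 3)
})

test_that("joint Pillai-trace test runs when requested", {
  set.seed(33)
  al <- data.frame(row.names = paste0("s", 1:12),
                   Shannon = rnorm(12), RaoQ = rnorm(12),
                   PDfaith = rnorm(12))
  at <- data.frame(row.names = paste0("s", 1:12),
                   dam_category = rep(c("Up", "Down"), each = 6))
  res <- factor_anova(al, at, "Shannon", "dam_category",
                      joint_indices = c("Shannon", "RaoQ", "PDfaith"))
  expect_true(!is.null(res$joint))
  expect_true(res$joint$p_value >= 0 && res$joint$p_value <= 1)
})
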