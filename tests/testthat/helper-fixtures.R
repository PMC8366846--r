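# small in-code fixtures shared across test files

toy_community <- function() {
  community_matrix(matrix(
    c(3, 0, 2,
      1, 2, 0,
      0, 4, 1,
      2, 2, 2),
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("s", 1:4), c("A", "B", "C"))))
}

star_tree <- function(n = 3, len = 1) {
  tips <- paste0("t", seq_len(n))
  ape::read.tree(text = paste0(
    "(", paste(sprintf("%s:%g", tips, len), collapse = ","), ");"))
}

random_tree <- function(n, seed) {
  generate_tree(n, lambda = 1, seed = seed)
}

# trait table with the default ten-trait schema, random but seeded
random_traits <- function(species, seed = 1) {
  set.seed(seed)
  n <- length(species)
  schema <- default_trait_schema()
  df <- as.data.frame(
    matrix(exp(rnorm(n * 7, 0, 0.4)), n, 7,
           dimnames = list(species, schema$continuous)))
  for (tr in names(schema$categorical))
    df[[tr]] <- sample(schema$categorical[[tr]], n, replace = TRUE)
  trait_table(df, schema)
}

# minimal trait_space wrapper around explicit coordinates
coord_space <- function(co) {
  structure(list(species = rownames(co), coordinates = co,
                 eigenvalues = NULL, cumulative_variance = 1,
                 correction = "none", correction_constant = 0,
                 n_axes = ncol(co),
                 distance_matrix = as.matrix(stats::dist(co))),
            class = "trait_space")
}

# Y-shaped network: two sources joining at a confluence, then the outlet
# segment; site/dam placements supplied by the caller
y_network <- function(dams = NULL, sites = NULL) {
  edges <- data.frame(edge = c("e1", "e2", "e3"),
                      from = c("hw1", "hw2", "c1"),
                      to = c("c1", "c1", "outlet"),
                      length = c(1, 1, 1))
  river_network(edges, dams = dams, sites = sites)
}

# seven-segment asymmetric network used by the Strahler/Dlink tests:
# sources e1, e2 join at c1 (-> e5); source e3 joins e5 at c2 (-> e6);
# source e4 joins e6 at c3 (-> e7 the outlet link)
chain_network <- function(dams = NULL, sites = NULL) {
  edges <- data.frame(
    edge = paste0("e", 1:7),
    from = c("hw1", "hw2", "hw3", "hw4", "c1", "c2", "c3"),
    to = c("c1", "c1", "c2", "c3", "c2", "c3", "outlet"),
    length = 1)
  river_network(edges, dams = dams, sites = sites)
}
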