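#' Top-quantile item set
#'
#' The `k = ceiling(q * n)` items with the highest values. Boundary ties
#' are broken deterministically by item-identifier order, so repeated runs
#' return identical sets.
#'
#' @param values named numeric vector
#' @param q fraction in (0, 1]
#' @return character vector of item identifiers
#' @export
top_set <- function(values, q) {
  if (q <= 0 || q > 1) stop("q must be in (0, 1]", call. = FALSE)
  if (is.null(names(values))) names(values) <- seq_along(values)
  k <- ceiling(q * length(values))
  ord <- order(-values, names(values))
  names(values)[ord][seq_len(k)]
}

#' Quantile-concordance congruence curve between diversity facets
#'
#' For each quantile fraction q in `quantiles`, the overlap is the size of
#' the intersection of the facets' top-q item sets divided by
#' `ceiling(q * n)`. Items are sites (alpha mode) or unordered site pairs
#' (beta mode); the curve always reaches 1 at q = 1.
#'
#' @param values_by_facet named list of 2 or 3 per-item numeric vectors
#'   with identical item names
#' @param mode `"alpha-sites"` or `"beta-pairs"` (metadata only; for beta
#'   matrices use [beta_pair_values()] to build the vectors)
#' @param quantiles fractions to evaluate (default 0.1 ... 1.0)
#' @return data.frame (class `congruence_curve`) with columns `q`,
#'   `overlap`, `k`
#' @export
congruence_curve <- function(values_by_facet,
                             mode = c("alpha-sites", "beta-pairs"),
                             quantiles = seq(0.1, 1, by = 0.1)) {
  mode <- match.arg(mode)
  if (length(values_by_facet) < 2)
    stop("need at least two facets", call. = FALSE)
  items <- names(values_by_facet[[1]])
  if (is.null(items)) stop("facet vectors must be named", call. = FALSE)
  for (v in values_by_facet[-1]) {
    if (!setequal(names(v), items))
      stop("facet vectors cover different item sets", call. = FALSE)
  }
  out <- data.frame(q = quantiles, overlap = NA_real_,
                    k = ceiling(quantiles * length(items)))
  for (i in seq_along(quantiles)) {
    sets <- lapply(values_by_facet, top_set, q = quantiles[i])
    out$overlap[i] <- length(Reduce(intersect, sets)) / out$k[i]
  }
  attr(out, "mode") <- mode
  attr(out, "facets") <- names(values_by_facet)
  class(out) <- c("congruence_curve", "data.frame")
  out
}

#' Upper-triangle values of a beta matrix as a named pair vector
#'
#' @param m site x site matrix
#' @return named vector, names `"site1|site2"`
#' @export
beta_pair_values <- function(m) {
  ut <- which(upper.tri(m), arr.ind = TRUE)
  setNames(m[upper.tri(m)],
           paste(rownames(m)[ut[, 1]], colnames(m)[ut[, 2]], sep = "|"))
}
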