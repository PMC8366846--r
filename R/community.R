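#' Construct a site-by-species community matrix
#'
#' The central container for abundance data: an integer matrix with sites as
#' rows and species as columns. Validation enforces the invariants every
#' downstream computation relies on: unique identifiers, non-negative integer
#' counts, no empty site and no species absent everywhere.
#'
#' @param abundance numeric matrix (or object coercible to one) of
#'   non-negative integer counts, sites in rows, species in columns.
#'   Dimnames are required and become the site / species identifiers.
#' @return an object of class `community_matrix` (an integer matrix with
#'   class attribute).
#' @export
community_matrix <- function(abundance) {
  m <- as.matrix(abundance)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("community matrix needs site row names and species column names",
         call. = FALSE)
  rownames(m) <- trimws(rownames(m))
  colnames(m) <- trimws(colnames(m))
  dup_s <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup_s))
    stop("duplicate site identifier(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  dup_p <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup_p))
    stop("duplicate species identifier(s): ", paste(dup_p, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(m))
    stop("community matrix contains non-numeric cells", call. = FALSE)
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "invalid count at site '%s', species '%s': counts must be integers >= 0",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
  empty_sites <- rownames(m)[rowSums(m) == 0]
  if (length(empty_sites))
    stop("site(s) with no individuals: ", paste(empty_sites, collapse = ", "),
         call. = FALSE)
  empty_sp <- colnames(m)[colSums(m) == 0]
  if (length(empty_sp))
    stop("species with zero total abundance: ",
         paste(empty_sp, collapse = ", "), call. = FALSE)
  storage.mode(m) <- "integer"
  structure(m, class = c("community_matrix", "matrix", "array"))
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d sites x %d species, %d individuals\n",
              nrow(x), ncol(x), sum(x)))
  cat(sprintf("  richness range: %d - %d\n",
              min(richness(x)), max(richness(x))))
  invisible(x)
}

#' Presence/absence view of a community matrix
#'
#' @param community a `community_matrix`
#' @return logical matrix of the same shape, TRUE where abundance > 0
#' @export
presence_absence <- function(community) {
  unclass(community) > 0
}

#' Per-site species richness
#' @param community a `community_matrix`
#' @return named integer vector of species counts per site
#' @export
richness <- function(community) {
  rowSums(presence_absence(community))
}

#' Species prevalence (occurrence fraction)
#'
#' Prevalence of a species is its number of occupied sites divided by the
#' number of sampling sites, a value in (0, 1].
#'
#' @param community a `community_matrix`
#' @return named numeric vector over species
#' @export
prevalence <- function(community) {
  colSums(presence_absence(community)) / nrow(community)
}

#' Average individuals per species at each site
#'
#' Total individuals collected at a site divided by the site's richness.
#'
#' @param community a `community_matrix`
#' @return named numeric vector over sites
#' @export
individuals_per_species <- function(community) {
  rowSums(community) / richness(community)
}

# relative-abundance vector for one site, restricted to present species
site_relabund <- function(community, site) {
  v <- unclass(community)[site, ]
  v <- v[v > 0]
  v / sum(v)
}
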