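#' Read and validate a rooted phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()] and enforces the invariants the diversity
#' computations need: rooted topology, labelled tips and non-negative branch
#' lengths. Underscores in tip labels are treated as spaces (the usual
#' Newick convention), then whitespace is normalised.
#'
#' @param path Newick file path
#' @param missing_lengths `"error"` (default) or `"zero"`: what to do when
#'   the file carries no branch lengths.
#' @return an [ape::read.tree()] `phylo` object
#' @export
read_tree <- function(path, missing_lengths = c("error", "zero")) {
  missing_lengths <- match.arg(missing_lengths)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("cannot parse Newick file: ", path, call. = FALSE)
  validate_tree(tree, missing_lengths)
}

validate_tree <- function(tree, missing_lengths = "error") {
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("tree has unlabeled tips", call. = FALSE)
  tree$tip.label <- normalize_species(tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length)) {
    if (missing_lengths == "error")
      stop("tree has no branch lengths", call. = FALSE)
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree has missing or negative branch lengths", call. = FALSE)
  # the basal node of the parsed Newick is taken as the root; basal
  # polytomies (which ape flags as "unrooted") are accepted
  tree
}

# species-name normalisation shared by trees and tables: trim, collapse
# whitespace, map underscores to spaces
normalize_species <- function(x) {
  gsub("\\s+", " ", trimws(gsub("_", " ", x)))
}

#' Check that a tree's tips cover a community's species
#'
#' @param tree a `phylo`
#' @param community a `community_matrix`
#' @return invisibly TRUE; errors listing the symmetric difference otherwise
#' @export
check_tree_coverage <- function(tree, community) {
  sp <- normalize_species(colnames(community))
  tips <- normalize_species(tree$tip.label)
  missing <- setdiff(sp, tips)
  extra <- setdiff(tips, sp)
  if (length(missing))
    stop("tree is missing community species: ",
         paste(missing, collapse = ", "),
         if (length(extra)) paste0("; tips absent from community: ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}
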