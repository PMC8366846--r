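#' Default functional-trait schema
#'
#' Ten traits commonly used for stream fish: seven continuous morphological
#' ratios (head length / standard length, eye diameter / head depth, snout
#' length / head length, head depth / body depth, pectoral-fin length /
#' standard length, caudal peduncle depth / caudal fin depth, body depth /
#' standard length) and three categorical traits (rheophily, position in
#' the water column, maximum life span binned in years). Life span is
#' ordered; the other two are nominal.
#'
#' @return a list with elements `continuous`, `categorical` (a named list of
#'   allowed levels) and `ordered` (names of ordered categorical traits)
#' @export
default_trait_schema <- function() {
  list(
    continuous = c("Hl.Sl", "Ed.Hd", "Snl.Hl", "Hd.Bd",
                   "PecFl.Sl", "CPd.CFd", "Bd.Sl"),
    categorical = list(
      rheophily = c("rheophilic", "limnophilic", "eurytopic"),
      water_column = c("benthic", "benthopelagic", "pelagic"),
      life_span = c("<=10", "10-20", ">20")
    ),
    ordered = "life_span"
  )
}

#' Construct a validated trait table
#'
#' @param df data.frame with species identifiers as row names
#' @param schema trait schema as returned by [default_trait_schema()];
#'   declares which columns are continuous and the closed level set of each
#'   categorical column.
#' @return object of class `trait_table`: the data.frame with categorical
#'   columns as (possibly ordered) factors and a `schema` attribute
#' @export
trait_table <- function(df, schema = default_trait_schema()) {
  df <- as.data.frame(df)
  if (is.null(rownames(df)))
    stop("trait table needs species row names", call. = FALSE)
  rownames(df) <- trimws(rownames(df))
  miss <- setdiff(c(schema$continuous, names(schema$categorical)), names(df))
  if (length(miss))
    stop("trait column(s) missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (tr in schema$continuous) {
    v <- df[[tr]]
    if (!is.numeric(v))
      stop("continuous trait '", tr, "' is not numeric", call. = FALSE)
    if (anyNA(v))
      stop("missing value in continuous trait '", tr, "' for species ",
           rownames(df)[which(is.na(v))[1]], call. = FALSE)
    if (any(v <= 0))
      stop("continuous trait '", tr, "' must be strictly positive (species ",
           rownames(df)[which(v <= 0)[1]], ")", call. = FALSE)
  }
  for (tr in names(schema$categorical)) {
    lev <- schema$categorical[[tr]]
    v <- as.character(df[[tr]])
    bad <- setdiff(unique(v[!is.na(v)]), lev)
    if (length(bad))
      stop("unknown level '", bad[1], "' in categorical trait '", tr,
           "'; allowed: {", paste(lev, collapse = ", "), "}", call. = FALSE)
    if (anyNA(v))
      stop("missing value in categorical trait '", tr, "'", call. = FALSE)
    df[[tr]] <- factor(v, levels = lev, ordered = tr %in% schema$ordered)
  }
  df <- df[, c(schema$continuous, names(schema$categorical)), drop = FALSE]
  structure(df, schema = schema, class = c("trait_table", "data.frame"))
}

#' Read a species trait table from delimited text
#'
#' @inheritParams read_community
#' @param schema trait schema ([default_trait_schema()] by default)
#' @param community optional `community_matrix`; every community species must
#'   be present in the trait table.
#' @return a `trait_table`
#' @export
read_traits <- function(path, schema = default_trait_schema(),
                        community = NULL, sep = NULL) {
  df <- read_delim_table(path, sep)
  tt <- trait_table(df, schema)
  if (!is.null(community)) check_species_coverage(tt, community)
  tt
}

check_species_coverage <- function(traits, community) {
  missing <- setdiff(colnames(community), rownames(traits))
  if (length(missing))
    stop("species missing from trait table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
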