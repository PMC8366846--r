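#' @importFrom utils read.table write.table combn head
#' @importFrom stats var sd quantile pnorm pf pt rnorm runif rexp rlnorm
#'   setNames dist median lm cor coef anova manova fligner.test ave
NULL

# Auto-detect tab vs comma delimiter from the first line of a file.
detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) >=
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

read_delim_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- detect_sep(path)
  read.table(path, header = TRUE, sep = sep, row.names = 1L,
             check.names = FALSE, stringsAsFactors = FALSE, quote = "\"")
}

#' Read a community matrix from delimited text
#'
#' @param path path to a tab- or comma-separated file with a header row and
#'   identifiers in the first column.
#' @param orientation `"sites-as-rows"` (default) or `"species-as-rows"`;
#'   the result is always normalised to sites x species.
#' @param sep optional delimiter override; auto-detected among tab/comma.
#' @return a [community_matrix()]
#' @export
read_community <- function(path, orientation = c("sites-as-rows",
                                                 "species-as-rows"),
                           sep = NULL) {
  orientation <- match.arg(orientation)
  df <- read_delim_table(path, sep)
  num <- vapply(df, is.numeric, logical(1))
  if (!all(num))
    stop("non-numeric cells in column(s): ",
         paste(names(df)[!num], collapse = ", "), call. = FALSE)
  m <- as.matrix(df)
  if (orientation == "species-as-rows") m <- t(m)
  community_matrix(m)
}

#' Write a result table to delimited text
#'
#' Values are written at full double precision so that a write/read
#' round-trip reproduces them to better than 1e-12.
#'
#' @param table data.frame or matrix
#' @param path output path
#' @param sep delimiter (default tab)
#' @param row_names write row names as a leading `id` column
#' @export
write_results <- function(table, path, sep = "\t", row_names = TRUE) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, format(x, digits = 17, scientific = TRUE,
                                trim = TRUE))
  })
  if (row_names) df <- cbind(id = rownames(df), df)
  ok <- tryCatch({
    suppressWarnings(write.table(df, path, sep = sep, quote = FALSE,
                                 row.names = FALSE))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a table written by [write_results()]
#' @param path input path
#' @param sep optional delimiter override
#' @return data.frame with the `id` column restored as row names when present
#' @export
read_results <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) >= 1 && names(df)[1] == "id") {
    rn <- df[[1]]
    df <- df[, -1, drop = FALSE]
    if (!anyDuplicated(rn)) rownames(df) <- rn
  }
  df
}

#' Read site attributes (coordinates and connectivity categories)
#'
#' Expects columns `x`, `y` and optionally `order_category`,
#' `dlink_category`, `dam_category`; categories are validated against their
#' closed level sets.
#'
#' @param path delimited text file, site identifiers in the first column
#' @param community optional `community_matrix` to check the site set against
#' @param sep optional delimiter override
#' @return data.frame with one row per site
#' @export
read_site_attributes <- function(path, community = NULL, sep = NULL) {
  df <- read_delim_table(path, sep)
  if (!all(c("x", "y") %in% names(df)))
    stop("site attribute table must contain columns 'x' and 'y'",
         call. = FALSE)
  if ("dlink_category" %in% names(df)) {
    bad <- setdiff(unique(df$dlink_category), dlink_levels())
    if (length(bad))
      stop("unknown dlink_category value(s): ", paste(bad, collapse = ", "),
           "; allowed: ", paste(dlink_levels(), collapse = ", "),
           call. = FALSE)
  }
  if ("dam_category" %in% names(df)) {
    bad <- setdiff(unique(df$dam_category), dam_levels())
    if (length(bad))
      stop("unknown dam_category value(s): ", paste(bad, collapse = ", "),
           "; allowed: ", paste(dam_levels(), collapse = ", "),
           call. = FALSE)
  }
  if (!is.null(community)) {
    missing <- setdiff(rownames(community), rownames(df))
    if (length(missing))
      stop("site attribute table missing site(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    df <- df[rownames(community), , drop = FALSE]
  }
  df
}

dlink_levels <- function() c("1-2", "2-3", "3-4")
dam_levels <- function() c("Up", "Down", "Up&Down", "None")

#' Read a plain-text `key = value` configuration file
#'
#' Blank lines and lines starting with `#` are ignored. Values that parse
#' as numbers are returned numeric.
#'
#' @param path config file path
#' @return named list
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  names(out) <- keys
  out
}

log_msg <- function(..., verbose = TRUE) {
  if (verbose) message(...)
  invisible(NULL)
}
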