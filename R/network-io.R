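#' Construct a validated plant-pollinator interaction network
#'
#' A `ppnet` wraps a labeled non-negative weight matrix of pollinator visits,
#' with plants as rows and pollinators as columns. Validation drops rows and
#' columns whose interactions are all zero (never-observed taxa occur in
#' published matrices) and rejects negative weights and duplicate labels.
#'
#' @param weights Numeric matrix, rows = plants, columns = pollinators, with
#'   dimnames giving plant and pollinator identifiers. Unnamed margins get
#'   `P1..Pn` / `A1..Am` labels.
#' @param network_id Single string identifying the network.
#' @param drop_empty Drop all-zero rows/columns (with a warning) instead of
#'   erroring. Default `TRUE`.
#'
#' @return An object of class `ppnet`: the weight matrix with attributes
#'   `network_id`.
#' @export
ppnet <- function(weights, network_id = "net", drop_empty = TRUE) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    abort("`weights` must be a numeric matrix")
  }
  storage.mode(weights) <- "double"
  if (is.null(rownames(weights))) rownames(weights) <- paste0("P", seq_len(nrow(weights)))
  if (is.null(colnames(weights))) colnames(weights) <- paste0("A", seq_len(ncol(weights)))
  if (anyNA(weights)) abort("interaction matrix contains missing values")
  neg <- which(weights < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf(
      "negative weight at plant '%s' x pollinator '%s'",
      rownames(weights)[neg[1, 1]], colnames(weights)[neg[1, 2]]
    ))
  }
  if (anyDuplicated(rownames(weights))) abort("duplicate plant identifiers")
  if (anyDuplicated(colnames(weights))) abort("duplicate pollinator identifiers")

  empty_r <- rowSums(weights) == 0
  empty_c <- colSums(weights) == 0
  if (any(empty_r) || any(empty_c)) {
    if (!drop_empty) abort("network contains all-zero rows or columns")
    dropped <- c(rownames(weights)[empty_r], colnames(weights)[empty_c])
    warn(sprintf(
      "network '%s': dropped %d empty row(s)/column(s): %s",
      network_id, length(dropped), paste(dropped, collapse = ", ")
    ))
    weights <- weights[!empty_r, !empty_c, drop = FALSE]
  }
  if (length(weights) == 0 || sum(weights) <= 0) {
    abort(sprintf("network '%s' has no positive interactions", network_id))
  }
  structure(weights, network_id = as.character(network_id), class = c("ppnet", "matrix"))
}

#' @export
print.ppnet <- function(x, ...) {
  cat(sprintf(
    "<ppnet '%s'>: %d plants x %d pollinators, total weight %g, fill %.3f\n",
    network_id(x), nrow(x), ncol(x), sum(x), mean(x > 0)
  ))
  invisible(x)
}

#' @rdname ppnet
#' @param x A `ppnet`.
#' @export
network_id <- function(x) attr(x, "network_id")

# strip the ppnet class for plain matrix work
as_matrix <- function(x) {
  y <- unclass(x)
  attr(y, "network_id") <- NULL
  y
}

detect_delim <- function(path) {
  line <- readLines(path, n = 1L, encoding = "UTF-8")
  counts <- vapply(c("\t", ",", ";"), function(d) {
    lengths(regmatches(line, gregexpr(d, line, fixed = TRUE)))
  }, integer(1))
  if (all(counts == 0)) abort(sprintf("cannot detect delimiter in '%s'", path))
  names(counts)[which.max(counts)]
}

#' Read an interaction matrix from delimited text
#'
#' Expects pollinator labels as the header row and plant labels in the first
#' column. The delimiter is auto-detected among tab, comma and semicolon
#' unless given. Matrices published with plants in columns can be read with
#' `transpose = TRUE`.
#'
#' @param path File path.
#' @param delim Field delimiter; `NULL` (default) auto-detects.
#' @param transpose Transpose after reading (for plants-in-columns sources).
#' @param network_id Identifier; defaults to the file name without extension.
#' @return A validated [ppnet].
#' @export
read_network <- function(path, delim = NULL, transpose = FALSE, network_id = NULL) {
  if (is.null(delim)) delim <- detect_delim(path)
  if (is.null(network_id)) network_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path,
    header = TRUE, sep = delim, row.names = 1, check.names = FALSE,
    stringsAsFactors = FALSE, encoding = "UTF-8", comment.char = ""
  )
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad)) {
    abort(sprintf(
      "non-numeric interaction values in column(s): %s",
      paste(colnames(df)[bad], collapse = ", ")
    ))
  }
  m <- as.matrix(df)
  if (transpose) m <- t(m)
  ppnet(m, network_id = network_id)
}

#' Write an interaction matrix as delimited text
#'
#' @param network A [ppnet].
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, delim = "\t") {
  m <- as_matrix(network)
  df <- data.frame(plant = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path,
    sep = delim, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Binarize a weighted network
#'
#' Every strictly positive visit count becomes 1 (any recorded visit is an
#' interaction); zeros and labels are unchanged. Idempotent.
#'
#' @param network A [ppnet].
#' @return A binary [ppnet].
#' @export
binarize <- function(network) {
  m <- as_matrix(network)
  m[] <- as.numeric(m > 0)
  ppnet(m, network_id = network_id(network))
}

trait_levels <- list(
  ploidy = c("diploid", "polyploid", "unknown"),
  mating = c("self_compatible", "self_incompatible", "unknown"),
  restrictiveness = c("unrestrictive", "low", "moderate", "high", "unknown")
)

#' Read a plant trait table
#'
#' Columns `species`, `ploidy` (diploid/polyploid), `mating`
#' (self_compatible/self_incompatible) and `restrictiveness`
#' (unrestrictive/low/moderate/high). Blank cells and the token `unknown`
#' map to explicit `"unknown"`; any other token is an error.
#'
#' @inheritParams read_network
#' @return A tibble with one row per species and closed factor-like columns.
#' @export
read_trait_table <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- detect_delim(path)
  df <- utils::read.table(path,
    header = TRUE, sep = delim, stringsAsFactors = FALSE,
    encoding = "UTF-8", comment.char = "", quote = "\"", na.strings = NULL,
    colClasses = "character"
  )
  need <- c("species", "ploidy", "mating", "restrictiveness")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) abort(sprintf("trait table lacks column(s): %s", paste(miss, collapse = ", ")))
  df <- tibble::as_tibble(df[need])
  df$species <- normalize_species(df$species)
  if (anyDuplicated(df$species)) {
    abort(sprintf(
      "duplicate species in trait table: %s",
      paste(unique(df$species[duplicated(df$species)]), collapse = ", ")
    ))
  }
  for (col in c("ploidy", "mating", "restrictiveness")) {
    v <- trimws(df[[col]])
    v[v == "" | is.na(v)] <- "unknown"
    bad <- setdiff(unique(v), trait_levels[[col]])
    if (length(bad) > 0) {
      abort(sprintf("unrecognized %s level(s): %s", col, paste(bad, collapse = ", ")))
    }
    df[[col]] <- v
  }
  attr(df, "species_norm") <- df$species
  df
}

#' Read a per-network covariate table
#'
#' Columns `network_id`, `latitude`, `longitude` and the four bioclimatic
#' covariates `bio4` (temperature seasonality), `bio10` (mean temperature of
#' the warmest quarter), `bio15` (precipitation seasonality) and `bio18`
#' (precipitation of the warmest quarter). Missing values are allowed.
#'
#' @inheritParams read_network
#' @return A tibble, one row per network.
#' @export
read_covariates <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- detect_delim(path)
  df <- utils::read.table(path,
    header = TRUE, sep = delim, stringsAsFactors = FALSE,
    encoding = "UTF-8", comment.char = ""
  )
  need <- c("network_id", "latitude", "longitude", "bio4", "bio10", "bio15", "bio18")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) abort(sprintf("covariate table lacks column(s): %s", paste(miss, collapse = ", ")))
  df <- tibble::as_tibble(df[need])
  df$network_id <- as.character(df$network_id)
  if (anyDuplicated(df$network_id)) abort("duplicate network_id in covariate table")
  chk <- function(ok, msg) if (any(!ok, na.rm = TRUE)) abort(msg)
  chk(df$latitude >= -90 & df$latitude <= 90, "latitude outside [-90, 90]")
  chk(df$longitude >= -180 & df$longitude <= 180, "longitude outside [-180, 180]")
  chk(df$bio18 >= 0, "bio18 must be non-negative")
  df
}

# exact-match keys: trim, collapse internal whitespace, lower-case
normalize_species <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
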