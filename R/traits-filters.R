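#' Collapse the four-level floral restrictiveness scale to a binary trait
#'
#' `unrestrictive` and `low` restriction collapse to `"not_restrictive"`,
#' `moderate` and `high` to `"restrictive"`; `unknown` stays `"unknown"`.
#'
#' @param level Character vector of restrictiveness levels.
#' @return Character vector over `{"not_restrictive", "restrictive", "unknown"}`.
#' @export
bin_restrictiveness <- function(level) {
  bad <- setdiff(unique(level), trait_levels$restrictiveness)
  if (length(bad) > 0) abort(sprintf("unrecognized restrictiveness level(s): %s", paste(bad, collapse = ", ")))
  out <- rep("unknown", length(level))
  out[level %in% c("unrestrictive", "low")] <- "not_restrictive"
  out[level %in% c("moderate", "high")] <- "restrictive"
  out
}

match_traits <- function(network, traits) {
  plants <- normalize_species(rownames(as_matrix(network)))
  key <- attr(traits, "species_norm")
  if (is.null(key) || length(key) != nrow(traits)) key <- normalize_species(traits$species)
  idx <- match(plants, key)
  n_unmatched <- sum(is.na(idx))
  if (n_unmatched > 0) {
    warn(sprintf(
      "network '%s': %d plant(s) not in trait table (treated as unknown)",
      network_id(network), n_unmatched
    ))
  }
  tibble::tibble(
    species = plants,
    ploidy = ifelse(is.na(idx), "unknown", traits$ploidy[idx]),
    mating = ifelse(is.na(idx), "unknown", traits$mating[idx]),
    restrictive = bin_restrictiveness(
      ifelse(is.na(idx), "unknown", traits$restrictiveness[idx])
    )
  )
}

#' Frequency of one trait state among a network's plants
#'
#' The frequency is computed over the plants with a known state for the
#' focal trait only (`NA` when no plant has a known state): polyploids among
#' ploidy-classified plants, self-compatible among mating-classified plants,
#' restrictive-flowered among restrictiveness-classified plants.
#'
#' @param network A [ppnet].
#' @param traits Trait table as from [read_trait_table()].
#' @param trait `"ploidy"`, `"mating"` or `"restrictiveness"`.
#' @return A one-row tibble with `frequency` and `n_known`.
#' @export
trait_frequency <- function(network, traits, trait = c("ploidy", "mating", "restrictiveness")) {
  trait <- match.arg(trait)
  tf <- trait_frequencies(network, traits)
  col <- c(ploidy = "pct_pp", mating = "pct_sc", restrictiveness = "pct_restrictive")[trait]
  ncol_ <- c(
    ploidy = "n_known_ploidy", mating = "n_known_mating",
    restrictiveness = "n_known_restrictive"
  )[trait]
  tibble::tibble(frequency = tf[[col]], n_known = tf[[ncol_]])
}

#' Network-level trait frequencies
#'
#' Computes %PP (polyploids among ploidy-classified plants), %SC
#' (self-compatible among mating-classified plants) and %Restrictive
#' (restrictive-flowered among restrictiveness-classified plants, after
#' binary binning) for one network, with the per-trait counts of classified
#' plants. Frequencies are `NA` when no plant is classified.
#'
#' @inheritParams trait_frequency
#' @return A one-row tibble: `network_id`, `n_plants`, `n_pollinators`,
#'   `pct_pp`, `pct_sc`, `pct_restrictive`, `n_known_ploidy`,
#'   `n_known_mating`, `n_known_restrictive`.
#' @export
trait_frequencies <- function(network, traits) {
  tt <- match_traits(network, traits)
  freq <- function(state, known) {
    n <- sum(known)
    if (n == 0) NA_real_ else sum(state) / n
  }
  tibble::tibble(
    network_id = network_id(network),
    n_plants = nrow(network),
    n_pollinators = ncol(network),
    pct_pp = freq(tt$ploidy == "polyploid", tt$ploidy != "unknown"),
    pct_sc = freq(tt$mating == "self_compatible", tt$mating != "unknown"),
    pct_restrictive = freq(tt$restrictive == "restrictive", tt$restrictive != "unknown"),
    n_known_ploidy = sum(tt$ploidy != "unknown"),
    n_known_mating = sum(tt$mating != "unknown"),
    n_known_restrictive = sum(tt$restrictive != "unknown")
  )
}

#' Network retention filters
#'
#' Retains networks that have (1) at least `min_pollinators` pollinator
#' taxa, (2) at least `min_ploidy_known` plants with assigned ploidy,
#' (3) ploidy classifications for at least `min_ploidy_coverage` of their
#' plant species (an exact rational comparison, so one-third coverage passes
#' the default), and (4) a covariate row with complete climate data. Every
#' rejected network is reported with all of its failed criteria.
#'
#' @param networks A list of [ppnet] objects.
#' @param traits Trait table.
#' @param covariates Covariate table as from [read_covariates()].
#' @param min_pollinators,min_ploidy_known,min_ploidy_coverage Thresholds.
#' @return A list with `retained` (the surviving networks) and `report`
#'   (a tibble: `network_id`, `retained`, `reasons` with comma-separated
#'   failure codes among `min_pollinators`, `min_ploidy_n`,
#'   `min_ploidy_coverage`, `no_climate`).
#' @export
apply_filters <- function(networks, traits, covariates,
                          min_pollinators = 6L, min_ploidy_known = 6L,
                          min_ploidy_coverage = 1 / 3) {
  rows <- purrr::map(networks, function(net) {
    tf <- trait_frequencies(net, traits)
    reasons <- character()
    if (tf$n_pollinators < min_pollinators) reasons <- c(reasons, "min_pollinators")
    if (tf$n_known_ploidy < min_ploidy_known) reasons <- c(reasons, "min_ploidy_n")
    # tolerance keeps the comparison exact for rational thresholds like 1/3
    if (tf$n_known_ploidy + 1e-9 < min_ploidy_coverage * tf$n_plants) {
      reasons <- c(reasons, "min_ploidy_coverage")
    }
    cov <- covariates[covariates$network_id == tf$network_id, , drop = FALSE]
    if (nrow(cov) != 1 || anyNA(cov[, c("bio4", "bio10", "bio15", "bio18")])) {
      reasons <- c(reasons, "no_climate")
    }
    tibble::tibble(
      network_id = tf$network_id,
      retained = length(reasons) == 0,
      reasons = paste(reasons, collapse = ",")
    )
  })
  report <- dplyr::bind_rows(rows)
  list(retained = networks[report$retained], report = report)
}

#' Path-analysis availability filter
#'
#' The path model needs at least some information on the mediator traits:
#' networks where both %SC and %Restrictive are undefined are dropped.
#' Applied after [apply_filters()].
#'
#' @param freqs A tibble with `pct_sc` and `pct_restrictive` columns (e.g.
#'   bound rows of [trait_frequencies()] or an analysis record table).
#' @return The retained rows.
#' @export
path_filter <- function(freqs) {
  dplyr::filter(freqs, !(is.na(.data$pct_sc) & is.na(.data$pct_restrictive)))
}
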