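#' Configuration for the synthetic community generator
#'
#' Defines the generative model for complete synthetic studies. Pollinators
#' occupy positions uniform on a single niche axis [0, 1]; each plant has a
#' niche center on the same axis and a Gaussian niche kernel whose breadth
#' is `sigma0` for diploids and `sigma0 * kappa` for polyploids. Visit
#' counts are Poisson with mean `lambda * exp(-(u - c)^2 / (2 sigma^2))`.
#' `kappa > 1` is the broadened-polyploid-niche scenario, `kappa < 1` the
#' narrowed one, `kappa = 1` the null in which ploidy carries no niche
#' signal.
#'
#' Network sizes are log-normal within the stated ranges, centered near the
#' 15.7 plants and 44.3 pollinators typical of assembled plant-pollinator
#' cohorts. The network-level polyploid fraction follows a logit model on
#' standardized log precipitation seasonality; per-plant self-compatibility
#' and floral restrictiveness follow ploidy-dependent logits whose default
#' signs are negative (polyploid-rich communities carry fewer
#' self-compatible and fewer restrictive-flowered species). Climate enters
#' the generator only through those trait models, so structural indices are
#' climate-independent by construction and `kappa` alone controls any
#' ploidy-structure association.
#'
#' @param n_networks Number of networks per study.
#' @param plants_range,pollinators_range Inclusive integer bounds.
#' @param plants_meanlog,plants_sdlog,pollinators_meanlog,pollinators_sdlog
#'   Log-normal size parameters (before clamping to the ranges).
#' @param pp_intercept,pp_bio15_beta Logit-scale intercept and slope of the
#'   network polyploid fraction on standardized log BIO15.
#' @param kappa Polyploid/diploid niche-breadth ratio (> 0).
#' @param sigma0 Diploid niche breadth on the [0, 1] axis.
#' @param lambda Peak Poisson visit intensity.
#' @param sc_intercept,trait_logit_pp_to_sc Logit model of per-plant
#'   self-compatibility on ploidy.
#' @param restrictive_intercept,trait_logit_pp_to_restrictive Logit model of
#'   per-plant floral restrictiveness on ploidy.
#' @param miss_ploidy,miss_mating,miss_restrictive Per-trait masking rates
#'   (probability a species' trait value is unknown).
#' @param seed Study seed; every network derives its own child seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_networks = 300L,
                         plants_range = c(6L, 100L),
                         pollinators_range = c(6L, 200L),
                         plants_meanlog = log(14), plants_sdlog = 0.35,
                         pollinators_meanlog = log(38), pollinators_sdlog = 0.45,
                         pp_intercept = qlogis(0.35), pp_bio15_beta = 0.5,
                         kappa = 1, sigma0 = 0.1, lambda = 8,
                         sc_intercept = 0, trait_logit_pp_to_sc = -0.9,
                         restrictive_intercept = 0, trait_logit_pp_to_restrictive = -1.6,
                         miss_ploidy = 0.3, miss_mating = 0.8, miss_restrictive = 0.3,
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$kappa > 0, cfg$sigma0 > 0, cfg$lambda > 0,
    all(unlist(cfg[c("miss_ploidy", "miss_mating", "miss_restrictive")]) >= 0),
    all(unlist(cfg[c("miss_ploidy", "miss_mating", "miss_restrictive")]) <= 1),
    diff(plants_range) >= 0, diff(pollinators_range) >= 0
  )
  structure(cfg, class = "synth_config")
}

draw_size <- function(meanlog, sdlog, range) {
  min(max(round(exp(rnorm(1, meanlog, sdlog))), range[1]), range[2])
}

#' Generate one synthetic interaction network
#'
#' Draws a plant-pollinator network under the niche model of
#' [synth_config()], redrawing (up to a capped retry count) until the
#' validated network keeps at least six plants and six pollinators.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; fixed seed gives a byte-identical network.
#' @param p_pp Network-level probability that a plant is polyploid
#'   (defaults to the config's logit intercept).
#' @param network_id Identifier for the generated network.
#' @return A list: `network` (a [ppnet]) and `ploidy`, a tibble with
#'   `species`, `ploidy` (true, unmasked) and realized niche breadth
#'   `sigma`.
#' @export
generate_network <- function(config, seed = 1L, p_pp = plogis(config$pp_intercept),
                             network_id = "synth") {
  with_seed_(seed, {
    for (try in 1:60) {
      n_p <- draw_size(config$plants_meanlog, config$plants_sdlog, config$plants_range)
      n_a <- draw_size(config$pollinators_meanlog, config$pollinators_sdlog, config$pollinators_range)
      ploidy <- rbinom(n_p, 1, p_pp)
      centers <- runif(n_p)
      u <- runif(n_a)
      sigma <- config$sigma0 * config$kappa^ploidy
      mu <- config$lambda * exp(-outer(centers, u, function(c_, u_) (u_ - c_)^2) / (2 * sigma^2))
      w <- matrix(rpois(n_p * n_a, mu), n_p, n_a)
      species <- paste0(network_id, "_p", seq_len(n_p))
      dimnames(w) <- list(species, paste0(network_id, "_a", seq_len(n_a)))
      keep_r <- rowSums(w) > 0
      keep_c <- colSums(w) > 0
      if (sum(keep_r) < 6 || sum(keep_c) < 6) next
      net <- suppressWarnings(ppnet(w, network_id = network_id))
      return(list(
        network = net,
        ploidy = tibble::tibble(
          species = species[keep_r],
          ploidy = ifelse(ploidy[keep_r] == 1, "polyploid", "diploid"),
          sigma = sigma[keep_r]
        )
      ))
    }
    abort(sprintf(
      "could not generate a network passing size validation in 60 tries (kappa=%g, sigma0=%g, lambda=%g)",
      config$kappa, config$sigma0, config$lambda
    ))
  })
}

#' Generate a complete synthetic study
#'
#' Produces networks, a masked plant trait table, a covariate table and the
#' ground truth needed for recovery tests. Per network: BIO15 is drawn
#' log-normal and standardized on the log scale across the study; the
#' polyploid fraction follows the config's logit model on that score; the
#' network is drawn with [generate_network()]; per-plant mating system and
#' restrictiveness are drawn with ploidy-dependent logits; each trait value
#' is masked to unknown at the config's missingness rate. Networks are
#' redrawn until they pass the cohort retention filters
#' ([apply_filters()]), so every generated study passes them by
#' construction.
#'
#' @param config A [synth_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A list: `networks` (list of [ppnet]), `traits` (masked trait
#'   table across all species), `covariates`, `ground_truth` (per-network
#'   true polyploid fraction before masking, realized kappa, mean niche
#'   breadths) and `config`.
#' @export
generate_study <- function(config = synth_config(), seed = config$seed) {
  n <- config$n_networks
  seeds <- child_seeds(seed, 2L * n + 1L)
  covs <- with_seed_(seeds[2L * n + 1L], {
    tibble::tibble(
      network_id = sprintf("synth%03d", seq_len(n)),
      latitude = runif(n, -60, 70),
      longitude = runif(n, -180, 180),
      bio4 = exp(rnorm(n, log(600), 0.5)),
      bio10 = rnorm(n, 18, 6),
      bio15 = exp(rnorm(n, log(40), 0.5)),
      bio18 = exp(rnorm(n, log(150), 0.8))
    )
  })
  z_bio15 <- as.numeric(scale(log(covs$bio15 + 1)))
  p_pp <- plogis(config$pp_intercept + config$pp_bio15_beta * z_bio15)

  networks <- vector("list", n)
  traits <- vector("list", n)
  truth <- vector("list", n)
  for (k in seq_len(n)) {
    ok <- FALSE
    for (try in 1:60) {
      gen <- generate_network(config, seed = seeds[k] + 7919L * (try - 1L),
                              p_pp = p_pp[k], network_id = covs$network_id[k])
      tt <- with_seed_(seeds[n + k] + 7919L * (try - 1L), {
        is_pp <- gen$ploidy$ploidy == "polyploid"
        sc <- rbinom(nrow(gen$ploidy), 1, plogis(config$sc_intercept +
          config$trait_logit_pp_to_sc * is_pp))
        restr <- rbinom(nrow(gen$ploidy), 1, plogis(config$restrictive_intercept +
          config$trait_logit_pp_to_restrictive * is_pp))
        lvl <- ifelse(restr == 1,
          sample(c("moderate", "high"), nrow(gen$ploidy), replace = TRUE),
          sample(c("unrestrictive", "low"), nrow(gen$ploidy), replace = TRUE)
        )
        tibble::tibble(
          species = gen$ploidy$species,
          ploidy = ifelse(runif(length(sc)) < config$miss_ploidy, "unknown", gen$ploidy$ploidy),
          mating = ifelse(runif(length(sc)) < config$miss_mating, "unknown",
            ifelse(sc == 1, "self_compatible", "self_incompatible")
          ),
          restrictiveness = ifelse(runif(length(sc)) < config$miss_restrictive, "unknown", lvl)
        )
      })
      n_known <- sum(tt$ploidy != "unknown")
      n_plants <- nrow(gen$network)
      if (n_known >= 6 && n_known + 1e-9 >= n_plants / 3) {
        networks[[k]] <- gen$network
        traits[[k]] <- tt
        truth[[k]] <- tibble::tibble(
          network_id = covs$network_id[k],
          true_pct_pp = mean(gen$ploidy$ploidy == "polyploid"),
          kappa = config$kappa,
          mean_sigma_diploid = mean(gen$ploidy$sigma[gen$ploidy$ploidy == "diploid"]),
          mean_sigma_polyploid = mean(gen$ploidy$sigma[gen$ploidy$ploidy == "polyploid"])
        )
        ok <- TRUE
        break
      }
    }
    if (!ok) abort(sprintf("network %d failed retention filters in 60 tries", k))
  }
  trait_tbl <- dplyr::bind_rows(traits)
  attr(trait_tbl, "species_norm") <- normalize_species(trait_tbl$species)
  list(
    networks = networks,
    traits = trait_tbl,
    covariates = covs,
    ground_truth = dplyr::bind_rows(truth),
    config = config
  )
}
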