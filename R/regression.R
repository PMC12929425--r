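#' Assemble the per-network analysis table
#'
#' Joins delta-standardized indices, trait frequencies and climate
#' covariates into one row per network, adding the transforms used
#' downstream: natural-log precipitation variables (`log(x + 1)`, since
#' summer precipitation can be 0) and the natural log of network size
#' (plants + pollinators).
#'
#' @param indices Bound rows of [delta_indices()].
#' @param freqs Bound rows of [trait_frequencies()].
#' @param covariates Covariate table as from [read_covariates()].
#' @return A tibble with one row per network: identifiers, sizes, raw and
#'   delta indices, `pct_pp`/`pct_sc`/`pct_restrictive`, `bio4`, `bio10`,
#'   `log_bio15`, `log_bio18`, `log_network_size`, `latitude`, `longitude`.
#' @export
build_records <- function(indices, freqs, covariates) {
  out <- indices |>
    dplyr::inner_join(
      dplyr::select(freqs, -dplyr::any_of(c("n_plants", "n_pollinators"))),
      by = "network_id"
    ) |>
    dplyr::inner_join(covariates, by = "network_id") |>
    dplyr::mutate(
      log_bio15 = log(.data$bio15 + 1),
      log_bio18 = log(.data$bio18 + 1),
      log_network_size = log(.data$n_plants + .data$n_pollinators)
    )
  tibble::as_tibble(out)
}

#' Univariate regression of one index on one predictor
#'
#' Ordinary least squares on the records where both fields are defined
#' (sample size therefore varies across predictors). Reports the Pearson
#' correlation `r`, the regression t statistic (identically
#' `r * sqrt(n - 2) / sqrt(1 - r^2)`), its two-sided p-value on n - 2
#' degrees of freedom, and the fitted slope and intercept.
#'
#' @param records Analysis table from [build_records()].
#' @param predictor,response Column names.
#' @return A one-row tibble: `predictor`, `response`, `n`, `r`, `t_stat`,
#'   `p`, `slope`, `intercept`.
#' @export
univariate_fit <- function(records, predictor, response) {
  d <- records[stats::complete.cases(records[, c(predictor, response)]), c(predictor, response)]
  n <- nrow(d)
  if (n < 3) abort(sprintf("fewer than 3 complete records for %s ~ %s", response, predictor))
  x <- d[[predictor]]
  y <- d[[response]]
  if (sd(x) == 0 || sd(y) == 0) {
    abort(sprintf("zero variance in %s ~ %s", response, predictor))
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  tibble::tibble(
    predictor = predictor, response = response, n = n,
    r = stats::cor(x, y),
    t_stat = sm$coefficients["x", "t value"],
    p = sm$coefficients["x", "Pr(>|t|)"],
    slope = coef(fit)[["x"]],
    intercept = coef(fit)[["(Intercept)"]]
  )
}

default_predictors <- c(
  "pct_pp", "pct_sc", "pct_restrictive",
  "bio4", "bio10", "log_bio15", "log_bio18", "log_network_size"
)
default_responses <- c(
  "delta_connectance", "delta_nestedness",
  "delta_modularity", "delta_robustness"
)

#' All univariate predictor-by-index regressions
#'
#' One [univariate_fit()] per predictor and delta index; the t statistic is
#' reported both as `t_stat` and under the conventional standardized-effect
#' label `beta` used in summary tables of this analysis.
#'
#' @param records Analysis table from [build_records()].
#' @param predictors,responses Column names to cross.
#' @return A tibble of fits, one row per (predictor, response).
#' @export
univariate_table <- function(records, predictors = default_predictors,
                             responses = default_responses) {
  grid <- tidyr::expand_grid(predictor = predictors, response = responses)
  out <- purrr::pmap(grid, function(predictor, response) {
    univariate_fit(records, predictor, response)
  })
  dplyr::bind_rows(out) |> dplyr::mutate(beta = .data$t_stat)
}

#' Moran's I test for residual spatial autocorrelation
#'
#' Moran's I with inverse great-circle-distance weights (row-standardized),
#' expectation -1/(n - 1) and a two-sided normal-approximation p-value.
#' Coincident points are given the weight of the smallest positive distance.
#'
#' @param residuals Numeric vector of model residuals.
#' @param latitude,longitude Coordinates in degrees, aligned with
#'   `residuals`.
#' @return A one-row tibble: `observed`, `expected`, `sd`, `p`.
#' @export
morans_i <- function(residuals, latitude, longitude) {
  n <- length(residuals)
  stopifnot(length(latitude) == n, length(longitude) == n)
  if (n < 4) abort("Moran's I needs at least 4 points")
  if (sd(residuals) == 0) abort("residuals have zero variance")
  pts <- cbind(longitude, latitude)
  d <- geosphere::distm(pts)
  pos <- d[d > 0]
  if (length(pos) == 0) abort("all points at an identical location")
  d[d == 0] <- min(pos)
  w <- 1 / d
  diag(w) <- 0
  w <- w / rowSums(w)
  res <- ape::Moran.I(residuals, w, scaled = FALSE, alternative = "two.sided")
  tibble::tibble(
    observed = res$observed, expected = res$expected,
    sd = res$sd, p = res$p.value
  )
}
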