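#' Run the full community analysis end-to-end
#'
#' Orchestrates: retention filters, delta-standardized structural indices
#' per network, trait frequencies, the per-network record table, the full
#' univariate regression table, the path-analysis filter, and the piecewise
#' path model with effect decomposition for each requested index. All
#' stochastic stages derive their seeds from the single run seed, so a
#' fixed seed reproduces the full bundle exactly.
#'
#' @param networks List of [ppnet] objects.
#' @param traits Plant trait table.
#' @param covariates Per-network covariate table.
#' @param n_null Null replicates per index.
#' @param n_orders Random removal orders for robustness.
#' @param restarts Modularity optimizer restarts.
#' @param seed Run seed.
#' @param null_variant Null scheme, see [null_matrix()].
#' @param sem_indices Indices to path-model (default all four).
#' @param sem_variant Path-model variant, see [sem_model()].
#' @param moran Also test each univariate fit's residuals for spatial
#'   autocorrelation (adds `moran_i`, `moran_p` to the regression table).
#' @param out_dir Optional directory; when given, every stage table is
#'   written there as TSV (`filter_report.tsv`, `indices.tsv`,
#'   `records.tsv`, `univariate.tsv`, `sem_coefficients.tsv`,
#'   `sem_summary.tsv`, `effects.tsv`) together with `run_info.tsv`
#'   recording seeds and settings.
#' @return A list: `filter_report`, `indices`, `records`, `univariate`,
#'   `sem` (list of [fit_sem()] objects by index), `sem_summary`,
#'   `effects`.
#' @export
run_study <- function(networks, traits, covariates,
                      n_null = 100L, n_orders = 100L, restarts = 10L, seed = 1L,
                      null_variant = "r2dtable",
                      sem_indices = c("connectance", "nestedness", "modularity", "robustness"),
                      sem_variant = "base", moran = FALSE, out_dir = NULL) {
  filt <- apply_filters(networks, traits, covariates)
  nets <- filt$retained
  if (length(nets) == 0) abort("no networks survive the retention filters")
  seeds <- child_seeds(seed, length(nets))

  indices <- dplyr::bind_rows(purrr::map2(nets, seeds, function(net, s) {
    delta_indices(net,
      n_null = n_null, seed = s, variant = null_variant,
      restarts = restarts, n_orders = n_orders
    )
  }))
  freqs <- dplyr::bind_rows(purrr::map(nets, trait_frequencies, traits = traits))
  records <- build_records(indices, freqs, covariates)

  univariate <- univariate_table(records)
  if (moran) {
    univariate <- dplyr::bind_cols(univariate, purrr::pmap_dfr(
      univariate[, c("predictor", "response")],
      function(predictor, response) {
        d <- records[stats::complete.cases(records[, c(predictor, response)]), ]
        resid <- stats::residuals(lm(d[[response]] ~ d[[predictor]]))
        mi <- morans_i(resid, d$latitude, d$longitude)
        tibble::tibble(moran_i = mi$observed, moran_p = mi$p)
      }
    ))
  }

  path_records <- path_filter(records)
  sems <- lapply(sem_indices, function(ix) {
    fit_sem(path_records, index = ix, variant = sem_variant)
  })
  names(sems) <- sem_indices
  sem_summary <- dplyr::bind_rows(lapply(sems, glance))
  effects <- dplyr::bind_rows(lapply(sem_indices, function(ix) {
    dplyr::mutate(decompose_effects(sems[[ix]]), index = ix, .before = 1)
  }))

  bundle <- list(
    filter_report = filt$report, indices = indices, records = records,
    univariate = univariate, sem = sems, sem_summary = sem_summary,
    effects = effects
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, f) readr::write_tsv(x, file.path(out_dir, f))
    wr(bundle$filter_report, "filter_report.tsv")
    wr(bundle$indices, "indices.tsv")
    wr(bundle$records, "records.tsv")
    wr(bundle$univariate, "univariate.tsv")
    wr(dplyr::bind_rows(lapply(sems, tidy)), "sem_coefficients.tsv")
    wr(bundle$sem_summary, "sem_summary.tsv")
    wr(bundle$effects, "effects.tsv")
    wr(tibble::tibble(
      seed = seed, n_null = n_null, n_orders = n_orders, restarts = restarts,
      null_variant = null_variant, sem_variant = sem_variant,
      n_networks_in = length(networks), n_networks_retained = length(nets)
    ), "run_info.tsv")
  }
  bundle
}

#' Scatter plots of delta indices against a predictor
#'
#' One panel per delta index with the univariate least-squares line, in the
#' style of a frequency-vs-structure summary figure.
#'
#' @param records Analysis table from [build_records()].
#' @param predictor Predictor column (default polyploid frequency).
#' @return A ggplot object.
#' @export
plot_associations <- function(records, predictor = "pct_pp") {
  long <- tidyr::pivot_longer(
    records,
    cols = dplyr::all_of(intersect(default_responses, names(records))),
    names_to = "index", values_to = "delta"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data[[predictor]], .data$delta)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, color = "steelblue") +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = predictor, y = "delta index") +
    ggplot2::theme_minimal()
}

#' Bar chart of the path-effect decomposition
#'
#' @param effects Effects table from [run_study()] or bound rows of
#'   [decompose_effects()] with an `index` column.
#' @return A ggplot object.
#' @export
plot_effects <- function(effects) {
  ggplot2::ggplot(
    effects,
    ggplot2::aes(.data$value, .data$effect, fill = .data$effect == "total")
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    { if ("index" %in% names(effects)) ggplot2::facet_wrap(~index) } +
    ggplot2::labs(x = "standardized effect of %PP", y = NULL) +
    ggplot2::theme_minimal()
}
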