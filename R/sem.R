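#' Specify the piecewise path model
#'
#' The directed acyclic path model linking precipitation seasonality
#' (log BIO15), polyploid frequency (%PP), the two mediator traits (%SC,
#' %Restrictive), log network size, and one focal delta-standardized
#' network index:
#' \preformatted{
#'   pct_pp          ~ log_bio15
#'   pct_sc          ~ pct_pp + log_bio15
#'   pct_restrictive ~ pct_pp + log_bio15
#'   log_network_size~ log_bio15
#'   delta_<index>   ~ pct_pp + pct_sc + pct_restrictive + log_bio15 +
#'                     log_network_size
#' }
#' Variants swap or augment the environmental variable (`bio10`, `both`) or
#' drop a mediator (`no_rs`, `no_sc`).
#'
#' @param index Focal network index (`"connectance"`, `"nestedness"`,
#'   `"modularity"` or `"robustness"`); its delta column is the terminal
#'   response.
#' @param variant Model variant.
#' @return An object of class `sem_model`: topologically ordered `vars` and
#'   a `parents` list defining the DAG.
#' @export
sem_model <- function(index = c("nestedness", "connectance", "modularity", "robustness"),
                      variant = c("base", "bio10", "both", "no_rs", "no_sc")) {
  index <- match.arg(index)
  variant <- match.arg(variant)
  env <- switch(variant, bio10 = "bio10", both = c("log_bio15", "bio10"), "log_bio15")
  y <- paste0("delta_", index)
  mediators <- c("pct_sc", "pct_restrictive")
  if (variant == "no_sc") mediators <- "pct_restrictive"
  if (variant == "no_rs") mediators <- "pct_sc"
  parents <- c(
    setNames(rep(list(character()), length(env)), env),
    list(pct_pp = env),
    setNames(lapply(mediators, function(m) c("pct_pp", env)), mediators),
    list(log_network_size = env),
    setNames(list(c("pct_pp", mediators, env, "log_network_size")), y)
  )
  structure(
    list(vars = names(parents), parents = parents, index = index, variant = variant, response = y),
    class = "sem_model"
  )
}

#' d-separation basis set of a path model
#'
#' One independence claim per unordered pair of non-adjacent variables
#' (pairs of exogenous variables are exempt: their correlation is not
#' constrained by the model). Each claim conditions on the union of the
#' pair's parents and is tested with the later variable in topological
#' order as the response.
#'
#' @param model A [sem_model()].
#' @return A tibble: `response`, `term`, `conditioning` (comma-separated).
#' @export
dsep_basis <- function(model) {
  vars <- model$vars
  adj <- function(a, b) {
    (a %in% model$parents[[b]]) || (b %in% model$parents[[a]])
  }
  claims <- list()
  for (i in seq_along(vars)) {
    for (j in seq_along(vars)) {
      if (i >= j) next
      a <- vars[i]
      b <- vars[j]
      if (adj(a, b)) next
      if (length(model$parents[[a]]) == 0 && length(model$parents[[b]]) == 0) next
      cond <- setdiff(union(model$parents[[a]], model$parents[[b]]), c(a, b))
      claims[[length(claims) + 1]] <- tibble::tibble(
        response = b, term = a, conditioning = paste(cond, collapse = ",")
      )
    }
  }
  dplyr::bind_rows(claims)
}

#' Fit the piecewise path model
#'
#' Each structural equation is estimated by ordinary least squares on its
#' own complete cases (the trait mediators have unequal coverage across
#' networks, so per-equation complete-case estimation retains far more of
#' the cohort than a global complete-case fit; the latter is available via
#' `complete_cases = TRUE`). Standardized coefficients are
#' `b * sd(x) / sd(y)` over the equation's cases. Model adequacy is tested
#' by Fisher's C over the d-separation basis set:
#' \eqn{C = -2 \sum_k \ln p_k \sim \chi^2_{2k}}.
#'
#' @param records Analysis table from [build_records()], already passed
#'   through [path_filter()].
#' @param index,variant Passed to [sem_model()].
#' @param complete_cases Restrict every equation to the records complete
#'   for all model variables.
#' @return An object of class `psem_fit` with `coefficients` (tidy tibble),
#'   `r2`, `claims`, `fisher_c`, `df`, `adequacy_p`, `n`, `model`.
#' @export
fit_sem <- function(records, index = "nestedness", variant = "base",
                    complete_cases = FALSE) {
  model <- sem_model(index, variant)
  if (!all(model$vars %in% names(records))) {
    abort(sprintf(
      "records lack model variable(s): %s",
      paste(setdiff(model$vars, names(records)), collapse = ", ")
    ))
  }
  data <- records[, model$vars]
  if (complete_cases) data <- data[stats::complete.cases(data), ]

  fit_eq <- function(response, terms, data) {
    d <- data[stats::complete.cases(data[, c(response, terms)]), c(response, terms)]
    if (nrow(d) < 3) abort(sprintf("fewer than 3 complete cases for equation %s", response))
    if (sd(d[[response]]) == 0) abort(sprintf("zero-variance response in equation %s", response))
    f <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
    fit <- lm(f, data = d)
    sm <- summary(fit)
    ct <- sm$coefficients
    sd_x <- vapply(terms, function(t) sd(d[[t]]), numeric(1))
    sd_y <- sd(d[[response]])
    tibble::tibble(
      response = rep(response, length(terms)),
      term = terms,
      estimate = unname(ct[terms, "Estimate"]),
      std_estimate = unname(ct[terms, "Estimate"] * sd_x / sd_y),
      t_stat = unname(ct[terms, "t value"]),
      p = unname(ct[terms, "Pr(>|t|)"]),
      n = nrow(d),
      r2 = sm$r.squared
    )
  }

  endo <- model$vars[lengths(model$parents[model$vars]) > 0]
  coefs <- dplyr::bind_rows(lapply(endo, function(v) fit_eq(v, model$parents[[v]], data)))
  r2 <- dplyr::distinct(coefs[, c("response", "n", "r2")])

  claims <- dsep_basis(model)
  if (nrow(claims) > 0) {
    claims$p <- purrr::pmap_dbl(claims, function(response, term, conditioning) {
      cond <- strsplit(conditioning, ",")[[1]]
      cond <- cond[nzchar(cond)]
      terms <- c(term, cond)
      d <- data[stats::complete.cases(data[, c(response, terms)]), c(response, terms)]
      f <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
      summary(lm(f, data = d))$coefficients[term, "Pr(>|t|)"]
    })
    fisher_c <- -2 * sum(log(claims$p))
    df <- 2L * nrow(claims)
    adequacy_p <- pchisq(fisher_c, df, lower.tail = FALSE)
  } else {
    fisher_c <- 0
    df <- 0L
    adequacy_p <- 1
  }

  structure(
    list(
      coefficients = coefs, r2 = r2, claims = claims,
      fisher_c = fisher_c, df = df, adequacy_p = adequacy_p,
      n = nrow(data), model = model
    ),
    class = "psem_fit"
  )
}

#' @export
print.psem_fit <- function(x, ...) {
  cat(sprintf(
    "Piecewise path model for delta %s (variant '%s'), n = %d\n",
    x$model$index, x$model$variant, x$n
  ))
  cat(sprintf(
    "Fisher's C = %.3f on %d df, adequacy p = %.3f\n",
    x$fisher_c, x$df, x$adequacy_p
  ))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' @rdname fit_sem
#' @param x A `psem_fit`.
#' @param ... Unused.
#' @export
tidy.psem_fit <- function(x, ...) x$coefficients

#' @rdname fit_sem
#' @export
glance.psem_fit <- function(x, ...) {
  tibble::tibble(
    fisher_c = x$fisher_c, df = x$df, adequacy_p = x$adequacy_p,
    n = x$n, n_claims = if (is.null(x$claims)) 0L else nrow(x$claims),
    index = x$model$index, variant = x$model$variant
  )
}

# all directed paths from `source` to `target` in the model DAG
enumerate_paths <- function(parents, source, target) {
  children <- function(v) names(parents)[vapply(parents, function(p) v %in% p, logical(1))]
  paths <- list()
  walk <- function(v, path) {
    if (v == target) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (ch in children(v)) walk(ch, c(path, ch))
  }
  walk(source, source)
  paths
}

#' Decompose the effect of polyploid frequency on a network index
#'
#' Enumerates every directed path from `source` to the terminal response in
#' the fitted DAG. The direct effect is the standardized coefficient of the
#' single-edge path; each multi-edge path contributes the product of the
#' standardized coefficients along its edges; the total effect is the sum
#' of all path contributions.
#'
#' @param fit A [fit_sem()] result, or a named vector of standardized edge
#'   coefficients `"from->to"` together with `model`.
#' @param source Source variable (default polyploid frequency).
#' @param model Required when `fit` is a coefficient vector.
#' @return A tibble: `effect` (`direct`, `indirect via ...`, `total`) and
#'   `value`; `total` is exactly the sum of the other rows.
#' @export
decompose_effects <- function(fit, source = "pct_pp", model = NULL) {
  if (inherits(fit, "psem_fit")) {
    model <- fit$model
    edges <- setNames(
      fit$coefficients$std_estimate,
      paste0(fit$coefficients$term, "->", fit$coefficients$response)
    )
  } else {
    if (is.null(model)) abort("`model` is required when `fit` is a coefficient vector")
    edges <- fit
  }
  target <- model$response
  paths <- enumerate_paths(model$parents, source, target)
  if (length(paths) == 0) {
    return(tibble::tibble(effect = c("direct", "total"), value = c(0, 0)))
  }
  rows <- purrr::map(paths, function(p) {
    edge_names <- paste0(p[-length(p)], "->", p[-1])
    miss <- setdiff(edge_names, names(edges))
    if (length(miss) > 0) abort(sprintf("missing edge coefficient(s): %s", paste(miss, collapse = ", ")))
    value <- prod(edges[edge_names])
    label <- if (length(p) == 2) {
      "direct"
    } else {
      paste("indirect via", paste(p[-c(1, length(p))], collapse = " -> "))
    }
    tibble::tibble(effect = label, value = value)
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$effect != "direct"), ]
  dplyr::bind_rows(out, tibble::tibble(effect = "total", value = sum(out$value)))
}

#' Simulate records from the path model
#'
#' Draws standardized (unit-variance, zero-mean) Gaussian data that follow
#' the path model exactly: each variable is a linear combination of its
#' parents with the requested standardized coefficients plus independent
#' Gaussian noise scaled so every variable has unit variance. Used for
#' calibration of the adequacy test and for parameter-recovery experiments.
#'
#' @param n Number of records.
#' @param coefs Named numeric vector of standardized edge coefficients
#'   `"from->to"`. Edges of the model not named default to 0.
#' @param index,variant Passed to [sem_model()].
#' @param seed Integer seed.
#' @return A tibble with the model's variables as columns.
#' @export
simulate_sem_records <- function(n, coefs = sem_default_coefs("nestedness"),
                                 index = "nestedness", variant = "base", seed = 1L) {
  model <- sem_model(index, variant)
  vars <- model$vars
  with_seed_(seed, {
    data <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))
    sigma <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
    for (v in vars) {
      pars <- model$parents[[v]]
      if (length(pars) == 0) {
        data[, v] <- rnorm(n)
        sigma[v, v] <- 1
        next
      }
      b <- vapply(pars, function(p) {
        nm <- paste0(p, "->", v)
        if (nm %in% names(coefs)) coefs[[nm]] else 0
      }, numeric(1))
      lin <- data[, pars, drop = FALSE] %*% b
      var_lin <- as.numeric(t(b) %*% sigma[pars, pars, drop = FALSE] %*% b)
      if (var_lin >= 1) abort(sprintf("implied variance of %s exceeds 1; shrink coefficients", v))
      data[, v] <- lin + rnorm(n, sd = sqrt(1 - var_lin))
      for (u in vars[seq_len(match(v, vars) - 1)]) {
        sigma[v, u] <- sigma[u, v] <- sum(b * sigma[pars, u])
      }
      sigma[v, v] <- 1
    }
    tibble::as_tibble(as.data.frame(data))
  })
}

#' Default standardized coefficients for path-model simulations
#'
#' Edge settings used by the simulation and recovery experiments. The
#' ploidy-related edges are set to the magnitudes this analysis is designed
#' to detect (polyploid frequency depressing both mediator traits, a
#' moderate direct effect on the index); the remaining edges are plausible
#' moderate values.
#'
#' @param index Focal index naming the terminal response column.
#' @return Named numeric vector of `"from->to"` standardized coefficients.
#' @export
sem_default_coefs <- function(index = "nestedness") {
  y <- paste0("delta_", index)
  setNames(
    c(0.25, -0.20, -0.375, -0.10, 0.10, 0.20, 0.206, -0.14, 0.12, -0.15, 0.15),
    c(
      "log_bio15->pct_pp",
      "pct_pp->pct_sc",
      "pct_pp->pct_restrictive",
      "log_bio15->pct_sc",
      "log_bio15->pct_restrictive",
      "log_bio15->log_network_size",
      paste0("pct_pp->", y),
      paste0("pct_sc->", y),
      paste0("pct_restrictive->", y),
      paste0("log_bio15->", y),
      paste0("log_network_size->", y)
    )
  )
}
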