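test_that("the basis set lists the four missing-edge claims", {
  basis <- dsep_basis(sem_model("nestedness"))
  expect_equal(nrow(basis), 4L)
  # none of the claims involves the terminal index (its equation is saturated)
  expect_false(any(grepl("delta_", c(basis$response, basis$term))))
  claimed <- paste(basis$term, basis$response)
  expect_setequal(claimed, c(
    "pct_sc pct_restrictive", "pct_pp log_network_size",
    "pct_sc log_network_size", "pct_restrictive log_network_size"
  ))
  # a saturated DAG has an empty basis set
  sat <- structure(list(
    vars = c("a", "b", "c"),
    parents = list(a = character(), b = "a", c = c("a", "b")),
    index = "nestedness", variant = "base", response = "c"
  ), class = "sem_model")
  expect_equal(nrow(dsep_basis(sat)), 0L)
})

test_that("Fisher's C is shared across index models fitted on the same records", {
  rec <- simulate_sem_records(400, seed = 2)
  rec$delta_modularity <- -0.5 * rec$delta_nestedness + rnorm(400, sd = 0.5)
  f1 <- fit_sem(rec, "nestedness")
  f2 <- fit_sem(rec, "modularity")
  expect_equal(f1$fisher_c, f2$fisher_c)
  expect_equal(f1$df, 8L)
  expect_equal(f1$fisher_c, -2 * sum(log(f1$claims$p)))
  expect_equal(f1$adequacy_p, pchisq(f1$fisher_c, 8, lower.tail = FALSE))
})

test_that("standardized univariate coefficients equal Pearson correlations", {
  rec <- simulate_sem_records(800, seed = 5)
  fit <- fit_sem(rec, "nestedness")
  td <- tidy(fit)
  est <- td$std_estimate[td$response == "log_network_size" & td$term == "log_bio15"]
  expect_equal(est, cor(rec$log_bio15, rec$log_network_size), tolerance = 1e-9)
})

test_that("simulated records recover the generator coefficients", {
  co <- sem_default_coefs("nestedness")
  rec <- simulate_sem_records(5000, co, seed = 11)
  # unit variances by construction
  expect_true(all(abs(vapply(rec, sd, numeric(1)) - 1) < 0.05))
  td <- tidy(fit_sem(rec, "nestedness"))
  for (edge in c("pct_pp->pct_sc", "pct_pp->pct_restrictive", "pct_pp->delta_nestedness")) {
    parts <- strsplit(edge, "->")[[1]]
    est <- td$std_estimate[td$term == parts[1] & td$response == parts[2]]
    expect_lt(abs(est - co[[edge]]), 0.03)
  }
})

test_that("per-equation complete cases keep unequal trait coverage usable", {
  rec <- simulate_sem_records(300, seed = 7)
  rec$pct_sc[1:200] <- NA
  fit <- fit_sem(rec, "nestedness")
  td <- tidy(fit)
  expect_equal(unique(td$n[td$response == "pct_sc"]), 100L)
  expect_equal(unique(td$n[td$response == "pct_restrictive"]), 300L)
  full <- fit_sem(rec, "nestedness", complete_cases = TRUE)
  expect_true(all(tidy(full)$n == 100L))
})

test_that("effect decomposition enumerates every directed path", {
  co <- sem_default_coefs("nestedness")
  fit <- fit_sem(simulate_sem_records(2000, co, seed = 3), "nestedness")
  eff <- decompose_effects(fit)
  total <- eff$value[eff$effect == "total"]
  expect_equal(total, sum(eff$value[eff$effect != "total"]))
  # matches the dynamic-programming oracle on the fitted coefficients
  edges <- setNames(
    fit$coefficients$std_estimate,
    paste0(fit$coefficients$term, "->", fit$coefficients$response)
  )
  expect_equal(
    total,
    total_effect_oracle(fit$model$parents, edges, "pct_pp", "delta_nestedness"),
    tolerance = 1e-12
  )

  # random DAGs: path enumeration equals the DP oracle
  set.seed(41)
  for (i in 1:25) {
    nv <- sample(4:8, 1)
    vars <- paste0("v", seq_len(nv))
    parents <- setNames(vector("list", nv), vars)
    for (k in seq_len(nv)) {
      parents[[k]] <- if (k == 1) character() else sample(vars[seq_len(k - 1)], sample(0:(k - 1), 1))
    }
    coefs <- c()
    for (v in vars) {
      for (p in parents[[v]]) coefs[paste0(p, "->", v)] <- rnorm(1)
    }
    model <- structure(list(
      vars = vars, parents = parents,
      index = "x", variant = "base", response = vars[nv]
    ), class = "sem_model")
    got <- decompose_effects(coefs, source = vars[1], model = model)
    want <- total_effect_oracle(parents, coefs, vars[1], vars[nv])
    expect_equal(got$value[got$effect == "total"], want, tolerance = 1e-10)
  }

  # removing the mediators leaves total = direct
  co2 <- co
  fit2 <- fit_sem(simulate_sem_records(500, co2, seed = 9, variant = "no_sc"),
    "nestedness",
    variant = "no_sc"
  )
  eff2 <- decompose_effects(fit2)
  expect_false(any(grepl("pct_sc", eff2$effect)))
})

test_that("model variants rewire the environmental and mediator structure", {
  m10 <- sem_model("robustness", "bio10")
  expect_true("bio10" %in% m10$vars)
  expect_false("log_bio15" %in% m10$vars)
  mboth <- sem_model("robustness", "both")
  expect_true(all(c("bio10", "log_bio15") %in% mboth$vars))
  expect_error(fit_sem(tibble::tibble(x = 1), "nestedness"), "lack")
})
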