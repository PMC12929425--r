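test_that("connectance is the binary fill and is scale invariant", {
  expect_equal(connectance(ppnet(diag(3))), 1 / 3)
  expect_equal(connectance(ppnet(matrix(1, 2, 4))), 1)
  expect_equal(connectance(ppnet(matrix(c(2, 0, 0, 3, 1, 0), 2, 3))), 0.5)
  net <- rand_net(5, 6, seed = 2)
  expect_equal(connectance(net), connectance(ppnet(unclass(net) * 17.3)))
})

test_that("weighted NODF matches its definition on canonical cases", {
  expect_equal(weighted_nodf(ppnet(matrix(1, 2, 2))), 0)
  nested <- ppnet(matrix(c(3, 2, 1, 2, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE))
  expect_equal(weighted_nodf(nested), 100)
})

test_that("weighted NODF equals the plain-R definitional oracle and vegan", {
  set.seed(31)
  for (i in 1:60) {
    net <- rand_net(sample(3:6, 1), sample(3:7, 1), lambda = 1.4)
    m <- unclass(net)
    expect_equal(weighted_nodf(net), wnodf_oracle(m), tolerance = 1e-12)
    veg <- unname(vegan::nestednodf(m, order = TRUE, weighted = TRUE)$statistic["NODF"])
    expect_equal(weighted_nodf(net), veg, tolerance = 1e-9)
  }
})

test_that("weighted NODF is invariant to row/column permutation", {
  set.seed(5)
  net <- rand_net(6, 8, lambda = 2)
  m <- unclass(net)
  for (i in 1:10) {
    p <- ppnet(m[sample(nrow(m)), sample(ncol(m))])
    expect_equal(weighted_nodf(p), weighted_nodf(net), tolerance = 1e-12)
  }
})

test_that("Barber modularity follows the Q formula", {
  net <- rand_net(4, 5, seed = 9)
  ids <- c(rownames(net), colnames(net))
  # single module: exactly zero by the algebraic identity
  expect_equal(barber_modularity(net, setNames(rep(1, length(ids)), ids)), 0)
  # two-block network with the true modules
  bn <- block_net()
  part <- setNames(c(1, 1, 2, 2, 1, 1, 2, 2), c(rownames(bn), colnames(bn)))
  expect_equal(barber_modularity(bn, part), 0.5)
  # arbitrary partitions agree with the direct-formula oracle
  set.seed(12)
  for (i in 1:20) {
    rl <- sample(1:3, nrow(net), replace = TRUE)
    cl <- sample(1:3, ncol(net), replace = TRUE)
    part <- setNames(c(rl, cl), ids)
    expect_equal(barber_modularity(net, part), barber_q_oracle(unclass(net), rl, cl),
      tolerance = 1e-12
    )
  }
  expect_error(barber_modularity(net, part[-1]), "missing")
})

test_that("the optimizer recovers planted modules and is deterministic", {
  bn <- block_net()
  opt <- optimize_modularity(bn, seed = 1)
  expect_equal(opt$q, 0.5)
  expect_equal(opt$q, optimize_modularity(bn, method = "exhaustive")$q)
  # planted blocks recovered
  expect_equal(length(unique(opt$assignment[c("P1", "P2", "A1", "A2")])), 1L)
  expect_equal(length(unique(opt$assignment[c("P3", "P4", "A3", "A4")])), 1L)

  net <- rand_net(8, 9, seed = 44)
  a <- optimize_modularity(net, seed = 123)
  b <- optimize_modularity(net, seed = 123)
  expect_identical(a, b)
  expect_error(
    optimize_modularity(rand_net(7, 6, seed = 1), method = "exhaustive"),
    "12 vertices"
  )
})

test_that("network_indices gathers the four raw indices", {
  net <- rand_net(6, 7, seed = 63, lambda = 2)
  tab <- network_indices(net, seed = 2, restarts = 3, n_orders = 10)
  expect_equal(tab$index, c("connectance", "nestedness", "modularity", "robustness"))
  expect_equal(tab$value[1], connectance(net))
  expect_equal(tab$value[2], weighted_nodf(net))
  expect_true(all(tab$value[c(1, 3, 4)] >= 0 & tab$value[c(1, 3, 4)] <= 1))
})

test_that("label propagation never beats nor falls far below exhaustive search", {
  set.seed(77)
  n_eq <- 0
  n_tot <- 0
  for (i in 1:60) {
    net <- rand_net(sample(3:6, 1), sample(3:6, 1), lambda = 1.2)
    lq <- optimize_modularity(net, seed = i)$q
    eq <- optimize_modularity(net, method = "exhaustive")$q
    expect_lte(lq, eq + 1e-9)
    expect_gte(lq, 0) # single-module fallback is always admissible
    n_tot <- n_tot + 1
    n_eq <- n_eq + (abs(lq - eq) < 1e-9)
  }
  expect_gte(n_eq / n_tot, 0.9)
})
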