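test_that("restrictiveness bins to the binary trait", {
  expect_equal(
    bin_restrictiveness(c("unrestrictive", "low", "moderate", "high", "unknown")),
    c("not_restrictive", "not_restrictive", "restrictive", "restrictive", "unknown")
  )
  expect_error(bin_restrictiveness("open"), "open")
})

make_net <- function(n_plants, n_poll, prefix = "sp") {
  m <- matrix(1, n_plants, n_poll)
  rownames(m) <- paste0(prefix, seq_len(n_plants))
  ppnet(m, network_id = prefix)
}

test_that("trait frequencies are computed over classified species only", {
  net <- make_net(7, 6)
  tt <- tibble::tibble(
    species = paste0("sp", 1:7),
    ploidy = c("polyploid", "polyploid", "diploid", "diploid", rep("unknown", 3)),
    mating = rep("unknown", 7),
    restrictiveness = c(rep("high", 3), rep("low", 2), "unknown", "unknown")
  )
  tf <- trait_frequencies(net, tt)
  expect_equal(tf$pct_pp, 0.5)
  expect_equal(tf$n_known_ploidy, 4L)
  expect_true(is.na(tf$pct_sc))
  expect_equal(tf$n_known_mating, 0L)
  expect_equal(tf$pct_restrictive, 3 / 5)

  # single-trait accessor agrees
  expect_equal(trait_frequency(net, tt, "ploidy")$frequency, 0.5)

  # all classified / all polyploid edge
  tt2 <- tibble::tibble(
    species = paste0("sp", 1:7), ploidy = "polyploid",
    mating = "unknown", restrictiveness = "unknown"
  )
  expect_equal(trait_frequencies(net, tt2)$pct_pp, 1)

  # species absent from the table count as unknown, with a warning
  expect_warning(tf3 <- trait_frequencies(net, tt[1:3, ]), "not in trait table")
  expect_equal(tf3$n_known_ploidy, 3L)

  # unknown-trait species never change the frequency, only n_known
  expect_equal(tf$pct_pp, trait_frequencies(make_net(4, 6), tt[1:4, ])$pct_pp)
})

test_that("retention filters enforce all four criteria with reasons", {
  traits <- tibble::tibble(
    species = c(paste0("sp", 1:18), paste0("tiny", 1:8), paste0("cov", 1:8)),
    ploidy = c(
      rep(c("polyploid", "diploid", "unknown"), each = 6),
      rep("polyploid", 16)
    ),
    mating = "unknown", restrictiveness = "unknown"
  )
  covs <- tibble::tibble(
    network_id = c("sp", "tiny"),
    latitude = 10, longitude = 10, bio4 = 500, bio10 = 20, bio15 = 50, bio18 = 100
  )
  nets <- list(
    make_net(18, 6, "sp"), # boundary: 6 pollinators, 6/18 = one third exactly
    make_net(8, 5, "tiny"), # too few pollinators
    make_net(8, 7, "cov") # no covariate row
  )
  res <- apply_filters(nets, traits, covs)
  expect_equal(res$report$retained, c(TRUE, FALSE, FALSE))
  expect_equal(res$report$reasons[2], "min_pollinators")
  expect_equal(res$report$reasons[3], "no_climate")
  expect_length(res$retained, 1L)

  # idempotence
  again <- apply_filters(res$retained, traits, covs)
  expect_true(all(again$report$retained))

  # ploidy-count and coverage failures are both reported
  few <- make_net(18, 7, "few")
  traits2 <- dplyr::bind_rows(traits, tibble::tibble(
    species = paste0("few", 1:18),
    ploidy = c(rep("polyploid", 5), rep("unknown", 13)),
    mating = "unknown", restrictiveness = "unknown"
  ))
  covs2 <- dplyr::bind_rows(covs, tibble::tibble(
    network_id = "few", latitude = 0, longitude = 0,
    bio4 = 1, bio10 = 1, bio15 = 1, bio18 = 1
  ))
  rep2 <- apply_filters(list(few), traits2, covs2)$report
  expect_match(rep2$reasons, "min_ploidy_n")
  expect_match(rep2$reasons, "min_ploidy_coverage")
})

test_that("the path filter needs at least one mediator frequency", {
  freqs <- tibble::tibble(
    network_id = c("a", "b", "c", "d"),
    pct_sc = c(NA, 0.5, NA, 0.2),
    pct_restrictive = c(0.3, NA, NA, 0.6)
  )
  kept <- path_filter(freqs)
  expect_equal(kept$network_id, c("a", "b", "d"))
})
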