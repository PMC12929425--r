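test_that("interaction matrices parse, validate, and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plant,A,B", "p1,1,0", "p2,0,2"), f)
  net <- read_network(f)
  expect_s3_class(net, "ppnet")
  expect_equal(dim(net), c(2L, 2L))
  expect_equal(sum(net), 3)

  # all-zero pollinator column is dropped with a warning
  writeLines(c("plant,A,B,C", "p1,1,0,0", "p2,0,2,0"), f)
  expect_warning(net <- read_network(f), "dropped")
  expect_equal(ncol(net), 2L)

  # negative entry rejected with coordinates
  writeLines(c("plant,A,B", "p1,1,-1", "p2,0,2"), f)
  expect_error(read_network(f), "p1.*B")

  # duplicate labels rejected
  expect_error(ppnet(matrix(1, 2, 2, dimnames = list(c("a", "a"), c("x", "y")))), "duplicate")

  # non-numeric body rejected
  writeLines(c("plant,A,B", "p1,1,z", "p2,0,2"), f)
  expect_error(read_network(f), "non-numeric")

  # write -> read reproduces labels and weights exactly
  net <- rand_net(5, 7, seed = 11)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, out)
  back <- read_network(out, network_id = network_id(net))
  expect_identical(unclass(back), unclass(net))

  # plants-in-columns sources come back through the transpose flag
  flipped <- read_network(out, transpose = TRUE, network_id = "t")
  expect_equal(unclass(flipped), t(unclass(net)), ignore_attr = TRUE)

  # validation only removes empty margins, never changes retained weights
  m <- matrix(c(2, 0, 0, 0, 0.5, 3), 2, 3)
  rownames(m) <- c("p1", "p2")
  colnames(m) <- c("a", "b", "c")
  expect_warning(v <- ppnet(m), "empty")
  expect_equal(unclass(v)[, , drop = FALSE], m[, colSums(m) > 0], ignore_attr = TRUE)
})

test_that("binarize maps positives to one and is idempotent", {
  net <- ppnet(matrix(c(2, 0.5, 0, 3), 2, 2))
  b <- binarize(net)
  expect_equal(unclass(b)[, ], matrix(c(1, 1, 0, 1), 2, 2), ignore_attr = TRUE)
  expect_identical(unclass(binarize(b)), unclass(b))
  already <- ppnet(matrix(c(1, 0, 1, 1), 2, 2))
  expect_identical(unclass(binarize(already)), unclass(already))
})

test_that("trait tables parse with explicit unknowns and closed enums", {
  f <- make_trait_file(c("Rosa x;polyploid;;low", "Iris y;diploid;self_compatible;high"))
  tt <- read_trait_table(f)
  expect_equal(tt$ploidy, c("polyploid", "diploid"))
  expect_equal(tt$mating, c("unknown", "self_compatible"))
  expect_equal(tt$restrictiveness, c("low", "high"))

  f2 <- make_trait_file(c("Rosa x;polyploid;;low", "Rosa x;diploid;;high"))
  expect_error(read_trait_table(f2), "duplicate")

  f3 <- make_trait_file(character())
  expect_equal(nrow(read_trait_table(f3)), 0L)

  f4 <- make_trait_file("Rosa x;tetraploid;;low")
  expect_error(read_trait_table(f4), "tetraploid")
})

test_that("the packaged synthetic demo files load through the readers", {
  nets <- lapply(1:3, function(i) {
    read_network(
      system.file("extdata", sprintf("synthetic_network_%d.tsv", i), package = "plonet"),
      network_id = sprintf("synth%03d", i)
    )
  })
  traits <- read_trait_table(system.file("extdata", "synthetic_traits.tsv", package = "plonet"))
  covs <- read_covariates(system.file("extdata", "synthetic_covariates.tsv", package = "plonet"))
  expect_true(all(vapply(nets, inherits, logical(1), "ppnet")))
  res <- apply_filters(nets, traits, covs)
  expect_true(all(res$report$retained))
})

test_that("covariate tables are validated", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "network_id\tlatitude\tlongitude\tbio4\tbio10\tbio15\tbio18",
    "n1\t45\t-120\t600\t18\t40\t150",
    "n2\t-30\t20\t900\t25\t80\tNA"
  ), f)
  cv <- read_covariates(f)
  expect_equal(nrow(cv), 2L)
  expect_true(is.na(cv$bio18[2]))
  writeLines(c(
    "network_id\tlatitude\tlongitude\tbio4\tbio10\tbio15\tbio18",
    "n1\t95\t-120\t600\t18\t40\t150"
  ), f)
  expect_error(read_covariates(f), "latitude")
})
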