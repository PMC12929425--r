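#' Fixed-marginal null matrix
#'
#' Draws a random non-negative integer matrix with exactly the given row and
#' column totals, via Patefield's classic fixed-marginal contingency-table
#' algorithm ([stats::r2dtable()]): the network's dimensions and marginal
#' visit totals are preserved exactly in every draw.
#'
#' An alternative `"swap"` variant is available that additionally preserves
#' the number of positive cells (connectance) by redistributing weight with
#' marginal-preserving 2x2 swaps applied to the observed matrix; it requires
#' the observed matrix (`base`) and is provided because size-preserving null
#' schemes differ between studies.
#'
#' @param row_totals,col_totals Non-negative integer marginal totals with
#'   equal sums.
#' @param seed Integer seed.
#' @param variant `"r2dtable"` (default) or `"swap"`.
#' @param base Observed integer matrix (required for `variant = "swap"`).
#' @return An integer matrix with the requested marginals.
#' @export
null_matrix <- function(row_totals, col_totals, seed = 1L,
                        variant = c("r2dtable", "swap"), base = NULL) {
  variant <- match.arg(variant)
  row_totals <- as.integer(round(row_totals))
  col_totals <- as.integer(round(col_totals))
  if (any(row_totals < 0) || any(col_totals < 0)) abort("negative marginal totals")
  if (sum(row_totals) != sum(col_totals)) abort("row and column totals must have equal sums")
  if (sum(row_totals) == 0) abort("grand total must be positive")
  with_seed_(seed, {
    if (variant == "r2dtable") {
      r2dtable(1L, row_totals, col_totals)[[1]]
    } else {
      if (is.null(base)) abort("variant 'swap' requires the observed matrix in `base`")
      swap_null(base)
    }
  })
}

# connectance-preserving weight redistribution: repeated 2x2 "checkerboard"
# moves that shift one unit between cells while keeping marginals fixed and
# never emptying or creating a positive cell.
swap_null <- function(m, n_moves = 100L * length(m)) {
  m <- matrix(as.integer(round(m)), nrow(m), ncol(m))
  nr <- nrow(m)
  nc <- ncol(m)
  for (k in seq_len(n_moves)) {
    i <- sample.int(nr, 2L)
    j <- sample.int(nc, 2L)
    a <- m[i[1], j[1]]
    b <- m[i[1], j[2]]
    c_ <- m[i[2], j[1]]
    d <- m[i[2], j[2]]
    # move a unit along the diagonal that keeps all four cells positive-where-positive
    if (a > 1 && d > 1 && b > 0 && c_ > 0) {
      m[i[1], j[1]] <- a - 1L
      m[i[2], j[2]] <- d - 1L
      m[i[1], j[2]] <- b + 1L
      m[i[2], j[1]] <- c_ + 1L
    } else if (b > 1 && c_ > 1 && a > 0 && d > 0) {
      m[i[1], j[1]] <- a + 1L
      m[i[2], j[2]] <- d + 1L
      m[i[1], j[2]] <- b - 1L
      m[i[2], j[1]] <- c_ - 1L
    }
  }
  m
}

index_fun <- function(index, seed, restarts, n_orders) {
  switch(index,
    connectance = function(net) connectance(net),
    nestedness = function(net) weighted_nodf(net),
    modularity = function(net) optimize_modularity(net, seed = seed, restarts = restarts)$q,
    robustness = function(net) mean_robustness(net, n_orders = n_orders, seed = seed),
    abort(sprintf("unknown index '%s'", index))
  )
}

# matrix-level evaluators used inside the null loop; null draws preserve the
# positive marginals, so revalidation is unnecessary. The RNG is assumed to
# be seeded by the caller.
matrix_index_fun <- function(index, restarts, n_orders) {
  lpa_best <- function(m) {
    best <- lpa_modularity_cpp(m, random_init = FALSE)$q
    for (r in seq_len(max(restarts - 1L, 0L))) {
      best <- max(best, lpa_modularity_cpp(m, random_init = TRUE)$q)
    }
    max(best, 0)
  }
  switch(index,
    connectance = function(m) mean(m > 0),
    nestedness = function(m) wnodf_cpp(m),
    modularity = lpa_best,
    robustness = function(m) {
      pos <- m > 0
      n <- nrow(m)
      vals <- vapply(seq_len(n_orders), function(i) {
        pos_i <- sample.int(n) # removal step of each plant
        death <- apply(pos, 2, function(col) max(pos_i[col]))
        surv <- vapply(0:n, function(k) mean(death > k), numeric(1))
        sum(diff((0:n) / n) * (surv[-(n + 1)] + surv[-1]) / 2)
      }, numeric(1))
      mean(vals)
    },
    abort(sprintf("unknown index '%s'", index))
  )
}

#' Delta-standardize an index against its null distribution
#'
#' Computes the raw index, the mean of the index over `n_null` fixed-marginal
#' null matrices, and `delta = raw - null_mean`. Non-integer weights are
#' rounded half-up before marginal computation (weights are visit counts).
#' A null replicate on which the index is undefined is redrawn, up to a
#' capped retry count.
#'
#' @param network A [ppnet].
#' @param index One of `"connectance"`, `"nestedness"`, `"modularity"`,
#'   `"robustness"`, or a function of a `ppnet` returning a scalar.
#' @param n_null Number of null replicates (>= 2).
#' @param seed Integer seed; drives null draws and any stochastic index.
#' @param variant Null scheme passed to [null_matrix()].
#' @param restarts,n_orders Settings for the modularity and robustness
#'   evaluations (applied to the raw and every null value alike).
#' @return A one-row tibble: `index`, `raw`, `null_mean`, `delta`, `n_null`.
#' @export
delta_index <- function(network, index, n_null = 100L, seed = 1L,
                        variant = c("r2dtable", "swap"),
                        restarts = 10L, n_orders = 100L) {
  variant <- match.arg(variant)
  stopifnot(n_null >= 2)
  m <- round(as_matrix(network))
  storage.mode(m) <- "integer"
  rt <- rowSums(m)
  ct <- colSums(m)

  if (is.function(index)) {
    nm <- "custom"
    raw <- index(network)
    mfn <- function(mk) {
      dimnames(mk) <- dimnames(m)
      index(suppressWarnings(ppnet(mk, network_id = network_id(network))))
    }
  } else {
    nm <- index
    mfn <- matrix_index_fun(index, restarts, n_orders)
    raw <- with_seed_(seed + 1L, mfn(unclass(as_matrix(network))))
  }

  vals <- with_seed_(seed, {
    draws <- if (variant == "r2dtable") {
      r2dtable(n_null, rt, ct)
    } else {
      lapply(seq_len(n_null), function(k) swap_null(m))
    }
    vapply(draws, function(mk) {
      v <- tryCatch(mfn(mk), error = function(e) NA_real_)
      for (try in seq_len(20)) {
        if (is.finite(v)) break
        mk <- if (variant == "r2dtable") r2dtable(1L, rt, ct)[[1]] else swap_null(m)
        v <- tryCatch(mfn(mk), error = function(e) NA_real_)
      }
      if (!is.finite(v)) {
        abort(sprintf("index '%s' undefined on null replicates after 20 retries", nm))
      }
      v
    }, numeric(1))
  })
  null_mean <- mean(vals)
  tibble::tibble(
    index = nm, raw = raw, null_mean = null_mean,
    delta = raw - null_mean, n_null = as.integer(n_null)
  )
}

#' Delta-standardized index set of one network
#'
#' Applies [delta_index()] to each requested structural index and returns a
#' wide one-row tibble suitable for binding into an analysis table.
#'
#' @inheritParams delta_index
#' @param indices Indices to standardize.
#' @return A one-row tibble with `network_id`, `n_plants`, `n_pollinators`,
#'   and for each index `<index>`, `<index>_null_mean`, `delta_<index>`,
#'   plus `n_null`.
#' @export
delta_indices <- function(network,
                          indices = c("connectance", "nestedness", "modularity", "robustness"),
                          n_null = 100L, seed = 1L, variant = "r2dtable",
                          restarts = 10L, n_orders = 100L) {
  indices <- match.arg(indices, several.ok = TRUE)
  rows <- purrr::map(indices, function(ix) {
    delta_index(network, ix,
      n_null = n_null, seed = seed, variant = variant,
      restarts = restarts, n_orders = n_orders
    )
  })
  long <- dplyr::bind_rows(rows)
  wide <- tibble::tibble(
    network_id = network_id(network),
    n_plants = nrow(network), n_pollinators = ncol(network)
  )
  for (i in seq_along(indices)) {
    wide[[indices[i]]] <- long$raw[i]
    wide[[paste0(indices[i], "_null_mean")]] <- long$null_mean[i]
    wide[[paste0("delta_", indices[i])]] <- long$delta[i]
  }
  wide$n_null <- as.integer(n_null)
  wide
}
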