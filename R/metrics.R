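#' Connectance of a bipartite network
#'
#' The proportion of realized interactions out of all possible plant x
#' pollinator links. Computed on the binarized matrix: any positive visit
#' count is a link.
#'
#' @param network A [ppnet].
#' @return A number in (0, 1].
#' @export
connectance <- function(network) {
  m <- as_matrix(network)
  if (length(m) == 0) abort("zero-dimension network")
  mean(m > 0)
}

#' Weighted NODF nestedness
#'
#' Nested overlap and decreasing fill on the weighted matrix, in [0, 100].
#' For each pair of rows the member with the strictly larger binary fill
#' (number of positive cells) is the "richer"; the pair contributes 100
#' times the fraction of the poorer row's positive cells that are strictly
#' smaller than the richer row's corresponding cells. Ties in fill
#' contribute 0 (the decreasing-fill condition is strict). Likewise over
#' column pairs; the index is the mean over all row and column pairs, and
#' is invariant to row/column permutations.
#'
#' @param network A [ppnet] with at least 2 plants and 2 pollinators.
#' @return A number in [0, 100].
#' @export
weighted_nodf <- function(network) {
  m <- as_matrix(network)
  wnodf_cpp(m)
}

#' Barber bipartite modularity of a given partition
#'
#' \deqn{Q = \frac{1}{m}\sum_{ij}\left(w_{ij} - \frac{r_i c_j}{m}\right)
#'   \delta(g_i, h_j)}
#' where \eqn{m} is the total matrix weight, \eqn{r_i, c_j} the marginal
#' totals and \eqn{\delta} indicates that plant \eqn{i} and pollinator
#' \eqn{j} share a module. A single shared module gives exactly 0.
#'
#' @param network A [ppnet].
#' @param partition Named integer/character vector (or list with
#'   `row_labels`/`col_labels`) mapping every plant and pollinator
#'   identifier to a module label, e.g. as returned by
#'   [optimize_modularity()].
#' @return Q in [-1, 1].
#' @export
barber_modularity <- function(network, partition) {
  m <- as_matrix(network)
  if (is.list(partition) && !is.null(partition$row_labels)) {
    rl <- partition$row_labels
    cl <- partition$col_labels
    if (length(rl) != nrow(m) || length(cl) != ncol(m)) {
      abort("partition does not cover all vertices")
    }
  } else {
    ids <- c(rownames(m), colnames(m))
    miss <- setdiff(ids, names(partition))
    if (length(miss) > 0) {
      abort(sprintf("vertices missing from partition: %s", paste(head(miss, 5), collapse = ", ")))
    }
    lab <- as.integer(factor(partition[ids]))
    rl <- lab[seq_len(nrow(m))]
    cl <- lab[nrow(m) + seq_len(ncol(m))]
  }
  barber_q_cpp(m, as.integer(rl), as.integer(cl))
}

#' Optimize Barber modularity
#'
#' Finds a module partition maximizing Barber's bipartite Q. The default
#' method is a seeded weighted label-propagation search with agglomerative
#' module merging (multiple restarts, best Q kept, ties broken by the first
#' restart). `method = "exhaustive"` enumerates all set partitions and is
#' only admissible for networks with at most 12 vertices.
#'
#' The returned Q is never below 0: the single-module partition (Q = 0) is
#' always admissible and is used as fallback.
#'
#' @param network A [ppnet].
#' @param seed Integer seed; fixed seed gives identical results.
#' @param method `"label_propagation"` (default) or `"exhaustive"`.
#' @param restarts Number of seeded restarts for label propagation.
#' @return A list with `q`, `row_labels`, `col_labels` (integer module ids
#'   aligned with plants and pollinators), and `assignment`, a named vector
#'   over all vertex identifiers.
#' @export
optimize_modularity <- function(network, seed = 1L,
                                method = c("label_propagation", "exhaustive"),
                                restarts = 10L) {
  method <- match.arg(method)
  m <- as_matrix(network)
  if (method == "exhaustive") {
    if (nrow(m) + ncol(m) > 12) {
      abort("exhaustive search only admissible for networks with <= 12 vertices")
    }
    res <- exhaustive_modularity_cpp(m)
  } else {
    res <- with_seed_(seed, {
      best <- NULL
      for (r in seq_len(restarts)) {
        cand <- lpa_modularity_cpp(m, random_init = r > 1)
        if (is.null(best) || cand$q > best$q + 1e-12) best <- cand
      }
      best
    })
  }
  if (res$q < 0) {
    res$q <- 0
    res$row_labels <- rep(0L, nrow(m))
    res$col_labels <- rep(0L, ncol(m))
  }
  res$assignment <- setNames(
    c(res$row_labels, res$col_labels),
    c(rownames(m), colnames(m))
  )
  res
}

#' Raw structural indices of one network
#'
#' @param network A [ppnet].
#' @param indices Which of `connectance`, `nestedness`, `modularity`,
#'   `robustness` to compute.
#' @param seed Seed driving modularity restarts and extinction orders.
#' @param restarts Restarts for the modularity optimizer.
#' @param n_orders Random plant-removal orders for robustness.
#' @return A tibble with columns `index` and `value`.
#' @export
network_indices <- function(network,
                            indices = c("connectance", "nestedness", "modularity", "robustness"),
                            seed = 1L, restarts = 10L, n_orders = 100L) {
  indices <- match.arg(indices, several.ok = TRUE)
  vals <- vapply(indices, function(ix) {
    switch(ix,
      connectance = connectance(network),
      nestedness = weighted_nodf(network),
      modularity = optimize_modularity(network, seed = seed, restarts = restarts)$q,
      robustness = mean_robustness(network, policy = "random", n_orders = n_orders, seed = seed)
    )
  }, numeric(1))
  tibble::tibble(index = indices, value = unname(vals))
}
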