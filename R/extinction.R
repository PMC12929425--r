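#' Extinction curve under a plant removal order
#'
#' Plants are removed one by one in the given order; a pollinator survives
#' as long as it retains at least one positive interaction with a remaining
#' plant. The curve starts at (0, 1) and, because validated networks have no
#' empty columns, ends at (1, 0).
#'
#' @param network A [ppnet].
#' @param removal_order Character vector: a permutation of the network's
#'   plant identifiers.
#' @return A tibble of class `ppn_curve` with columns `fraction_removed`
#'   (strictly increasing, length n_plants + 1) and `fraction_surviving`
#'   (non-increasing).
#' @export
extinction_curve <- function(network, removal_order) {
  m <- as_matrix(network)
  plants <- rownames(m)
  if (length(removal_order) != length(plants) ||
    !setequal(removal_order, plants) || anyDuplicated(removal_order)) {
    abort("`removal_order` must be a permutation of the network's plants")
  }
  n <- length(plants)
  pos <- match(plants, removal_order) # removal step of each plant
  # a pollinator dies at the step its last partner is removed
  death <- apply(m > 0, 2, function(col) max(pos[col]))
  surv <- vapply(0:n, function(k) mean(death > k), numeric(1))
  out <- tibble::tibble(
    fraction_removed = (0:n) / n,
    fraction_surviving = surv
  )
  class(out) <- c("ppn_curve", class(out))
  out
}

#' Robustness: area under an extinction curve
#'
#' Trapezoidal area under the (fraction removed, fraction surviving)
#' polyline, in [0, 1].
#'
#' @param curve A curve from [extinction_curve()], or any data frame with
#'   `fraction_removed` and `fraction_surviving` columns.
#' @return A number in [0, 1].
#' @export
robustness <- function(curve) {
  x <- curve$fraction_removed
  y <- curve$fraction_surviving
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Mean robustness over seeded removal orders
#'
#' Under `policy = "random"`, removal orders are uniform permutations of
#' the plants. The ploidy-targeted policies remove all plants of the
#' targeted cytotype first (in random order among themselves), then the
#' remaining plants; plants of unknown ploidy are grouped with the
#' non-targeted block.
#'
#' @param network A [ppnet].
#' @param policy `"random"`, `"diploids_first"` or `"polyploids_first"`.
#' @param n_orders Number of seeded removal orders to average over.
#' @param seed Integer seed; fixed seed gives identical results.
#' @param ploidy For targeted policies: named character vector mapping plant
#'   identifiers to `"diploid"`/`"polyploid"`/`"unknown"`, or a trait table
#'   with `species` and `ploidy` columns.
#' @return Mean trapezoidal robustness, in [0, 1].
#' @export
mean_robustness <- function(network, policy = c("random", "diploids_first", "polyploids_first"),
                            n_orders = 100L, seed = 1L, ploidy = NULL) {
  policy <- match.arg(policy)
  stopifnot(n_orders >= 1)
  plants <- rownames(as_matrix(network))
  if (policy != "random") {
    if (is.data.frame(ploidy)) {
      ploidy <- setNames(ploidy$ploidy, ploidy$species)
    }
    if (is.null(ploidy)) abort("targeted policies require a `ploidy` map")
    names(ploidy) <- normalize_species(names(ploidy))
    pl <- unname(ploidy[normalize_species(plants)])
    pl[is.na(pl)] <- "unknown"
    target <- if (policy == "diploids_first") "diploid" else "polyploid"
    if (!any(pl == target)) {
      abort(sprintf("no plants classified as %s; targeted policy undefined", target))
    }
    first <- plants[pl == target]
    rest <- plants[pl != target]
  }
  vals <- with_seed_(seed, {
    vapply(seq_len(n_orders), function(i) {
      ord <- if (policy == "random") {
        sample(plants)
      } else {
        c(sample(first), if (length(rest) > 0) sample(rest))
      }
      robustness(extinction_curve(network, ord))
    }, numeric(1))
  })
  mean(vals)
}

#' @export
autoplot.ppn_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fraction_removed, .data$fraction_surviving)) +
    ggplot2::geom_step(direction = "hv", color = "grey50") +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "Fraction of plants removed",
      y = "Fraction of pollinators surviving"
    ) +
    ggplot2::theme_minimal()
}
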