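# Fixtures and plain-R oracles, independent of the package's compiled paths.

rand_net <- function(nr, nc, lambda = 1.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    m <- matrix(rpois(nr * nc, lambda), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      return(ppnet(m, network_id = "rand"))
    }
  }
}

block_net <- function() {
  m <- matrix(0, 4, 4)
  m[1:2, 1:2] <- 1
  m[3:4, 3:4] <- 1
  ppnet(m, network_id = "blocks")
}

# definitional weighted NODF, written as direct prose-to-R translation
wnodf_oracle <- function(m) {
  score_pairs <- function(mat) {
    fills <- rowSums(mat > 0)
    n <- nrow(mat)
    vals <- c()
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        if (fills[a] == fills[b]) {
          vals <- c(vals, 0)
          next
        }
        rich <- if (fills[a] > fills[b]) a else b
        poor <- if (rich == a) b else a
        num <- sum(mat[poor, ] > 0 & mat[poor, ] < mat[rich, ])
        vals <- c(vals, 100 * num / fills[poor])
      }
    }
    vals
  }
  mean(c(score_pairs(m), score_pairs(t(m))))
}

# Barber Q evaluated straight from the formula
barber_q_oracle <- function(m, rlab, clab) {
  tot <- sum(m)
  q <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (rlab[i] == clab[j]) {
        q <- q + m[i, j] - sum(m[i, ]) * sum(m[, j]) / tot
      }
    }
  }
  q / tot
}

# every permutation of a small vector
all_perms <- function(x) {
  if (length(x) <= 1) {
    return(list(x))
  }
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

# total source->target effect in a DAG by dynamic programming over parents:
# effect(v) = sum_p coef(p->v) * effect(p), effect(source) = 1
total_effect_oracle <- function(parents, coefs, source, target) {
  eff <- setNames(numeric(length(parents)), names(parents))
  eff[source] <- 1
  for (v in names(parents)) {
    if (v == source) next
    for (p in parents[[v]]) {
      cf <- coefs[paste0(p, "->", v)]
      if (!is.na(cf)) eff[v] <- eff[v] + cf * eff[p]
    }
  }
  unname(eff[target])
}

make_trait_file <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(c("species;ploidy;mating;restrictiveness", lines), f)
  f
}
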