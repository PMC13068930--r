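# Independent oracles and small fixture builders shared across test files.

# Conditional expectation of a single tree given a feature subset S
# (1-based feature ids): features in S follow x, absent features average
# both children weighted by node covers.
tree_expvalue <- function(tr, x, S, node = 1) {
  if (tr$left[node] < 0) return(tr$value[node])
  f <- tr$feature[node] + 1L
  l <- tr$left[node] + 1L
  r <- tr$right[node] + 1L
  if (f %in% S) {
    if (x[f] <= tr$threshold[node]) tree_expvalue(tr, x, S, l)
    else tree_expvalue(tr, x, S, r)
  } else {
    (tr$cover[l] * tree_expvalue(tr, x, S, l) +
       tr$cover[r] * tree_expvalue(tr, x, S, r)) / tr$cover[node]
  }
}

# Brute-force Shapley values of one tree by subset enumeration (small p).
brute_tree_shap <- function(tr, x, p) {
  phi <- numeric(p)
  for (j in seq_len(p)) {
    others <- setdiff(seq_len(p), j)
    for (k in 0:length(others)) {
      sets <- if (k == 0) list(integer(0)) else
        combn(others, k, simplify = FALSE)
      for (S in sets) {
        w <- factorial(k) * factorial(p - k - 1) / factorial(p)
        phi[j] <- phi[j] +
          w * (tree_expvalue(tr, x, c(S, j)) - tree_expvalue(tr, x, S))
      }
    }
  }
  phi
}

# Extract tree arrays (with covers from `background`) from a ranger fit,
# mirroring the package's internal representation.
ranger_tree_arrays <- function(fit, k, background) {
  ti <- ranger::treeInfo(fit, k)
  leaf <- ti$terminal
  tr <- list(left = ifelse(leaf, -1L, as.integer(ti$leftChild)),
             right = ifelse(leaf, -1L, as.integer(ti$rightChild)),
             feature = ifelse(leaf, 0L, as.integer(ti$splitvarID)),
             threshold = ifelse(leaf, 0, ti$splitval),
             value = ifelse(leaf, ti$prediction, 0))
  node <- function(i, X) {
    n <- integer(nrow(X))
    for (r in seq_len(nrow(X))) {
      j <- 1L
      while (tr$left[j] >= 0) {
        j <- if (X[r, tr$feature[j] + 1L] <= tr$threshold[j])
          tr$left[j] + 1L else tr$right[j] + 1L
      }
      n[r] <- j
    }
    n
  }
  cover <- numeric(length(tr$left))
  for (r in seq_len(nrow(background))) {
    j <- 1L
    repeat {
      cover[j] <- cover[j] + 1
      if (tr$left[j] < 0) break
      j <- if (background[r, tr$feature[j] + 1L] <= tr$threshold[j])
        tr$left[j] + 1L else tr$right[j] + 1L
    }
  }
  tr$cover <- cover
  tr
}

# Brute-force Benjamini-Hochberg step-up oracle: for sorted p, the adjusted
# value is min over j >= i of p_(j) * m / j, clipped at 1.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Small all-null cohort configuration used by several files.
null_effects <- function(k = 4) {
  out <- lapply(seq_len(k), function(i) {
    effect_spec(sprintf("null_%02d", i), "null", 0)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

small_config <- function(n = 400, seed = 1, ...) {
  cohort_config(n_participants = n, n_regions = 20,
                granularity_levels = c(20, 10), noise_sd_gm = 10,
                seed = seed, ...)
}
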