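# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive `k` independent sub-seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Linear index of unordered pairs (i < j) over n nodes, ordered
# (1,2),(1,3),...,(1,n),(2,3),...  Used for set membership of edges.
pair_index <- function(i, j, n) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  (lo - 1) * n - lo * (lo + 1) / 2 + hi
}

# Inverse of pair_index for a vector of indices.
pair_unindex <- function(k, n) {
  offsets <- c(0, cumsum((n - 1):1))  # offsets[i] = #pairs with lo < i
  lo <- findInterval(k - 1, offsets, left.open = FALSE)
  hi <- k - offsets[lo] + lo
  cbind(lo, hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
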