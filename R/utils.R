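# Internal helpers: seed plumbing, argument checks, union-find.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so no global RNG state leaks out.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministically derive a child seed from (seed, offset); keeps results
# in [1, 2^31 - 2] so set.seed() always accepts them. The xor/shift mixing
# steps make the map non-affine, so composed derivations (scene seed ->
# per-channel seeds) cannot collapse distinct master seeds onto one stream.
derive_seed <- function(seed, offset) {
  m <- 2147483647
  x <- as.integer(abs(as.numeric(seed)) %% (m - 1) + 1)
  y <- as.integer(abs(as.numeric(offset)) %% (m - 1) + 1)
  for (i in 1:3) {
    x <- as.integer((as.numeric(x) * 48271) %% m)
    x <- bitwXor(x, y)
    x <- bitwXor(x, bitwShiftR(x, 11))
    x <- bitwXor(x, bitwShiftL(bitwAnd(x, 65535L), 7))
    x <- as.integer(abs(as.numeric(x)) %% m)
    y <- as.integer((as.numeric(y) * 16807 + 104729) %% m)
  }
  as.integer(abs(as.numeric(x)) %% (m - 2) + 1)
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || any(!is.finite(x)) ||
      (strict && any(x <= 0)) || (!strict && any(x < 0))) {
    abort(sprintf(
      "`%s` must be %s, got %s", name,
      if (strict) "strictly positive" else "non-negative",
      paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must lie in [0, 1], got %s", name, format(x)))
  }
  invisible(x)
}

# Minimal union-find over integers 1..n.
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# Union the id pairs in `pairs` (2-column matrix); returns root labels 1..n.
uf_components <- function(n, pairs) {
  parent <- uf_new(n)
  if (length(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      a <- uf_find(parent, pairs[k, 1])
      b <- uf_find(parent, pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
}
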