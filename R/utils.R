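# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

# Permutation p-value with the +1 correction: with B permutations the
# smallest attainable value is 1/(B + 1).
perm_pvalue <- function(n_ge, n_perm) (n_ge + 1) / (n_perm + 1)

# Derive distinct child seeds from one master seed (kept below 2^31).
child_seeds <- function(seed, n, salt = 0L) {
  (as.integer(seed) %% 100000L) * 10000L + salt * 1000L + seq_len(n)
}

check_square_distance <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
    stop("distance matrix must be square and symmetric", call. = FALSE)
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero",
                              call. = FALSE)
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  d
}
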