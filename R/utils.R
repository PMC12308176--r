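# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never clobber user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_if_not_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                      integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  if (x < min || x > max)
    stop(sprintf("`%s` must be in [%s, %s]", name, format(min), format(max)),
         call. = FALSE)
  invisible(x)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softplus <- function(x) {
  # log(1 + exp(x)) computed without overflow for large x
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# Row-wise log-sum-exp of a matrix.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# L2-normalise matrix rows; errors (naming the offender) on zero rows.
normalize_rows <- function(z, ids = NULL, what = "embedding") {
  nrm <- sqrt(rowSums(z^2))
  if (any(nrm < 1e-12)) {
    bad <- which(nrm < 1e-12)[1L]
    lab <- if (!is.null(ids)) ids[bad] else as.character(bad)
    stop(sprintf(
      "cosine similarity undefined: %s row for cell '%s' is all zero",
      what, lab), call. = FALSE)
  }
  z / nrm
}

`%||%` <- function(a, b) if (is.null(a)) b else a
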