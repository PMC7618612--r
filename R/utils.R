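# Internal helpers shared across modules.

# Round half away from zero (printed tables use half-up, base round() is
# round-half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All generator randomness flows through this.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Normalise an angle in degrees to the half-open interval (-90, 90].
normalize_angle <- function(theta) {
  out <- (theta + 90) %% 180 - 90
  ifelse(out == -90, 90, out)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    abort(sprintf("`%s` must be finite (got %s).", what,
                  paste(utils::head(x[!is.finite(x)], 3), collapse = ", ")))
  }
  invisible(x)
}
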