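# Integer allocation helpers used by the deterministic simulator and the
# deterministic degradation mode. Both conserve the requested total exactly.

# Largest-remainder allocation of integer `total` across weights.
# Ties on the fractional part are broken by position (earlier wins), which
# keeps the result deterministic.
allocate_lr <- function(total, weights) {
  stopifnot(total >= 0, all(weights >= 0))
  if (total == 0) {
    return(rep(0L, length(weights)))
  }
  s <- sum(weights)
  if (s <= 0) abort("allocate_lr: all weights zero with positive total.")
  x <- total * weights / s
  n <- floor(x)
  short <- as.integer(round(total - sum(n)))
  if (short > 0) {
    frac <- x - n
    take <- order(-frac, seq_along(frac))[seq_len(short)]
    n[take] <- n[take] + 1
  }
  as.integer(n)
}

# Sequential allocation with a carried remainder: allocates `total` across
# `weights` while accumulating the rounding residual in `carry` so that a
# chain of calls (one per stratum) stays globally proportional even when each
# stratum total is small. Returns list(counts, carry).
allocate_carry <- function(total, weights, carry = rep(0, length(weights))) {
  stopifnot(length(weights) == length(carry))
  if (total == 0 || sum(weights) <= 0) {
    return(list(counts = rep(0L, length(weights)), carry = carry))
  }
  x <- total * weights / sum(weights) + carry
  x[x < 0] <- 0
  n <- floor(x)
  short <- as.integer(total - sum(n))
  if (short > 0) {
    frac <- x - n
    take <- order(-frac, seq_along(frac))[seq_len(short)]
    n[take] <- n[take] + 1
  } else if (short < 0) {
    # carried surplus: remove from the largest allocations
    take <- order(-n, seq_along(n))[seq_len(-short)]
    n[take] <- pmax(n[take] - 1, 0)
  }
  list(counts = as.integer(n), carry = x - n)
}
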