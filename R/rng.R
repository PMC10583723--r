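# Internal randomness primitives.
#
# Both allocation engines (the R reference implementation and the compiled
# one) draw from R's global RNG stream through exactly the same sequence of
# uniform deviates, so that `set.seed(s)` followed by either engine yields
# bit-identical allocations. Every helper consumes a fixed number of draws
# regardless of ties, which is what makes the two engines interchangeable.

# one uniform draw -> integer in 0..(n-1)
rng_int <- function(n) {
  v <- floor(stats::runif(1L) * n)
  if (v >= n) v <- n - 1L # guard against runif() returning exactly 1
  as.integer(v)
}

# uniform pick from a vector; always consumes one draw
uniform_pick <- function(x) x[rng_int(length(x)) + 1L]

# uniform s-subset via partial Fisher-Yates; consumes s draws
random_subset <- function(x, s) {
  m <- length(x)
  for (i in seq_len(s)) {
    j <- i + rng_int(m - i + 1L)
    tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
  }
  sort(x[seq_len(s)])
}

# counter-free derivation of per-allocation seeds from a master seed
derive_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(2147483647L, n, replace = FALSE)
}
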