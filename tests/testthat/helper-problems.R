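# Random feasible problems with derived (near-equal) batch sizes, the input
# surface the tool actually exposes.
random_problem <- function() {
  T_ <- sample(2:6, 1)
  t <- sample(1:8, T_, replace = TRUE)
  allocation_problem(t, max_batch_size = sample(1:T_, 1))
}

# Brute-force enumeration of every ordered binary remainder allocation, by
# independent means (no canonicalization, no pruning beyond counts); used as
# the oracle for the canonical enumerator.
naive_enumerate <- function(problem) {
  pre <- preallocate(problem)
  B <- length(pre$b_star)
  T_ <- length(pre$t_star)
  out <- list()
  recurse <- function(k, t_rem, rows) {
    if (k > B) {
      if (all(t_rem == 0L)) {
        N <- matrix(0L, B, T_)
        for (kk in seq_len(B)) N[kk, rows[[kk]]] <- 1L
        out[[length(out) + 1L]] <<- pre$N_star + N
      }
      return(invisible(NULL))
    }
    sets <- if (pre$b_star[k] == 0L) list(integer(0)) else
      utils::combn(T_, pre$b_star[k], simplify = FALSE)
    for (set in sets) {
      if (any(t_rem[set] <= 0L)) next
      t_new <- t_rem
      t_new[set] <- t_new[set] - 1L
      rows[[k]] <- set
      recurse(k + 1L, t_new, rows)
    }
  }
  recurse(1L, pre$t_star, vector("list", B))
  out
}

expect_valid_allocation <- function(alloc, problem) {
  expect_true(all(colSums(alloc$incidence) == problem$t))
  expect_true(all(rowSums(alloc$incidence) == problem$b))
}
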