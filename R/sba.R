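#' @name allocation_state
#' @title Mid-allocation state of the batch-filling loop
#'
#' @description
#' The batch-filling loop maintains a mutable state: the binary remainder
#' incidence matrix `N` (B x T), the concurrence matrix `Lambda = N^T N`
#' restricted to the batches completed so far, the remaining per-treatment
#' counts `t_star`, the residual batch capacities `b_star`, and the index `k`
#' of the batch currently being filled. `new_allocation_state()` builds the
#' initial state from a preallocation; the selection rules below read and the
#' batch step advances it. Randomness comes from R's global RNG stream:
#' callers seed it once per allocation.
#'
#' @param prealloc A [preallocate()] result.
#' @return `new_allocation_state()`: an object of class `allocation_state`.
NULL

#' @rdname allocation_state
#' @export
new_allocation_state <- function(prealloc) {
  T_ <- length(prealloc$t_star)
  B <- length(prealloc$b_star)
  structure(
    list(N = matrix(0L, B, T_),
         Lambda = matrix(0L, T_, T_),
         t_star = as.integer(prealloc$t_star),
         b_star = as.integer(prealloc$b_star),
         k = 1L, B = B),
    class = "allocation_state"
  )
}

#' Selection rules of the stochastic batch-allocation heuristic
#'
#' These four rules decide, in priority order, which treatments fill the
#' current batch:
#' \describe{
#'   \item{`forced_treatments()`}{treatments whose remaining count equals the
#'     number of remaining batches (`t*_i == B - (k - 1)`); they must appear
#'     in every remaining batch or the allocation cannot complete.}
#'   \item{`never_chosen_treatments()`}{treatments still awaiting their first
#'     slot in the remainder problem, recognizable by a zero on the diagonal
#'     of the concurrence matrix.}
#'   \item{`seed_pair()`}{when the batch is still empty, the pair of available
#'     treatments with the smallest off-diagonal concurrence, ties broken
#'     uniformly at random.}
#'   \item{`next_treatment()`}{the available treatment with the smallest
#'     summed concurrence against the treatments already chosen for the
#'     batch (the lowest column sum of `Lambda[chosen, candidates]`), ties
#'     broken uniformly at random.}
#' }
#'
#' @param state An `allocation_state`.
#' @param candidates Integer vector of candidate treatment indices.
#' @param chosen Integer vector of treatment indices already in the batch.
#' @return Treatment indices (into the problem's label order).
#' @name selection_rules
NULL

#' @rdname selection_rules
#' @export
forced_treatments <- function(state) {
  remaining <- state$B - (state$k - 1L)
  forced <- which(state$t_star > 0L & state$t_star == remaining)
  if (length(forced) > state$b_star[state$k]) {
    stop(sprintf(
      "infeasible: %d treatments are forced into batch %d but only %d slots remain",
      length(forced), state$k, state$b_star[state$k]), call. = FALSE)
  }
  forced
}

#' @rdname selection_rules
#' @export
never_chosen_treatments <- function(state) {
  which(state$t_star > 0L & diag(state$Lambda) == 0L)
}

#' @rdname selection_rules
#' @export
seed_pair <- function(state, candidates) {
  if (length(candidates) < 2L) {
    stop("seed_pair needs at least two candidate treatments", call. = FALSE)
  }
  sub <- state$Lambda[candidates, candidates, drop = FALSE]
  off <- upper.tri(sub)
  lo <- min(sub[off])
  tied <- which(off & sub == lo, arr.ind = TRUE)
  pick <- rng_int(nrow(tied)) + 1L
  c(candidates[tied[pick, 1L]], candidates[tied[pick, 2L]])
}

#' @rdname selection_rules
#' @export
next_treatment <- function(state, chosen, candidates) {
  stopifnot(length(chosen) >= 1L, length(candidates) >= 1L)
  colsum <- colSums(state$Lambda[chosen, candidates, drop = FALSE])
  tied <- candidates[colsum == min(colsum)]
  uniform_pick(tied)
}

#' Fill the current batch and advance the state
#'
#' Applies the selection rules in priority order until the batch holds
#' `min(b*_k, #available treatments)` treatments, then updates the incidence
#' and concurrence matrices and the remaining counts in one step (matrices
#' are updated only after the whole batch is chosen) and moves to the next
#' batch. If the never-chosen treatments outnumber the remaining capacity, a
#' uniformly random subset of them is taken. An empty batch with capacity one
#' (no seed pair possible) receives a uniformly random available treatment.
#'
#' @param state An `allocation_state` with `k <= B`.
#' @param rule How to fill the batch: `"sba"` applies the concurrence-guided
#'   selection rules; `"rba"` keeps only the forced-treatment rule and fills
#'   the rest uniformly at random (the random-binary baseline).
#' @return The advanced `allocation_state`.
#' @export
allocate_batch <- function(state, rule = c("sba", "rba")) {
  rule <- match.arg(rule)
  k <- state$k
  stopifnot(k <= state$B)
  cap <- state$b_star[k]
  if (cap > 0L) {
    avail <- which(state$t_star > 0L)
    chosen <- forced_treatments(state)
    cand <- setdiff(avail, chosen)
    if (rule == "sba") {
      if (length(chosen) < cap) {
        nz <- intersect(cand, never_chosen_treatments(state))
        room <- cap - length(chosen)
        if (length(nz) > room) nz <- random_subset(nz, room)
        chosen <- c(chosen, nz)
        cand <- setdiff(cand, nz)
      }
      if (length(chosen) == 0L && cap >= 2L && length(cand) >= 2L) {
        pair <- seed_pair(state, cand)
        chosen <- pair
        cand <- setdiff(cand, pair)
      }
      while (length(chosen) < cap && length(cand) > 0L) {
        j <- if (length(chosen) == 0L) uniform_pick(cand)
             else next_treatment(state, chosen, cand)
        chosen <- c(chosen, j)
        cand <- setdiff(cand, j)
      }
    } else {
      need <- min(cap - length(chosen), length(cand))
      if (need > 0L) {
        extra <- if (need < length(cand)) random_subset(cand, need) else cand
        chosen <- c(chosen, extra)
      }
    }
    state$N[k, chosen] <- 1L
    state$Lambda[chosen, chosen] <- state$Lambda[chosen, chosen] + 1L
    state$t_star[chosen] <- state$t_star[chosen] - 1L
  }
  state$k <- k + 1L
  state
}

# shared driver for both algorithms and both engines
allocate_impl <- function(problem, seed, algorithm, engine) {
  problem <- validate_problem(problem)
  pre <- preallocate(problem)
  set.seed(seed)
  if (engine == "cpp") {
    N <- fill_batches_cpp(pre$t_star, pre$b_star, algorithm == "sba")
  } else {
    state <- new_allocation_state(pre)
    for (k in seq_along(pre$b_star)) state <- allocate_batch(state, algorithm)
    N <- state$N
  }
  if (any(colSums(N) != pre$t_star)) {
    stop("infeasible: some subjects could not be placed (check that batch sizes do not exceed the number of treatments)",
         call. = FALSE)
  }
  incidence <- pre$N_star + N
  colnames(incidence) <- problem$treatment_labels
  scored_allocation(incidence, problem = problem, seed = seed,
                    algorithm = algorithm)
}

#' Stochastic batch allocation (SBA)
#'
#' Runs the full heuristic: preallocation, then one batch at a time filled by
#' the concurrence-guided selection rules, then recombination of the
#' preallocated and binary parts into the final incidence matrix. The result
#' is deterministic given `(problem, seed)`.
#'
#' @param problem An [allocation_problem()].
#' @param seed Integer seed; the sole source of randomness.
#' @param engine `"cpp"` (default, compiled) or `"r"` (reference
#'   implementation built from the exported selection rules). Both engines
#'   consume the RNG stream identically and return identical allocations.
#' @return A [scored_allocation()] whose incidence matrix has column sums
#'   `t` and row sums `b`.
#' @examples
#' p <- allocation_problem(c(A = 6, B = 6, C = 6, D = 6, E = 6), max_batch_size = 3)
#' sba_allocate(p, seed = 1)
#' @export
sba_allocate <- function(problem, seed, engine = c("cpp", "r")) {
  allocate_impl(problem, seed, "sba", match.arg(engine))
}
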