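#' Estimated size of the binary allocation search space
#'
#' The number of ways to fill the batches one at a time after preallocation,
#' `prod(choose(T, b*_k))`. This overestimates the number of distinct
#' allocations (it ignores the column-sum constraints and the
#' interchangeability of equal batches) but tracks how quickly exhaustive
#' search becomes impractical.
#'
#' @param problem An [allocation_problem()].
#' @return The exact product as a decimal digit string (it routinely
#'   overflows doubles); convert with `as.numeric()` when an approximation
#'   suffices.
#' @examples
#' p <- allocation_problem(c(6, 6, 6, 6, 6), max_batch_size = 3)
#' search_space_size(p) # "10000000000" = C(5,3)^10
#' @export
search_space_size <- function(problem) {
  pre <- preallocate(problem)
  T_ <- length(problem$t)
  factors <- choose(T_, pre$b_star)
  # exact running product in base-1e7 limbs: every factor is a small integer
  limbs <- 1
  for (f in factors) {
    limbs <- limbs * f
    carry <- 0
    for (i in seq_along(limbs)) {
      v <- limbs[i] + carry
      limbs[i] <- v %% 1e7
      carry <- v %/% 1e7
    }
    while (carry > 0) {
      limbs <- c(limbs, carry %% 1e7)
      carry <- carry %/% 1e7
    }
  }
  n <- length(limbs)
  paste0(format(limbs[n], scientific = FALSE),
         paste(sprintf("%07d", rev(limbs[-n])), collapse = ""))
}

#' Enumerate every binary remainder allocation of a small problem
#'
#' Yields each feasible binary allocation of the remainder problem exactly
#' once up to reordering of equal-sized batches: consecutive batches of equal
#' residual capacity are constrained to nondecreasing lexicographic row
#' order, which is harmless because the D-criterion is invariant under row
#' permutations. Rows with the preallocated part added back are returned.
#'
#' @param problem An [allocation_problem()].
#' @param max_space Budget cap on [search_space_size()]; above it the
#'   enumeration refuses to run (exhaustive search rapidly becomes
#'   impractical beyond desk scale).
#' @return List of B x T incidence matrices.
#' @export
enumerate_allocations <- function(problem, max_space = 1e7) {
  problem <- validate_problem(problem)
  if (as.numeric(search_space_size(problem)) > max_space) {
    stop(sprintf(
      "search space %s exceeds the enumeration budget of %g",
      search_space_size(problem), max_space), call. = FALSE)
  }
  pre <- preallocate(problem)
  B <- length(pre$b_star)
  T_ <- length(pre$t_star)
  subsets_of_size <- lapply(0:T_, function(s) {
    if (s == 0L) list(integer(0)) else
      utils::combn(T_, s, simplify = FALSE)
  })
  out <- list()
  rows <- vector("list", B)

  # lexicographic key of a chosen subset as a binary row
  row_key <- function(set) {
    r <- integer(T_)
    r[set] <- 1L
    paste(r, collapse = "")
  }

  recurse <- function(k, t_rem) {
    if (k > B) {
      N <- matrix(0L, B, T_)
      for (kk in seq_len(B)) N[kk, rows[[kk]]] <- 1L
      inc <- pre$N_star + N
      colnames(inc) <- problem$treatment_labels
      out[[length(out) + 1L]] <<- inc
      return(invisible(NULL))
    }
    cap <- pre$b_star[k]
    remaining_batches <- B - k + 1L
    for (set in subsets_of_size[[cap + 1L]]) {
      if (any(t_rem[set] == 0L)) next
      t_new <- t_rem
      t_new[set] <- t_new[set] - 1L
      # feasibility: no treatment may need more batches than remain
      if (any(t_new > remaining_batches - 1L)) next
      # canonical order among equal-capacity neighbours
      if (k > 1L && pre$b_star[k - 1L] == cap &&
          row_key(set) < row_key(rows[[k - 1L]])) next
      rows[[k]] <<- set
      recurse(k + 1L, t_new)
    }
  }
  recurse(1L, pre$t_star)
  out
}

#' Exhaustively optimal allocation of a small problem
#'
#' Scores every allocation from [enumerate_allocations()] and returns one
#' with the maximal D-criterion (the first encountered among ties).
#'
#' @inheritParams enumerate_allocations
#' @return A [scored_allocation()] with `algorithm = "exhaustive"`.
#' @export
optimal_allocation <- function(problem, max_space = 1e7) {
  allocations <- enumerate_allocations(problem, max_space)
  if (length(allocations) == 0L) stop("no feasible allocation", call. = FALSE)
  best <- NULL
  best_exact <- "0"
  for (inc in allocations) {
    d <- d_criterion(inc, exact = TRUE)
    if (is.null(best) || compare_scores(d, best_exact) > 0L) {
      best <- inc
      best_exact <- d
    }
  }
  scored_allocation(best, problem = problem, algorithm = "exhaustive")
}

#' Unreduced balanced incomplete-block incidence matrix
#'
#' The design whose batches are all `choose(n_treatments, batch_size)`
#' distinct treatment subsets of the given size, one batch each. Every
#' treatment pair co-occurs equally often, so when the cohort fits it this
#' is the optimal allocation (e.g. five treatments of six subjects in ten
#' batches of three).
#'
#' @param n_treatments,batch_size Design dimensions.
#' @return A `choose(n_treatments, batch_size)` x `n_treatments` binary
#'   incidence matrix.
#' @export
bibd_incidence <- function(n_treatments, batch_size) {
  sets <- utils::combn(n_treatments, batch_size, simplify = FALSE)
  N <- matrix(0L, length(sets), n_treatments)
  for (k in seq_along(sets)) N[k, sets[[k]]] <- 1L
  N
}
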