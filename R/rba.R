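#' Random binary allocation (RBA)
#'
#' The baseline the heuristic is compared against: the same preallocation,
#' followed by a uniformly random binary allocation of the remainder. Each
#' batch receives a uniformly random set of distinct available treatments,
#' except that treatments whose remaining count equals the number of
#' remaining batches are always included (without this the allocation could
#' dead-end or confound; with it RBA always completes on feasible problems).
#'
#' @inheritParams sba_allocate
#' @return A [scored_allocation()]; deterministic given `(problem, seed)`.
#' @export
rba_allocate <- function(problem, seed, engine = c("cpp", "r")) {
  allocate_impl(problem, seed, "rba", match.arg(engine))
}
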