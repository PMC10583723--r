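#' Preallocation: split off the identical-per-batch part
#'
#' Every batch first receives the integer quotient `q_i = floor(t_i / B)`
#' subjects of each treatment. What remains is a binary allocation problem:
#' the remainders `t*_i = t_i - B * q_i` are all smaller than the number of
#' batches, so each treatment can appear at most once more per batch. Because
#' the preallocated part is identical across batches it has no influence on
#' the quality of the subsequent binary allocation, and the concurrence
#' bookkeeping of the heuristic starts from zero.
#'
#' @param problem A validated [allocation_problem()].
#' @return A list of class `preallocation` with fields
#'   \describe{
#'     \item{q}{per-treatment count placed in every batch (length T)}
#'     \item{t_star}{remaining per-treatment counts, all `< B` (length T)}
#'     \item{b_star}{residual batch capacities `b_k - sum(q)` (length B)}
#'     \item{N_star}{the B x T preallocated incidence matrix, every row `q`}
#'   }
#' @examples
#' p <- allocation_problem(c(5, 6, 7, 8, 9, 9), batch_sizes = c(8, 8, 7, 7, 7, 7))
#' preallocate(p)
#' @export
preallocate <- function(problem) {
  problem <- validate_problem(problem)
  B <- length(problem$b)
  q <- problem$t %/% B
  t_star <- problem$t - B * q
  b_star <- problem$b - sum(q)
  if (any(b_star < 0L)) {
    stop(sprintf(
      "infeasible: batch capacity %d cannot hold the per-batch quota %d",
      min(problem$b), sum(q)), call. = FALSE)
  }
  structure(
    list(q = q, t_star = t_star, b_star = b_star,
         N_star = matrix(rep(q, each = B), nrow = B,
                         dimnames = list(NULL, problem$treatment_labels))),
    class = "preallocation"
  )
}
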