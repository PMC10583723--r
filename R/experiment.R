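#' Benchmark settings for the allocation algorithms
#'
#' Four reference cohorts spanning the axes that matter for batch
#' allocation: treatment-size balance, problem size, and batch size relative
#' to the number of treatments. None can be simplified by preallocation.
#' \describe{
#'   \item{A}{five treatments of 6 subjects, batches of 3 (10 batches); the
#'     optimum is the unreduced balanced incomplete-block design.}
#'   \item{B}{ten treatments of 10 subjects, batches of 5 (20 batches); a
#'     balanced design does not exist for these sizes.}
#'   \item{C}{five treatments of 6, 7, 8, 8, 9 subjects, batches of 3
#'     (thirteen batches, the last of size 2); small but imbalanced.}
#'   \item{D}{ten treatments of 5, 5, 8, 8, 10, 10, 12, 12, 15, 15 subjects,
#'     batches of 5 (20 batches); large and imbalanced.}
#' }
#'
#' @param setting `"A"`, `"B"`, `"C"` or `"D"`.
#' @return An [allocation_problem()].
#' @export
design_setting <- function(setting = c("A", "B", "C", "D")) {
  setting <- match.arg(setting)
  def <- switch(setting,
    A = list(t = rep(6L, 5), max = 3L),
    B = list(t = rep(10L, 10), max = 5L),
    C = list(t = c(6L, 7L, 8L, 8L, 9L), max = 3L),
    D = list(t = c(5L, 5L, 8L, 8L, 10L, 10L, 12L, 12L, 15L, 15L), max = 5L)
  )
  treatments <- stats::setNames(def$t, LETTERS[seq_along(def$t)])
  allocation_problem(treatments, max_batch_size = def$max)
}

allocator <- function(algorithm) {
  switch(algorithm, sba = sba_allocate, rba = rba_allocate,
         stop("unknown algorithm: ", algorithm, call. = FALSE))
}

#' Best allocation out of n attempts
#'
#' Runs the chosen algorithm `n` times with seeds derived from the master
#' seed and keeps the allocation with the highest D-criterion (earliest
#' among exact ties).
#'
#' @param problem An [allocation_problem()].
#' @param algorithm `"sba"` or `"rba"`.
#' @param n Number of allocations.
#' @param seed Master seed from which the `n` allocation seeds are derived.
#' @return A [scored_allocation()], with `run_index` set to the index of the
#'   winning allocation.
#' @export
best_of_n <- function(problem, algorithm = c("sba", "rba"), n, seed) {
  algorithm <- match.arg(algorithm)
  fn <- allocator(algorithm)
  seeds <- derive_seeds(seed, n)
  best <- NULL
  for (i in seq_len(n)) {
    alloc <- fn(problem, seeds[i])
    if (is.null(best) || compare_scores(alloc$d_exact, best$d_exact) > 0L) {
      best <- alloc
      best$run_index <- i
    }
  }
  best
}

#' Multi-run evaluation of an allocation algorithm
#'
#' The evaluation design: `n_runs` independent runs, each run producing
#' `n_alloc` allocations and keeping the best by D-criterion. The report
#' carries every allocation score (as exact digit strings), the per-run
#' bests, and summary fractions; with heavily recurring scores the per-run
#' best distribution concentrates on a handful of values.
#'
#' @inheritParams best_of_n
#' @param n_runs,n_alloc Number of runs and allocations per run.
#' @param reference_score Optional exact score (digit string); when given,
#'   the report includes the fraction of all allocations attaining it.
#' @param setting Optional label stored in the report.
#' @param keep_scores Keep the full per-allocation score vector (default) or
#'   only the per-run bests.
#' @return An object of class `experiment_report`.
#' @export
run_experiment <- function(problem, algorithm = c("sba", "rba"),
                           n_runs, n_alloc, seed,
                           reference_score = NULL, setting = NA_character_,
                           keep_scores = TRUE) {
  algorithm <- match.arg(algorithm)
  fn <- allocator(algorithm)
  seeds <- derive_seeds(seed, n_runs * n_alloc)
  scores <- character(if (keep_scores) n_runs * n_alloc else 0L)
  run_best <- character(n_runs)
  n_confounded <- 0L
  n_at_ref <- 0L
  idx <- 0L
  for (r in seq_len(n_runs)) {
    best <- NULL
    for (i in seq_len(n_alloc)) {
      idx <- idx + 1L
      alloc <- fn(problem, seeds[idx])
      if (alloc$confounded) n_confounded <- n_confounded + 1L
      if (!is.null(reference_score) &&
          compare_scores(alloc$d_exact, reference_score) == 0L) {
        n_at_ref <- n_at_ref + 1L
      }
      if (keep_scores) scores[idx] <- alloc$d_exact
      if (is.null(best) || compare_scores(alloc$d_exact, best) > 0L) {
        best <- alloc$d_exact
      }
    }
    run_best[r] <- best
  }
  structure(
    list(setting = setting, algorithm = algorithm,
         n_runs = n_runs, n_alloc = n_alloc, seed = seed,
         scores = if (keep_scores) scores else NULL,
         run_best = run_best,
         n_confounded = n_confounded,
         reference_score = reference_score,
         fraction_at_reference = if (is.null(reference_score)) NA_real_
                                 else n_at_ref / (n_runs * n_alloc),
         median_run_best = median_score(run_best)),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment report: %s, %d runs x %d allocations (seed %d)\n",
              x$algorithm, x$n_runs, x$n_alloc, x$seed))
  if (!is.na(x$setting)) cat("  setting:", x$setting, "\n")
  cat("  median per-run best D:", x$median_run_best, "\n")
  cat("  confounded allocations:", x$n_confounded, "\n")
  if (!is.null(x$reference_score)) {
    cat(sprintf("  fraction of allocations at reference score %s: %.4f\n",
                x$reference_score, x$fraction_at_reference))
  }
  tab <- sort(table(x$run_best), decreasing = TRUE)
  cat("  per-run best score frequencies:\n")
  for (i in seq_len(min(5L, length(tab)))) {
    cat(sprintf("    %s: %d\n", names(tab)[i], tab[[i]]))
  }
  invisible(x)
}

#' Run the heuristic until the score stops improving
#'
#' The stopping rule for settings where exhaustive search is impractical:
#' keep drawing allocations and stop once `patience_x` consecutive
#' allocations have failed to improve on the incumbent best score.
#'
#' @param problem An [allocation_problem()].
#' @param patience_x Number of consecutive non-improving allocations that
#'   ends the search (trade-off between time spent and the chance of a
#'   further improvement).
#' @param seed Master seed.
#' @param algorithm `"sba"` (default) or `"rba"`.
#' @return The incumbent [scored_allocation()]; its `run_index` is the
#'   iteration that produced it.
#' @export
run_until_stable <- function(problem, patience_x, seed,
                             algorithm = c("sba", "rba")) {
  algorithm <- match.arg(algorithm)
  stopifnot(patience_x >= 1L)
  fn <- allocator(algorithm)
  # seeds drawn in blocks so the total need not be known in advance
  block <- max(patience_x, 256L)
  seeds <- derive_seeds(seed, block)
  incumbent <- NULL
  stale <- 0L
  i <- 0L
  while (is.null(incumbent) || stale < patience_x) {
    i <- i + 1L
    if (i > length(seeds)) {
      seeds <- c(seeds, derive_seeds(seeds[length(seeds)], block))
    }
    alloc <- fn(problem, seeds[i])
    if (is.null(incumbent) ||
        compare_scores(alloc$d_exact, incumbent$d_exact) > 0L) {
      incumbent <- alloc
      incumbent$run_index <- i
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
  }
  incumbent
}

#' Tidy per-allocation table of an experiment report
#'
#' @param report An `experiment_report` built with `keep_scores = TRUE`.
#' @return A data frame with one row per allocation: `run`, `allocation`,
#'   `score` (exact digit string), `score_num` (double approximation).
#' @export
report_table <- function(report) {
  stopifnot(!is.null(report$scores))
  data.frame(
    run = rep(seq_len(report$n_runs), each = report$n_alloc),
    allocation = rep(seq_len(report$n_alloc), report$n_runs),
    score = report$scores,
    score_num = as.numeric(report$scores),
    stringsAsFactors = FALSE
  )
}
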