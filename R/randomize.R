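#' Randomize the order of the batches
#'
#' Premultiplies the incidence matrix by a random permutation matrix (i.e.
#' shuffles its rows). Batch identity is arbitrary until processing order is
#' fixed, and the D-criterion is invariant under row permutations, so this
#' step costs nothing and removes any structure the allocation order left
#' behind.
#'
#' @param incidence B x T incidence matrix.
#' @param seed Integer seed.
#' @return The incidence matrix with rows permuted.
#' @export
permute_batches <- function(incidence, seed) {
  set.seed(seed)
  incidence[sample.int(nrow(incidence)), , drop = FALSE]
}

#' Read and validate a sample manifest
#'
#' A manifest is a CSV with columns `sample_id` and `treatment`, one row per
#' collected sample.
#'
#' @param path CSV file path.
#' @return A data frame with character columns `sample_id`, `treatment`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  if (!all(c("sample_id", "treatment") %in% names(m))) {
    stop("manifest must have columns sample_id, treatment", call. = FALSE)
  }
  if (anyDuplicated(m$sample_id)) {
    stop("duplicate sample_id in manifest", call. = FALSE)
  }
  m[c("sample_id", "treatment")]
}

#' Randomly assign named samples to the slots of an allocation
#'
#' The incidence matrix reserves, per batch, a number of slots for each
#' treatment; which concrete sample fills which slot is exchangeable. Within
#' every treatment, samples are assigned to that treatment's slots uniformly
#' at random.
#'
#' @param incidence B x T incidence matrix with treatment labels as column
#'   names.
#' @param manifest Data frame with columns `sample_id`, `treatment`; the
#'   per-treatment counts must match the incidence column sums.
#' @param seed Integer seed.
#' @return A processing plan: data frame with columns `sample_id`,
#'   `treatment`, `batch`, `position` (1-based; positions are initially in
#'   slot order, see [order_within_batches()]).
#' @export
assign_subjects <- function(incidence, manifest, seed) {
  labels <- colnames(incidence)
  if (is.null(labels)) labels <- paste0("T", seq_len(ncol(incidence)))
  counts <- colSums(incidence)
  have <- table(factor(manifest$treatment, levels = labels))
  if (!all(have == counts)) {
    bad <- labels[which(have != counts)]
    stop(sprintf("manifest counts disagree with the allocation for: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (!all(manifest$treatment %in% labels)) {
    stop("manifest contains treatments unknown to the allocation",
         call. = FALSE)
  }
  set.seed(seed)
  plan <- NULL
  for (j in seq_along(labels)) {
    ids <- manifest$sample_id[manifest$treatment == labels[j]]
    ids <- ids[sample.int(length(ids))]
    batches <- rep(seq_len(nrow(incidence)), times = incidence[, j])
    plan <- rbind(plan, data.frame(sample_id = ids, treatment = labels[j],
                                   batch = batches,
                                   stringsAsFactors = FALSE))
  }
  plan <- plan[order(plan$batch), ]
  plan$position <- stats::ave(seq_len(nrow(plan)), plan$batch,
                              FUN = seq_along)
  rownames(plan) <- NULL
  plan
}

#' Randomize the processing order within each batch
#'
#' Permutes `position` uniformly and independently per batch; batch
#' compositions are untouched.
#'
#' @param plan A processing plan from [assign_subjects()].
#' @param seed Integer seed.
#' @return The plan with shuffled `position`, sorted by batch and position.
#' @export
order_within_batches <- function(plan, seed) {
  set.seed(seed)
  for (k in unique(plan$batch)) {
    idx <- which(plan$batch == k)
    plan$position[idx] <- sample.int(length(idx))
  }
  plan <- plan[order(plan$batch, plan$position), ]
  rownames(plan) <- NULL
  plan
}

#' Full processing plan for a sample manifest
#'
#' Runs the complete pipeline: allocate (best of `best_of` attempts),
#' randomize batch order, assign samples to slots, and randomize the
#' within-batch processing order. Each randomization step gets its own seed
#' derived from the master seed.
#'
#' @param problem An [allocation_problem()] whose treatment labels and counts
#'   match the manifest.
#' @param manifest Data frame from [read_manifest()].
#' @param seed Master seed.
#' @param algorithm `"sba"` or `"rba"`.
#' @param best_of Number of allocations to draw before keeping the best.
#' @return A list with fields `plan` (the processing-plan data frame),
#'   `allocation` (the winning [scored_allocation()], rows in randomized
#'   batch order) and `provenance` (seeds, algorithm, scores).
#' @export
make_plan <- function(problem, manifest, seed, algorithm = c("sba", "rba"),
                      best_of = 1000L) {
  algorithm <- match.arg(algorithm)
  step_seeds <- derive_seeds(seed, 4L)
  best <- best_of_n(problem, algorithm, n = best_of, seed = step_seeds[1])
  inc <- permute_batches(best$incidence, step_seeds[2])
  plan <- assign_subjects(inc, manifest, step_seeds[3])
  plan <- order_within_batches(plan, step_seeds[4])
  list(
    plan = plan,
    allocation = best,
    provenance = list(algorithm = algorithm, master_seed = seed,
                      step_seeds = step_seeds, best_of = best_of,
                      d_score = best$d_exact, confounded = best$confounded)
  )
}

# incidence matrix implied by a processing plan (for conservation checks)
plan_incidence <- function(plan, treatment_labels) {
  batches <- sort(unique(plan$batch))
  N <- matrix(0L, length(batches), length(treatment_labels),
              dimnames = list(NULL, treatment_labels))
  for (r in seq_len(nrow(plan))) {
    k <- match(plan$batch[r], batches)
    j <- match(plan$treatment[r], treatment_labels)
    N[k, j] <- N[k, j] + 1L
  }
  N
}
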