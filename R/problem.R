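#' Define a batch-allocation problem
#'
#' An allocation problem fixes the cohort (how many subjects received each
#' treatment) and the batch structure (how many subjects each processing batch
#' holds). The cohort must fit the batches exactly: partially filled batches
#' are rejected rather than silently padded.
#'
#' @param treatments Either a named integer vector of per-treatment subject
#'   counts (names become the treatment labels), or an unnamed integer vector
#'   (labels default to `T1, T2, ...`).
#' @param batch_sizes Integer vector of batch sizes. Exactly one of
#'   `batch_sizes` and `max_batch_size` must be given.
#' @param max_batch_size Scalar maximum batch size; batch sizes are derived
#'   with [derive_batch_sizes()].
#'
#' @return An object of class `allocation_problem` with fields
#'   `treatment_labels`, `t` (per-treatment counts) and `b` (batch sizes).
#' @examples
#' # five treatment arms of six subjects each, processed in batches of three
#' allocation_problem(c(A = 6, B = 6, C = 6, D = 6, E = 6), max_batch_size = 3)
#' @export
allocation_problem <- function(treatments, batch_sizes = NULL,
                               max_batch_size = NULL) {
  if (is.null(batch_sizes) == is.null(max_batch_size)) {
    stop("give exactly one of `batch_sizes` or `max_batch_size`", call. = FALSE)
  }
  t <- as.integer(treatments)
  labels <- names(treatments)
  if (is.null(labels)) labels <- paste0("T", seq_along(t))
  if (is.null(batch_sizes)) {
    batch_sizes <- derive_batch_sizes(sum(t), max_batch_size)
  }
  problem <- structure(
    list(treatment_labels = labels, t = t, b = as.integer(batch_sizes)),
    class = "allocation_problem"
  )
  validate_problem(problem)
}

#' Derive batch sizes from a scalar maximum
#'
#' Splits `total_subjects` into `ceiling(total_subjects / max_batch_size)`
#' batches of near-equal size (differing by at most one), larger batches
#' first, each no larger than `max_batch_size`.
#'
#' @param total_subjects Total number of subjects (positive integer).
#' @param max_batch_size Maximum number of subjects per batch (positive
#'   integer).
#' @return Integer vector of batch sizes summing to `total_subjects`.
#' @examples
#' derive_batch_sizes(44, 8) # 8 8 7 7 7 7
#' @export
derive_batch_sizes <- function(total_subjects, max_batch_size) {
  total_subjects <- as.integer(total_subjects)
  max_batch_size <- as.integer(max_batch_size)
  stopifnot(length(total_subjects) == 1L, length(max_batch_size) == 1L,
            total_subjects >= 1L, max_batch_size >= 1L)
  n_batches <- (total_subjects + max_batch_size - 1L) %/% max_batch_size
  base <- total_subjects %/% n_batches
  n_large <- total_subjects - base * n_batches
  sizes <- rep(base, n_batches)
  if (n_large > 0L) sizes[seq_len(n_large)] <- base + 1L
  sizes
}

#' Validate an allocation problem
#'
#' Checks the problem invariants: at least two treatments, positive counts and
#' batch sizes, unique labels, and the exact-fit requirement
#' `sum(t) == sum(b)`.
#'
#' @param problem An `allocation_problem`.
#' @return The problem, unchanged, if valid; otherwise an error is thrown.
#' @export
validate_problem <- function(problem) {
  stopifnot(inherits(problem, "allocation_problem"))
  t <- problem$t
  b <- problem$b
  labels <- problem$treatment_labels
  if (length(t) < 2L) stop("need at least two treatments", call. = FALSE)
  if (length(b) < 1L) stop("need at least one batch", call. = FALSE)
  if (length(labels) != length(t)) {
    stop("treatment_labels and t differ in length", call. = FALSE)
  }
  if (anyDuplicated(labels)) stop("duplicate treatment labels", call. = FALSE)
  if (any(is.na(t)) || any(t < 1L)) {
    stop("all treatment counts must be >= 1", call. = FALSE)
  }
  if (any(is.na(b)) || any(b < 1L)) {
    stop("all batch sizes must be >= 1", call. = FALSE)
  }
  if (sum(t) != sum(b)) {
    stop(sprintf("size mismatch: sum(t) = %d but sum(b) = %d (exact fit required)",
                 sum(t), sum(b)), call. = FALSE)
  }
  problem
}

#' @export
print.allocation_problem <- function(x, ...) {
  cat("Batch allocation problem\n")
  cat("  treatments:", paste0(x$treatment_labels, " (", x$t, ")",
                              collapse = ", "), "\n")
  cat("  batches:   ", length(x$b), "with sizes",
      paste(x$b, collapse = " "), "\n")
  invisible(x)
}

#' Read an allocation problem from a YAML or JSON config
#'
#' The config must contain a `treatments` mapping from label to subject count
#' and either `batch_sizes` (a list) or `max_batch_size` (a scalar).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `allocation_problem`.
#' @export
read_problem <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$treatments)) stop("config lacks `treatments`", call. = FALSE)
  treatments <- unlist(cfg$treatments)
  allocation_problem(treatments,
                     batch_sizes = cfg$batch_sizes,
                     max_batch_size = cfg$max_batch_size)
}
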