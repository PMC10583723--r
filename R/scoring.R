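#' Build the design matrix of the intercept + treatment + batch model
#'
#' One row per subject, in canonical order (batch-major, treatment-minor;
#' the information matrix is invariant to row order). Columns are an
#' intercept, `T - 1` treatment indicators (first treatment is the reference
#' level) and `B - 1` batch indicators (first batch is the reference level).
#' A full set of indicators plus intercept would be singular for any
#' allocation, so one level of each factor must be dropped; which one is
#' dropped does not affect the D-criterion (see [d_criterion()]).
#'
#' @param incidence B x T incidence matrix (batches in rows, treatments in
#'   columns; entries count subjects).
#' @return A `sum(incidence)` x `(1 + (T-1) + (B-1))` 0/1 matrix.
#' @export
build_design_matrix <- function(incidence) {
  B <- nrow(incidence)
  T_ <- ncol(incidence)
  n <- sum(incidence)
  p <- 1L + (T_ - 1L) + (B - 1L)
  X <- matrix(0, n, p)
  X[, 1L] <- 1
  row <- 0L
  for (k in seq_len(B)) {
    for (j in seq_len(T_)) {
      m <- incidence[k, j]
      if (m > 0) {
        idx <- row + seq_len(m)
        if (j > 1L) X[idx, j] <- 1
        if (k > 1L) X[idx, T_ - 1L + k] <- 1
        row <- row + m
      }
    }
  }
  X
}

# information matrix X^T X assembled directly from the incidence matrix
# (identical to crossprod(build_design_matrix(incidence)), but O(p^2))
information_matrix <- function(incidence) {
  B <- nrow(incidence)
  T_ <- ncol(incidence)
  t <- colSums(incidence)
  b <- rowSums(incidence)
  p <- 1L + (T_ - 1L) + (B - 1L)
  M <- matrix(0, p, p)
  M[1L, 1L] <- sum(t)
  if (T_ > 1L) {
    jt <- 2L:T_
    M[1L, jt] <- M[jt, 1L] <- t[jt]
    M[cbind(jt, jt)] <- t[jt]
  }
  if (B > 1L) {
    kb <- 2L:B
    cb <- T_ - 1L + kb
    M[1L, cb] <- M[cb, 1L] <- b[kb]
    M[cbind(cb, cb)] <- b[kb]
    if (T_ > 1L) {
      M[2L:T_, cb] <- t(incidence[kb, 2L:T_, drop = FALSE])
      M[cb, 2L:T_] <- incidence[kb, 2L:T_, drop = FALSE]
    }
  }
  M
}

#' D-criterion of an allocation
#'
#' The determinant of the information matrix `X^T X` of the intercept +
#' treatment + batch model, computed in exact integer arithmetic (residues
#' modulo a set of 31-bit primes combined by the Chinese remainder theorem),
#' so that scores compare exactly even when they exceed the 53-bit precision
#' of a double. A zero determinant means treatment and batch effects are
#' confounded. Scores order allocations within one problem; they are not
#' comparable across problems. The determinant is invariant under relabeling
#' of batches or treatments: row permutations of `X^T X` and reference-level
#' changes are unimodular reparameterizations.
#'
#' @param incidence B x T incidence matrix.
#' @param exact If `TRUE`, return the exact value as a decimal digit string;
#'   otherwise return it as a double (exact whenever it fits in 53 bits).
#' @return Nonnegative numeric, or a digit string when `exact = TRUE`.
#' @examples
#' # a single batch holding one subject of each of two treatments
#' d_criterion(matrix(c(1, 1), 1, 2)) # det of [[2,1],[1,1]] = 1
#' @export
d_criterion <- function(incidence, exact = FALSE) {
  res <- det_exact_cpp(information_matrix(incidence))
  if (exact) res$digits else res$value
}

#' Is an allocation confounded?
#'
#' `TRUE` when the information matrix is singular, i.e. the D-criterion is
#' exactly zero and not all treatment and batch effects are estimable.
#'
#' @param incidence B x T incidence matrix.
#' @return Logical scalar.
#' @export
is_confounded <- function(incidence) {
  identical(d_criterion(incidence, exact = TRUE), "0")
}

#' Variances of the simple treatment contrasts
#'
#' For every unordered pair of treatments, the variance of the estimated
#' difference between their effects under the intercept + treatment + batch
#' model, read from the inverse information matrix. The common error
#' variance is taken as 1, so values are meaningful relative to each other
#' (and across allocations of the same problem), not in absolute units.
#'
#' @param incidence B x T non-confounded incidence matrix.
#' @return Named numeric vector of length `T (T - 1) / 2`, names `"i-j"` from
#'   the incidence column names (or indices).
#' @examples
#' contrast_variances(matrix(c(3, 3), 1, 2)) # one batch: 1/3 + 1/3
#' @export
contrast_variances <- function(incidence) {
  if (is_confounded(incidence)) {
    stop("allocation is confounded: information matrix is singular",
         call. = FALSE)
  }
  T_ <- ncol(incidence)
  V <- solve(information_matrix(incidence))
  labels <- colnames(incidence)
  if (is.null(labels)) labels <- as.character(seq_len(T_))
  out <- numeric(0)
  for (i in seq_len(T_ - 1L)) {
    for (j in (i + 1L):T_) {
      # treatment j (j >= 2) is parameter column j; treatment 1 is the reference
      v <- if (i == 1L) V[j, j] else V[i, i] + V[j, j] - 2 * V[i, j]
      out <- c(out, structure(v, names = paste0(labels[i], "-", labels[j])))
    }
  }
  out
}

#' Scored allocation
#'
#' Couples an incidence matrix with its exact D-criterion score, the
#' confounding flag, and provenance (algorithm, seed, run index).
#'
#' @param incidence B x T incidence matrix.
#' @param problem Optional [allocation_problem()] for label/consistency checks.
#' @param seed,algorithm,run_index Provenance, stored as given.
#' @return An object of class `scored_allocation` with fields `incidence`,
#'   `d_score` (double), `d_exact` (digit string), `confounded`, `seed`,
#'   `algorithm`, `run_index`.
#' @export
scored_allocation <- function(incidence, problem = NULL, seed = NA_integer_,
                              algorithm = NA_character_,
                              run_index = NA_integer_) {
  if (!is.null(problem)) {
    if (ncol(incidence) != length(problem$t) ||
        nrow(incidence) != length(problem$b) ||
        any(colSums(incidence) != problem$t) ||
        any(rowSums(incidence) != problem$b)) {
      stop("incidence matrix does not match the problem's counts",
           call. = FALSE)
    }
  }
  res <- det_exact_cpp(information_matrix(incidence))
  structure(
    list(incidence = incidence, d_score = res$value, d_exact = res$digits,
         confounded = identical(res$digits, "0"), seed = seed,
         algorithm = algorithm, run_index = run_index),
    class = "scored_allocation"
  )
}

#' @export
print.scored_allocation <- function(x, ...) {
  cat(sprintf("Scored allocation (%s, seed %s): D = %s%s\n",
              x$algorithm, x$seed, x$d_exact,
              if (x$confounded) " [CONFOUNDED]" else ""))
  print(x$incidence)
  invisible(x)
}

#' Compare two exact D-criterion scores
#'
#' Scores are exact nonnegative integers carried as decimal digit strings;
#' this compares them without loss of precision.
#'
#' @param a,b Digit strings (vectors recycle as usual).
#' @return Integer vector: -1 where `a < b`, 0 where equal, 1 where `a > b`.
#' @export
compare_scores <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- integer(n)
  la <- nchar(a)
  lb <- nchar(b)
  out[la < lb] <- -1L
  out[la > lb] <- 1L
  eq <- la == lb
  out[eq & a < b] <- -1L
  out[eq & a > b] <- 1L
  out
}

# order statistics over exact scores: indices that sort ascending
order_scores <- function(x) order(nchar(x), x)

# lower-middle order statistic (type-1 median): with heavily recurring
# scores the two middle values coincide in practice
median_score <- function(x) {
  x[order_scores(x)][ceiling(length(x) / 2)]
}
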