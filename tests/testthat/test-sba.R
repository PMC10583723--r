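make_state <- function(t_star, b_star, Lambda = NULL, N = NULL, k = 1L) {
  T_ <- length(t_star)
  B <- length(b_star)
  st <- new_allocation_state(list(t_star = t_star, b_star = b_star))
  if (!is.null(Lambda)) st$Lambda <- Lambda
  if (!is.null(N)) st$N <- N
  st$k <- k
  st
}

test_that("forced treatments are those whose count equals the remaining batches", {
  st <- make_state(c(1L, 2L, 2L), rep(2L, 3), k = 2L)
  expect_identical(forced_treatments(st), c(2L, 3L))
  st <- make_state(c(1L, 1L, 1L), rep(1L, 10), k = 1L)
  expect_identical(forced_treatments(st), integer(0))
})

test_that("an oversized forced set signals infeasibility", {
  st <- make_state(c(3L, 3L), c(1L, 2L, 3L), k = 1L)
  expect_error(forced_treatments(st), "infeasible")
  # one forced treatment fits in capacity one
  st <- make_state(c(3L, 1L), c(1L, 2L, 1L), k = 1L)
  expect_identical(forced_treatments(st), 1L)
})

test_that("never-chosen treatments have a zero concurrence diagonal", {
  L <- matrix(0L, 4, 4)
  L[1:2, 1:2] <- 1L
  st <- make_state(rep(1L, 4), rep(2L, 2), Lambda = L)
  expect_identical(never_chosen_treatments(st), c(3L, 4L))
  st$Lambda <- matrix(0L, 4, 4)
  expect_identical(never_chosen_treatments(st), 1:4)
  diag(st$Lambda) <- 1L
  expect_identical(never_chosen_treatments(st), integer(0))
})

test_that("never-chosen ignores treatments with nothing left to allocate", {
  st <- make_state(c(0L, 1L), c(1L), Lambda = matrix(0L, 2, 2))
  expect_identical(never_chosen_treatments(st), 2L)
})

test_that("seed_pair picks the minimal off-diagonal concurrence pair", {
  L <- matrix(0L, 3, 3)
  L[1, 2] <- L[2, 1] <- 2L
  L[1, 3] <- L[3, 1] <- 0L
  L[2, 3] <- L[3, 2] <- 1L
  diag(L) <- 5L # the diagonal (replication counts) must be ignored
  st <- make_state(rep(1L, 3), 2L, Lambda = L)
  set.seed(1)
  expect_identical(sort(seed_pair(st, 1:3)), c(1L, 3L))
  expect_error(seed_pair(st, 1L), "two candidate")
})

test_that("seed_pair breaks ties uniformly at random", {
  st <- make_state(rep(1L, 3), 2L)
  set.seed(42)
  picks <- replicate(600, paste(sort(seed_pair(st, 1:3)), collapse = "-"))
  tab <- table(picks)
  expect_setequal(names(tab), c("1-2", "1-3", "2-3"))
  expect_gt(chisq.test(tab)$p.value, 1e-6)
})

test_that("next_treatment minimizes the concurrence column sum", {
  L <- matrix(0L, 3, 3)
  L[1, 2] <- L[2, 1] <- 3L
  L[1, 3] <- L[3, 1] <- 1L
  st <- make_state(rep(1L, 3), 2L, Lambda = L)
  expect_identical(suppressWarnings(next_treatment(st, 1L, c(2L, 3L))), 3L)
  expect_identical(next_treatment(st, 1L, 2L), 2L)
})

test_that("next_treatment ties are uniform", {
  L <- matrix(2L, 4, 4)
  st <- make_state(rep(1L, 4), 2L, Lambda = L)
  set.seed(9)
  picks <- replicate(400, next_treatment(st, c(1L, 2L), c(3L, 4L)))
  tab <- table(picks)
  expect_setequal(names(tab), c("3", "4"))
  expect_gt(chisq.test(tab)$p.value, 1e-6)
})

test_that("allocate_batch fills forced treatments then completes the batch", {
  # two remaining subjects of treatment 1 over two batches force it into both
  set.seed(3)
  st <- make_state(c(2L, 1L), c(2L, 1L))
  st <- allocate_batch(st)
  expect_identical(st$N[1, ], c(1L, 1L))
  st <- allocate_batch(st)
  expect_identical(st$N[2, ], c(1L, 0L))
  expect_identical(st$t_star, c(0L, 0L))
})

test_that("allocate_batch updates Lambda and t_star after the whole batch", {
  pre <- preallocate(allocation_problem(rep(1, 5), batch_sizes = c(3, 2)))
  set.seed(5)
  st <- allocate_batch(new_allocation_state(pre))
  chosen <- which(st$N[1, ] == 1L)
  expect_length(chosen, 3)
  expect_true(all(st$Lambda[chosen, chosen] == 1L))
  expect_true(all(st$Lambda[-chosen, ] == 0L))
  expect_identical(st$t_star[chosen], rep(0L, 3))
  expect_identical(st$k, 2L)
})

test_that("a fully symmetric batch is a uniform random subset", {
  pre <- preallocate(allocation_problem(rep(1, 4), batch_sizes = c(2, 2)))
  set.seed(8)
  picks <- replicate(900, {
    st <- allocate_batch(new_allocation_state(pre))
    paste(which(st$N[1, ] == 1L), collapse = "-")
  })
  tab <- table(picks)
  expect_length(tab, 6) # all C(4,2) subsets occur
  expect_gt(chisq.test(tab)$p.value, 1e-6)
})

test_that("sba_allocate conserves row and column sums on random problems", {
  set.seed(31)
  for (i in 1:60) {
    p <- random_problem()
    alloc <- sba_allocate(p, seed = i)
    expect_valid_allocation(alloc, p)
    expect_true(all(alloc$incidence >= 0L))
  }
})

test_that("the binary remainder and Lambda = N^T N identity hold at termination", {
  set.seed(32)
  for (i in 1:25) {
    p <- random_problem()
    pre <- preallocate(p)
    set.seed(i * 7L)
    st <- new_allocation_state(pre)
    for (k in seq_along(pre$b_star)) st <- allocate_batch(st)
    expect_true(all(st$N %in% c(0L, 1L)))
    expect_equal(st$Lambda, crossprod(st$N), ignore_attr = TRUE)
    expect_true(all(colSums(st$N) == pre$t_star))
  }
})

test_that("identical seeds reproduce identical allocations, distinct seeds vary", {
  p <- design_setting("A")
  a1 <- sba_allocate(p, 123)
  a2 <- sba_allocate(p, 123)
  expect_identical(a1$incidence, a2$incidence)
  expect_identical(a1$d_exact, a2$d_exact)
  many <- vapply(1:20, function(s) paste(sba_allocate(p, s)$incidence,
                                         collapse = ""), character(1))
  expect_gt(length(unique(many)), 1)
})

test_that("compiled and reference engines produce identical allocations", {
  set.seed(33)
  for (i in 1:30) {
    p <- random_problem()
    expect_identical(sba_allocate(p, i, engine = "cpp")$incidence,
                     sba_allocate(p, i, engine = "r")$incidence)
    expect_identical(rba_allocate(p, i, engine = "cpp")$incidence,
                     rba_allocate(p, i, engine = "r")$incidence)
  }
  pD <- design_setting("D")
  expect_identical(sba_allocate(pD, 5, engine = "cpp")$incidence,
                   sba_allocate(pD, 5, engine = "r")$incidence)
})

test_that("a two-treatment, two-batch fit has the unique feasible allocation", {
  p <- allocation_problem(c(2, 2), batch_sizes = c(2, 2))
  expect_equal(sba_allocate(p, 1)$incidence,
               matrix(1L, 2, 2), ignore_attr = TRUE)
  expect_equal(rba_allocate(p, 1)$incidence,
               matrix(1L, 2, 2), ignore_attr = TRUE)
})
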