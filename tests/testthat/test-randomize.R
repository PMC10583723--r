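make_manifest <- function(problem) {
  data.frame(
    sample_id = sprintf("S%03d", seq_len(sum(problem$t))),
    treatment = rep(problem$treatment_labels, times = problem$t),
    stringsAsFactors = FALSE
  )
}

test_that("permute_batches preserves rows and the D-criterion", {
  p <- design_setting("A")
  inc <- sba_allocate(p, 81)$incidence
  perm <- permute_batches(inc, seed = 82)
  expect_identical(dim(perm), dim(inc))
  expect_identical(sort(apply(perm, 1, paste, collapse = "")),
                   sort(apply(inc, 1, paste, collapse = "")))
  expect_identical(d_criterion(perm, exact = TRUE),
                   d_criterion(inc, exact = TRUE))
  expect_identical(permute_batches(inc, 82), permute_batches(inc, 82))
  # single batch: nothing to permute
  one <- matrix(c(1L, 1L), 1, 2)
  expect_identical(permute_batches(one, 1), one)
})

test_that("assign_subjects builds a plan matching the incidence exactly", {
  p <- design_setting("A")
  inc <- sba_allocate(p, 83)$incidence
  manifest <- make_manifest(p)
  plan <- assign_subjects(inc, manifest, seed = 84)
  expect_identical(nrow(plan), 30L)
  expect_setequal(plan$sample_id, manifest$sample_id)
  expect_equal(plan_incidence <- batchalloc:::plan_incidence(plan, p$treatment_labels),
               inc, ignore_attr = TRUE)
  # positions are 1..b_k within each batch
  for (k in unique(plan$batch)) {
    expect_setequal(plan$position[plan$batch == k], seq_len(sum(inc[k, ])))
  }
})

test_that("assign_subjects rejects mismatched manifests", {
  p <- design_setting("A")
  inc <- sba_allocate(p, 85)$incidence
  manifest <- make_manifest(p)
  expect_error(assign_subjects(inc, manifest[-1, ], seed = 1), "disagree")
  bad <- manifest
  bad$treatment[1] <- "Z"
  expect_error(assign_subjects(inc, bad, seed = 1), "disagree|unknown")
})

test_that("subject assignment within a treatment is random but slot-consistent", {
  p <- allocation_problem(c(a = 2, b = 2), batch_sizes = c(2, 2))
  inc <- sba_allocate(p, 86)$incidence
  manifest <- data.frame(sample_id = c("x1", "x2", "y1", "y2"),
                         treatment = c("a", "a", "b", "b"))
  batches_of_x1 <- vapply(1:40, function(s) {
    pl <- assign_subjects(inc, manifest, seed = s)
    pl$batch[pl$sample_id == "x1"]
  }, integer(1))
  expect_setequal(unique(batches_of_x1), 1:2)
})

test_that("order_within_batches shuffles positions and conserves composition", {
  p <- design_setting("C")
  inc <- sba_allocate(p, 87)$incidence
  plan <- assign_subjects(inc, make_manifest(p), seed = 88)
  shuffled <- order_within_batches(plan, seed = 89)
  expect_setequal(shuffled$sample_id, plan$sample_id)
  expect_equal(batchalloc:::plan_incidence(shuffled, p$treatment_labels),
               inc, ignore_attr = TRUE)
  for (k in unique(shuffled$batch)) {
    expect_setequal(shuffled$position[shuffled$batch == k],
                    seq_len(sum(inc[k, ])))
  }
  expect_identical(order_within_batches(plan, 89), shuffled)
})

test_that("manifests round-trip through CSV with validation", {
  p <- design_setting("C")
  manifest <- make_manifest(p)
  path <- tempfile(fileext = ".csv")
  write.csv(manifest, path, row.names = FALSE)
  expect_identical(read_manifest(path), manifest)
  dup <- rbind(manifest, manifest[1, ])
  write.csv(dup, path, row.names = FALSE)
  expect_error(read_manifest(path), "duplicate")
})

test_that("make_plan runs the full pipeline and conserves everything", {
  p <- design_setting("C")
  manifest <- make_manifest(p)
  res <- make_plan(p, manifest, seed = 90, algorithm = "sba", best_of = 25)
  expect_setequal(res$plan$sample_id, manifest$sample_id)
  # the plan-implied incidence scores identically to the chosen allocation
  inc2 <- batchalloc:::plan_incidence(res$plan, p$treatment_labels)
  expect_identical(d_criterion(inc2, exact = TRUE),
                   res$allocation$d_exact)
  expect_identical(res$provenance$d_score, res$allocation$d_exact)
  # reproducible end to end
  res2 <- make_plan(p, manifest, seed = 90, algorithm = "sba", best_of = 25)
  expect_identical(res$plan, res2$plan)
})
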