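# Success curves, stratification, distinct set, enrichment.

fake_prediction <- function(records) {
  # records: query_id, best_rank, target (the known target)
  purrr::pmap(records, function(query_id, best_rank, target, n_targets) {
    others <- setdiff(sprintf("X%03d", seq_len(n_targets)), target)
    ranks <- seq_len(n_targets)
    tids <- character(n_targets)
    tids[best_rank] <- target
    tids[-best_rank] <- others[seq_len(n_targets - 1)]
    tibble::tibble(query_id = query_id, rank = ranks, target_id = tids,
                   probability = 1 - ranks / (n_targets + 1),
                   score3d = 0.5, score2d = 0.5,
                   best_3d_active_id = NA_character_,
                   best_2d_active_id = NA_character_)
  }) |> dplyr::bind_rows()
}

test_that("success at rank counts best ranks against cutoffs", {
  rec <- tibble::tibble(query_id = letters[1:4], best_rank = c(1, 3, 20, 2))
  curve <- success_at_rank(rec, c(1, 5, 100))
  expect_equal(curve$success, c(25, 75, 100))
  expect_true(all(diff(curve$success) >= 0))  # monotone
  all1 <- success_at_rank(tibble::tibble(query_id = "q", best_rank = 1), 1)
  expect_equal(all1$success, 100)
  expect_error(success_at_rank(rec[0, ], 1), class = "revscreen_input_error")
})

test_that("evaluation records take the best rank over multiple known targets", {
  pred <- fake_prediction(tibble::tibble(
    query_id = c("q1", "q2"), best_rank = c(3, 1),
    target = c("T1", "T2"), n_targets = 10))
  truth <- tibble::tibble(query_id = c("q1", "q1", "q2"),
                          target_id = c("T1", "X005", "T2"))
  rec <- evaluation_records(pred, truth)
  # q1 knows T1 (rank 3) and X005 (some other rank): best of the two
  q1_ranks <- pred$rank[pred$query_id == "q1" &
                          pred$target_id %in% c("T1", "X005")]
  expect_equal(rec$best_rank[rec$query_id == "q1"], min(q1_ranks))
  expect_equal(rec$n_known[rec$query_id == "q1"], 2)
})

test_that("size-class curves partition the global curve", {
  set.seed(17)
  n <- 200
  rec <- tibble::tibble(query_id = sprintf("q%03d", 1:n),
                        best_rank = sample(1:50, n, replace = TRUE))
  sizes <- tibble::tibble(compound_id = rec$query_id,
                          heavy_atoms = sample(c(8, 25, 70), n, replace = TRUE))
  per_class <- success_by_size_class(rec, sizes, cutoffs = c(1, 5, 15))
  global <- success_at_rank(rec, c(1, 5, 15))
  # single-class input equals the global curve
  one <- success_by_size_class(rec, dplyr::mutate(sizes, heavy_atoms = 30),
                               cutoffs = c(1, 5, 15))
  expect_equal(one$success, global$success)
  # record-count weighted average of class successes recovers the global one
  for (cc in c(1, 5, 15)) {
    sub <- per_class[per_class$cutoff == cc, ]
    expect_equal(sum(sub$success * sub$n) / sum(sub$n),
                 global$success[global$cutoff == cc])
  }
})

test_that("knowledge stratification bins by the best-ranked known target", {
  pred <- fake_prediction(tibble::tibble(
    query_id = c("q1", "q2", "q3"), best_rank = c(1, 2, 1),
    target = c("T1", "T2", "T3"), n_targets = 20))
  truth <- tibble::tibble(query_id = c("q1", "q2", "q3"),
                          target_id = c("T1", "T2", "T3"))
  rec <- evaluation_records(pred, truth)
  screening <- tibble::tibble(
    target_id = c(rep("T1", 5), rep("T2", 50), rep("T3", 200)),
    compound_id = sprintf("a%03d", 1:255))
  strat <- stratify_by_target_knowledge(rec, screening,
                                        breaks = c(0, 10, 100, Inf),
                                        cutoffs = c(1, 5))
  expect_equal(nrow(strat), 6)  # 3 occupied bins x 2 cutoffs
  # all targets in one bin -> equals the global curve
  one_bin <- stratify_by_target_knowledge(rec, screening,
                                          breaks = c(0, Inf), cutoffs = 1)
  expect_equal(one_bin$success, success_at_rank(rec, 1)$success)
  expect_error(stratify_by_target_knowledge(rec, screening,
                                            breaks = c(0, 10, 5)),
               class = "revscreen_configuration_error")
})

test_that("scaffold-diversity stratification counts distinct non-empty scaffolds", {
  pred <- fake_prediction(tibble::tibble(
    query_id = c("q1", "q2"), best_rank = c(1, 4),
    target = c("T1", "T2"), n_targets = 10))
  truth <- tibble::tibble(query_id = c("q1", "q2"),
                          target_id = c("T1", "T2"))
  rec <- evaluation_records(pred, truth)
  screening <- tibble::tibble(
    target_id = c("T1", "T1", "T1", "T1", "T1", "T2", "T2"),
    compound_id = c("a1", "a2", "a3", "a4", "a5", "b1", "b2"))
  scaffolds <- tibble::tibble(
    compound_id = c("a1", "a2", "a3", "a4", "a5", "b1", "b2"),
    murcko = c("s1", "s1", "s2", "s3", "", "s1", "s1"),
    oprea = c("o1", "o1", "o1", "o2", "", "o1", "o1"))
  # T1 has 3 distinct murcko scaffolds (empty excluded), T2 has 1
  m <- stratify_by_scaffold_diversity(rec, screening, scaffolds, "murcko",
                                      breaks = c(0, 2, 10), cutoffs = 1)
  expect_equal(nrow(m), 2)
  o <- stratify_by_scaffold_diversity(rec, screening, scaffolds, "oprea",
                                      breaks = c(0, 2, 10), cutoffs = 1)
  # both stratifications cover every record
  expect_equal(sum(m$n), 2)
  expect_equal(sum(o$n), 2)
})

test_that("the distinct set requires both scaffolds to be novel", {
  training <- tibble::tibble(compound_id = c("t1", "t2"),
                             murcko = c("m1", "m2"),
                             oprea = c("o1", "o2"))
  test <- tibble::tibble(
    compound_id = c("shared_murcko", "shared_oprea", "both_novel", "both_shared"),
    murcko = c("m1", "m9", "m8", "m2"),
    oprea = c("o9", "o1", "o8", "o2"))
  expect_equal(build_distinct_test_set(test, training), "both_novel")
  expect_equal(build_distinct_test_set(training, training), character(0))
})

test_that("enrichment factors follow the rank-normalized definition", {
  expect_equal(enrichment_factor(100, 1000, 1000), 1)
  expect_equal(enrichment_factor(50, 1, 1000), 500)
  expect_error(enrichment_factor(50, 0, 10), class = "revscreen_input_error")
  # uniform random ranking -> EF about 1 at every cutoff
  set.seed(23)
  n_targets <- 100
  ranks <- sample(n_targets, 2e5, replace = TRUE)
  for (cc in c(1, 10, 50)) {
    succ <- 100 * mean(ranks <= cc)
    ef <- enrichment_factor(succ, cc, n_targets)
    expect_equal(ef, 1, tolerance = 0.1)
  }
})

test_that("random rankings match the 1/N baseline within 3 binomial SEs", {
  set.seed(29)
  n_targets <- 50
  n_queries <- 10000
  best_rank <- sample(n_targets, n_queries, replace = TRUE)
  succ1 <- mean(best_rank <= 1)
  p <- 1 / n_targets
  se <- sqrt(p * (1 - p) / n_queries)
  expect_lt(abs(succ1 - p), 3 * se)
})

test_that("success curves plot without error", {
  curve <- success_at_rank(tibble::tibble(query_id = letters[1:4],
                                          best_rank = c(1, 3, 20, 2)),
                           c(1, 5, 100))
  p <- ggplot2::autoplot(curve)
  expect_s3_class(p, "ggplot")
  strata <- tibble::tibble(bin = c("a", "a", "b", "b"),
                           cutoff = c(1, 5, 1, 5),
                           success = c(10, 20, 30, 40))
  expect_s3_class(plot_stratified_success(strata), "ggplot")
})
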