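toy_index <- function() {
  dataset_index(data.frame(
    structure_id = c("a1", "a2", "a3", "b1", "b2", "c1", "c2"),
    fold_id = c("FA", "FA", "FA", "FB", "FB", "FC", "FC"),
    superfamily_id = paste0("sf", 1:7),
    class_id = c("a", "a", "a", "b", "b", "a/b", "a/b")))
}

test_that("pair sets: within-fold positives, representative negatives", {
  ps <- build_pair_sets(toy_index(), "FA")
  expect_equal(nrow(ps$positives), 3L)       # C(3,2)
  expect_equal(nrow(ps$negatives), 4L)       # a1 vs the 4 foreign structures
  expect_true(all(ps$negatives$query_id == "a1"))
  ps2 <- build_pair_sets(toy_index(), "FB")
  expect_equal(nrow(ps2$positives), 1L)
  expect_error(build_pair_sets(toy_index(), "FD"))
  one_fold <- dataset_index(data.frame(
    structure_id = c("x1", "x2"), fold_id = "F", superfamily_id = c("s1", "s2"),
    class_id = "a"))
  expect_error(build_pair_sets(one_fold, "F"), "negatives")
})

test_that("roc_curve worked examples", {
  expect_equal(roc_curve(c(0.9, 0.8), c(0.1, 0.2))$auc, 1.0)
  expect_equal(roc_curve(rep(0.5, 3), rep(0.5, 4))$auc, 0.5)
  expect_equal(roc_curve(c(0.9, 0.4), c(0.6, 0.1))$auc, 0.75)
  expect_error(roc_curve(numeric(0), 1), "required")
})

test_that("roc_curve equals the Mann-Whitney oracle with ties", {
  set.seed(99)
  for (rep in 1:200) {
    pos <- sample(seq(0, 1, 0.1), sample(1:8, 1L), replace = TRUE)
    neg <- sample(seq(0, 1, 0.1), sample(1:8, 1L), replace = TRUE)
    curve <- roc_curve(pos, neg)
    expect_equal(curve$auc, brute_mw_auc(pos, neg))
    expect_true(all(diff(curve$points[, "fpr"]) >= 0))
    expect_true(all(diff(curve$points[, "tpr"]) >= 0))
    expect_equal(curve$points[1L, ], c(fpr = 0, tpr = 0))
    expect_equal(curve$points[nrow(curve$points), ], c(fpr = 1, tpr = 1))
  }
})

test_that("average_roc: identity, idempotence and analytic mean", {
  set.seed(4)
  c1 <- roc_curve(c(0.9, 0.8, 0.7), c(0.1, 0.2, 0.3))  # auc 1
  c2 <- roc_curve(rep(0.5, 3), rep(0.5, 3))            # auc 0.5 (diagonal)
  expect_equal(average_roc(list(c1))$auc, c1$auc, tolerance = 1e-3)
  expect_equal(average_roc(list(c2, c2, c2))$auc, 0.5, tolerance = 1e-10)
  expect_equal(average_roc(list(c1, c2))$auc, 0.75, tolerance = 1e-3)
  mixed <- roc_curve(c(0.9, 0.4), c(0.6, 0.1))
  expect_equal(average_roc(list(mixed, mixed))$auc, mixed$auc,
               tolerance = 1e-3)
})

test_that("best_definition_per_fold counts ties and applies the filter", {
  tab <- data.frame(
    fold_id = c("F1", "F1", "F2", "F2", "F3", "F3"),
    definition = c("CB_6.5", "CA_7", "CB_6.5", "CA_7", "CB_6.5", "CA_7"),
    auc = c(0.85, 0.70, 0.80, 0.80, 0.65, 0.60))
  counts <- best_definition_per_fold(tab, min_auc = 0.7)
  expect_equal(counts[["CB_6.5"]], 2L)   # F1 unique best + F2 tie
  expect_equal(counts[["CA_7"]], 1L)     # F2 tie; F3 filtered out (< 0.7)
  none <- best_definition_per_fold(tab[tab$fold_id == "F3", ], 0.7)
  expect_length(none, 0L)
})

test_that("best_tmscore_by_rank applies the tie rule and running max", {
  r <- best_tmscore_by_rank(c(0.9, 0.5), c(0.8, 0.3))
  expect_equal(r$best_tm, c(0.8, 0.8))
  r2 <- best_tmscore_by_rank(c(0.5, 0.5), c(0.2, 0.6))
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$best_tm, 0.4)
  set.seed(2)
  r3 <- best_tmscore_by_rank(runif(30), runif(30))
  expect_true(all(diff(r3$best_tm) >= 0))
  expect_true(all(diff(r3$fcc) <= 0))
})

test_that("run_retrieval on the synthetic benchmark separates folds", {
  bm <- make_benchmark(n_folds = 3L, members_per_fold = 3L, seed = 311L)
  res <- run_retrieval(bm$index, bm$structures, bm$alignments,
                       list(contact_definition("CB", 6.5)))
  expect_gt(res$summary$avg_auc, 0.9)
  expect_equal(nrow(res$auc_table), 3L)
  # restricting to one class drops the other folds
  res_b <- run_retrieval(bm$index, bm$structures, bm$alignments,
                         list(contact_definition("CB", 6.5)),
                         class_filter = "b")
  expect_lt(nrow(res_b$auc_table), nrow(res$auc_table))
  expect_error(run_retrieval(bm$index, bm$structures, bm$alignments,
                             list(contact_definition("CB", 6.5)),
                             class_filter = "other"), "no groups")
})

test_that("separation binning and superfamily level are wired through", {
  bm <- make_benchmark(n_folds = 2L, members_per_fold = 2L, seed = 17L)
  res <- run_retrieval(bm$index, bm$structures, bm$alignments,
                       list(contact_definition("CB", 6.5)),
                       separation_bin = c(5, 10))
  expect_true(is.finite(res$summary$avg_auc))
  # superfamily level: every superfamily here is a singleton, so no group
  # has two members and retrieval is undefined
  expect_error(run_retrieval(bm$index, bm$structures, bm$alignments,
                             list(contact_definition("CB", 6.5)),
                             level = "superfamily_id"),
               "at least 2 members")
})

test_that("occupancy_auc_profile sorts by occupancy without gaps", {
  bm <- make_benchmark(n_folds = 2L, members_per_fold = 2L, seed = 23L)
  defs <- definition_grid(cutoffs = c(6.5, 12))
  res <- run_retrieval(bm$index, bm$structures, bm$alignments, defs)
  prof <- occupancy_auc_profile(res$summary)
  expect_equal(nrow(prof), length(defs))
  expect_true(all(diff(prof$mean_occupancy) >= 0))
  expect_setequal(prof$base, c("CA", "CB", "HEAVY"))
})

test_that("dataset index TSV round trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dataset_index(toy_index(), f)
  idx <- read_dataset_index(f)
  expect_equal(idx$entries, toy_index()$entries)
  expect_error(dataset_index(data.frame(
    structure_id = c("x", "x"), fold_id = "f", superfamily_id = "s",
    class_id = "a")), "duplicate")
})
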