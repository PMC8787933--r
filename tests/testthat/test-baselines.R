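test_that("grid search is exhaustive, reports in-grid parameters, and breaks ties first-in-grid", {
  sch <- small_schema()
  reg <- small_registry(200, seed = 1, noise = 0.1)
  x <- one_hot_encode(reg, sch, "decision")$matrix
  tr <- 1:150; va <- 151:200
  y <- reg$ca_performed

  one <- model_grid("decision_tree", list(maxdepth = 4, cp = 0.01))
  res <- grid_search(one, x[tr, ], y[tr], x[va, ], y[va])
  expect_identical(res$best_params$maxdepth, 4)
  expect_identical(nrow(res$all_results), 1L)

  g <- model_grid("xgboost", list(max_depth = c(2, 4), eta = 0.3,
                                  nrounds = c(20, 50)))
  res <- grid_search(g, x[tr, ], y[tr], x[va, ], y[va])
  expect_true(res$best_params$max_depth %in% c(2, 4))
  expect_true(res$best_params$nrounds %in% c(20, 50))
  # selection optimality: the reported best dominates every grid point
  expect_true(all(res$best_val_auroc >= res$all_results$val_auroc))
  expect_identical(res$best_val_auroc,
                   res$all_results$val_auroc[
                     which.max(res$all_results$val_auroc)])
  expect_error(model_grid("xgboost", list()), "non-empty")
  expect_error(grid_search(one, x[tr, ], rep(1, 150), x[va, ], y[va]),
               "single-class")
})

test_that("every classical family masters the separable toy registry", {
  sch <- small_schema()
  reg <- small_registry(300, seed = 5)
  x <- one_hot_encode(reg, sch, "decision")$matrix
  tr <- 1:200; va <- 201:300
  y <- reg$ca_performed
  for (family in names(default_grids())) {
    g <- model_grid(family, seed = 3)
    g$grid <- lapply(g$grid, function(v) v[seq_len(min(2, length(v)))])
    res <- grid_search(g, x[tr, ], y[tr], x[va, ], y[va])
    expect_gte(res$best_val_auroc, 0.95)
  }
})

test_that("the leaderboard covers all families and both tasks on identical splits, never touching held-out rows", {
  sch <- small_schema()
  reg <- small_registry(260, seed = 7, noise = 0.15)
  split <- split_data(reg, seed = 4)
  grids <- lapply(default_grids(seed = 2), function(g) {
    g$grid <- lapply(g$grid, function(v) v[1]); g
  })
  bundle <- train_efcn_pair(reg, sch, split_indices(split, "train"),
                            split_indices(split, "validation"),
                            quick_arch(), list(max_epochs = 4, patience = 4),
                            seed = 2)
  lb <- run_leaderboard(reg, sch, split, grids, bundle)
  expect_identical(nrow(lb), 18L)  # 8 classical + efcn, both tasks
  expect_setequal(unique(lb$family), c(names(grids), "efcn"))
  expect_setequal(unique(lb$task), c("decision", "survival"))
  expect_true(all(lb$val_auroc >= 0 & lb$val_auroc <= 1))
  used <- unlist(attr(lb, "used_indices"))
  expect_length(intersect(used, split_indices(split, "cohort_analysis")),
                0L)
})

test_that("label shuffling drives leaderboard AUROCs to chance", {
  sch <- small_schema()
  reg <- small_registry(600, seed = 9)
  set.seed(31)
  reg$ca_performed <- sample(reg$ca_performed)
  reg$outcome_class <- sample(reg$outcome_class)
  split <- split_data(reg, seed = 1)
  grids <- default_grids(seed = 5)[c("xgboost", "logistic")]
  grids <- lapply(grids, function(g) {
    g$grid <- lapply(g$grid, function(v) v[1]); g
  })
  lb <- run_leaderboard(reg, sch, split, grids)
  expect_true(all(lb$test_auroc > 0.35 & lb$test_auroc < 0.65))
})
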