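#' Classical-model grids for the comparison harness
#'
#' One grid per model family.  All classical families consume full
#' one-hot inputs; only the EFCN consumes index/embedding inputs.  The
#' boosting entries are both backed by the xgboost library with distinct
#' configurations: `"xgboost"` searches deeper trees, `"gradient_boost"`
#' the classical shallow-tree shrinkage regime.  Grids are modest,
#' documented defaults; pass your own named list of candidate vectors to
#' override.
#'
#' @param family one of `"xgboost"`, `"gradient_boost"`, `"decision_tree"`,
#'   `"random_forest"`, `"knn"`, `"logistic"`, `"svm"`, `"dense_nn"`.
#' @param grid named list of candidate parameter vectors (defaults used
#'   when `NULL`).
#' @param seed seed for stochastic fitters.
#' @return object of class `model_grid`.
#' @export
model_grid <- function(family, grid = NULL, seed = 1L) {
  family <- match.arg(family, names(.family_registry))
  if (is.null(grid)) grid <- .family_registry[[family]]$default_grid
  if (!length(grid) || !all(lengths(grid) >= 1)) stop("grid must be non-empty")
  structure(list(family = family, grid = grid, seed = as.integer(seed)),
            class = "model_grid")
}

#' Default grids for all classical families
#' @param seed seed passed to every grid.
#' @return named list of `model_grid` objects.
#' @export
default_grids <- function(seed = 1L)
  lapply(stats::setNames(nm = names(.family_registry)), model_grid,
         grid = NULL, seed = seed)

# Internal registry: per family a default grid, a fit(x, y, params, seed)
# returning a scorer closure over new one-hot matrices.
.family_registry <- list(
  xgboost = list(
    default_grid = list(max_depth = c(3, 5), eta = c(0.1, 0.3),
                        nrounds = c(100, 300)),
    fit = function(x, y, params, seed) {
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      fit <- withr_seed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth, eta = params$eta,
                      nthread = 1), data = dtrain,
        nrounds = params$nrounds, verbose = 0))
      function(newx) stats::predict(fit, xgboost::xgb.DMatrix(newx))
    }),
  gradient_boost = list(
    default_grid = list(max_depth = c(1, 2), eta = c(0.05, 0.1),
                        nrounds = 200),
    fit = function(x, y, params, seed) {
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      fit <- withr_seed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth, eta = params$eta,
                      subsample = 0.8, nthread = 1), data = dtrain,
        nrounds = params$nrounds, verbose = 0))
      function(newx) stats::predict(fit, xgboost::xgb.DMatrix(newx))
    }),
  decision_tree = list(
    default_grid = list(maxdepth = c(3, 5, 10), cp = c(0.001, 0.01)),
    fit = function(x, y, params, seed) {
      df <- as.data.frame(x); df$.y <- factor(y, levels = 0:1)
      fit <- withr_seed(seed, rpart::rpart(
        .y ~ ., data = df, method = "class",
        control = rpart::rpart.control(maxdepth = params$maxdepth,
                                       cp = params$cp)))
      function(newx) stats::predict(fit, as.data.frame(newx))[, "1"]
    }),
  random_forest = list(
    default_grid = list(ntree = 300, mtry = c(5, 9, 15)),
    fit = function(x, y, params, seed) {
      fit <- withr_seed(seed, randomForest::randomForest(
        x, factor(y, levels = 0:1), ntree = params$ntree,
        mtry = min(params$mtry, ncol(x))))
      function(newx) stats::predict(fit, newx, type = "prob")[, "1"]
    }),
  knn = list(
    default_grid = list(k = c(5, 11, 21)),
    fit = function(x, y, params, seed) {
      cl <- factor(y, levels = 0:1)
      function(newx) {
        pred <- withr_seed(seed, class::knn(x, newx, cl, k = params$k,
                                            prob = TRUE))
        pw <- attr(pred, "prob")
        ifelse(pred == "1", pw, 1 - pw)
      }
    }),
  logistic = list(
    default_grid = list(lambda = c(1e-4, 1e-3, 1e-2, 1e-1)),
    fit = function(x, y, params, seed) {
      fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                            lambda = params$lambda)
      function(newx) drop(stats::predict(fit, newx, s = params$lambda,
                                         type = "response"))
    }),
  svm = list(
    default_grid = list(cost = c(0.1, 1, 10)),
    fit = function(x, y, params, seed) {
      fit <- withr_seed(seed, e1071::svm(
        x, factor(y, levels = 0:1), kernel = "radial",
        cost = params$cost, probability = TRUE))
      function(newx) {
        p <- stats::predict(fit, newx, probability = TRUE)
        attr(p, "probabilities")[, "1"]
      }
    }),
  dense_nn = list(
    default_grid = list(size = c(8, 16), decay = c(1e-3, 1e-2)),
    fit = function(x, y, params, seed) {
      fit <- withr_seed(seed, nnet::nnet(
        x, y, size = params$size, decay = params$decay, maxit = 200,
        entropy = TRUE, trace = FALSE, MaxNWts = 1e5))
      function(newx) drop(stats::predict(fit, newx))
    })
)

#' Exhaustive grid search selected by validation AUROC
#'
#' Fits every point of the grid on the training set, scores it on the
#' validation set, and returns the fit with the best validation AUROC
#' (ties broken by first-in-grid order).  Deterministic given the grid
#' seed.
#'
#' @param grid a [model_grid()].
#' @param x_train,x_val one-hot matrices for disjoint train/validation sets.
#' @param y_train,y_val binary labels.
#' @return list of class `grid_search_result`: `family`, `best_params`,
#'   `best_val_auroc`, `scorer` (closure over new one-hot matrices),
#'   `all_results` (data frame of every grid point and its validation
#'   AUROC, in grid order).
#' @export
grid_search <- function(grid, x_train, y_train, x_val, y_val) {
  stopifnot(inherits(grid, "model_grid"))
  if (length(unique(y_train)) < 2) stop("training labels are single-class")
  pts <- expand.grid(grid$grid, KEEP.OUT.ATTRS = FALSE)
  fit_fun <- .family_registry[[grid$family]]$fit
  scorers <- vector("list", nrow(pts))
  vals <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    params <- as.list(pts[i, , drop = FALSE])
    scorers[[i]] <- fit_fun(x_train, y_train, params, grid$seed)
    vals[i] <- auroc(scorers[[i]](x_val), y_val)
  }
  best <- which.max(vals)  # which.max returns the first maximum
  structure(list(family = grid$family,
                 best_params = as.list(pts[best, , drop = FALSE]),
                 best_val_auroc = vals[best],
                 scorer = scorers[[best]],
                 all_results = cbind(pts, val_auroc = vals)),
            class = "grid_search_result")
}

#' Run the full model leaderboard on both tasks
#'
#' Fits every classical family by [grid_search()] on identical
#' train/validation splits for the decision (CA) task and the survival
#' (CPC-class) task, adds the EFCN pair, and evaluates everything on the
#' held-out test set.  Only train, validation and test subsets are ever
#' touched; the cohort-analysis subset is reserved for
#' [counterfactual_audit()].
#'
#' @param registry registry data frame.
#' @param schema a [feature_schema()].
#' @param split a [split_data()] result for the registry.
#' @param grids named list of [model_grid()]s (default [default_grids()]).
#' @param efcn_bundle optional [train_efcn_pair()] result evaluated on
#'   the same splits.
#' @param threshold classification threshold for test metrics.
#' @return object of class `leaderboard`: data frame with one row per
#'   (family, task) carrying best parameters, validation AUROC and test
#'   metrics; full [compute_metrics()] reports in
#'   `attr(, "test_reports")`.
#' @export
run_leaderboard <- function(registry, schema, split, grids = default_grids(),
                            efcn_bundle = NULL, threshold = 0.5) {
  idx <- lapply(stats::setNames(nm = c("train", "validation", "test")),
                function(s) split_indices(split, s))
  tasks <- list(
    decision = list(input_set = "decision", y = registry$ca_performed),
    survival = list(input_set = "survival",
                    y = registry[[schema$outcome_field]]))
  rows <- list()
  reports <- list()
  for (task in names(tasks)) {
    x <- one_hot_encode(registry, schema, tasks[[task]]$input_set)$matrix
    y <- tasks[[task]]$y
    for (family in names(grids)) {
      res <- grid_search(grids[[family]], x[idx$train, , drop = FALSE],
                         y[idx$train], x[idx$validation, , drop = FALSE],
                         y[idx$validation])
      test_scores <- res$scorer(x[idx$test, , drop = FALSE])
      rep <- compute_metrics(test_scores, y[idx$test], threshold)
      reports[[paste(family, task, sep = ".")]] <- rep
      rows[[length(rows) + 1L]] <- data.frame(
        family = family, task = task,
        best_params = paste(names(res$best_params),
                            unlist(res$best_params),
                            sep = "=", collapse = ", "),
        val_auroc = res$best_val_auroc, test_auroc = rep$auroc,
        test_auprc = rep$auprc, test_f1 = rep$f1, test_mcc = rep$mcc,
        test_brier = rep$brier, stringsAsFactors = FALSE)
    }
    if (!is.null(efcn_bundle)) {
      model <- if (task == "decision") efcn_bundle$decision_model
               else efcn_bundle$survival_model
      val_scores <- predict(model, registry[idx$validation, , drop = FALSE])
      test_scores <- predict(model, registry[idx$test, , drop = FALSE])
      rep <- compute_metrics(test_scores, y[idx$test], threshold)
      reports[[paste("efcn", task, sep = ".")]] <- rep
      rows[[length(rows) + 1L]] <- data.frame(
        family = "efcn", task = task, best_params = "transfer pair",
        val_auroc = auroc(val_scores, y[idx$validation]),
        test_auroc = rep$auroc, test_auprc = rep$auprc, test_f1 = rep$f1,
        test_mcc = rep$mcc, test_brier = rep$brier,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "test_reports") <- reports
  attr(out, "used_indices") <- idx
  class(out) <- c("leaderboard", "data.frame")
  out
}

#' @export
print.leaderboard <- function(x, digits = 4, ...) {
  cat("Validation AUROC by model family\n")
  wide <- stats::reshape(
    x[, c("family", "task", "val_auroc")], direction = "wide",
    idvar = "family", timevar = "task")
  names(wide) <- sub("^val_auroc\\.", "", names(wide))
  ord <- order(-apply(wide[, -1, drop = FALSE], 1, max))
  print(format(wide[ord, ], digits = digits), row.names = FALSE)
  invisible(x)
}

#' Write a leaderboard as CSV
#' @param lb a `leaderboard`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_leaderboard <- function(lb, path) {
  utils::write.csv(as.data.frame(lb), path, row.names = FALSE)
  invisible(path)
}
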