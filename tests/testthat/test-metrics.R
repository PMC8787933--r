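test_that("auroc matches hand cases and the all-pairs oracle", {
  expect_equal(auroc(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(auroc(c(0.1, 0.9), c(1, 0)), 0)
  expect_equal(auroc(rep(0.4, 8), rep(0:1, 4)), 0.5)
  expect_error(auroc(c(0.1, 0.9), c(1, 1)), "both classes")

  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    scores <- round(stats::runif(n), sample(1:3, 1))  # force ties
    labels <- stats::rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), auroc_allpairs(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("auroc is invariant under monotone transforms and anti-symmetric in labels", {
  set.seed(7)
  scores <- stats::runif(100)
  labels <- stats::rbinom(100, 1, 0.3)
  a <- auroc(scores, labels)
  expect_equal(auroc(stats::qlogis(scores), labels), a)
  expect_equal(auroc(scores^3 + 2, labels), a)
  expect_equal(auroc(scores, 1 - labels), 1 - a)
})

test_that("auprc handles the perfect, constant and hand-computed cases", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # all scores tied: single threshold at prevalence precision
  expect_equal(auprc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  # scores 0.9(+), 0.7(-), 0.5(+): steps at recall 1/2 (prec 1) and 1 (prec 2/3)
  expect_equal(auprc(c(0.9, 0.7, 0.5), c(1, 0, 1)), 0.5 * 1 + 0.5 * (2 / 3))
})

test_that("thresholded metrics match closed forms and the documented tie rule", {
  perfect <- compute_metrics(c(0.99, 0.98, 0.01, 0.02), c(1, 1, 0, 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$mcc, 1)
  expect_lt(perfect$brier, 1e-3)

  # TP=5 FP=2 FN=3 TN=10 realized through scores at 0.9 / 0.1
  scores <- c(rep(0.9, 7), rep(0.1, 13))
  labels <- c(rep(1, 5), rep(0, 2), rep(1, 3), rep(0, 10))
  m <- compute_metrics(scores, labels)
  expect_identical(unname(m$confusion["1", "1"]), 5L)
  mcc_hand <- (5 * 10 - 2 * 3) / sqrt(7 * 8 * 12 * 13)
  expect_equal(m$mcc, mcc_hand)
  expect_equal(m$f1, 2 * 5 / (2 * 5 + 2 + 3))
  expect_equal(m$brier, mean((scores - labels)^2))

  # scores equal to the threshold classify as positive
  tie <- compute_metrics(rep(0.5, 10), c(rep(1, 3), rep(0, 7)),
                         threshold = 0.5)
  expect_equal(tie$accuracy, 0.3)

  # MCC defined as 0 when a marginal is empty
  degenerate <- compute_metrics(c(0.9, 0.9, 0.8), c(1, 0, 1))
  expect_equal(degenerate$mcc, 0)
})

test_that("the Brier score is proper: the generating probabilities beat distorted copies", {
  cfg <- small_config(n = 4000, seed = 5,
                      dec_off = c(-1, -0.3, 0.4, 0.9))
  cfg$calibrated <- TRUE
  g <- generate_registry(cfg, seed = 6)
  p <- g$sidecar$p_ca
  y <- g$registry$ca_performed
  truth <- mean((p - y)^2)
  distortions <- list(function(q) stats::plogis(2 * stats::qlogis(q)),
                      function(q) stats::plogis(0.4 * stats::qlogis(q)),
                      function(q) pmin(pmax(q + 0.15, 0.001), 0.999))
  for (d in distortions) expect_gt(mean((d(p) - y)^2), truth)
})

test_that("sampled attributions match exact Shapley enumeration and are locally accurate", {
  # additive scorer over three categorical features
  sch <- small_schema()
  score_fun <- function(df)
    2 * (df$rhythm == "Shockable") - 1 * (df$witnessed == "Yes") +
    0.5 * (df$age_band == "Old")
  set.seed(3)
  records <- small_registry(6, seed = 9)
  background <- small_registry(30, seed = 10)
  feats <- c("rhythm", "witnessed", "age_band")
  rep <- attribution(score_fun, records, background, feats,
                     n_perm = 200, seed = 2)
  # local accuracy is exact by telescoping
  expect_equal(unname(rep$base_value + rowSums(rep$per_record)),
               unname(rep$scores), tolerance = 1e-12)
  # against exact enumeration with a single fixed background record
  bg1 <- background[1, , drop = FALSE]
  rep1 <- attribution(score_fun, records[1, , drop = FALSE], bg1, feats,
                      n_perm = 400, seed = 5)
  exact <- shapley_exact(score_fun, records[1, , drop = FALSE], bg1, feats)
  expect_equal(unname(rep1$per_record[1, ]), unname(exact),
               tolerance = 0.01)
})

test_that("a feature the model ignores receives near-zero attribution", {
  score_fun <- function(df) as.numeric(df$rhythm == "Shockable")
  records <- small_registry(40, seed = 4)
  background <- small_registry(40, seed = 5)
  rep <- attribution(score_fun, records, background,
                     c("rhythm", "witnessed", "age_band"),
                     n_perm = 30, seed = 1)
  expect_lt(abs(mean(rep$per_record[, "witnessed"])), 0.01)
  expect_lt(abs(mean(rep$per_record[, "age_band"])), 0.01)
})
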