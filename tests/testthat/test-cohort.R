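test_that("hospitals stratify into ordered cohorts with deterministic tie-breaking", {
  set.seed(2)
  n_h <- 18
  per <- 60
  rates <- seq(0.45, 0.05, length.out = n_h)
  reg <- data.frame(
    hospital_id = rep(sprintf("H%02d", 1:n_h), each = per),
    outcome_class = unlist(lapply(rates, function(r)
      stats::rbinom(per, 1, 1 - r))),
    stringsAsFactors = FALSE)
  sch <- small_schema()
  ca <- assign_cohorts(reg, sch, min_instances = 50,
                       hospitals_per_cohort = 5, n_cohorts = 3)
  expect_length(ca$cohorts, 3L)
  expect_true(all(lengths(ca$cohorts) == 5L))
  expect_true(all(diff(ca$cpc12_rates) < 0))  # best to worst
  expect_length(intersect(ca$cohorts[[1]], ca$cohorts[[2]]), 0L)

  # ties broken by volume then id
  tie <- data.frame(
    hospital_id = c(rep("HB", 10), rep("HA", 12), rep("HC", 12)),
    outcome_class = 0L, stringsAsFactors = FALSE)
  ta <- assign_cohorts(tie, sch, min_instances = 5,
                       hospitals_per_cohort = 1, n_cohorts = 3)
  expect_identical(unlist(ta$cohorts, use.names = FALSE),
                   c("HA", "HC", "HB"))

  expect_error(assign_cohorts(reg, sch, min_instances = 1000,
                              hospitals_per_cohort = 5, n_cohorts = 3),
               "0 hospitals")
})

test_that("eligibility can be judged on the full study period while rates use train+validation", {
  reg <- data.frame(
    hospital_id = rep(c("HA", "HB"), each = 40),
    outcome_class = rep(c(0L, 1L), 40), stringsAsFactors = FALSE)
  tv <- reg[1:40, ]  # HA only in train+validation
  sch <- small_schema()
  expect_error(assign_cohorts(tv, sch, min_instances = 30,
                              hospitals_per_cohort = 1, n_cohorts = 2))
  ca <- assign_cohorts(reg, sch, min_instances = 30,
                       hospitals_per_cohort = 1, n_cohorts = 2,
                       volume_records = reg)
  expect_identical(sort(unlist(ca$cohorts, use.names = FALSE)),
                   c("HA", "HB"))
})

test_that("cohort stratification recovers the generator's hospital quality ordering", {
  n_h <- 9
  cfg <- small_config(n = n_h * 500, n_hospitals = n_h,
                      qual_off = seq(-1.5, 1.5, length.out = n_h),
                      seed = 5)
  cfg$calibrated <- TRUE
  g <- generate_registry(cfg, seed = 21)
  ca <- assign_cohorts(g$registry, small_schema(), min_instances = 100,
                       hospitals_per_cohort = 3, n_cohorts = 3)
  ranked <- unlist(ca$cohorts, use.names = FALSE)
  true_order <- sprintf("H%02d", order(cfg$hospital_quality_offsets))
  rho <- stats::cor(match(ranked, true_order), seq_len(n_h),
                    method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("zero-epoch fine-tuning is the identity and the source bundle is preserved", {
  sch <- small_schema()
  reg <- small_registry(240, seed = 3, noise = 0.2)
  bundle <- train_efcn_pair(reg, sch, 1:160, 161:240, quick_arch(),
                            list(max_epochs = 4, patience = 4), seed = 1)
  snapshot <- bundle$decision_model$params
  same <- retrain_on_cohort(bundle, reg, sch, 1:100, 161:200,
                            hyper = list(max_epochs = 0), seed = 2)
  expect_identical(same$decision_model$params, bundle$decision_model$params)
  expect_identical(same$survival_model$params, bundle$survival_model$params)

  tuned <- retrain_on_cohort(bundle, reg, sch, 1:100, 161:200,
                             hyper = list(max_epochs = 3, patience = 3),
                             seed = 2)
  tuned2 <- retrain_on_cohort(bundle, reg, sch, 1:100, 161:200,
                              hyper = list(max_epochs = 3, patience = 3),
                              seed = 2)
  expect_identical(tuned$decision_model$params,
                   tuned2$decision_model$params)
  expect_identical(bundle$decision_model$params, snapshot)
  expect_error(retrain_on_cohort(bundle, reg, sch, 1:100, 50:120),
               "overlap")
})

test_that("the counterfactual audit matches hand enumeration on a six-patient cohort", {
  # hand-specified scores keyed by patient id:
  #   decision >= 0.5 flips ids 2, 4, 5 (id 6 already had CA; id 1, 3 low)
  #   survival: id 2 improves (1 -> 0), id 4 unchanged, id 5 worsens (0 -> 1)
  target <- data.frame(id = 1:6,
                       ca_performed = c(0L, 0L, 0L, 0L, 0L, 1L),
                       outcome_class = c(1L, 1L, 0L, 1L, 0L, 0L),
                       stringsAsFactors = FALSE)
  d_scores <- c(`1` = 0.10, `2` = 0.90, `3` = 0.20, `4` = 0.50, `5` = 0.70)
  s0 <- c(`2` = 0.80, `4` = 0.90, `5` = 0.10)  # class at CA = 0
  s1 <- c(`2` = 0.20, `4` = 0.85, `5` = 0.95)  # class at CA = 1
  bundle <- stub_bundle(
    function(df) unname(d_scores[as.character(df$id)]),
    function(df) {
      tab <- if (all(df$ca_performed == 0L)) s0 else s1
      unname(tab[as.character(df$id)])
    })
  ct <- counterfactual_audit(bundle, target, small_schema(),
                             threshold = 0.5)
  expect_identical(ct$counts$n_total, 6L)
  expect_identical(ct$counts$n_no_initial_ca, 5L)
  expect_identical(ct$counts$n_flipped_to_ca, 3L)
  expect_identical(ct$counts$n_positive_change, 1L)
  expect_identical(ct$counts$n_negative_change, 1L)
  expect_identical(ct$counts$n_no_change, 1L)

  # a decision model that never reaches the threshold flips nobody
  none <- stub_bundle(function(df) rep(0.49, nrow(df)),
                      function(df) rep(0.2, nrow(df)))
  ct0 <- counterfactual_audit(none, target, small_schema(), 0.5)
  expect_identical(ct0$counts$n_flipped_to_ca, 0L)
  expect_identical(ct0$counts$n_no_change, 0L)

  all_ca <- target[target$ca_performed == 1L, , drop = FALSE]
  expect_warning(counterfactual_audit(none, all_ca, small_schema()),
                 "no patients")
})

test_that("the audit accounting identity and threshold monotonicity hold under fuzzing", {
  sch <- small_schema()
  set.seed(77)
  for (i in 1:60) {
    n <- sample(5:40, 1)
    target <- data.frame(id = seq_len(n),
                         ca_performed = stats::rbinom(n, 1, 0.3),
                         outcome_class = stats::rbinom(n, 1, 0.6))
    dsc <- stats::runif(n); s0 <- stats::runif(n); s1 <- stats::runif(n)
    bundle <- stub_bundle(
      function(df) dsc[df$id],
      function(df) ifelse(df$ca_performed == 1L, s1[df$id], s0[df$id]))
    thr <- stats::runif(1, 0.05, 0.95)
    ct <- counterfactual_audit(bundle, target, sch, thr)$counts
    expect_identical(ct$n_flipped_to_ca,
                     ct$n_no_change + ct$n_positive_change +
                       ct$n_negative_change)
    expect_lte(ct$n_flipped_to_ca, ct$n_no_initial_ca)
    expect_lte(ct$n_no_initial_ca, ct$n_total)
    higher <- counterfactual_audit(bundle, target, sch,
                                   min(thr + 0.2, 0.99))$counts
    expect_lte(higher$n_flipped_to_ca, ct$n_flipped_to_ca)
  }
})

test_that("summary percentages recompute from counts with half-up rounding", {
  ct <- new_counterfactual_table(
    c(218L, 175L, 33L, 23L, 10L, 0L), 0.5, "worst tertile")
  s <- summarize_table(ct)
  expect_equal(s$percent, c(18.86, 69.7, 30.3, 0))
  expect_identical(s$fraction, c("33/175", "23/33", "10/33", "0/33"))

  empty <- new_counterfactual_table(c(10L, 0L, 0L, 0L, 0L, 0L), 0.5, NULL)
  expect_true(all(is.na(summarize_table(empty)$percent)))

  # half-up rounding differs from round-half-even where it matters
  expect_equal(pct_half_up(5, 8, 0), 63)
  expect_equal(pct_half_up(1, 8, 1), 12.5)
  expect_true(is.na(pct_half_up(1, 0)))
})

test_that("percentile bootstrap intervals behave on constant and simple statistics", {
  const <- bootstrap_ci(rep(1, 50), mean, replicates = 200, seed = 1)
  expect_equal(const$lower, const$upper)
  expect_equal(const$point, 1)

  set.seed(4)
  x <- stats::rbinom(200, 1, 0.3)
  ci <- bootstrap_ci(x, mean, replicates = 500, seed = 9)
  expect_lte(ci$lower, ci$point)
  expect_gte(ci$upper, ci$point)
  expect_identical(bootstrap_ci(x, mean, replicates = 500, seed = 9)$lower,
                   ci$lower)
  expect_error(bootstrap_ci(x, mean, replicates = 50), "at least 100")

  skip_stat <- function(v) if (sum(v) == 0) NA_real_ else mean(v)
  expect_warning(
    bootstrap_ci(c(rep(0, 30), 1), skip_stat, replicates = 200, seed = 2),
    "degenerate")
})
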