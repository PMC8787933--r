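# Shared fixtures: everything is built in code at test time.

# A small 4-feature schema (plus CA) for fast unit tests.
small_schema <- function() {
  feature_schema(
    features = list(
      rhythm = c("Shockable", "Nonshockable", "Unknown"),
      witnessed = c("No", "Yes"),
      cpr_initiation = c("Lay Person", "First Responder", "EMS Personnel"),
      age_band = c("Young", "Middle", "Old"),
      coronary_angiography = c("0", "1")),
    decision_inputs = c("rhythm", "witnessed", "cpr_initiation", "age_band"),
    ca_feature = "coronary_angiography")
}

# Uniform-marginal generator over the small schema with explicit effects.
small_config <- function(n = 500, n_hospitals = 4,
                         decision_coeffs = NULL, outcome_coeffs = NULL,
                         dec_off = NULL, qual_off = NULL,
                         ca_effect = -0.8, seed = 1L) {
  sch <- small_schema()
  zero_coeffs <- lapply(sch$features[sch$decision_inputs], function(lv)
    stats::setNames(rep(0, length(lv)), lv))
  marg <- lapply(sch$features[sch$decision_inputs], function(lv)
    rep(1 / length(lv), length(lv)))
  generator_config(
    schema = sch, n_patients = n,
    hospital_volume_weights = rep(1 / n_hospitals, n_hospitals),
    covariate_marginals = marg,
    decision_coeffs = if (is.null(decision_coeffs)) zero_coeffs
                      else decision_coeffs,
    decision_intercept = 0,
    hospital_decision_offsets = if (is.null(dec_off))
      rep(0, n_hospitals) else dec_off,
    outcome_coeffs = if (is.null(outcome_coeffs)) zero_coeffs
                     else outcome_coeffs,
    outcome_intercept = 0,
    hospital_quality_offsets = if (is.null(qual_off))
      rep(0, n_hospitals) else qual_off,
    ca_outcome_effect = ca_effect, seed = seed)
}

# A registry over the small schema with labels driven by the rhythm
# feature; separable when noise = 0.
small_registry <- function(n = 300, seed = 1L, noise = 0) {
  sch <- small_schema()
  set.seed(seed)
  df <- data.frame(
    rhythm = sample(sch$features$rhythm, n, TRUE),
    witnessed = sample(sch$features$witnessed, n, TRUE),
    cpr_initiation = sample(sch$features$cpr_initiation, n, TRUE),
    age_band = sample(sch$features$age_band, n, TRUE),
    hospital_id = sample(c("A", "B"), n, TRUE),
    stringsAsFactors = FALSE)
  y <- as.integer(df$rhythm == "Shockable")
  if (noise > 0) {
    flip <- as.logical(stats::rbinom(n, 1, noise))
    y[flip] <- 1L - y[flip]
  }
  df$ca_performed <- y
  df$outcome_class <- y
  df
}

# A fast, small EFCN architecture for unit tests.
quick_arch <- function() {
  efcn_architecture(conv_filters = c(8L, 8L), kernel_widths = c(3L, 3L))
}

# Independent AUROC oracle: brute force over all (positive, negative)
# pairs, ties counted one half.
auroc_allpairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Stub scorer dispatching on a lookup of hand-specified scores by a key
# column, used to drive counterfactual_audit with exact known scores.
stub_model <- function(score_fun) {
  structure(list(score_fun = score_fun, trained = TRUE),
            class = c("stub_model"))
}

stub_bundle <- function(decision_fun, survival_fun) {
  structure(list(decision_model = stub_model(decision_fun),
                 survival_model = stub_model(survival_fun)),
            class = "efcn_bundle")
}

predict.stub_model <- function(object, newdata, ...) {
  object$score_fun(newdata)
}
registerS3method("predict", "stub_model", predict.stub_model,
                 envir = asNamespace("stats"))

# Exact Shapley values by full coalition enumeration against a single
# fixed background record (oracle for the sampling estimator).
shapley_exact <- function(score_fun, record, background_row, features) {
  k <- length(features)
  phi <- stats::setNames(numeric(k), features)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  val <- function(mask) {
    r <- background_row
    r[features[mask]] <- record[features[mask]]
    score_fun(r)
  }
  for (j in seq_len(k)) {
    for (s in seq_len(nrow(subsets))) {
      mask <- unlist(subsets[s, ])
      if (mask[j]) next
      size <- sum(mask)
      w <- factorial(size) * factorial(k - size - 1) / factorial(k)
      with_j <- mask; with_j[j] <- TRUE
      phi[j] <- phi[j] + w * (val(with_j) - val(mask))
    }
  }
  phi
}
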