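#' Construct a synthetic registry generator configuration
#'
#' The generator emulates the statistical structure of a post-arrest
#' hospital registry: exclusively categorical covariates, a binary
#' coronary-angiography (CA) decision driven by a logistic model with a
#' hospital-level policy offset, and a binary neurologic outcome
#' (Class 1 = CPC 3/4/5, non-functional) driven by a second logistic
#' model with a causal CA effect and a hospital-level quality offset.
#' Decision precedes outcome, and the CA decision is the only extra
#' input the outcome model sees.
#'
#' @param schema a [feature_schema()].
#' @param n_patients default registry size.
#' @param hospital_volume_weights simplex over hospitals (sums to 1).
#' @param covariate_marginals named list, per decision feature, of level
#'   probability vectors (each sums to 1, schema level order).
#' @param decision_coeffs,outcome_coeffs named lists, per feature, of
#'   per-level log-odds contributions to CA and to Class 1 respectively.
#' @param decision_intercept,outcome_intercept log-odds intercepts.
#' @param hospital_decision_offsets,hospital_quality_offsets per-hospital
#'   additive log-odds shifts on the CA decision and on Class 1.  A
#'   negative quality offset means a better hospital.
#' @param ca_outcome_effect log-odds added to Class 1 when CA is given;
#'   negative means CA improves outcomes.
#' @param covariate_sampler optional function `(n)` returning a data frame
#'   of feature levels, replacing independent-marginal sampling for users
#'   who need covariate dependence.  It is called inside the generator's
#'   seeded RNG scope.
#' @param seed integer seed used by [generate_registry()].
#' @return object of class `generator_config`.
#' @export
generator_config <- function(schema, n_patients, hospital_volume_weights,
                             covariate_marginals, decision_coeffs,
                             decision_intercept, hospital_decision_offsets,
                             outcome_coeffs, outcome_intercept,
                             hospital_quality_offsets, ca_outcome_effect,
                             covariate_sampler = NULL, seed = 1L) {
  stopifnot(inherits(schema, "feature_schema"))
  if (abs(sum(hospital_volume_weights) - 1) > 1e-8)
    stop("hospital_volume_weights must sum to 1")
  for (f in schema$decision_inputs) {
    p <- covariate_marginals[[f]]
    if (is.null(p) || abs(sum(p) - 1) > 1e-8 ||
        length(p) != length(schema$features[[f]]))
      stop(sprintf("covariate_marginals['%s'] must sum to 1 over the schema levels", f))
  }
  n_h <- length(hospital_volume_weights)
  stopifnot(length(hospital_decision_offsets) == n_h,
            length(hospital_quality_offsets) == n_h)
  structure(list(
    schema = schema, n_patients = as.integer(n_patients),
    n_hospitals = n_h,
    hospital_ids = sprintf("H%02d", seq_len(n_h)),
    hospital_volume_weights = hospital_volume_weights,
    covariate_marginals = covariate_marginals,
    decision_coeffs = decision_coeffs,
    decision_intercept = decision_intercept,
    hospital_decision_offsets = hospital_decision_offsets,
    outcome_coeffs = outcome_coeffs,
    outcome_intercept = outcome_intercept,
    hospital_quality_offsets = hospital_quality_offsets,
    ca_outcome_effect = ca_outcome_effect,
    covariate_sampler = covariate_sampler,
    calibrated = FALSE, seed = as.integer(seed)
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  %d patients, %d hospitals, %d decision features\n",
              x$n_patients, x$n_hospitals, length(x$schema$decision_inputs)))
  cat(sprintf("  CA effect on Class-1 log-odds: %+.2f; calibrated: %s\n",
              x$ca_outcome_effect, x$calibrated))
  invisible(x)
}

#' Default calibrated generator configuration
#'
#' Emulates the study conditions of a large urban EMS system: 2398
#' admitted patients across 33 receiving hospitals of which roughly 15
#' exceed 75 patients, a ~21.5% CA rate and a ~20.8% functional-outcome
#' (Class 0) rate.  Covariate marginals and feature coefficients are
#' drawn once from the configuration seed; hospital CA-policy offsets
#' are anti-correlated with quality offsets (better hospitals provide
#' more CA), which is what makes a cross-cohort decision audit
#' informative.  Intercepts are calibrated by [calibrate_intercepts()].
#'
#' @param n_patients registry size (the study size by default).
#' @param seed configuration seed; identical seeds give identical configs.
#' @param target_ca_rate,target_class0_rate marginal rates to calibrate to.
#' @param calibrate set `FALSE` to skip intercept calibration.
#' @return a calibrated `generator_config`.
#' @export
default_config <- function(n_patients = 2398L, seed = 1L,
                           target_ca_rate = 0.215,
                           target_class0_rate = 0.208,
                           calibrate = TRUE) {
  schema <- default_schema()
  # 15 high-volume hospitals (>75 expected patients at n = 2398) and 18
  # low-volume ones; weights fixed, not seed-dependent
  w_high <- seq(0.038, 0.052, length.out = 15)
  w_low <- seq(0.010, 0.026, length.out = 18)
  w_low <- w_low * (1 - sum(w_high)) / sum(w_low)
  w <- c(w_high, w_low)
  cfg <- withr_seed(seed + 101L, {
    marg <- lapply(schema$features[schema$decision_inputs], function(lv) {
      g <- stats::rgamma(length(lv), shape = 2)
      g / sum(g)
    })
    dcoef <- lapply(schema$features[schema$decision_inputs], function(lv) {
      b <- stats::rnorm(length(lv), 0, 0.45)
      stats::setNames(b - mean(b), lv)
    })
    ocoef <- lapply(schema$features[schema$decision_inputs], function(lv) {
      b <- stats::rnorm(length(lv), 0, 0.45)
      stats::setNames(b - mean(b), lv)
    })
    qual <- stats::rnorm(33, 0, 0.6)
    qual <- qual - mean(qual)
    dec_off <- -0.8 * qual + stats::rnorm(33, 0, 0.3)
    dec_off <- dec_off - mean(dec_off)
    generator_config(
      schema = schema, n_patients = n_patients,
      hospital_volume_weights = w,
      covariate_marginals = marg,
      decision_coeffs = dcoef, decision_intercept = 0,
      hospital_decision_offsets = dec_off,
      outcome_coeffs = ocoef, outcome_intercept = 0,
      hospital_quality_offsets = qual,
      ca_outcome_effect = -0.8, seed = seed)
  })
  if (calibrate)
    cfg <- calibrate_intercepts(cfg, target_ca_rate, target_class0_rate)
  cfg
}

# Monte-Carlo draw of covariate/hospital linear-predictor components,
# shared by calibration; returns intercept-free decision and outcome
# linear predictors for mc_n hypothetical patients.
mc_linear_predictors <- function(config, mc_n, seed) {
  withr_seed(seed, {
    hosp <- sample.int(config$n_hospitals, mc_n, replace = TRUE,
                       prob = config$hospital_volume_weights)
    lp_d <- config$hospital_decision_offsets[hosp]
    lp_o <- config$hospital_quality_offsets[hosp]
    for (f in config$schema$decision_inputs) {
      p <- config$covariate_marginals[[f]]
      idx <- sample.int(length(p), mc_n, replace = TRUE, prob = p)
      lp_d <- lp_d + config$decision_coeffs[[f]][idx]
      lp_o <- lp_o + config$outcome_coeffs[[f]][idx]
    }
    list(decision = unname(lp_d), outcome = unname(lp_o))
  })
}

#' Calibrate generator intercepts to target marginal rates
#'
#' Solves, by monotone 1-D root finding against a Monte-Carlo estimate of
#' the marginal, for the decision intercept giving the target CA rate and
#' then (accounting for the CA-dependent outcome shift) for the outcome
#' intercept giving the target Class-0 rate.
#'
#' @param config a `generator_config`.
#' @param target_ca_rate,target_class0_rate target marginal rates in (0, 1).
#' @param mc_n Monte-Carlo sample size for the marginal estimate.
#' @return the config with calibrated intercepts and `calibrated = TRUE`.
#' @export
calibrate_intercepts <- function(config, target_ca_rate = 0.215,
                                 target_class0_rate = 0.208,
                                 mc_n = 100000L) {
  stopifnot(inherits(config, "generator_config"))
  for (t in c(target_ca_rate, target_class0_rate))
    if (!(t > 0 && t < 1)) stop("targets must lie strictly inside (0, 1)")
  lp <- mc_linear_predictors(config, mc_n, seed = config$seed + 202L)
  root <- function(f) {
    lo <- f(-20); hi <- f(20)
    if (sign(lo) == sign(hi))
      stop("target rate not bracketable: coefficients force the marginal outside (0,1)")
    stats::uniroot(f, c(-20, 20), tol = 1e-9)$root
  }
  a <- root(function(a) mean(stats::plogis(a + lp$decision)) - target_ca_rate)
  p_ca <- stats::plogis(a + lp$decision)
  eff <- config$ca_outcome_effect
  target_class1 <- 1 - target_class0_rate
  b <- root(function(b) {
    mean(p_ca * stats::plogis(b + lp$outcome + eff) +
           (1 - p_ca) * stats::plogis(b + lp$outcome)) - target_class1
  })
  config$decision_intercept <- a
  config$outcome_intercept <- b
  config$calibrated <- TRUE
  config
}

#' Generate a synthetic registry with a latent-truth sidecar
#'
#' Per patient, in order: hospital drawn from the volume weights;
#' covariates from independent marginals (or the config's custom
#' sampler); CA from the logistic decision model; outcome class from the
#' logistic outcome model evaluated at the realized CA.  The sidecar
#' retains the exact probabilities used — the true CA propensity and the
#' true Class-1 probability under both CA = 0 and CA = 1 — which gives
#' every downstream model an exact performance ceiling
#' ([bayes_auroc()]) and the cohort analysis a ground truth.
#'
#' @param config a calibrated `generator_config`.
#' @param n number of patients (default `config$n_patients`).
#' @param seed seed (default `config$seed`); output is deterministic given it.
#' @return list of class `synthetic_registry`: `registry` (data frame:
#'   decision features, `hospital_id`, `ca_performed`, `outcome_class`)
#'   and `sidecar` (data frame: `p_ca`, `p_class1_ca0`, `p_class1_ca1`).
#' @export
generate_registry <- function(config, n = config$n_patients,
                              seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (!isTRUE(config$calibrated))
    warning("generator config is not calibrated; marginal rates are untargeted")
  withr_seed(seed, {
    hosp <- sample.int(config$n_hospitals, n, replace = TRUE,
                       prob = config$hospital_volume_weights)
    if (is.null(config$covariate_sampler)) {
      cov <- lapply(config$schema$decision_inputs, function(f) {
        p <- config$covariate_marginals[[f]]
        lv <- config$schema$features[[f]]
        lv[sample.int(length(p), n, replace = TRUE, prob = p)]
      })
      names(cov) <- config$schema$decision_inputs
      cov <- as.data.frame(cov, check.names = FALSE,
                           stringsAsFactors = FALSE)
    } else {
      cov <- config$covariate_sampler(n)
    }
    lp_d <- config$decision_intercept + config$hospital_decision_offsets[hosp]
    lp_o <- config$outcome_intercept + config$hospital_quality_offsets[hosp]
    for (f in config$schema$decision_inputs) {
      idx <- match(cov[[f]], config$schema$features[[f]])
      lp_d <- lp_d + unname(config$decision_coeffs[[f]][idx])
      lp_o <- lp_o + unname(config$outcome_coeffs[[f]][idx])
    }
    p_ca <- stats::plogis(lp_d)
    ca <- stats::rbinom(n, 1L, p_ca)
    p1_0 <- stats::plogis(lp_o)
    p1_1 <- stats::plogis(lp_o + config$ca_outcome_effect)
    p1 <- ifelse(ca == 1L, p1_1, p1_0)
    outcome <- stats::rbinom(n, 1L, p1)
    registry <- cov
    registry[[config$schema$hospital_field]] <- config$hospital_ids[hosp]
    registry$ca_performed <- as.integer(ca)
    registry[[config$schema$outcome_field]] <- as.integer(outcome)
    structure(list(
      registry = registry,
      sidecar = data.frame(p_ca = p_ca, p_class1_ca0 = p1_0,
                           p_class1_ca1 = p1_1)
    ), class = "synthetic_registry")
  })
}

#' @export
print.synthetic_registry <- function(x, ...) {
  cat("<synthetic_registry>", nrow(x$registry), "patients,",
      length(unique(x$registry$hospital_id)), "hospitals\n")
  cat(sprintf("  CA rate %.1f%%, Class-0 rate %.1f%%\n",
              100 * mean(x$registry$ca_performed),
              100 * mean(x$registry$outcome_class == 0)))
  invisible(x)
}

#' Bayes-optimal AUROC ceiling of a synthetic registry
#'
#' The AUROC of the true generating probability against the realized
#' labels: no model can beat this in expectation, so it bounds what any
#' trained classifier should approach on held-out data.
#'
#' @param synth a `synthetic_registry` from [generate_registry()].
#' @param task `"decision"` (CA propensity vs. realized CA) or
#'   `"outcome"` (true Class-1 probability at the realized CA vs. class).
#' @return the ceiling AUROC.
#' @export
bayes_auroc <- function(synth, task = c("decision", "outcome")) {
  task <- match.arg(task)
  stopifnot(inherits(synth, "synthetic_registry"))
  if (task == "decision") {
    auroc(synth$sidecar$p_ca, synth$registry$ca_performed)
  } else {
    p <- ifelse(synth$registry$ca_performed == 1L,
                synth$sidecar$p_class1_ca1, synth$sidecar$p_class1_ca0)
    auroc(p, synth$registry$outcome_class)
  }
}
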