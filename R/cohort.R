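#' Stratify hospitals into outcome-quality cohorts
#'
#' Hospitals with at least `min_instances` records among the supplied
#' (train + validation) instances are ranked by their CPC 1/2 rate —
#' the fraction of Class-0, functional-outcome patients — and grouped
#' best-to-worst into cohorts of `hospitals_per_cohort`.  Ties in rate
#' are broken by larger volume, then lexical hospital id, so the
#' assignment is deterministic.
#'
#' @param records train + validation registry rows (the subset on which
#'   cohort rates are defined; held-out rows must not enter here).
#' @param schema a [feature_schema()].
#' @param min_instances minimum study records for a hospital to qualify.
#' @param hospitals_per_cohort hospitals per cohort.
#' @param n_cohorts number of cohorts (best = cohort 1).
#' @param volume_records registry rows on which the volume threshold is
#'   judged; defaults to `records`, but eligibility is naturally defined
#'   over the whole study period, so pass the full registry when
#'   `records` is only its train + validation part.  Outcomes in
#'   `volume_records` are never read — only hospital ids are counted.
#' @return object of class `cohort_assignment`: `cohorts` (list of
#'   hospital-id vectors, best first), `cpc12_rates` (per cohort),
#'   `hospital_table` (per-hospital rate/volume), `excluded_hospitals`.
#' @export
assign_cohorts <- function(records, schema, min_instances = 75L,
                           hospitals_per_cohort = 5L, n_cohorts = 3L,
                           volume_records = records) {
  hosp <- records[[schema$hospital_field]]
  cls0 <- records[[schema$outcome_field]] == 0L
  vol <- table(volume_records[[schema$hospital_field]])
  tab <- data.frame(hospital = sort(unique(hosp)), stringsAsFactors = FALSE)
  tab$n <- as.integer(vol[tab$hospital])
  tab$n[is.na(tab$n)] <- 0L
  tab$cpc12_rate <- vapply(tab$hospital,
                           function(h) mean(cls0[hosp == h]), numeric(1))
  qualifying <- tab[tab$n >= min_instances, , drop = FALSE]
  excluded <- tab$hospital[tab$n < min_instances]
  need <- n_cohorts * hospitals_per_cohort
  if (nrow(qualifying) < need)
    stop(sprintf("only %d hospitals have >= %d instances; %d needed",
                 nrow(qualifying), min_instances, need))
  ord <- order(-qualifying$cpc12_rate, -qualifying$n, qualifying$hospital)
  qualifying <- qualifying[ord, , drop = FALSE]
  picked <- qualifying[seq_len(need), , drop = FALSE]
  grp <- rep(seq_len(n_cohorts), each = hospitals_per_cohort)
  cohorts <- split(picked$hospital, grp)
  names(cohorts) <- paste0("cohort", seq_len(n_cohorts))
  rates <- vapply(cohorts, function(h) {
    sel <- hosp %in% h
    mean(cls0[sel])
  }, numeric(1))
  structure(list(cohorts = cohorts, cpc12_rates = rates,
                 hospital_table = qualifying,
                 excluded_hospitals = excluded,
                 min_instances = min_instances,
                 hospitals_per_cohort = hospitals_per_cohort),
            class = "cohort_assignment")
}

#' @export
print.cohort_assignment <- function(x, ...) {
  cat("<cohort_assignment>", length(x$cohorts), "cohorts of",
      x$hospitals_per_cohort, "hospitals (min", x$min_instances,
      "instances);", length(x$excluded_hospitals), "hospitals excluded\n")
  for (i in seq_along(x$cohorts))
    cat(sprintf("  %s: CPC1/2 rate %.1f%% (%s)\n", names(x$cohorts)[i],
                100 * x$cpc12_rates[i],
                paste(x$cohorts[[i]], collapse = ", ")))
  invisible(x)
}

#' Fine-tune the EFCN pair on one cohort's data
#'
#' Warm-starts both networks from the full-data weights (the original
#' bundle is never modified) and re-optimizes them on the cohort's
#' training rows with early stopping on the cohort's validation rows.
#' With `max_epochs = 0` the result is identical to the input bundle.
#'
#' @param bundle an [train_efcn_pair()] result fitted on the full data.
#' @param registry the registry data frame.
#' @param schema a [feature_schema()].
#' @param train_idx,val_idx cohort row indices within `registry`
#'   (disjoint; typically the intersection of the cohort's hospitals
#'   with the global train and validation subsets).
#' @param hyper hyperparameter overrides for the fine-tuning runs.
#' @param seed base seed for the fine-tuning runs.
#' @return a new `efcn_bundle` adapted to the cohort.
#' @export
retrain_on_cohort <- function(bundle, registry, schema, train_idx, val_idx,
                              hyper = list(), seed = 1L) {
  stopifnot(inherits(bundle, "efcn_bundle"))
  if (length(intersect(train_idx, val_idx)))
    stop("cohort training and validation indices overlap")
  y_ca <- registry$ca_performed
  y_out <- registry[[schema$outcome_field]]
  if (length(unique(y_ca[train_idx])) < 2 ||
      length(unique(y_out[train_idx])) < 2)
    stop("cohort training labels are single-class")
  x_dec <- index_encode(registry, schema, "decision")
  x_sur <- index_encode(registry, schema, "survival")
  sub <- function(x, idx) { x$matrix <- x$matrix[idx, , drop = FALSE]; x }
  dec <- bundle$decision_model
  sur <- bundle$survival_model
  dec <- train_efcn(dec, sub(x_dec, train_idx), y_ca[train_idx],
                    sub(x_dec, val_idx), y_ca[val_idx],
                    utils::modifyList(hyper, list(seed = seed + 31L)))
  sur <- train_efcn(sur, sub(x_sur, train_idx), y_out[train_idx],
                    sub(x_sur, val_idx), y_out[val_idx],
                    utils::modifyList(hyper, list(seed = seed + 47L)))
  structure(list(decision_model = dec, survival_model = sur,
                 transfer_manifest = bundle$transfer_manifest,
                 seeds = c(bundle$seeds, fine_tune = seed),
                 fine_tuned = TRUE), class = "efcn_bundle")
}

#' Counterfactual decision audit of a target cohort
#'
#' Applies the best cohort's fine-tuned decision model to another
#' cohort's held-out patients who did not receive coronary angiography.
#' A patient whose decision score reaches the threshold is "flipped" to
#' CA; for flipped patients the survival model is scored under CA = 0
#' and CA = 1 and each score classified at the same threshold.  A
#' positive change is predicted class 1 -> 0 (non-functional to
#' functional); negative is 0 -> 1; otherwise no change.  Only the
#' no-CA-to-CA direction is audited — patients who received CA are
#' never counterfactually denied it.
#'
#' @param bundle the best cohort's fine-tuned `efcn_bundle`.
#' @param target_records held-out (cohort-analysis split) rows of the
#'   target cohort; must be disjoint from all training/validation data.
#' @param schema a [feature_schema()].
#' @param threshold decision/classification threshold; scores at the
#'   threshold count as positive.
#' @param label optional cohort label carried into the rendered table.
#' @return object of class `counterfactual_table` with counts `n_total`,
#'   `n_no_initial_ca`, `n_flipped_to_ca`, `n_no_change`,
#'   `n_positive_change`, `n_negative_change` and matching percentages.
#' @export
counterfactual_audit <- function(bundle, target_records, schema,
                                 threshold = 0.5, label = NULL) {
  stopifnot(inherits(bundle, "efcn_bundle"))
  n_total <- nrow(target_records)
  no_ca <- target_records[target_records$ca_performed == 0L, , drop = FALSE]
  n0 <- nrow(no_ca)
  if (n0 == 0L) {
    warning("target cohort has no patients without an initial CA")
    counts <- c(n_total = n_total, n_no_initial_ca = 0L,
                n_flipped_to_ca = 0L, n_no_change = 0L,
                n_positive_change = 0L, n_negative_change = 0L)
    return(new_counterfactual_table(counts, threshold, label))
  }
  d_scores <- predict(bundle$decision_model, no_ca)
  flipped <- no_ca[d_scores >= threshold, , drop = FALSE]
  nf <- nrow(flipped)
  n_pos <- n_neg <- n_none <- 0L
  if (nf > 0) {
    r0 <- flipped; r0$ca_performed <- 0L
    r1 <- flipped; r1$ca_performed <- 1L
    c0 <- as.integer(predict(bundle$survival_model, r0) >= threshold)
    c1 <- as.integer(predict(bundle$survival_model, r1) >= threshold)
    n_pos <- sum(c0 == 1L & c1 == 0L)
    n_neg <- sum(c0 == 0L & c1 == 1L)
    n_none <- nf - n_pos - n_neg
  }
  counts <- c(n_total = n_total, n_no_initial_ca = n0,
              n_flipped_to_ca = nf, n_no_change = n_none,
              n_positive_change = n_pos, n_negative_change = n_neg)
  new_counterfactual_table(counts, threshold, label)
}

#' Construct a counterfactual table from known counts
#'
#' Builds the same object [counterfactual_audit()] produces, from
#' externally known counts — e.g. to recompute derived percentages from
#' a published audit table.  The accounting identities are enforced:
#' flipped = no change + positive + negative, and
#' flipped <= no-initial-CA <= total.
#'
#' @param n_total patients in the target cohort.
#' @param n_no_initial_ca patients without an initial CA.
#' @param n_flipped_to_ca no-CA patients the decision model flips.
#' @param n_no_change,n_positive_change,n_negative_change predicted
#'   CPC-class changes among flipped patients.
#' @param threshold threshold the counts were produced at.
#' @param label optional cohort label.
#' @return a `counterfactual_table`.
#' @export
counterfactual_table <- function(n_total, n_no_initial_ca,
                                 n_flipped_to_ca, n_no_change,
                                 n_positive_change, n_negative_change,
                                 threshold = 0.5, label = NULL) {
  if (n_flipped_to_ca !=
      n_no_change + n_positive_change + n_negative_change)
    stop("flipped count must equal no-change + positive + negative")
  if (n_flipped_to_ca > n_no_initial_ca || n_no_initial_ca > n_total)
    stop("counts must nest: flipped <= no-initial-CA <= total")
  new_counterfactual_table(
    c(n_total, n_no_initial_ca, n_flipped_to_ca, n_no_change,
      n_positive_change, n_negative_change), threshold, label)
}

new_counterfactual_table <- function(counts, threshold, label) {
  counts <- as.integer(counts)
  names(counts) <- c("n_total", "n_no_initial_ca", "n_flipped_to_ca",
                     "n_no_change", "n_positive_change", "n_negative_change")
  structure(list(counts = as.list(counts), threshold = threshold,
                 label = label), class = "counterfactual_table")
}

#' Half-up percentage of a count fraction
#'
#' `100 * num / den` rounded half-up at `decimals` places (the
#' convention used in the rendered audit tables; R's own `round()` is
#' round-half-even).  A zero denominator yields `NA`.
#'
#' @param num,den numerator and denominator counts.
#' @param decimals decimal places.
#' @return numeric percentage, or `NA` for an undefined fraction.
#' @export
pct_half_up <- function(num, den, decimals = 2L) {
  if (den == 0) return(NA_real_)
  x <- 100 * num / den
  floor(x * 10^decimals + 0.5) / 10^decimals
}

#' Render a counterfactual table with derived percentages
#'
#' Percentages recompute exactly from the counts: the flip rate over
#' patients without an initial CA, and the change rates over flipped
#' patients, each rounded half-up at the configured number of decimals.
#' Fraction strings `"a/b"` are preserved alongside.
#'
#' @param table a `counterfactual_table`.
#' @param decimals named vector: decimals for the `flip` row and the
#'   `change` rows.
#' @return data frame of class `counterfactual_summary` with columns
#'   `quantity`, `fraction`, `percent`.
#' @export
summarize_table <- function(table, decimals = c(flip = 2L, change = 1L)) {
  ct <- table$counts
  rows <- list(
    list("patients not initially given CA, flipped to CA by the model",
         ct$n_flipped_to_ca, ct$n_no_initial_ca, decimals[["flip"]]),
    list("no change in CPC class",
         ct$n_no_change, ct$n_flipped_to_ca, decimals[["change"]]),
    list("positive change in CPC class",
         ct$n_positive_change, ct$n_flipped_to_ca, decimals[["change"]]),
    list("negative change in CPC class",
         ct$n_negative_change, ct$n_flipped_to_ca, decimals[["change"]]))
  out <- data.frame(
    quantity = vapply(rows, `[[`, character(1), 1),
    fraction = vapply(rows, function(r) sprintf("%d/%d", r[[2]], r[[3]]),
                      character(1)),
    percent = vapply(rows, function(r) pct_half_up(r[[2]], r[[3]], r[[4]]),
                     numeric(1)),
    stringsAsFactors = FALSE)
  attr(out, "label") <- table$label
  attr(out, "n_total") <- ct$n_total
  class(out) <- c("counterfactual_summary", "data.frame")
  out
}

#' @export
print.counterfactual_table <- function(x, ...) {
  lab <- if (is.null(x$label)) "" else paste0(" [", x$label, "]")
  cat(sprintf("<counterfactual_table>%s N = %d, threshold %.2f\n",
              lab, x$counts$n_total, x$threshold))
  s <- summarize_table(x)
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-55s %9s (%s%%)\n", s$quantity[i], s$fraction[i],
                ifelse(is.na(s$percent[i]), "NA", s$percent[i])))
  invisible(x)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples rows (patients) with replacement and takes empirical
#' quantiles of the replicated statistic.  Replicates where the
#' statistic is undefined (`NA`; e.g. a resample with no CA = 0
#' patients) are skipped and counted, with a warning if more than 1% are
#' skipped.
#'
#' @param data data frame (rows resampled) or vector.
#' @param statistic function of a resampled `data` returning a scalar
#'   (may return `NA` for degenerate resamples).
#' @param replicates bootstrap replicates (>= 100).
#' @param conf two-sided confidence level.
#' @param seed RNG seed.
#' @return object of class `interval_estimate` with `point`, `lower`,
#'   `upper`, `method`, `replicates`, `n_skipped`, `seed`.
#' @export
bootstrap_ci <- function(data, statistic, replicates = 1000L, conf = 0.95,
                         seed = 1L) {
  if (replicates < 100) stop("use at least 100 bootstrap replicates")
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  point <- statistic(data)
  stats_r <- withr_seed(seed, {
    vapply(seq_len(replicates), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      res <- if (is.data.frame(data))
        statistic(data[idx, , drop = FALSE]) else statistic(data[idx])
      as.numeric(res)
    }, numeric(1))
  })
  skipped <- sum(is.na(stats_r))
  if (skipped > 0.01 * replicates)
    warning(sprintf("%d of %d bootstrap replicates degenerate and skipped",
                    skipped, replicates))
  q <- stats::quantile(stats_r, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       na.rm = TRUE, names = FALSE)
  structure(list(point = point, lower = q[1], upper = q[2],
                 method = "percentile bootstrap, patient-level resampling",
                 conf = conf, replicates = replicates,
                 n_skipped = skipped, seed = seed),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%.*f (CI %.*f-%.*f), %g%% %s, %d replicates\n",
              digits, x$point, digits, x$lower, digits, x$upper,
              100 * x$conf, x$method, x$replicates))
  invisible(x)
}

#' Audit-statistic closure for bootstrap intervals
#'
#' Builds a function of a target-records data frame computing either the
#' flip rate (flipped / no-initial-CA) or the positive-change rate
#' (positive change / flipped) from a [counterfactual_audit()] run, as a
#' fraction; `NA` when the denominator is empty.
#'
#' @param bundle fine-tuned `efcn_bundle` used by the audit.
#' @param schema a [feature_schema()].
#' @param statistic which rate to compute.
#' @param threshold audit threshold.
#' @return function mapping a records data frame to a scalar.
#' @export
audit_statistic <- function(bundle, schema,
                            statistic = c("flip_rate",
                                          "positive_change_rate"),
                            threshold = 0.5) {
  statistic <- match.arg(statistic)
  function(records) {
    ct <- suppressWarnings(
      counterfactual_audit(bundle, records, schema, threshold))$counts
    if (statistic == "flip_rate") {
      if (ct$n_no_initial_ca == 0) NA_real_
      else ct$n_flipped_to_ca / ct$n_no_initial_ca
    } else {
      if (ct$n_flipped_to_ca == 0) NA_real_
      else ct$n_positive_change / ct$n_flipped_to_ca
    }
  }
}
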