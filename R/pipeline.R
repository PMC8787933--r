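#' Pipeline configuration
#'
#' One document controls the full analysis: registry generation, the
#' four-way split, EFCN pair training, the classical leaderboard, and
#' the cohort counterfactual audit.  A single global seed fans out to
#' per-stage seeds through a fixed derivation so each stage is
#' independently reproducible.
#'
#' @param n_patients registry size.
#' @param seed global seed.
#' @param proportions split fractions (train, validation, test,
#'   cohort_analysis).
#' @param conv_filters,kernel_widths EFCN architecture.
#' @param hyper EFCN training overrides ([train_efcn()]).
#' @param fine_tune_hyper overrides for cohort fine-tuning (defaults to
#'   `hyper`).
#' @param grids classical grids (`NULL` = [default_grids()]).
#' @param min_instances,hospitals_per_cohort,n_cohorts cohort rules.
#' @param threshold decision/classification threshold.
#' @param bootstrap_replicates replicates for audit CIs (0 disables).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_patients = 2398L, seed = 1L,
                            proportions = c(train = 0.40,
                                            validation = 0.10,
                                            test = 0.25,
                                            cohort_analysis = 0.25),
                            conv_filters = c(32L, 64L, 32L),
                            kernel_widths = c(8L, 5L, 3L),
                            hyper = list(), fine_tune_hyper = NULL,
                            grids = NULL, min_instances = 75L,
                            hospitals_per_cohort = 5L, n_cohorts = 3L,
                            threshold = 0.5,
                            bootstrap_replicates = 1000L) {
  structure(list(n_patients = n_patients, seed = as.integer(seed),
                 proportions = proportions, conv_filters = conv_filters,
                 kernel_widths = kernel_widths, hyper = hyper,
                 fine_tune_hyper = if (is.null(fine_tune_hyper)) hyper
                                   else fine_tune_hyper,
                 grids = grids, min_instances = min_instances,
                 hospitals_per_cohort = hospitals_per_cohort,
                 n_cohorts = n_cohorts, threshold = threshold,
                 bootstrap_replicates = bootstrap_replicates),
            class = "pipeline_config")
}

# Fixed fan-out of the global seed into per-stage seeds (kept < 2^30 so
# small further offsets can never overflow R's 32-bit integers).
stage_seeds <- function(seed) {
  offs <- c(generate = 1L, split = 2L, efcn = 3L, grids = 4L,
            cohort = 5L, bootstrap = 6L)
  stats::setNames(as.integer((as.numeric(seed) * 101 + offs * 10007) %% 2^30),
                  names(offs))
}

#' Run the end-to-end analysis pipeline
#'
#' Stages, in causal order: generate the synthetic registry; split it
#' 40/10/25/25; train the decision EFCN, transfer its embeddings and
#' train the survival EFCN; run the classical leaderboard on identical
#' splits; stratify hospitals into cohorts on train + validation rows;
#' fine-tune the pair on the best cohort; counterfactually audit the
#' remaining cohorts on their cohort-analysis rows only, with optional
#' bootstrap intervals.  All artifacts are written under `out_dir` as
#' plain text (CSV/JSON) together with a manifest recording seeds,
#' sizes, paths and wall times.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param quiet suppress stage messages.
#' @return invisible list of class `pipeline_result`: `manifest` plus
#'   all in-memory artifacts (`synth`, `split`, `bundle`, `leaderboard`,
#'   `cohorts`, `cohort1_bundle`, `audits`, `cis`).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         out_dir = tempfile("postrosc_run_"),
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stage_seeds(config$seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  times <- list(); artifacts <- list(); paths <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      manifest <- list(seed = config$seed, stage_seeds = as.list(seeds),
                       completed_stages = names(times), failed_stage = name,
                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    times[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    res
  }
  schema <- default_schema()
  arch <- efcn_architecture(config$conv_filters, config$kernel_widths)

  say("stage generate: %d patients", config$n_patients)
  synth <- stage("generate", {
    gen <- default_config(n_patients = config$n_patients,
                          seed = seeds[["generate"]])
    s <- generate_registry(gen)
    paths$registry <- file.path(out_dir, "registry.csv")
    paths$sidecar <- file.path(out_dir, "sidecar.csv")
    write_registry(s$registry, paths$registry)
    utils::write.csv(s$sidecar, paths$sidecar, row.names = FALSE)
    s
  })
  reg <- synth$registry

  split <- stage("split", split_data(reg, config$proportions,
                                     seed = seeds[["split"]]))
  say("stage split: %s", paste(split$sizes, collapse = "/"))
  tr <- split_indices(split, "train"); va <- split_indices(split, "validation")

  say("stage efcn: training decision model, transferring, training survival model")
  bundle <- stage("efcn", train_efcn_pair(reg, schema, tr, va, arch,
                                          config$hyper,
                                          seed = seeds[["efcn"]]))

  say("stage leaderboard: %d classical families + efcn",
      length(if (is.null(config$grids)) default_grids() else config$grids))
  lb <- stage("leaderboard", {
    grids <- if (is.null(config$grids))
      default_grids(seed = seeds[["grids"]]) else config$grids
    l <- run_leaderboard(reg, schema, split, grids, bundle,
                         config$threshold)
    paths$leaderboard <- file.path(out_dir, "leaderboard.csv")
    write_leaderboard(l, paths$leaderboard)
    l
  })

  say("stage cohorts: stratifying hospitals and fine-tuning on cohort 1")
  cohort_out <- stage("cohorts", {
    tv <- c(tr, va)
    cohorts <- assign_cohorts(reg[tv, , drop = FALSE], schema,
                              config$min_instances,
                              config$hospitals_per_cohort,
                              config$n_cohorts, volume_records = reg)
    c1 <- cohorts$cohorts[[1]]
    c1_tr <- intersect(tr, which(reg[[schema$hospital_field]] %in% c1))
    c1_va <- intersect(va, which(reg[[schema$hospital_field]] %in% c1))
    c1_bundle <- retrain_on_cohort(bundle, reg, schema, c1_tr, c1_va,
                                   config$fine_tune_hyper,
                                   seed = seeds[["cohort"]])
    ca_idx <- split_indices(split, "cohort_analysis")
    audits <- list(); cis <- list()
    for (i in seq_along(cohorts$cohorts)[-1]) {
      lab <- names(cohorts$cohorts)[i]
      target <- reg[intersect(ca_idx, which(
        reg[[schema$hospital_field]] %in% cohorts$cohorts[[i]])), ,
        drop = FALSE]
      audits[[lab]] <- counterfactual_audit(c1_bundle, target, schema,
                                            config$threshold, label = lab)
      if (config$bootstrap_replicates > 0) {
        cis[[lab]] <- list(
          flip_rate = bootstrap_ci(
            target, audit_statistic(c1_bundle, schema, "flip_rate",
                                    config$threshold),
            config$bootstrap_replicates, seed = seeds[["bootstrap"]]),
          positive_change_rate = bootstrap_ci(
            target, audit_statistic(c1_bundle, schema,
                                    "positive_change_rate",
                                    config$threshold),
            config$bootstrap_replicates,
            seed = seeds[["bootstrap"]] + 1L))
      }
    }
    paths$audit <- file.path(out_dir, "audit.csv")
    audit_df <- do.call(rbind, lapply(names(audits), function(lab) {
      s <- summarize_table(audits[[lab]])
      cbind(cohort = lab, n_total = attr(s, "n_total"),
            as.data.frame(s))
    }))
    utils::write.csv(audit_df, paths$audit, row.names = FALSE)
    list(cohorts = cohorts, c1_bundle = c1_bundle, audits = audits,
         cis = cis)
  })

  paths$config <- file.path(out_dir, "config.json")
  cfg_json <- config
  cfg_json$grids <- NULL  # closures are not serializable; grids logged by name
  jsonlite::write_json(cfg_json, paths$config, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("postrosc")),
    seed = config$seed, stage_seeds = as.list(seeds),
    config_hash = unname(tools::md5sum(paths$config)),
    split_sizes = as.list(split$sizes),
    artifact_paths = paths, stage_seconds = times)
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  say("pipeline complete: %s", out_dir)
  invisible(structure(list(manifest = manifest, out_dir = out_dir,
                           schema = schema, synth = synth, split = split,
                           bundle = bundle, leaderboard = lb,
                           cohorts = cohort_out$cohorts,
                           cohort1_bundle = cohort_out$c1_bundle,
                           audits = cohort_out$audits,
                           cis = cohort_out$cis),
                      class = "pipeline_result"))
}

#' Human-readable report of a pipeline run
#'
#' Assembles the leaderboard, the EFCN test metrics, the cohort
#' stratification and the counterfactual audit tables (with bootstrap
#' intervals when computed) into one text document.  Every number is
#' recomputed from the run's in-memory artifacts.
#'
#' @param result a `pipeline_result`.
#' @param path optional file to write the report to.
#' @return character vector of report lines, invisibly when written.
#' @export
make_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  need <- c("leaderboard", "cohorts", "audits", "split")
  missing <- need[!vapply(need, function(f) !is.null(result[[f]]),
                          logical(1))]
  if (length(missing))
    stop("missing artifacts: ", paste(missing, collapse = ", "))
  fmt <- function(x) utils::capture.output(print(x))
  lines <- c(
    "== post-ROSC decision/outcome modeling run ==",
    sprintf("seed %d; splits %s", result$manifest$seed,
            paste(unlist(result$manifest$split_sizes), collapse = "/")),
    "",
    "-- model leaderboard (validation AUROC) --",
    fmt(result$leaderboard),
    "",
    "-- hospital cohorts (train+validation CPC1/2 rates) --",
    fmt(result$cohorts),
    "",
    "-- counterfactual audit: cohort-1 policy applied to other cohorts --")
  for (lab in names(result$audits)) {
    lines <- c(lines, fmt(result$audits[[lab]]))
    if (length(result$cis) && !is.null(result$cis[[lab]])) {
      for (s in names(result$cis[[lab]])) {
        ci <- result$cis[[lab]][[s]]
        lines <- c(lines, sprintf(
          "  %s %s: %.1f%% (CI %.1f-%.1f)", lab, s, 100 * ci$point,
          100 * ci$lower, 100 * ci$upper))
      }
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
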