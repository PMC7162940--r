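# End-to-end run: simulate (or ingest) -> performance metrics -> state model
# -> dynamics tests -> learner classification, with CSV/JSON outputs and a
# checksummed manifest.

.trial_log_columns <- c("participant_id", "config", "button", "label",
                        "trial_index", "duration", "direction", "loudness",
                        "freq_hz", "speed", "is_target", "response", "correct")

#' Write / read a trial-log CSV
#'
#' One row per trial with participant metadata repeated per row (columns:
#' participant_id, config, button, label, trial_index, duration, direction,
#' loudness, freq_hz, speed, is_target, response, correct).
#'
#' @param cohort a `cohort` object (or any list with a `trials` data frame).
#' @param path file path.
#' @return `write_trial_log` returns `path` invisibly; `read_trial_log`
#'   returns the trial data frame.
#' @export
write_trial_log <- function(cohort, path) {
  trials <- if (is.data.frame(cohort)) cohort else cohort$trials
  utils::write.csv(trials[, .trial_log_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Validate a trial log
#'
#' Schema and semantic checks on a trial log: required columns, legal values,
#' exactly 240 trials per participant with indices 1..240, and correctness
#' flags consistent with response and target flag. Semantic violations are
#' collected (with row numbers) rather than thrown.
#'
#' @param x path to a trial-log CSV, or an already-read trial data frame.
#' @return list with `trials` (the validated data frame) and `violations`
#'   (data frame `row`, `participant_id`, `issue`; zero rows when clean).
#' @export
validate_trial_log <- function(x) {
  trials <- if (is.character(x)) read_trial_log(x) else x
  missing <- setdiff(.trial_log_columns, names(trials))
  if (length(missing)) {
    stop("malformed trial log; missing columns: ",
         paste(missing, collapse = ", "))
  }
  viol <- list()
  note <- function(rows, ids, issue) {
    if (length(rows)) {
      viol[[length(viol) + 1L]] <<- data.frame(
        row = rows, participant_id = ids, issue = issue,
        stringsAsFactors = FALSE)
    }
  }
  bad <- which(!trials$config %in% 1:4)
  note(bad, trials$participant_id[bad], "illegal config")
  bad <- which(!trials$button %in% c("left", "right"))
  note(bad, trials$participant_id[bad], "illegal button")
  bad <- which(!trials$response %in% c("target_button", "nontarget_button",
                                       "none"))
  note(bad, trials$participant_id[bad], "illegal response")
  bad <- which(!trials$duration %in% c("short", "long") |
                 !trials$direction %in% c("up", "down"))
  note(bad, trials$participant_id[bad], "illegal tone feature")
  expected_correct <- (trials$is_target & trials$response == "target_button") |
    (!trials$is_target & trials$response == "nontarget_button")
  bad <- which(trials$correct != expected_correct)
  note(bad, trials$participant_id[bad], "correct flag inconsistent")
  for (id in unique(trials$participant_id)) {
    idx <- trials$trial_index[trials$participant_id == id]
    if (!identical(sort(idx), seq_len(240L)) && !identical(sort(as.integer(idx)),
                                                           1:240)) {
      note(min(which(trials$participant_id == id)), id,
           sprintf("expected trials 1..240, found %d trials", length(idx)))
    }
  }
  violations <- if (length(viol)) {
    do.call(rbind, viol)
  } else {
    data.frame(row = integer(0), participant_id = character(0),
               issue = character(0), stringsAsFactors = FALSE)
  }
  list(trials = trials, violations = violations)
}

#' Run configuration
#'
#' Bundles the pipeline's tunables: master seed, block sizes for the state
#' analysis (10) and the classifier features (40), number of mixture
#' components, CV folds, the participant allocation and the generator's
#' effect sizes.
#'
#' @param seed master seed; all stage seeds are derived from it.
#' @param block_size_q1 block size for the state analysis (must divide 240).
#' @param block_size_q3 block size for classifier features (must divide 240).
#' @param K mixture components for the state model.
#' @param cv_folds folds for classifier evaluation.
#' @param allocation participant allocation table.
#' @param config_effect,button_effect generator effect sizes.
#' @param out_dir output directory for stage files.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(seed = 1L, block_size_q1 = 10L, block_size_q3 = 40L,
                       K = 3L, cv_folds = 5L,
                       allocation = default_allocation(),
                       config_effect = c(0, 0, 0.30, 0),
                       button_effect = c(left = 0.05, right = 0),
                       out_dir = tempfile("audlearn_run_")) {
  if (240L %% block_size_q1 != 0L || 240L %% block_size_q3 != 0L) {
    stop("block sizes must divide 240")
  }
  if (K < 1L) stop("K must be >= 1")
  if (cv_folds < 2L) stop("cv_folds must be >= 2")
  structure(list(seed = as.integer(seed), block_size_q1 = block_size_q1,
                 block_size_q3 = block_size_q3, K = K, cv_folds = cv_folds,
                 allocation = allocation, config_effect = config_effect,
                 button_effect = button_effect, out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort (or ingests a trial log), computes block coefficient
#' tables, fits the state mixture models for sensitivity and specificity,
#' assigns block states, runs the button and configuration tests, evaluates
#' the learner classifier over all feature subspaces, and writes every stage
#' output under `config$out_dir` together with a checksummed manifest.
#'
#' @param config a [run_config()].
#' @param trial_log optional path to an existing trial-log CSV; when given it
#'   is validated and used instead of a simulated cohort (an error is thrown
#'   on semantic violations).
#' @return the manifest, class `run_manifest`: config echo, stage output
#'   paths, md5 checksums, package version.
#' @export
run_pipeline <- function(config = run_config(), trial_log = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # 1. cohort
  trials <- stage("cohort", {
    if (is.null(trial_log)) {
      cohort <- generate_cohort(allocation = config$allocation,
                                config_effect = config$config_effect,
                                button_effect = config$button_effect,
                                master_seed = derive_seed(config$seed, 101L))
      write_trial_log(cohort, out("cohort.csv"))
      cohort$trials
    } else {
      v <- validate_trial_log(trial_log)
      if (nrow(v$violations)) {
        stop("trial log has ", nrow(v$violations), " violations")
      }
      write_trial_log(v, out("cohort.csv"))
      v$trials
    }
  })
  meta <- unique(trials[, c("participant_id", "config", "button", "label")])

  # 2. block metrics
  blocks <- stage("metrics", {
    b <- lapply(c("sensitivity", "specificity"), function(cc) {
      tab <- block_series_table(trials, cc, config$block_size_q1)
      utils::write.csv(tab, out(paste0("blocks_", cc, ".csv")),
                       row.names = FALSE)
      tab
    })
    names(b) <- c("sensitivity", "specificity")
    for (cc in names(b)) {
      utils::write.csv(mean_cumulative_curves(trials, cc),
                       out(paste0("curves_", cc, ".csv")), row.names = FALSE)
    }
    b
  })

  # 3. state models + assignments
  states <- stage("states", {
    res <- lapply(names(blocks), function(cc) {
      tab <- blocks[[cc]]
      fit <- gmm1d(tab$value, K = config$K,
                   seed = derive_seed(config$seed, 103L))
      labels <- if (config$K == 3L) label_components(fit) else
        as.character(seq_len(config$K))
      comp <- assign_states(fit, tab$value)
      st <- data.frame(participant_id = tab$participant_id,
                       block = tab$block, state = labels[comp],
                       stringsAsFactors = FALSE)
      utils::write.csv(st, out(paste0("states_", cc, ".csv")),
                       row.names = FALSE)
      jsonlite::write_json(
        list(coefficient = cc, K = fit$K, weights = fit$weights,
             means = fit$means, sds = fit$sds, variances = fit$sds^2,
             log_likelihood = fit$logLik,
             bic_n_values = bic_gmm(fit),
             bic_n_participants = bic_gmm(fit, n = nrow(meta)),
             converged = fit$converged, component_labels = labels),
        out(paste0("model_", cc, ".json")), auto_unbox = TRUE, digits = NA)
      st
    })
    names(res) <- names(blocks)
    res
  })

  # 4. dynamics
  stage("dynamics", {
    dyn <- lapply(names(states), function(cc) {
      counts <- high_block_counts(states[[cc]], meta)
      bt <- button_effect_test(counts)
      cfg <- lapply(c("total", "partition1", "partition2", "partition3"),
                    function(sc) {
        m <- pairwise_config_tests(counts, sc)
        list(scope = sc, tests = as.data.frame(m))
      })
      list(coefficient = cc,
           counts = counts,
           button_test = list(U = bt$U, p = bt$p, n1 = bt$n1, n2 = bt$n2,
                              method = bt$method,
                              category = significance_category(bt$p)),
           config_tests = cfg)
    })
    names(dyn) <- names(states)
    for (cc in names(dyn)) {
      utils::write.csv(dyn[[cc]]$counts, out(paste0("counts_", cc, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(lapply(dyn, function(d) d[c("coefficient",
                                                     "button_test",
                                                     "config_tests")]),
                         out("dynamics.json"), auto_unbox = TRUE, digits = NA)
    dyn
  })

  # 5. classification
  stage("classify", {
    tab <- build_feature_table(list(participants = meta, trials = trials))
    utils::write.csv(cbind(participant_id = rownames(tab), tab),
                     out("features.csv"), row.names = FALSE)
    reports <- lapply(c(paste0("upto_", 40 * 1:5), "complete"), function(sp) {
      r <- stratified_cv(tab, sp, k = config$cv_folds,
                         seed = derive_seed(config$seed, 105L))
      list(subspace = sp, fold_scores = r$fold_scores, mean = r$mean,
           ci_half_width = r$ci_half, importance = r$importance)
    })
    jsonlite::write_json(reports, out("classification.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  files <- c("cohort.csv", "blocks_sensitivity.csv", "blocks_specificity.csv",
             "curves_sensitivity.csv", "curves_specificity.csv",
             "states_sensitivity.csv", "states_specificity.csv",
             "model_sensitivity.json", "model_specificity.json",
             "counts_sensitivity.csv", "counts_specificity.csv",
             "dynamics.json", "features.csv", "classification.json")
  manifest <- structure(
    list(seed = config$seed, K = config$K,
         block_size_q1 = config$block_size_q1,
         block_size_q3 = config$block_size_q3,
         out_dir = config$out_dir,
         files = files,
         checksums = stats::setNames(
           as.character(tools::md5sum(file.path(config$out_dir, files))),
           files),
         version = as.character(utils::packageVersion("audlearn")),
         timestamp = format(Sys.time(), tz = "UTC")),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest), out("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ") -> ", x$out_dir, "\n", sep = "")
  cat(length(x$files), "stage outputs written\n")
  invisible(x)
}
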