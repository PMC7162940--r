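# Block and cumulative performance coefficients.
#
# Sensitivity is the hit rate on target trials (target button pressed when a
# target tone played); specificity is the correct-rejection rate on
# non-target trials. Block coefficients are computed within contiguous
# blocks; cumulative coefficients at trial i use the strict prefix of trials
# 1..i-1. A response recorded as anything other than the required button
# (including "none") counts as incorrect for both coefficients.

.is_hit <- function(trials) trials$is_target & trials$response == "target_button"
.is_cr <- function(trials) !trials$is_target & trials$response == "nontarget_button"

#' Block sensitivity
#'
#' Proportion of target trials in a block for which the target button was
#' pressed.
#'
#' @param trials data frame of the block's trials with columns `is_target`
#'   and `response`.
#' @return ratio in \[0, 1\].
#' @export
block_sensitivity <- function(trials) {
  n_target <- sum(trials$is_target)
  if (n_target == 0L) stop("block contains no target trials")
  sum(.is_hit(trials)) / n_target
}

#' Block specificity
#'
#' Proportion of non-target trials in a block for which the nontarget button
#' was pressed.
#'
#' @inheritParams block_sensitivity
#' @return ratio in \[0, 1\].
#' @export
block_specificity <- function(trials) {
  n_nontarget <- sum(!trials$is_target)
  if (n_nontarget == 0L) stop("block contains no non-target trials")
  sum(.is_cr(trials)) / n_nontarget
}

#' Cumulative sensitivity / specificity at one trial
#'
#' The coefficient over the strict prefix of trials 1..i-1 (the trials a
#' participant has already experienced when trial i starts). When the prefix
#' contains no trial of the required kind the value is undefined and `NA` is
#' returned.
#'
#' @param trials a participant's trials, ordered by `trial_index`.
#' @param i trial index, >= 2.
#' @return ratio in \[0, 1\], or `NA` when undefined.
#' @export
cumulative_sensitivity <- function(trials, i) {
  if (i < 2L) stop("cumulative coefficients are defined for i >= 2")
  pre <- trials[trials$trial_index < i, , drop = FALSE]
  n_target <- sum(pre$is_target)
  if (n_target == 0L) return(NA_real_)
  sum(.is_hit(pre)) / n_target
}

#' @rdname cumulative_sensitivity
#' @export
cumulative_specificity <- function(trials, i) {
  if (i < 2L) stop("cumulative coefficients are defined for i >= 2")
  pre <- trials[trials$trial_index < i, , drop = FALSE]
  n_nontarget <- sum(!pre$is_target)
  if (n_nontarget == 0L) return(NA_real_)
  sum(.is_cr(pre)) / n_nontarget
}

#' Per-block coefficient series for one participant
#'
#' Partitions the 240 trials into contiguous equal blocks and computes the
#' chosen coefficient per block (24 values at block size 10; 6 values at
#' block size 40).
#'
#' @param trials one participant's trials (240 rows, `trial_index` 1..240).
#' @param coefficient `"sensitivity"` or `"specificity"`.
#' @param block_size block length in trials; must divide the number of trials.
#' @return numeric vector of length `n_trials / block_size`, with attributes
#'   `coefficient` and `block_size`.
#' @export
block_series <- function(trials, coefficient = c("sensitivity", "specificity"),
                         block_size = 10L) {
  coefficient <- match.arg(coefficient)
  n <- nrow(trials)
  if (n %% block_size != 0L) {
    stop("`block_size` (", block_size, ") must divide the number of trials (",
         n, ")")
  }
  trials <- trials[order(trials$trial_index), , drop = FALSE]
  f <- if (coefficient == "sensitivity") block_sensitivity else block_specificity
  blocks <- (seq_len(n) - 1L) %/% block_size + 1L
  vals <- vapply(split(seq_len(n), blocks), function(idx) {
    f(trials[idx, , drop = FALSE])
  }, numeric(1))
  structure(as.numeric(vals), coefficient = coefficient,
            block_size = as.integer(block_size))
}

#' Block-coefficient table for a whole cohort
#'
#' @param trials long trial log (multiple participants).
#' @inheritParams block_series
#' @return long data frame: `participant_id`, `block`, `value`.
#' @export
block_series_table <- function(trials,
                               coefficient = c("sensitivity", "specificity"),
                               block_size = 10L) {
  coefficient <- match.arg(coefficient)
  ids <- unique(trials$participant_id)
  out <- lapply(ids, function(id) {
    v <- block_series(trials[trials$participant_id == id, , drop = FALSE],
                      coefficient, block_size)
    data.frame(participant_id = id, block = seq_along(v), value = as.numeric(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cumulative coefficient curve for one participant
#'
#' @inheritParams block_series
#' @return data frame `trial` (2..n), `value` (`NA` where undefined).
#' @export
cumulative_curve <- function(trials,
                             coefficient = c("sensitivity", "specificity")) {
  coefficient <- match.arg(coefficient)
  trials <- trials[order(trials$trial_index), , drop = FALSE]
  num <- if (coefficient == "sensitivity") .is_hit(trials) else .is_cr(trials)
  den <- if (coefficient == "sensitivity") trials$is_target else !trials$is_target
  cn <- cumsum(num)
  cd <- cumsum(den)
  i <- 2:nrow(trials)
  v <- ifelse(cd[i - 1L] > 0L, cn[i - 1L] / cd[i - 1L], NA_real_)
  data.frame(trial = i, value = v)
}

#' Group means of cumulative curves
#'
#' Pointwise mean of the per-participant cumulative coefficient over every
#' (configuration, button) group. Participants whose value is undefined at a
#' trial are skipped at that trial (reduced n early on) rather than imputed.
#'
#' @param trials long trial log with `config` and `button` columns.
#' @inheritParams block_series
#' @return data frame `config`, `button`, `trial`, `value`, `n_defined`.
#' @export
mean_cumulative_curves <- function(trials,
                                   coefficient = c("sensitivity", "specificity")) {
  coefficient <- match.arg(coefficient)
  if (nrow(trials) == 0L) stop("empty trial log")
  meta <- unique(trials[, c("participant_id", "config", "button")])
  groups <- split(meta$participant_id, list(meta$config, meta$button), drop = TRUE)
  out <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    curves <- lapply(ids, function(id) {
      cumulative_curve(trials[trials$participant_id == id, , drop = FALSE],
                       coefficient)
    })
    vals <- do.call(cbind, lapply(curves, `[[`, "value"))
    key <- strsplit(g, ".", fixed = TRUE)[[1]]
    data.frame(
      config = as.integer(key[1]), button = key[2],
      trial = curves[[1]]$trial,
      value = rowMeans(vals, na.rm = TRUE),
      n_defined = rowSums(!is.na(vals)),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  res$value[res$n_defined == 0L] <- NA_real_
  res
}
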