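# Shared fixtures and independent counting oracles. The oracles are written
# as explicit loops over trials/pairs so that the vectorised implementations
# are checked against first-principles counting.

# A minimal trial data frame from parallel flags.
make_trials <- function(is_target, press_target) {
  data.frame(
    trial_index = seq_along(is_target),
    is_target = is_target,
    response = ifelse(press_target, "target_button", "nontarget_button"),
    stringsAsFactors = FALSE
  )
}

# Random trial block with at least one target and one non-target.
random_block <- function(n = 10L) {
  repeat {
    tg <- stats::runif(n) < 0.25
    if (any(tg) && any(!tg)) break
  }
  make_trials(tg, stats::runif(n) < 0.6)
}

# Loop-based oracles for the performance coefficients.
oracle_sensitivity <- function(trials) {
  num <- 0L
  den <- 0L
  for (i in seq_len(nrow(trials))) {
    if (trials$is_target[i]) {
      den <- den + 1L
      if (trials$response[i] == "target_button") num <- num + 1L
    }
  }
  num / den
}

oracle_specificity <- function(trials) {
  num <- 0L
  den <- 0L
  for (i in seq_len(nrow(trials))) {
    if (!trials$is_target[i]) {
      den <- den + 1L
      if (trials$response[i] == "nontarget_button") num <- num + 1L
    }
  }
  num / den
}

# All-pairs oracle for the Mann-Whitney U statistic (ties count 1/2).
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# Assigned high/med/low state table for a cohort, via the fitted mixture.
fit_states <- function(cohort, seed = 1L, coefficient = "sensitivity") {
  tab <- block_series_table(cohort$trials, coefficient, 10L)
  fit <- gmm1d(tab$value, K = 3L, seed = seed)
  labels <- label_components(fit)
  data.frame(participant_id = tab$participant_id, block = tab$block,
             state = labels[assign_states(fit, tab$value)],
             stringsAsFactors = FALSE)
}

# Cohort with a deliberately wide gap between learner and non-learner
# profiles: learners are pinned near the high state, non-learners near low.
strong_separation_cohort <- function(master_seed = 1L, n_per_cell = NULL) {
  profiles <- list(
    L = learner_profile(init = c(low = 0, med = 0.1, high = 0.9),
                        trans = rbind(c(0.05, 0.05, 0.90),
                                      c(0.02, 0.08, 0.90),
                                      c(0.01, 0.04, 0.95))),
    notL = learner_profile(init = c(low = 0.9, med = 0.1, high = 0),
                           trans = rbind(c(0.90, 0.09, 0.01),
                                         c(0.60, 0.39, 0.01),
                                         c(0.50, 0.45, 0.05)))
  )
  alloc <- default_allocation()
  if (!is.null(n_per_cell)) alloc$n <- n_per_cell
  generate_cohort(allocation = alloc, profiles = profiles,
                  config_effect = c(0, 0, 0, 0),
                  button_effect = c(left = 0, right = 0),
                  master_seed = master_seed)
}
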