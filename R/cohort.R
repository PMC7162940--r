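# Synthetic cohort generator: stimulus space, balanced trial schedules,
# Markov performance-state dynamics and Bernoulli response emissions.

# The four target configurations: which duration x direction pair is "target".
.config_table <- data.frame(
  config    = 1:4,
  duration  = c("short", "short", "long", "long"),
  direction = c("up", "down", "up", "down"),
  stringsAsFactors = FALSE
)

.states <- c("low", "med", "high")

#' Enumerate the stimulus space
#'
#' The task's tones vary over five features: duration (short 400 ms / long
#' 800 ms), direction of pitch change (up / down), loudness (low 76-81 dB /
#' high 86-91 dB), centre frequency (five low 500-831 Hz and five high
#' 1630-2639 Hz bands) and modulation speed (slow 0.25 / fast 0.5 oct/s),
#' giving 2 x 2 x 2 x 2 x 10 = 160 distinct tones. Duration and direction are
#' the category-determining features; the rest are irrelevant variation.
#'
#' @return a data frame with one row per tone and columns `duration`,
#'   `direction`, `loudness`, `freq_hz`, `speed`.
#' @examples
#' nrow(enumerate_tones())  # 160
#' @export
enumerate_tones <- function() {
  freqs <- tone_frequencies()
  out <- expand.grid(
    duration  = c("short", "long"),
    direction = c("up", "down"),
    loudness  = c("low", "high"),
    speed     = c("slow", "fast"),
    freq_hz   = freqs,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  out <- out[order(out$duration, out$direction, out$loudness, out$speed,
                   out$freq_hz),
             c("duration", "direction", "loudness", "freq_hz", "speed")]
  rownames(out) <- NULL
  out
}

# Ten centre frequencies: five geometrically spaced in each of the low
# (500-831 Hz) and high (1630-2639 Hz) ranges.
tone_frequencies <- function() {
  low <- 500 * (831 / 500)^((0:4) / 4)
  high <- 1630 * (2639 / 1630)^((0:4) / 4)
  round(c(low, high))
}

#' Target configurations
#'
#' Mapping from configuration id 1-4 to the duration x direction pair that
#' defines the target category: 1 = short/up, 2 = short/down, 3 = long/up,
#' 4 = long/down.
#'
#' @return data frame with columns `config`, `duration`, `direction`.
#' @export
target_configurations <- function() .config_table

#' Generate a balanced 240-trial schedule
#'
#' Each session has 240 trials; 25% (60) present the participant's target
#' duration x direction combination. The pseudo-randomisation balances the
#' four duration x direction combinations so that each occurs exactly 60
#' times over the session and 2 or 3 times within every consecutive 10-trial
#' block (each combination occurs exactly 5 times per 20-trial window, split
#' 2/3 or 3/2 between the window's two blocks at random). The non-determining
#' features (loudness, frequency, speed) are sampled uniformly.
#'
#' @param config target configuration id in 1..4.
#' @param seed integer seed; identical `(config, seed)` give identical
#'   schedules.
#' @return data frame of 240 rows: `trial_index`, `duration`, `direction`,
#'   `loudness`, `freq_hz`, `speed`, `is_target`.
#' @export
make_schedule <- function(config, seed) {
  if (length(config) != 1L || !config %in% 1:4) {
    stop("`config` must be one of 1, 2, 3, 4")
  }
  with_seed(seed, {
    combos <- .config_table[, c("duration", "direction")]
    n_windows <- 12L # 12 windows of 20 trials
    combo_idx <- integer(0)
    for (w in seq_len(n_windows)) {
      # each combination 5 times per window; two combinations get 3 in the
      # first 10-block, the other two get 2 (complement in the second block)
      three_first <- sample(1:4, 2L)
      blk1 <- c(rep(three_first, each = 3L),
                rep(setdiff(1:4, three_first), each = 2L))
      blk2 <- rep(1:4, times = 5L - tabulate(blk1, 4L))
      combo_idx <- c(combo_idx, sample(blk1), sample(blk2))
    }
    n <- length(combo_idx) # 240
    freqs <- tone_frequencies()
    out <- data.frame(
      trial_index = seq_len(n),
      duration    = combos$duration[combo_idx],
      direction   = combos$direction[combo_idx],
      loudness    = sample(c("low", "high"), n, replace = TRUE),
      freq_hz     = sample(freqs, n, replace = TRUE),
      speed       = sample(c("slow", "fast"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    out$is_target <- out$duration == combos$duration[config] &
      out$direction == combos$direction[config]
    out
  })
}

#' Construct a latent performance-state profile
#'
#' A participant's behaviour is generated from a three-state Markov chain
#' (low / med / high performance) over 10-trial blocks. Within a block every
#' target trial elicits a target-button press with probability
#' `hit_prob[state]` and every non-target trial a nontarget-button press with
#' probability `cr_prob[state]`. The default emission probabilities equal the
#' fitted block-sensitivity state means (low 0.358, med 0.6922, high 1.0) and
#' block-specificity state means (low 0.5916, med 0.8351, high 1.0), so that
#' mixture-model parameter recovery on simulated cohorts is a closed loop.
#'
#' @param init probability vector over (low, med, high) for the first block.
#' @param trans 3x3 row-stochastic matrix of per-block state transitions,
#'   rows/cols ordered (low, med, high).
#' @param hit_prob per-state probability of pressing the target button on a
#'   target trial.
#' @param cr_prob per-state probability of pressing the nontarget button on a
#'   non-target trial.
#' @return an object of class `learner_profile`.
#' @export
learner_profile <- function(init = c(low = 1, med = 0, high = 0),
                            trans = diag(3),
                            hit_prob = c(low = 0.358, med = 0.6922, high = 1.0),
                            cr_prob = c(low = 0.5916, med = 0.8351, high = 1.0)) {
  init <- as.numeric(init)
  trans <- as.matrix(trans)
  if (length(init) != 3L || any(init < 0) || abs(sum(init) - 1) > 1e-12) {
    stop("`init` must be a probability vector of length 3")
  }
  if (!all(dim(trans) == c(3L, 3L)) || any(trans < 0) ||
      any(abs(rowSums(trans) - 1) > 1e-12)) {
    stop("`trans` must be a 3x3 row-stochastic matrix")
  }
  stopifnot(length(hit_prob) == 3L, length(cr_prob) == 3L,
            all(hit_prob >= 0 & hit_prob <= 1),
            all(cr_prob >= 0 & cr_prob <= 1))
  structure(
    list(init = stats::setNames(init, .states),
         trans = matrix(trans, 3, 3, dimnames = list(.states, .states)),
         hit_prob = stats::setNames(as.numeric(hit_prob), .states),
         cr_prob = stats::setNames(as.numeric(cr_prob), .states)),
    class = "learner_profile"
  )
}

#' Default profiles for learners and non-learners
#'
#' The learner (`L`) profile starts mostly in the low/med states and is
#' attracted into an almost-absorbing high state; the non-learner (`notL`)
#' profile rarely reaches and does not retain the high state. These dynamics
#' are chosen to reproduce the qualitative population picture: most
#' participants accumulate runs of adjacent high-performance blocks late in
#' the session, while non-learners stay in low/med throughout.
#'
#' @param label `"L"` or `"notL"`.
#' @return a `learner_profile`.
#' @export
default_profile <- function(label = c("L", "notL")) {
  label <- match.arg(label)
  if (label == "L") {
    learner_profile(
      init = c(low = 0.75, med = 0.22, high = 0.03),
      trans = rbind(low  = c(0.55, 0.40, 0.05),
                    med  = c(0.10, 0.62, 0.28),
                    high = c(0.03, 0.12, 0.85))
    )
  } else {
    learner_profile(
      init = c(low = 0.80, med = 0.20, high = 0.00),
      trans = rbind(low  = c(0.70, 0.28, 0.02),
                    med  = c(0.35, 0.60, 0.05),
                    high = c(0.20, 0.45, 0.35))
    )
  }
}

#' Shift a profile's attraction toward the high state
#'
#' Task-design effects (target configuration, response button) enter the
#' generator as an additive shift `delta` on the probability of transitioning
#' into the high state (and of starting there); all probabilities are then
#' clipped to \[0, 1\] and rows renormalised.
#'
#' @param profile a `learner_profile`.
#' @param delta additive shift on transition probability into `high`.
#' @return the shifted `learner_profile`.
#' @export
apply_high_shift <- function(profile, delta) {
  stopifnot(inherits(profile, "learner_profile"))
  if (delta == 0) return(profile)
  shift_row <- function(p) {
    p["high"] <- p["high"] + delta
    p <- pmin(pmax(p, 0), 1)
    p / sum(p)
  }
  trans <- t(apply(profile$trans, 1L, shift_row))
  dimnames(trans) <- dimnames(profile$trans)
  learner_profile(shift_row(profile$init), trans,
                  profile$hit_prob, profile$cr_prob)
}

#' Simulate one participant's session
#'
#' Draws a balanced schedule for the participant's configuration, a latent
#' performance state per 10-trial block from the profile's Markov chain, and
#' a Bernoulli response per trial from the state's emission probabilities.
#' Correctness is recomputed from the response and target flag.
#'
#' @param profile a `learner_profile`.
#' @param config target configuration id 1..4.
#' @param button response button, `"left"` or `"right"`.
#' @param seed integer seed; the full record is reproducible from
#'   `(profile, config, button, seed)`.
#' @param id participant identifier.
#' @param label learner label stored with the record (`"L"`/`"notL"`).
#' @return a list of class `participant_record` with elements `id`, `config`,
#'   `button`, `label`, `states` (true latent state per block) and `trials`
#'   (240-row data frame).
#' @export
simulate_participant <- function(profile, config, button, seed,
                                 id = "P1", label = "L") {
  stopifnot(inherits(profile, "learner_profile"))
  if (!button %in% c("left", "right")) stop("`button` must be 'left' or 'right'")
  sched <- make_schedule(config, derive_seed(seed, 1L))
  with_seed(derive_seed(seed, 2L), {
    n_blocks <- nrow(sched) %/% 10L
    states <- character(n_blocks)
    s <- sample(.states, 1L, prob = profile$init)
    for (b in seq_len(n_blocks)) {
      states[b] <- s
      s <- sample(.states, 1L, prob = profile$trans[s, ])
    }
    block_of <- (sched$trial_index - 1L) %/% 10L + 1L
    st <- states[block_of]
    p_press_target <- ifelse(sched$is_target,
                             profile$hit_prob[st],
                             1 - profile$cr_prob[st])
    press_target <- stats::runif(nrow(sched)) < p_press_target
    trials <- sched
    trials$response <- ifelse(press_target, "target_button", "nontarget_button")
    trials$correct <- (trials$is_target & trials$response == "target_button") |
      (!trials$is_target & trials$response == "nontarget_button")
    structure(
      list(id = id, config = as.integer(config), button = button,
           label = label, states = states, trials = trials),
      class = "participant_record"
    )
  })
}

#' @export
print.participant_record <- function(x, ...) {
  cat("Participant", x$id, "- config", x$config, "- button", x$button,
      "- label", x$label, "\n")
  cat("  ", nrow(x$trials), "trials,",
      sum(x$trials$is_target), "targets,",
      sum(x$trials$correct), "correct\n")
  invisible(x)
}

#' Default participant allocation
#'
#' The allocation of 76 participants across the four target configurations,
#' two response buttons and the learner labels: 35 left / 41 right, 62 L /
#' 14 notL, with per-cell counts matching the original design (e.g.
#' configuration 1, left button: 10 participants, all L).
#'
#' @return data frame with columns `config`, `button`, `label`, `n`.
#' @export
default_allocation <- function() {
  alloc <- rbind(
    c(1, "left", 10, 0), c(1, "right", 9, 1),
    c(2, "left", 8, 0), c(2, "right", 6, 5),
    c(3, "left", 8, 1), c(3, "right", 6, 3),
    c(4, "left", 6, 2), c(4, "right", 9, 2)
  )
  out <- data.frame(
    config = rep(as.integer(alloc[, 1]), each = 2L),
    button = rep(alloc[, 2], each = 2L),
    label = rep(c("L", "notL"), times = nrow(alloc)),
    n = as.integer(t(alloc[, 3:4])),
    stringsAsFactors = FALSE
  )
  out
}

#' Generate a synthetic cohort
#'
#' One simulated participant per allocated slot. Learners and non-learners
#' use their respective default profiles (overridable), and the
#' configuration / button effects shift each participant's transition
#' probability into the high state additively before simulation.
#'
#' @param allocation data frame `config`, `button`, `label`, `n`; defaults to
#'   the design allocation of 76 participants.
#' @param profiles named list with elements `L` and `notL`.
#' @param config_effect numeric length 4, additive high-state shift per
#'   configuration. The default boosts configuration 3 (long/up), the
#'   configuration observed to yield more high-performance blocks.
#' @param button_effect named numeric (`left`, `right`); the default favours
#'   the left (index-finger) button.
#' @param master_seed integer; per-participant seeds are derived from it.
#' @return an object of class `cohort`: list with `participants` (metadata
#'   data frame), `trials` (long trial log), `states` (true latent states,
#'   participants x blocks).
#' @export
generate_cohort <- function(allocation = default_allocation(),
                            profiles = list(L = default_profile("L"),
                                            notL = default_profile("notL")),
                            config_effect = c(0, 0, 0.30, 0),
                            button_effect = c(left = 0.05, right = 0),
                            master_seed = 1L) {
  stopifnot(is.data.frame(allocation),
            all(c("config", "button", "label", "n") %in% names(allocation)))
  if (any(allocation$n < 0)) stop("allocation counts must be non-negative")
  slots <- allocation[rep(seq_len(nrow(allocation)), allocation$n), , drop = FALSE]
  n <- nrow(slots)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- slots$config[i]
    btn <- slots$button[i]
    lab <- slots$label[i]
    delta <- config_effect[cfg] + button_effect[[btn]]
    prof <- apply_high_shift(profiles[[lab]], delta)
    records[[i]] <- simulate_participant(
      prof, cfg, btn, seed = derive_seed(master_seed, i),
      id = sprintf("P%03d", i), label = lab
    )
  }
  meta <- data.frame(
    participant_id = vapply(records, `[[`, "", "id"),
    config = vapply(records, `[[`, 0L, "config"),
    button = vapply(records, `[[`, "", "button"),
    label = vapply(records, `[[`, "", "label"),
    stringsAsFactors = FALSE
  )
  trials <- do.call(rbind, lapply(records, function(r) {
    cbind(data.frame(participant_id = r$id, config = r$config,
                     button = r$button, label = r$label,
                     stringsAsFactors = FALSE),
          r$trials)
  }))
  rownames(trials) <- NULL
  states <- do.call(rbind, lapply(records, `[[`, "states"))
  rownames(states) <- meta$participant_id
  structure(list(participants = meta, trials = trials, states = states),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$participants), "participants,",
      nrow(x$trials), "trials\n")
  print(table(config = x$participants$config, button = x$participants$button))
  cat("labels:", paste(names(table(x$participants$label)),
                       table(x$participants$label), collapse = ", "), "\n")
  invisible(x)
}
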