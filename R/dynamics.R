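# Evolution toward learning: counts of high-performance blocks and
# Mann-Whitney U tests of the response-button and target-configuration
# effects on those counts.

#' Count occurrences of a state in a state sequence
#'
#' @param state_seq character vector of per-block state labels.
#' @param state the state to count.
#' @param allowed the legal label set.
#' @return integer count.
#' @export
count_state_blocks <- function(state_seq, state = "high",
                               allowed = c("low", "med", "high")) {
  if (!state %in% allowed) {
    stop("unknown state label '", state, "'")
  }
  sum(state_seq == state)
}

#' Per-partition state counts
#'
#' Splits a block-state sequence into `n_partitions` contiguous equal
#' partitions in temporal order (for 24 blocks and 3 partitions: beginning /
#' middle / end, 8 blocks each) and counts the state in each.
#'
#' @inheritParams count_state_blocks
#' @param n_partitions number of contiguous partitions.
#' @return integer vector of length `n_partitions`.
#' @export
partition_counts <- function(state_seq, state = "high", n_partitions = 3L,
                             allowed = c("low", "med", "high")) {
  n <- length(state_seq)
  if (n %% n_partitions != 0L) {
    stop("sequence length (", n, ") is not divisible by ", n_partitions)
  }
  if (!state %in% allowed) stop("unknown state label '", state, "'")
  part <- rep(seq_len(n_partitions), each = n %/% n_partitions)
  as.integer(vapply(split(state_seq, part), function(s) sum(s == state),
                    numeric(1)))
}

#' Per-participant high-performance block counts
#'
#' Builds the main dynamics statistic: for each participant, how many blocks
#' were assigned to the given state, overall and within each of the three
#' experiment partitions.
#'
#' @param states data frame `participant_id`, `block`, `state` (one row per
#'   block, as produced by the pipeline's state-assignment stage).
#' @param meta participant metadata (`participant_id`, `config`, `button`,
#'   and optionally `label`).
#' @param state state to count.
#' @param n_partitions number of contiguous partitions.
#' @return data frame: metadata columns plus `count_total` and
#'   `count_part1..count_partk`.
#' @export
high_block_counts <- function(states, meta, state = "high", n_partitions = 3L) {
  ids <- meta$participant_id
  rows <- lapply(ids, function(id) {
    s <- states[states$participant_id == id, , drop = FALSE]
    s <- s$state[order(s$block)]
    parts <- partition_counts(s, state, n_partitions)
    c(count_total = count_state_blocks(s, state),
      stats::setNames(parts, paste0("count_part", seq_len(n_partitions))))
  })
  cbind(meta, do.call(rbind, rows))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The statistic `U` is the
#' number of pairs `(x_i, y_j)` with `x_i > y_j`, counting ties as 1/2
#' (computed via midranks). The p-value is exact — by enumeration of all
#' group assignments — for small tie-free samples (`n1 + n2 <= 12`), and
#' otherwise uses the normal approximation with tie correction and
#' continuity correction. Exposed directly because the analysis needs the U
#' statistic in a fixed orientation (first sample) together with the tie
#' handling used on heavily tied count data.
#'
#' @param x,y numeric samples.
#' @param alternative `"two_sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @return object of class `utest`: list with `U`, `p`, `n1`, `n2`,
#'   `method` (`"exact"` or `"normal_tie_corrected"`), `alternative`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x)
  y <- as.numeric(y)
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty")
  comb <- c(x, y)
  r <- rank(comb) # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(comb) > 0L

  if (!ties && n1 + n2 <= 12L) {
    # exact null distribution by enumeration of all C(n1+n2, n1) assignments
    ranks <- seq_len(n1 + n2)
    sets <- utils::combn(ranks, n1)
    us <- colSums(sets) - n1 * (n1 + 1) / 2
    p_less <- mean(us <= U)
    p_greater <- mean(us >= U)
    p <- switch(alternative,
      two_sided = min(1, 2 * min(p_less, p_greater)),
      greater = p_greater,
      less = p_less
    )
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    N <- n1 + n2
    tie_tab <- table(comb)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      sigma <- sqrt(sigma2)
      p <- switch(alternative,
        two_sided = min(1, 2 * stats::pnorm(
          -(max(abs(U - mu) - 0.5, 0)) / sigma)),
        greater = stats::pnorm((U - mu - 0.5) / sigma, lower.tail = FALSE),
        less = stats::pnorm((U - mu + 0.5) / sigma)
      )
    }
    method <- "normal_tie_corrected"
  }
  structure(list(U = U, p = p, n1 = n1, n2 = n2, method = method,
                 alternative = alternative),
            class = "utest")
}

#' @export
print.utest <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s, %s)\n", x$method, x$alternative))
  cat(sprintf("  U = %.2f  (n1 = %d, n2 = %d),  p = %.4g\n",
              x$U, x$n1, x$n2, x$p))
  invisible(x)
}

#' Significance category
#'
#' Three-band scheme used for the configuration comparisons, which are run
#' as confound checks without multiple-comparison correction: `significant`
#' (p < 0.05), `marginal` (0.05 <= p < 0.2), `n.s.` (p >= 0.2).
#'
#' @param p p-value(s).
#' @return character vector of categories.
#' @export
significance_category <- function(p) {
  ifelse(p < 0.05, "significant", ifelse(p < 0.2, "marginal", "n.s."))
}

#' Button effect on high-performance block counts
#'
#' Mann-Whitney U test of `count_total` between left-button and right-button
#' participants; `U` is oriented to the left-button sample.
#'
#' @param counts output of [high_block_counts()] (needs `button`,
#'   `count_total`).
#' @param alternative as in [mann_whitney_u()].
#' @return a `utest`.
#' @export
button_effect_test <- function(counts, alternative = "two_sided") {
  btn <- counts$button
  if (length(unique(btn)) < 2L) stop("need both button groups")
  mann_whitney_u(counts$count_total[btn == "left"],
                 counts$count_total[btn == "right"],
                 alternative = alternative)
}

#' Pairwise configuration comparisons
#'
#' Two-sided Mann-Whitney U tests of the high-performance block count
#' between every pair of target configurations, either on the whole session
#' (`scope = "total"`) or within one of the three partitions. P-values are
#' deliberately not corrected for multiple comparisons: the comparisons
#' screen for design confounds rather than test substantive hypotheses.
#'
#' @param counts output of [high_block_counts()].
#' @param scope `"total"` or `"partition1"`/`"partition2"`/`"partition3"`.
#' @return object of class `config_tests`: data frame `config_a`, `config_b`,
#'   `U`, `p`, `category` (one row per unordered pair), with attribute
#'   `p_matrix` (symmetric 4x4 matrix).
#' @export
pairwise_config_tests <- function(counts,
                                  scope = c("total", "partition1",
                                            "partition2", "partition3")) {
  scope <- match.arg(scope)
  col <- if (scope == "total") "count_total" else sub("partition", "count_part", scope)
  cfgs <- sort(unique(counts$config))
  if (!all(1:4 %in% cfgs)) stop("all four configuration groups must be present")
  pairs <- utils::combn(cfgs, 2L)
  rows <- apply(pairs, 2L, function(pr) {
    a <- counts[[col]][counts$config == pr[1]]
    b <- counts[[col]][counts$config == pr[2]]
    tt <- mann_whitney_u(a, b, "two_sided")
    data.frame(config_a = pr[1], config_b = pr[2], U = tt$U, p = tt$p,
               category = significance_category(tt$p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pm <- matrix(NA_real_, 4, 4, dimnames = list(cfgs, cfgs))
  for (i in seq_len(nrow(out))) {
    pm[out$config_a[i], out$config_b[i]] <- out$p[i]
    pm[out$config_b[i], out$config_a[i]] <- out$p[i]
  }
  structure(out, p_matrix = pm, scope = scope, class = c("config_tests",
                                                         "data.frame"))
}

#' @export
print.config_tests <- function(x, ...) {
  cat("Pairwise configuration comparisons (", attr(x, "scope"), ")\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}
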