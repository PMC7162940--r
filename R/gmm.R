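# One-dimensional Gaussian mixture model fitted by EM.
#
# This is the package's core estimator: pooled block-performance coefficients
# are modelled as a K-component univariate Gaussian mixture, the number of
# components is judged with BIC, and each block is assigned to the component
# with the highest posterior probability. Because block coefficients are
# ratios quantised on a small grid (e.g. multiples of 1/3 for blocks with 3
# targets), near-degenerate components with tiny spread are legitimate; the
# variance floor keeps them proper densities instead of likelihood spikes.

#' Fit a univariate Gaussian mixture by EM
#'
#' Maximum-likelihood fit of a K-component normal mixture to a numeric
#' vector, with multiple restarts and a variance floor. The first restart is
#' initialised deterministically at quantile-spread means with the pooled
#' standard deviation and uniform weights; further restarts jitter the means.
#' The restart with the highest log-likelihood is returned.
#'
#' @param x numeric observations (more than `K` values).
#' @param K number of mixture components (>= 1).
#' @param n_init number of EM restarts.
#' @param tol convergence tolerance on the relative log-likelihood change.
#' @param max_iter maximum EM iterations per restart.
#' @param var_floor lower bound on component variances. The floor (default
#'   1e-6, i.e. sd 1e-3) admits near-point components, which arise naturally
#'   when many blocks share the exact value 1.
#' @param seed integer seed governing the restart jitter; `NULL` uses the
#'   current RNG state.
#' @return an object of class `gmm1d`: list with `K`, `weights`, `means`,
#'   `sds` (all length K, unordered), `logLik`, `n_obs`, `iterations`,
#'   `converged`, `loglik_trace` (of the winning restart), `degenerate`
#'   (TRUE when two components coincide), `var_floor` and the data `x`.
#' @seealso [bic_gmm()], [scan_k()], [assign_states()], [label_components()]
#' @examples
#' x <- c(rnorm(100, 0.2, 0.02), rnorm(100, 0.8, 0.02))
#' fit <- gmm1d(x, K = 2, seed = 1)
#' coef(fit)
#' @export
gmm1d <- function(x, K = 3L, n_init = 10L, tol = 1e-8, max_iter = 500L,
                  var_floor = 1e-6, seed = NULL) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("`x` must not contain NA")
  K <- as.integer(K)
  if (K < 1L) stop("`K` must be >= 1")
  if (length(x) <= K) stop("need more observations than components")

  if (K == 1L) {
    # closed form
    mu <- mean(x)
    v <- max(mean((x - mu)^2), var_floor)
    ll <- sum(stats::dnorm(x, mu, sqrt(v), log = TRUE))
    return(new_gmm1d(K, 1, mu, sqrt(v), ll, x, iterations = 0L,
                     converged = TRUE, loglik_trace = ll,
                     var_floor = var_floor))
  }

  sd0 <- max(stats::sd(x), sqrt(var_floor))
  mu0 <- as.numeric(stats::quantile(x, probs = (2 * seq_len(K) - 1) / (2 * K)))
  fits <- vector("list", n_init)
  with_seed(seed, {
    for (r in seq_len(n_init)) {
      mu_r <- if (r == 1L) mu0 else mu0 + stats::rnorm(K, 0, sd0 / 2)
      fits[[r]] <- em_gmm1d(x, mu_r, rep(sd0, K), rep(1 / K, K),
                            tol = tol, max_iter = max_iter,
                            var_floor = var_floor)
    }
  })
  lls <- vapply(fits, `[[`, 0, "logLik")
  dup <- vapply(fits, function(f) any(diff(sort(f$means)) < 1e-6), logical(1))
  # a solution with duplicate component means is an equivalent-likelihood
  # reparameterisation of a smaller mixture; prefer a distinct-mean restart
  # when one matches the best log-likelihood to numerical tolerance
  best_i <- which.max(lls)
  if (dup[best_i]) {
    ok <- which(!dup & lls >= lls[best_i] - 1e-3)
    if (length(ok)) best_i <- ok[which.max(lls[ok])]
  }
  best <- fits[[best_i]]
  new_gmm1d(K, best$weights, best$means, best$sds, best$logLik, x,
            iterations = best$iterations, converged = best$converged,
            loglik_trace = best$trace, var_floor = var_floor)
}

# Single EM run from a given starting point.
em_gmm1d <- function(x, mu, sd, w, tol, max_iter, var_floor) {
  n <- length(x)
  K <- length(mu)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    # E step, in log space: components can be near-degenerate
    logd <- vapply(seq_len(K), function(k) {
      stats::dnorm(x, mu[k], sd[k], log = TRUE) + log(w[k])
    }, numeric(n))
    lse <- row_logsumexp(logd)
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    ll_old <- ll
    resp <- exp(logd - lse)
    nk <- pmax(colSums(resp), 1e-300)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    v <- vapply(seq_len(K), function(k) {
      sum(resp[, k] * (x - mu[k])^2) / nk[k]
    }, numeric(1))
    # constrained M step: the variance maximiser under v >= floor is the
    # unconstrained MLE clipped at the floor, so EM stays monotone
    sd <- sqrt(pmax(v, var_floor))
  }
  list(weights = w, means = mu, sds = sd, logLik = ll,
       iterations = it, converged = converged, trace = trace)
}

new_gmm1d <- function(K, weights, means, sds, logLik, x, iterations,
                      converged, loglik_trace, var_floor) {
  degenerate <- FALSE
  if (K > 1L) {
    o <- order(means)
    degenerate <- any(diff(means[o]) < 1e-8 & abs(diff(sds[o])) < 1e-8)
  }
  structure(
    list(K = K, weights = as.numeric(weights), means = as.numeric(means),
         sds = as.numeric(sds), logLik = logLik, n_obs = length(x),
         iterations = iterations, converged = converged,
         loglik_trace = loglik_trace, degenerate = degenerate,
         var_floor = var_floor, x = x),
    class = "gmm1d"
  )
}

#' Construct a mixture model with known parameters
#'
#' Builds a `gmm1d` object directly from component parameters, without
#' fitting — e.g. to simulate from published state parameters or to serve as
#' a planted ground truth.
#'
#' @param means,sds,weights component parameters (equal lengths; weights are
#'   normalised to sum 1).
#' @return a `gmm1d` object with `n_obs = 0` and no data.
#' @export
gmm1d_model <- function(means, sds, weights = rep(1 / length(means), length(means))) {
  stopifnot(length(means) == length(sds), length(means) == length(weights),
            all(sds > 0), all(weights >= 0), sum(weights) > 0)
  structure(
    list(K = length(means), weights = as.numeric(weights / sum(weights)),
         means = as.numeric(means), sds = as.numeric(sds),
         logLik = NA_real_, n_obs = 0L, iterations = 0L, converged = NA,
         loglik_trace = numeric(0), degenerate = FALSE,
         var_floor = 0, x = numeric(0)),
    class = "gmm1d"
  )
}

#' @export
print.gmm1d <- function(x, digits = 4, ...) {
  cat("Gaussian mixture (1-D), K =", x$K, "\n")
  print(round(coef(x), digits))
  if (!is.na(x$logLik)) {
    cat("log-likelihood:", format(x$logLik, digits = digits + 2),
        "on", x$n_obs, "observations\n")
  }
  if (isTRUE(x$degenerate)) cat("note: degenerate duplicate components\n")
  invisible(x)
}

#' @export
coef.gmm1d <- function(object, ...) {
  rbind(weight = object$weights, mean = object$means, sd = object$sds)
}

#' @export
logLik.gmm1d <- function(object, ...) {
  structure(object$logLik, df = 3L * object$K, nobs = object$n_obs,
            class = "logLik")
}

#' @export
nobs.gmm1d <- function(object, ...) object$n_obs

#' @export
summary.gmm1d <- function(object, ...) {
  out <- list(
    coef = coef(object), K = object$K, logLik = object$logLik,
    n_obs = object$n_obs, bic = if (object$n_obs > 0) bic_gmm(object) else NA,
    converged = object$converged, iterations = object$iterations,
    labels = if (object$K == 3L && !anyDuplicated(object$means)) {
      label_components(object)
    } else {
      NULL
    }
  )
  class(out) <- "summary.gmm1d"
  out
}

#' @export
print.summary.gmm1d <- function(x, digits = 4, ...) {
  cat("Gaussian mixture (1-D), K =", x$K, "\n\n")
  cc <- x$coef
  if (!is.null(x$labels)) colnames(cc) <- x$labels
  print(round(cc, digits))
  cat("\nlog-likelihood:", format(x$logLik, digits = digits + 2),
      "  BIC(n = n_obs):", format(x$bic, digits = digits + 2), "\n")
  cat("converged:", x$converged, "after", x$iterations, "iterations\n")
  invisible(x)
}

#' Bayesian information criterion for a fitted mixture
#'
#' `BIC = ln(n) * 3K - 2 * logLik`, counting 3 parameters per component
#' (weight, mean, sd). The effective sample size `n` is a modelling choice:
#' the pooled likelihood uses one value per block, but when blocks of the
#' same participant are treated as repeated measures it is conventional to
#' penalise by the number of participants instead. `n` therefore defaults to
#' the number of fitted values and should be set explicitly (e.g. to the
#' number of participants) when that convention is wanted.
#'
#' @param object a fitted `gmm1d`.
#' @param n effective sample size used in the penalty.
#' @return the BIC value.
#' @export
bic_gmm <- function(object, n = nobs(object)) {
  stopifnot(inherits(object, "gmm1d"), n >= 1)
  log(n) * 3 * object$K - 2 * object$logLik
}

#' Fit mixtures over a range of component counts
#'
#' Fits `gmm1d` for K = 1..`k_max` and reports each fit's BIC, to support
#' choosing the number of performance states. Also reports the elbow
#' suggested by the largest second difference of the BIC curve; selection is
#' left to the caller (the pipeline default is K = 3).
#'
#' @inheritParams gmm1d
#' @param k_max largest component count to try.
#' @param n effective sample size passed to [bic_gmm()].
#' @param ... further arguments to [gmm1d()].
#' @return data frame `K`, `logLik`, `BIC`, with attributes `models` (list of
#'   fits) and `elbow_k`.
#' @export
scan_k <- function(x, k_max = 10L, n = length(x), seed = NULL, ...) {
  if (k_max >= length(x)) stop("`k_max` must be smaller than the number of values")
  models <- lapply(seq_len(k_max), function(k) {
    gmm1d(x, K = k, seed = if (is.null(seed)) NULL else derive_seed(seed, k), ...)
  })
  out <- data.frame(
    K = seq_len(k_max),
    logLik = vapply(models, `[[`, 0, "logLik"),
    BIC = vapply(models, bic_gmm, 0, n = n)
  )
  elbow <- if (k_max >= 3L) {
    d2 <- diff(diff(out$BIC))
    as.integer(which.max(d2) + 1L)
  } else {
    NA_integer_
  }
  attr(out, "models") <- models
  attr(out, "elbow_k") <- elbow
  out
}

#' Posterior probabilities and state assignment
#'
#' `predict(type = "posterior")` returns the n x K matrix of posterior
#' component probabilities P(Z = k | x), including the mixture weights.
#' `type = "state"` returns the maximum-posterior component index per value;
#' exact posterior ties are broken toward the component with the larger mean
#' (the more favourable performance state).
#'
#' @param object a `gmm1d`.
#' @param newdata numeric values; defaults to the fitted data.
#' @param type `"state"` or `"posterior"`.
#' @param ... unused.
#' @return integer vector of component indices, or a posterior matrix.
#' @export
predict.gmm1d <- function(object, newdata = object$x,
                          type = c("state", "posterior"), ...) {
  type <- match.arg(type)
  x <- as.numeric(newdata)
  logd <- vapply(seq_len(object$K), function(k) {
    stats::dnorm(x, object$means[k], object$sds[k], log = TRUE) +
      log(object$weights[k])
  }, numeric(length(x)))
  logd <- matrix(logd, nrow = length(x))
  post <- exp(logd - row_logsumexp(logd))
  if (type == "posterior") return(post)
  # ties (to numerical tolerance) toward the larger mean: among columns whose
  # posterior is within 1e-12 of the row maximum, keep the largest-mean one
  o <- order(object$means)
  po <- post[, o, drop = FALSE]
  cand <- po >= apply(po, 1L, max) - 1e-12
  idx <- max.col(cand, ties.method = "last")
  o[idx]
}

#' @rdname predict.gmm1d
#' @param values numeric values to assign.
#' @export
assign_states <- function(object, values = object$x) {
  predict(object, newdata = values, type = "state")
}

#' Label the components of a 3-state model
#'
#' Maps the three components to performance-state names by mean:
#' the largest mean is `high`, then `med`, then `low`.
#'
#' @param object a `gmm1d` with `K = 3`.
#' @return character vector of length 3: label of each component, in
#'   component order.
#' @export
label_components <- function(object) {
  stopifnot(inherits(object, "gmm1d"))
  if (object$K != 3L) stop("state labelling requires K = 3")
  if (anyDuplicated(object$means)) {
    stop("equal component means: labelling is ambiguous")
  }
  lab <- character(3L)
  lab[order(object$means, decreasing = TRUE)] <- c("high", "med", "low")
  lab
}

#' Simulate from a mixture model
#'
#' @param object a `gmm1d` (fitted or built with [gmm1d_model()]).
#' @param nsim number of draws.
#' @param seed integer seed or `NULL`.
#' @param ... unused.
#' @return numeric vector of draws with attribute `component` (the latent
#'   component of each draw).
#' @export
simulate.gmm1d <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    z <- sample.int(object$K, nsim, replace = TRUE, prob = object$weights)
    structure(stats::rnorm(nsim, object$means[z], object$sds[z]),
              component = z)
  })
}

#' Plot a fitted mixture over its data
#'
#' Histogram of the fitted values with the mixture density and the weighted
#' component densities overlaid.
#'
#' @param x a fitted `gmm1d`.
#' @param breaks histogram breaks.
#' @param ... passed to [graphics::hist()].
#' @export
plot.gmm1d <- function(x, breaks = 30, ...) {
  if (x$n_obs == 0L) stop("model carries no data to plot")
  h <- graphics::hist(x$x, breaks = breaks, freq = FALSE,
                      main = sprintf("Gaussian mixture, K = %d", x$K),
                      xlab = "value", ...)
  xs <- seq(min(h$breaks), max(h$breaks), length.out = 512)
  dens <- sapply(seq_len(x$K), function(k) {
    x$weights[k] * stats::dnorm(xs, x$means[k], x$sds[k])
  })
  for (k in seq_len(x$K)) graphics::lines(xs, dens[, k], lty = 2, col = k + 1)
  graphics::lines(xs, rowSums(dens), lwd = 2)
  invisible(x)
}
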