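#' Acquisition-function specification
#'
#' Chooses how the optimizer trades off exploiting the surrogate's predicted
#' minimum against exploring its uncertainty (minimization convention
#' throughout):
#'
#' * `EI` — expected improvement over the best observed score, with
#'   exploration margin `xi` (default 0.01);
#' * `PI` — probability of improvement, margin `xi`;
#' * `LCB` — lower confidence bound `mean - kappa * std` (default
#'   `kappa = 1.96`), whose minimizer is the suggestion.
#'
#' @param kind One of `"EI"`, `"PI"`, `"LCB"`.
#' @param xi Non-negative exploration margin for EI/PI.
#' @param kappa Non-negative width multiplier for LCB.
#' @return Object of class `acq_spec`.
#' @export
acq_spec <- function(kind = c("EI", "PI", "LCB"), xi = 0.01, kappa = 1.96) {
  kind <- match.arg(kind)
  if (xi < 0) stop("xi must be >= 0", call. = FALSE)
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  structure(list(kind = kind, xi = xi, kappa = kappa), class = "acq_spec")
}

#' Expected improvement (minimization)
#'
#' Closed form for Y ~ Normal(mu, sd^2):
#' `EI = (best - mu - xi) * pnorm(z) + sd * dnorm(z)` with
#' `z = (best - mu - xi) / sd`; degenerates to `max(best - mu - xi, 0)` at
#' `sd = 0`. Always non-negative.
#'
#' @param mu,sd Predictive mean and standard deviation (sd >= 0); vectorized.
#' @param best Best (lowest) observed score.
#' @param xi Exploration margin (>= 0).
#' @export
expected_improvement <- function(mu, sd, best, xi = 0) {
  if (any(!is.finite(mu)) || any(!is.finite(sd)) || !is.finite(best) ||
      !is.finite(xi)) {
    stop("non-finite acquisition inputs", call. = FALSE)
  }
  if (any(sd < 0)) stop("sd must be >= 0", call. = FALSE)
  n <- max(length(mu), length(sd))
  mu <- rep_len(mu, n); sd <- rep_len(sd, n)
  imp <- best - mu - xi
  out <- pmax(imp, 0)
  pos <- sd > 0
  if (any(pos)) {
    z <- imp[pos] / sd[pos]
    out[pos] <- imp[pos] * stats::pnorm(z) + sd[pos] * stats::dnorm(z)
  }
  pmax(out, 0)
}

#' Probability of improvement (minimization)
#'
#' `PI = pnorm((best - mu - xi) / sd)`; at `sd = 0` it is the indicator of
#' `mu < best - xi`.
#'
#' @inheritParams expected_improvement
#' @export
probability_of_improvement <- function(mu, sd, best, xi = 0) {
  if (any(!is.finite(mu)) || any(!is.finite(sd)) || !is.finite(best) ||
      !is.finite(xi)) {
    stop("non-finite acquisition inputs", call. = FALSE)
  }
  if (any(sd < 0)) stop("sd must be >= 0", call. = FALSE)
  n <- max(length(mu), length(sd))
  mu <- rep_len(mu, n); sd <- rep_len(sd, n)
  imp <- best - mu - xi
  out <- as.numeric(imp > 0)
  pos <- sd > 0
  out[pos] <- stats::pnorm(imp[pos] / sd[pos])
  out
}

#' Lower confidence bound (minimization)
#'
#' `LCB = mu - kappa * sd`; lower values are more promising.
#'
#' @param mu,sd Predictive mean and standard deviation (sd >= 0); vectorized.
#' @param kappa Non-negative width multiplier.
#' @export
lcb <- function(mu, sd, kappa = 1.96) {
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (any(sd < 0)) stop("sd must be >= 0", call. = FALSE)
  mu - kappa * sd
}

# acquisition "utility" to MAXIMIZE, evaluated at unit coordinates
acq_utility <- function(U, model, spec, best) {
  pr <- gp_predict(model, U)
  switch(spec$kind,
    EI = expected_improvement(pr$mean, pr$std_model, best, spec$xi),
    PI = probability_of_improvement(pr$mean, pr$std_model, best, spec$xi),
    LCB = -lcb(pr$mean, pr$std_model, spec$kappa)
  )
}

# maximize fn (on unit coords, bounded [0,1]) from a set of starts
polish_unit <- function(starts, fn) {
  width <- ncol(starts)
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[r, ], function(u) -fn(matrix(u, nrow = 1)),
                   method = "L-BFGS-B",
                   lower = rep(0, width), upper = rep(1, width),
                   control = list(maxit = 50)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  best
}

#' Maximize an acquisition function over the feasible space
#'
#' Scores a seeded batch of uniform feasible candidate recipes, locally
#' polishes the most promising ones in unit coordinates (bounded
#' quasi-Newton), decodes, and returns the best feasible suggestion. Integer
#' and categorical dimensions are optimized through their continuous
#' relaxation and re-scored after decoding. Deterministic given the RNG seed.
#'
#' @param model Fitted `gp_model`.
#' @param space A `search_space`.
#' @param constraints Optional constraints (see [satisfies()]).
#' @param spec An [acq_spec()].
#' @param best Best observed score so far (defaults to the minimum of the
#'   model's training targets).
#' @param n_candidates Uniform candidates scored (default 1000).
#' @param n_polish Candidates refined locally (default 5).
#' @return The suggested recipe.
#' @export
argmax_acquisition <- function(model, space, constraints = NULL,
                               spec = acq_spec(), best = min(model$y),
                               n_candidates = 1000, n_polish = 5) {
  cand <- sample_space(space, n_candidates, constraints)
  U <- encode_points(space, cand)
  util <- acq_utility(U, model, spec, best)
  ord <- order(util, decreasing = TRUE)

  best_x <- cand[[ord[1]]]
  best_u <- util[ord[1]]
  fn <- function(u) acq_utility(u, model, spec, best)
  top <- U[ord[seq_len(min(n_polish, length(ord)))], , drop = FALSE]
  for (r in seq_len(nrow(top))) {
    res <- polish_unit(top[r, , drop = FALSE], fn)
    if (is.null(res)) next
    x <- from_unit(space, res$par)  # snap ints/categories, then re-score
    if (!satisfies(constraints, x, space)) next
    u_dec <- fn(matrix(to_unit(space, x), nrow = 1))
    if (u_dec > best_u) {
      best_u <- u_dec
      best_x <- x
    }
  }
  best_x
}
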