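#' Matern-5/2 covariance between unit-cube points
#'
#' Anisotropic Matern-5/2 kernel
#' \deqn{k(u, v) = \sigma_f^2 (1 + \sqrt{5} r + 5 r^2 / 3) e^{-\sqrt{5} r},
#'   \quad r^2 = \sum_j ((u_j - v_j)/\ell_j)^2.}
#' Twice-differentiable sample paths; the standard default covariance for
#' Bayesian optimization surrogates.
#'
#' @param U,V Matrices of unit coordinates (rows are points); vectors are
#'   treated as single points.
#' @param lengthscales Positive per-coordinate length scales.
#' @param sigma_f2 Signal variance (> 0).
#' @return `nrow(U) x nrow(V)` covariance matrix.
#' @export
kernel_matern52 <- function(U, V, lengthscales, sigma_f2 = 1) {
  if (is.null(dim(U))) U <- matrix(U, nrow = 1)
  if (is.null(dim(V))) V <- matrix(V, nrow = 1)
  if (any(!is.finite(lengthscales)) || any(lengthscales <= 0)) {
    stop("length scales must be positive", call. = FALSE)
  }
  A <- sweep(U, 2, lengthscales, "/")
  B <- sweep(V, 2, lengthscales, "/")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  r <- sqrt(pmax(d2, 0))
  sigma_f2 * (1 + sqrt(5) * r + (5 / 3) * r^2) * exp(-sqrt(5) * r)
}

gp_chol <- function(K) {
  # escalate jitter until the Cholesky succeeds
  jit <- 0
  for (i in 0:8) {
    L <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jit <- if (jit == 0) 1e-10 else jit * 10
  }
  stop("covariance matrix is not positive definite", call. = FALSE)
}

# negative log marginal likelihood of standardized targets
gp_nll <- function(par, X, y_std) {
  d <- ncol(X)
  ls <- exp(par[1:d]); sf2 <- exp(par[d + 1]); sn2 <- exp(par[d + 2])
  K <- kernel_matern52(X, X, ls, sf2) + diag(sn2, nrow(X))
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), y_std))
  0.5 * sum(y_std * alpha) + sum(log(diag(L))) + 0.5 * length(y_std) * log(2 * pi)
}

#' Fit a Gaussian-process surrogate
#'
#' Inputs must be unit-cube coordinates (see [to_unit()]); targets are
#' standardized internally to zero mean and unit variance, so the length-scale
#' and variance hyperparameters are scale-free. Hyperparameters (per-coordinate
#' length scales, signal variance, observation-noise variance) are chosen by
#' maximizing the log marginal likelihood with bounded quasi-Newton from a
#' fixed fallback start (all length scales 0.3, signal variance 1, noise
#' variance 0.01) plus `n_restarts` log-uniform random restarts. The fit is
#' guaranteed at least as good (in marginal likelihood) as the fallback.
#'
#' @param X Matrix of unit coordinates, one row per observation (a list of
#'   recipes plus a `space` also works via [encode_points()]).
#' @param y Numeric targets, finite, one per row.
#' @param n_restarts Random restarts for hyperparameter search (default 5).
#' @param noise_floor Lower bound on the noise variance of the standardized
#'   targets; default 1e-10 (jitter scale).
#' @return Object of class `gp_model`.
#' @export
gp_fit <- function(X, y, n_restarts = 5, noise_floor = 1e-10) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) == 0L) stop("cannot fit a GP with no observations", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (any(!is.finite(y))) stop("targets must be finite", call. = FALSE)

  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1  # constant or single y
  y_std <- (y - y_mean) / y_sd
  d <- ncol(X)

  sn2_hi <- stats::var(y_std) + 1
  if (!is.finite(sn2_hi)) sn2_hi <- 2
  lower <- c(rep(log(1e-3), d), log(1e-6), log(noise_floor))
  upper <- c(rep(log(1e3), d), log(1e3), log(max(sn2_hi, noise_floor * 10)))
  fallback <- c(rep(log(0.3), d), log(1), log(0.01))

  starts <- list(fallback)
  for (i in seq_len(n_restarts)) {
    starts[[i + 1L]] <- lower + stats::runif(d + 2) * (upper - lower)
  }

  best_par <- fallback
  best_val <- gp_nll(fallback, X, y_std)
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, gp_nll, X = X, y_std = y_std, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 100)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) && fit$value < best_val) {
      best_val <- fit$value
      best_par <- fit$par
    }
  }

  ls <- exp(best_par[1:d]); sf2 <- exp(best_par[d + 1]); sn2 <- exp(best_par[d + 2])
  K <- kernel_matern52(X, X, ls, sf2) + diag(sn2, nrow(X))
  L <- gp_chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), y_std))
  structure(list(
    X = X, y = y, y_mean = y_mean, y_sd = y_sd,
    lengthscales = ls, sigma_f2 = sf2, sigma_n2 = sn2,
    L = L, alpha = alpha, log_marginal_likelihood = -best_val
  ), class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat("<gp_model> n =", nrow(x$X),
      "| lengthscales:", paste(signif(x$lengthscales, 3), collapse = ", "),
      "| signal var:", signif(x$sigma_f2, 3),
      "| noise var:", signif(x$sigma_n2, 3),
      "| logML:", signif(x$log_marginal_likelihood, 5), "\n")
  invisible(x)
}

#' Posterior prediction from a fitted GP
#'
#' Returns the predictive mean and two standard deviations per query point:
#' `std_model`, the epistemic (model) uncertainty, and `std_with_noise`, which
#' additionally includes the learned observation noise — useful for showing
#' or hiding experimental noise in plots and reports.
#'
#' @param model A `gp_model`.
#' @param X Matrix of unit coordinates (rows are query points).
#' @param include_noise If `TRUE`, the `std` column is `std_with_noise`,
#'   otherwise `std_model`. Both are always returned.
#' @return `data.frame` with columns `mean`, `std_model`, `std_with_noise`,
#'   `std` — all in the original units of `y`.
#' @export
gp_predict <- function(model, X, include_noise = FALSE) {
  if (!inherits(model, "gp_model")) stop("model is not a fitted gp_model",
                                         call. = FALSE)
  if (is.null(dim(X))) X <- matrix(X, ncol = ncol(model$X))
  Ks <- kernel_matern52(model$X, X, model$lengthscales, model$sigma_f2)
  mu <- drop(crossprod(Ks, model$alpha))
  v <- forwardsolve(t(model$L), Ks)
  var_m <- pmax(model$sigma_f2 - colSums(v^2), 0)
  std_model <- sqrt(var_m) * model$y_sd
  std_noise <- sqrt(var_m + model$sigma_n2) * model$y_sd
  data.frame(
    mean = model$y_mean + mu * model$y_sd,
    std_model = std_model,
    std_with_noise = std_noise,
    std = if (include_noise) std_noise else std_model
  )
}

#' Serialize a fitted GP to a JSON-ready list
#'
#' @param model A `gp_model`.
#' @return A plain list (hyperparameters + training data) suitable for
#'   `jsonlite::toJSON`.
#' @export
gp_to_list <- function(model) {
  list(
    lengthscales = unname(model$lengthscales),
    sigma_f2 = model$sigma_f2,
    sigma_n2 = model$sigma_n2,
    y_mean = model$y_mean,
    y_sd = model$y_sd,
    log_marginal_likelihood = model$log_marginal_likelihood,
    X = unname(as.matrix(model$X)),
    y = unname(model$y)
  )
}
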