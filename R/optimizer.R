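#' Create an ask/tell Bayesian optimizer
#'
#' The optimizer first serves `n_initial_points` Latin-hypercube recipes
#' ("initial design", chosen with no consideration of experimental data),
#' then fits a Gaussian-process surrogate to all told observations and
#' suggests the recipe maximizing the acquisition function. Everything is a
#' pure function of `(space, settings, seed, told data)`: replaying the same
#' tells yields the identical suggestion sequence.
#'
#' Minimization convention: lower scores are better.
#'
#' @param space A [search_space()].
#' @param n_initial_points Size of the initial LHS design (>= 1; default 4).
#' @param acq An [acq_spec()]; default expected improvement with `xi = 0.01`.
#' @param seed Integer seed governing the initial design, surrogate restarts
#'   and candidate generation.
#' @param constraints Optional list of constraints (see [satisfies()]).
#' @return An optimizer object (mutable environment of class `bo_optimizer`).
#' @examples
#' sp <- search_space(dim_real("Acid", 30, 85), dim_real("Indicator", 5, 40))
#' opt <- bo_optimizer(sp, n_initial_points = 4, seed = 1)
#' x <- ask(opt)
#' result <- tell(opt, list(80, 35), 50.8)
#' @export
bo_optimizer <- function(space, n_initial_points = 4, acq = acq_spec(),
                         seed = 1L, constraints = NULL) {
  stopifnot(inherits(space, "search_space"))
  if (n_initial_points < 1L) stop("n_initial_points must be >= 1", call. = FALSE)
  if (!inherits(acq, "acq_spec")) stop("acq must be an acq_spec", call. = FALSE)
  if (!is.null(constraints)) {
    if (inherits(constraints, "labopt_constraint")) constraints <- list(constraints)
    check_constraint_names(constraints, space)
  }
  opt <- new.env(parent = emptyenv())
  opt$space <- space
  opt$constraints <- constraints
  opt$n_initial <- as.integer(n_initial_points)
  opt$acq <- acq
  opt$seed <- as.integer(seed)
  opt$queue <- withr::with_seed(derive_seed(seed, 0L), {
    q <- lhs_design(space, n_initial_points)
    if (!is.null(constraints)) {
      # keep feasible LHS points; top up with rejection sampling
      keep <- Filter(function(p) satisfies(constraints, p, space), q)
      if (length(keep) < n_initial_points) {
        keep <- c(keep, sample_space(space, n_initial_points - length(keep),
                                     constraints))
      }
      q <- keep
    }
    q
  })
  opt$xs <- list()
  opt$ys <- numeric(0)
  opt$origins <- character(0)
  opt$cache <- NULL       # cached suggestion: list(x, origin)
  opt$pending <- list()   # untold batch suggestions (model phase)
  opt$model <- NULL
  opt$model_n <- -1L
  opt$models <- list()    # one surrogate per refit on real data
  class(opt) <- c("bo_optimizer", "environment")
  opt
}

#' @export
print.bo_optimizer <- function(x, ...) {
  cat("<bo_optimizer> ", length(x$xs), " observations, ",
      length(x$queue), " initial points pending, acquisition ", x$acq$kind,
      "\n", sep = "")
  invisible(x)
}

# deterministic seed stream: one sub-seed per (seed, event) pair
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 97651 * 20011 + as.numeric(k) * 7919 + 12345) %%
               2147483647)
}

recipes_equal <- function(space, a, b) {
  a <- as_recipe(space, a); b <- as_recipe(space, b)
  for (i in seq_along(space$dims)) {
    if (space$dims[[i]]$kind == "categorical") {
      if (!identical(a[[i]], b[[i]])) return(FALSE)
    } else if (abs(a[[i]] - b[[i]]) > 1e-9) return(FALSE)
  }
  TRUE
}

# fit (or reuse) the surrogate on the real observations
ensure_model <- function(opt) {
  n <- length(opt$xs)
  if (n < 1L) stop("no observations to fit a model on", call. = FALSE)
  if (opt$model_n != n || is.null(opt$model)) {
    X <- encode_points(opt$space, opt$xs)
    opt$model <- withr::with_seed(derive_seed(opt$seed, 50000L + n),
                                  gp_fit(X, opt$ys))
    opt$model_n <- n
    opt$models[[length(opt$models) + 1L]] <- opt$model
  }
  opt$model
}

# one model-phase suggestion given extra pseudo-observations (lies)
suggest_model_point <- function(opt, lie_xs = list(), lie_ys = numeric(0)) {
  n_eff <- length(opt$xs) + length(lie_xs)
  model <- if (length(lie_xs) == 0L) {
    ensure_model(opt)
  } else {
    X <- encode_points(opt$space, c(opt$xs, lie_xs))
    y <- c(opt$ys, lie_ys)
    withr::with_seed(derive_seed(opt$seed, 50000L + n_eff), gp_fit(X, y))
  }
  withr::with_seed(
    derive_seed(opt$seed, 1000L + n_eff),
    argmax_acquisition(model, opt$space, opt$constraints, opt$acq,
                       best = min(opt$ys))
  )
}

#' Ask the optimizer for the next experiment
#'
#' Returns the pending cached suggestion if one exists (asking twice without
#' telling returns the same recipe — no physical experiment is wasted), else
#' the next initial-design point, else the acquisition maximizer of a
#' surrogate fitted to all observations.
#'
#' @param opt A `bo_optimizer`.
#' @return The suggested recipe (named list).
#' @export
ask <- function(opt) {
  stopifnot(inherits(opt, "bo_optimizer"))
  if (!is.null(opt$cache)) return(opt$cache$x)
  if (length(opt$queue) > 0L) {
    x <- opt$queue[[1L]]
    opt$queue <- opt$queue[-1L]
    opt$cache <- list(x = x, origin = "initial")
    return(x)
  }
  x <- suggest_model_point(opt)
  opt$cache <- list(x = x, origin = "model")
  x
}

#' Report an experiment result to the optimizer
#'
#' Appends the observation, clears the cached suggestion and any batch
#' pseudo-observations, and (once the initial design is complete) refits the
#' surrogate. Points never asked for may be told too (origin `"manual"`),
#' e.g. to import historical data.
#'
#' @param opt A `bo_optimizer`.
#' @param x The recipe that was run (must lie within the space bounds).
#' @param y Its measured score (finite number; lower is better).
#' @param origin Optional override of the recorded origin (used when
#'   replaying persisted logs).
#' @return A `bo_result` (see [get_result()]).
#' @export
tell <- function(opt, x, y, origin = NULL) {
  stopifnot(inherits(opt, "bo_optimizer"))
  x <- as_recipe(opt$space, x)
  y <- as.numeric(y)
  if (length(y) != 1L || !is.finite(y)) stop("score must be a finite number",
                                             call. = FALSE)
  in_initial <- length(opt$queue) > 0L ||
    (!is.null(opt$cache) && opt$cache$origin == "initial")
  if (is.null(origin)) {
    origin <- if (in_initial) {
      "initial"
    } else if (!is.null(opt$cache) &&
               recipes_equal(opt$space, x, opt$cache$x)) {
      "model"
    } else if (any(vapply(opt$pending, function(p)
      recipes_equal(opt$space, x, p), logical(1)))) {
      "model"
    } else {
      "manual"
    }
  }
  # consume one initial-design slot per tell while the design is being served
  if (is.null(opt$cache) && length(opt$queue) > 0L) {
    opt$queue <- opt$queue[-1L]
  }
  opt$cache <- NULL
  keep <- !vapply(opt$pending, function(p) recipes_equal(opt$space, x, p),
                  logical(1))
  opt$pending <- opt$pending[keep]
  opt$xs[[length(opt$xs) + 1L]] <- x
  opt$ys <- c(opt$ys, y)
  opt$origins <- c(opt$origins, origin)
  if (length(opt$xs) >= opt$n_initial) ensure_model(opt)
  get_result(opt)
}

#' Ask for a batch of experiments at once
#'
#' Serves remaining initial-design points first; model-phase slots are filled
#' iteratively with the constant-liar heuristic: after each suggestion a
#' pseudo-observation (the minimum, mean, or maximum of the real scores, per
#' `strategy`) is imputed at it and the surrogate refitted, so later
#' suggestions avoid duplication. The pseudo-observations are discarded
#' afterwards; the optimizer's real observations are untouched.
#'
#' @param opt A `bo_optimizer`.
#' @param n Number of suggestions (>= 1).
#' @param strategy `"cl_min"` (default, most exploitative), `"cl_mean"`, or
#'   `"cl_max"`.
#' @return List of `n` recipes, in suggestion order.
#' @export
ask_batch <- function(opt, n, strategy = c("cl_min", "cl_mean", "cl_max")) {
  stopifnot(inherits(opt, "bo_optimizer"))
  strategy <- match.arg(strategy)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (n == 1L) return(list(ask(opt)))
  lie_of <- function() switch(strategy,
    cl_min = min(opt$ys), cl_mean = mean(opt$ys), cl_max = max(opt$ys))
  pts <- vector("list", n)
  lie_xs <- list(); lie_ys <- numeric(0)
  for (j in seq_len(n)) {
    if (j == 1L && !is.null(opt$cache)) {
      x <- opt$cache$x
      if (opt$cache$origin == "model") {
        lie_xs <- c(lie_xs, list(x)); lie_ys <- c(lie_ys, lie_of())
      }
    } else if (length(opt$queue) > 0L) {
      x <- opt$queue[[1L]]
      opt$queue <- opt$queue[-1L]
    } else {
      if (length(opt$xs) == 0L) {
        stop("batch asks beyond the initial design need at least one told ",
             "observation", call. = FALSE)
      }
      x <- suggest_model_point(opt, lie_xs, lie_ys)
      lie_xs <- c(lie_xs, list(x)); lie_ys <- c(lie_ys, lie_of())
      opt$pending <- c(opt$pending, list(x))
    }
    pts[[j]] <- x
  }
  pts
}

#' Extract the optimization result
#'
#' @param opt A `bo_optimizer`.
#' @return A `bo_result`: the observation table, best observed recipe and
#'   score, the current surrogate (`NULL` during the initial phase), the
#'   history of fitted surrogates, and the space/settings needed to analyse
#'   the run ([expected_min()], [convergence_trace()],
#'   [partial_dependence()]).
#' @export
get_result <- function(opt) {
  stopifnot(inherits(opt, "bo_optimizer"))
  n <- length(opt$xs)
  obs <- observations_df(opt$space, opt$xs, opt$ys, opt$origins)
  best_i <- if (n > 0L) which.min(opt$ys) else NA_integer_
  structure(list(
    space = opt$space,
    constraints = opt$constraints,
    seed = opt$seed,
    n_initial_points = opt$n_initial,
    observations = obs,
    xs = opt$xs,
    ys = opt$ys,
    best_x = if (n > 0L) opt$xs[[best_i]] else NULL,
    best_y = if (n > 0L) opt$ys[best_i] else NA_real_,
    model = opt$model,
    model_history = opt$models
  ), class = "bo_result")
}

observations_df <- function(space, xs, ys, origins) {
  nms <- dim_names(space)
  cols <- lapply(seq_along(space$dims), function(i) {
    v <- lapply(xs, `[[`, i)
    if (space$dims[[i]]$kind == "categorical") as.character(unlist(v, use.names = FALSE))
    else as.numeric(unlist(v, use.names = FALSE))
  })
  if (length(xs) == 0L) {
    cols <- lapply(space$dims, function(d)
      if (d$kind == "categorical") character(0) else numeric(0))
  }
  names(cols) <- nms
  df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  df$iteration <- seq_len(length(ys))
  df$y <- ys
  df$origin <- origins
  df[, c("iteration", nms, "y", "origin"), drop = FALSE]
}

#' @export
print.bo_result <- function(x, ...) {
  cat("<bo_result> ", nrow(x$observations), " observations; best y = ",
      format(x$best_y), "\n", sep = "")
  if (!is.null(x$best_x)) {
    cat("  best recipe:", paste(names(x$best_x), "=",
                                vapply(x$best_x, format, ""), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Best-so-far convergence trace
#'
#' Element i is the minimum score among the first i observations; the trace
#' is non-increasing and is the standard diagnostic for deciding whether an
#' optimization campaign has converged.
#'
#' @param result A `bo_result`.
#' @return Numeric vector, one element per observation.
#' @export
convergence_trace <- function(result) {
  stopifnot(inherits(result, "bo_result"))
  if (length(result$ys) == 0L) stop("no observations yet", call. = FALSE)
  cummin(result$ys)
}

#' Expected minimum of the fitted surrogate
#'
#' Minimizes the surrogate's predictive mean over the feasible space (seeded
#' uniform candidates, local polish from the most promising candidates and
#' from every observed recipe) and reports the minimizing recipe with its
#' predicted score and standard deviation. By default the standard deviation
#' is the model (epistemic) uncertainty only; set `include_noise = TRUE` to
#' add the learned observation noise.
#'
#' @param result A `bo_result` with a fitted model.
#' @param include_noise Include observation noise in the reported std?
#' @param n_candidates Seeded uniform candidates (default 1000).
#' @param n_polish Candidates polished locally, besides the observed recipes
#'   (default 5).
#' @return List with elements `x` (recipe), `mean`, `std`.
#' @export
expected_min <- function(result, include_noise = FALSE, n_candidates = 1000,
                         n_polish = 5) {
  stopifnot(inherits(result, "bo_result"))
  model <- result$model
  if (is.null(model)) stop("result has no fitted model yet", call. = FALSE)
  space <- result$space
  cand <- withr::with_seed(
    derive_seed(result$seed, 90000L + length(result$ys)),
    sample_space(space, n_candidates, result$constraints))
  U <- encode_points(space, cand)
  mu <- gp_predict(model, U)$mean
  ord <- order(mu)
  starts <- rbind(U[ord[seq_len(min(n_polish, nrow(U)))], , drop = FALSE],
                  encode_points(space, result$xs))
  best_x <- cand[[ord[1]]]
  best_mu <- mu[ord[1]]
  fn <- function(u) -gp_predict(model, u)$mean  # polish_unit maximizes
  for (r in seq_len(nrow(starts))) {
    res <- polish_unit(starts[r, , drop = FALSE], fn)
    if (is.null(res)) next
    x <- from_unit(space, res$par)
    if (!satisfies(result$constraints, x, space)) next
    m <- gp_predict(model, matrix(to_unit(space, x), nrow = 1))$mean
    if (m < best_mu) { best_mu <- m; best_x <- x }
  }
  # observed recipes are feasible starts in their own right
  for (i in seq_along(result$xs)) {
    m <- gp_predict(model, matrix(to_unit(space, result$xs[[i]]), nrow = 1))$mean
    if (m < best_mu) { best_mu <- m; best_x <- result$xs[[i]] }
  }
  pr <- gp_predict(model, matrix(to_unit(space, best_x), nrow = 1),
                   include_noise = include_noise)
  list(x = best_x, mean = pr$mean, std = pr$std)
}

#' Partial-dependence profile of the surrogate
#'
#' For each grid value of the chosen dimension(s), averages the surrogate's
#' predictive mean over seeded background samples of the remaining
#' dimensions — the plot-ready summary behind objective plots.
#'
#' @param result A `bo_result` with a fitted model.
#' @param dims One dimension name (1-D profile) or two (2-D grid).
#' @param grid_size Grid points per numeric dimension (default 20).
#' @param n_background Background samples to average over (default 50).
#' @return `data.frame` with the grid coordinate column(s), `mean`, and `std`
#'   (the averaged model std at the grid points).
#' @export
partial_dependence <- function(result, dims, grid_size = 20,
                               n_background = 50) {
  stopifnot(inherits(result, "bo_result"))
  model <- result$model
  if (is.null(model)) stop("result has no fitted model yet", call. = FALSE)
  space <- result$space
  nms <- dim_names(space)
  if (!all(dims %in% nms)) {
    stop("unknown dimension(s): ", paste(setdiff(dims, nms), collapse = ", "),
         call. = FALSE)
  }
  if (!length(dims) %in% 1:2) stop("dims must have length 1 or 2", call. = FALSE)
  bg <- withr::with_seed(
    derive_seed(result$seed, 70000L + length(result$ys)),
    sample_space(space, n_background, result$constraints))
  grid_values <- function(nm) {
    d <- space$dims[[match(nm, nms)]]
    if (d$kind == "categorical") d$categories
    else if (d$kind == "integer") unique(round(seq(d$low, d$high,
                                                   length.out = grid_size)))
    else seq(d$low, d$high, length.out = grid_size)
  }
  gl <- lapply(dims, grid_values)
  names(gl) <- dims
  grid <- expand.grid(gl, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  means <- numeric(nrow(grid)); stds <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pts <- lapply(bg, function(p) {
      for (nm in dims) p[[nm]] <- grid[[nm]][g]
      p
    })
    pr <- gp_predict(model, encode_points(space, pts))
    means[g] <- mean(pr$mean)
    stds[g] <- mean(pr$std_model)
  }
  grid$mean <- means
  grid$std <- stds
  grid
}

#' Export a result to JSON
#'
#' Writes observations, the best recipe/score, settings, and the
#' hyperparameters of every interim surrogate. [result_from_json()] restores
#' an equivalent `bo_result` (without refitting the surrogate history's
#' factorization caches: the final model is refitted from the stored data).
#'
#' @param result A `bo_result`.
#' @param path Output file.
#' @export
result_to_json <- function(result, path) {
  obj <- list(
    schema = "labopt/result/1",
    space = space_to_list(result$space),
    constraints = constraints_to_list(result$constraints),
    seed = result$seed,
    n_initial_points = result$n_initial_points,
    observations = result$observations,
    best_y = result$best_y,
    best_x = result$best_x,
    models = lapply(result$model_history, function(m)
      gp_to_list(m)[c("lengthscales", "sigma_f2", "sigma_n2",
                      "log_marginal_likelihood")])
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname result_to_json
#' @export
result_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  space <- space_from_list(obj$space)
  constraints <- constraints_from_list(obj$constraints)
  opt <- bo_optimizer(space, n_initial_points = obj$n_initial_points,
                      seed = obj$seed, constraints = constraints)
  for (row in obj$observations) {
    tell(opt, row[dim_names(space)], row$y, origin = row$origin)
  }
  get_result(opt)
}
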