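# Shared fixtures and independent oracles used across the suite.

# the two-factor color space (acid %, indicator uL), with and without grid
color_space <- function(grid = TRUE) {
  step <- if (grid) 5 else NULL
  search_space(dim_real("Acid", 30, 85, grid_step = step),
               dim_real("Indicator", 5, 40, grid_step = step))
}

unit_space_1d <- function() search_space(dim_real("x", 0, 1))

# exact LHS stratification check: each of the n strata of every numeric
# dimension must contain exactly one point
lhs_stratified <- function(space, points) {
  n <- length(points)
  for (i in seq_along(space$dims)) {
    d <- space$dims[[i]]
    if (d$kind == "categorical") next
    u <- vapply(points, function(p) (p[[i]] - d$low) / (d$high - d$low),
                numeric(1))
    counts <- tabulate(pmin(floor(u * n) + 1L, n), nbins = n)
    if (!all(counts == 1L)) return(FALSE)
  }
  TRUE
}

# brute-force non-dominated sorting by repeated pairwise dominance scans
brute_force_fronts <- function(objectives) {
  objectives <- as.matrix(objectives)
  remaining <- seq_len(nrow(objectives))
  fronts <- list()
  while (length(remaining) > 0L) {
    nd <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) {
        i != j && all(objectives[j, ] <= objectives[i, ]) &&
          any(objectives[j, ] < objectives[i, ])
      }, logical(1)))
    }, logical(1))]
    fronts[[length(fronts) + 1L]] <- sort(nd)
    remaining <- setdiff(remaining, nd)
  }
  fronts
}

# 2-D hypervolume (minimization) w.r.t. a reference point: rectangle sweep
hypervolume_2d <- function(front, ref) {
  front <- as.matrix(front)
  front <- front[front[, 1] <= ref[1] & front[, 2] <= ref[2], , drop = FALSE]
  if (nrow(front) == 0L) return(0)
  front <- front[order(front[, 1], front[, 2]), , drop = FALSE]
  # non-dominated staircase: obj2 strictly decreasing as obj1 increases
  nd <- list()
  best2 <- Inf
  for (i in seq_len(nrow(front))) {
    if (front[i, 2] < best2) {
      nd[[length(nd) + 1L]] <- front[i, ]
      best2 <- front[i, 2]
    }
  }
  nd <- do.call(rbind, nd)
  hv <- 0
  right <- ref[1]
  for (i in rev(seq_len(nrow(nd)))) {
    hv <- hv + (right - nd[i, 1]) * (ref[2] - nd[i, 2])
    right <- nd[i, 1]
  }
  hv
}

# dense linear-algebra GP oracle: recompute posterior mean/std with solve()
gp_oracle_predict <- function(model, Xq) {
  ys <- (model$y - model$y_mean) / model$y_sd
  K <- kernel_matern52(model$X, model$X, model$lengthscales, model$sigma_f2) +
    diag(model$sigma_n2, nrow(model$X))
  Kinv <- solve(K)
  Ks <- kernel_matern52(Xq, model$X, model$lengthscales, model$sigma_f2)
  mu <- as.numeric(Ks %*% Kinv %*% ys)
  var_m <- model$sigma_f2 - rowSums((Ks %*% Kinv) * Ks)
  data.frame(mean = model$y_mean + mu * model$y_sd,
             std_model = sqrt(pmax(var_m, 0)) * model$y_sd)
}

# Monte-Carlo oracle for expected improvement (minimization)
mc_expected_improvement <- function(mu, sd, best, xi, n = 1e6) {
  y <- stats::rnorm(n, mu, sd)
  mean(pmax(best - xi - y, 0))
}

# EI utility at a recipe, computed from exported pieces (for argmax checks)
ei_at <- function(model, space, x, best, xi = 0.01) {
  pr <- gp_predict(model, matrix(to_unit(space, x), nrow = 1))
  expected_improvement(pr$mean, pr$std_model, best, xi)
}
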