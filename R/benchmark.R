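#' Benchmark an optimizer configuration on a model system
#'
#' Runs the full ask -> simulate -> tell loop for `budget` experiments per
#' replicate. Suggestions are snapped to the preparation grid (a no-op for
#' dimensions without a `grid_step`) before being scored and told, matching
#' how recipes are actually run at the bench. After each replicate the
#' expected minimum is extracted, grid-rounded, and — when the system's
#' optimum is known — evaluated noise-free against the truth.
#'
#' @param system A [model_system()].
#' @param budget Experiments per replicate (>= `n_initial_points`).
#' @param n_reps Number of replicate campaigns (default 5); replicate r uses
#'   seed `seed + r - 1`.
#' @param seed Master seed.
#' @param n_initial_points Initial LHS design size (default 4).
#' @param acq Acquisition spec (default EI).
#' @return A `benchmark_summary`: per-replicate best-so-far `traces`
#'   (budget x n_reps matrix), a per-replicate table (`final_best`,
#'   `expected_min` recipe and prediction, `true_at_expected_min`), and
#'   aggregate medians and IQRs.
#' @export
run_benchmark <- function(system, budget = 24, n_reps = 5, seed = 1L,
                          n_initial_points = 4, acq = acq_spec()) {
  stopifnot(inherits(system, "model_system"))
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  if (budget < n_initial_points) {
    stop("budget (", budget, ") must be at least n_initial_points (",
         n_initial_points, ")", call. = FALSE)
  }
  space <- system$space
  traces <- matrix(NA_real_, nrow = budget, ncol = n_reps)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rep_seed <- as.integer(seed + r - 1L)
    opt <- bo_optimizer(space, n_initial_points = n_initial_points, acq = acq,
                        seed = rep_seed)
    result <- withr::with_seed(derive_seed(rep_seed, 777L), {
      res <- NULL
      for (i in seq_len(budget)) {
        x <- ask(opt)
        x_run <- round_to_grid(x, space)
        y <- get_score(system, x_run)
        res <- tell(opt, x_run, y)
      }
      res
    })
    traces[, r] <- convergence_trace(result)
    em <- expected_min(result)
    em_grid <- round_to_grid(em$x, space)
    true_em <- system$truth(em_grid)
    reps[[r]] <- data.frame(
      rep = r, seed = rep_seed,
      final_best = result$best_y,
      em_mean = em$mean, em_std = em$std,
      true_at_expected_min = true_em,
      stringsAsFactors = FALSE
    )
    reps[[r]]$em_recipe <- I(list(em_grid))
  }
  per_rep <- do.call(rbind, reps)
  structure(list(
    system = system$name,
    budget = budget,
    n_reps = n_reps,
    traces = traces,
    per_rep = per_rep,
    median_final_best = stats::median(per_rep$final_best),
    iqr_final_best = stats::IQR(per_rep$final_best),
    median_true_at_expected_min = stats::median(per_rep$true_at_expected_min),
    iqr_true_at_expected_min = stats::IQR(per_rep$true_at_expected_min)
  ), class = "benchmark_summary")
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat("<benchmark_summary> system:", x$system,
      "| budget:", x$budget, "| replicates:", x$n_reps, "\n")
  cat("  median final best-so-far: ", format(x$median_final_best),
      " (IQR ", format(x$iqr_final_best), ")\n", sep = "")
  cat("  median true score at grid-rounded expected min: ",
      format(x$median_true_at_expected_min),
      " (IQR ", format(x$iqr_true_at_expected_min), ")\n", sep = "")
  invisible(x)
}
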