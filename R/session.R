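#' Durable optimization sessions
#'
#' A session is a directory holding the state of record of a (possibly
#' weeks-long) physical campaign: `config.yaml` (space + settings) and
#' `log.csv`, an append-only observation log with columns `iteration`, one
#' column per factor, `y`, `origin`. All derived state is reconstructed by
#' replay, so sessions survive crashes and machine moves; because suggestions
#' are pure functions of (seed, told data), replay reproduces the identical
#' next suggestion.
#'
#' @param dir Session directory (created if needed).
#' @param space A `search_space`.
#' @param constraints Optional constraints.
#' @param n_initial_points,acq,seed Optimizer settings.
#' @return The session directory, invisibly.
#' @export
session_init <- function(dir, space, constraints = NULL, n_initial_points = 4,
                         acq = acq_spec(), seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_config(space, file.path(dir, "config.yaml"), constraints,
              n_initial_points, acq, seed)
  log_path <- file.path(dir, "log.csv")
  if (!file.exists(log_path)) {
    hdr <- c("iteration", dim_names(space), "y", "origin")
    writeLines(paste(hdr, collapse = ","), log_path)
  }
  invisible(dir)
}

session_paths <- function(dir) {
  list(config = file.path(dir, "config.yaml"),
       log = file.path(dir, "log.csv"))
}

read_session_log <- function(path, space) {
  log <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = NA),
    error = function(e) stop("corrupt session log '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  need <- c("iteration", dim_names(space), "y", "origin")
  miss <- setdiff(need, names(log))
  if (length(miss)) stop("corrupt session log: missing column(s) ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(log) > 0L && any(!is.finite(log$y))) {
    stop("corrupt session log: non-finite score at line ",
         which(!is.finite(log$y))[1] + 1L, call. = FALSE)
  }
  log
}

#' Rebuild the optimizer from a session directory
#'
#' Reads the config, replays every logged observation (with its recorded
#' origin) into a fresh optimizer, and returns it.
#'
#' @param dir Session directory.
#' @return A `bo_optimizer`.
#' @export
session_replay <- function(dir) {
  p <- session_paths(dir)
  cfg <- load_config(p$config)
  opt <- bo_optimizer(cfg$space, n_initial_points = cfg$n_initial_points,
                      acq = cfg$acq, seed = cfg$seed,
                      constraints = cfg$constraints)
  log <- read_session_log(p$log, cfg$space)
  for (i in seq_len(nrow(log))) {
    x <- as.list(log[i, dim_names(cfg$space), drop = FALSE])
    tell(opt, x, log$y[i], origin = log$origin[i])
  }
  opt
}

format_recipe <- function(space, x) {
  x <- as_recipe(space, x)
  paste(vapply(seq_along(x), function(i) {
    v <- x[[i]]
    paste0(names(x)[i], " = ", if (is.numeric(v)) format(signif(v, 6)) else v)
  }, ""), collapse = ", ")
}

#' Ask for the next experiment(s) in a session
#'
#' Replays the session, asks for `n` suggestions, prints them with factor
#' names, and records them in `pending.csv` for reference. Asking again
#' without telling reproduces the same suggestion.
#'
#' @param dir Session directory.
#' @param n Number of suggestions (default 1).
#' @param strategy Constant-liar strategy for `n > 1` (see [ask_batch()]).
#' @param quiet Suppress printing.
#' @return List of recipes, invisibly.
#' @export
cli_ask <- function(dir, n = 1, strategy = "cl_min", quiet = FALSE) {
  opt <- session_replay(dir)
  pts <- if (n == 1L) list(ask(opt)) else ask_batch(opt, n, strategy)
  space <- opt$space
  pending <- observations_df(space, pts, rep(NA_real_, length(pts)),
                             rep("pending", length(pts)))
  utils::write.csv(pending, file.path(dir, "pending.csv"), row.names = FALSE)
  if (!quiet) {
    for (i in seq_along(pts)) {
      cat(sprintf("suggestion %d: %s\n", i, format_recipe(space, pts[[i]])))
    }
  }
  invisible(pts)
}

#' Report an experiment result into a session
#'
#' Validates the recipe against the space, appends one row to the log, and
#' prints the running best. The log is untouched on any validation error.
#'
#' @param dir Session directory.
#' @param recipe Recipe values (vector or list, dimension order or named).
#' @param score Measured score (finite number).
#' @param quiet Suppress printing.
#' @return The updated `bo_result`, invisibly.
#' @export
cli_tell <- function(dir, recipe, score, quiet = FALSE) {
  score <- suppressWarnings(as.numeric(score))
  if (length(score) != 1L || !is.finite(score)) {
    stop("score must be a finite number", call. = FALSE)
  }
  opt <- session_replay(dir)
  result <- tell(opt, recipe, score)   # validates before the log is touched
  n <- nrow(result$observations)
  row <- result$observations[n, , drop = FALSE]
  line <- paste(vapply(row[1, ], function(v)
    if (is.numeric(v)) format(v, digits = 15) else as.character(v), ""),
    collapse = ",")
  cat(line, "\n", sep = "", file = file.path(dir, "log.csv"), append = TRUE)
  if (!quiet) {
    cat(sprintf("observation %d recorded; best so far: %s at %s\n",
                n, format(result$best_y),
                format_recipe(opt$space, result$best_x)))
  }
  invisible(result)
}

#' Report on a session: best observed, expected minimum, convergence
#'
#' Requires at least `n_initial_points` observations. Prints the best
#' observed recipe, the surrogate's expected-minimum recipe with predicted
#' score +/- standard deviation (model-only by default; `include_noise` adds
#' the learned observation noise), and the convergence trace. Writes
#' `result.json` and one partial-dependence CSV per factor into the session
#' directory.
#'
#' @param dir Session directory.
#' @param include_noise Include observation noise in the reported std?
#' @param quiet Suppress printing.
#' @return List with `result`, `expected_min`, `trace`, invisibly.
#' @export
cli_report <- function(dir, include_noise = FALSE, quiet = FALSE) {
  opt <- session_replay(dir)
  cfg <- load_config(session_paths(dir)$config)
  n <- length(opt$xs)
  if (n < cfg$n_initial_points) {
    stop("only ", n, " observation(s) logged; the report needs at least the ",
         cfg$n_initial_points, " initial-design observations - run more ",
         "experiments and tell their results first", call. = FALSE)
  }
  result <- get_result(opt)
  em <- expected_min(result, include_noise = include_noise)
  trace <- convergence_trace(result)
  result_to_json(result, file.path(dir, "result.json"))
  for (nm in dim_names(opt$space)) {
    pd <- partial_dependence(result, nm)
    utils::write.csv(pd, file.path(dir, paste0("partial_dependence_", nm,
                                               ".csv")),
                     row.names = FALSE)
  }
  if (!quiet) {
    cat("observations:", n, "\n")
    cat("best observed:", format(result$best_y), "at",
        format_recipe(opt$space, result$best_x), "\n")
    cat(sprintf("expected minimum: %s -> predicted %s +/- %s%s\n",
                format_recipe(opt$space, em$x), format(signif(em$mean, 6)),
                format(signif(em$std, 6)),
                if (include_noise) " (incl. noise)" else ""))
    cat("convergence trace:", paste(signif(trace, 6), collapse = ", "), "\n")
  }
  invisible(list(result = result, expected_min = em, trace = trace))
}

#' Run a registered benchmark from the command line layer
#'
#' @param system_name `"color_ph"`, or the path of a 96-row plate CSV
#'   (see [grid_from_csv()]).
#' @param budget,reps,seed Benchmark settings (see [run_benchmark()]).
#' @param out Optional directory for `traces.csv` and `summary.csv`.
#' @param quiet Suppress printing.
#' @return A `benchmark_summary`, invisibly.
#' @export
cli_benchmark <- function(system_name = "color_ph", budget = 24, reps = 5,
                          seed = 1L, out = NULL, quiet = FALSE) {
  registered <- c("color_ph")
  system <- if (file.exists(system_name)) {
    color_ph_system(grid = grid_from_csv(system_name))
  } else if (system_name %in% registered) {
    color_ph_system()
  } else {
    stop("unknown model system '", system_name, "'; registered: ",
         paste(registered, collapse = ", "), call. = FALSE)
  }
  bench <- run_benchmark(system, budget = budget, n_reps = reps, seed = seed)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(bench$traces),
                     file.path(out, "traces.csv"), row.names = FALSE)
    per <- bench$per_rep
    per$em_recipe <- vapply(per$em_recipe, function(x)
      paste(unlist(x), collapse = "/"), "")
    utils::write.csv(per, file.path(out, "summary.csv"), row.names = FALSE)
  }
  if (!quiet) print(bench)
  invisible(bench)
}
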