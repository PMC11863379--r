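write_color_config <- function(path, seed = 1L) {
  save_config(color_space(), path, n_initial_points = 4, seed = seed)
  path
}

test_that("YAML configs load the two-factor setup and round-trip losslessly", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "dimensions:",
    "  - {name: Acid, kind: real, low: 30, high: 85, grid_step: 5}",
    "  - {name: Indicator, kind: real, low: 5, high: 40, grid_step: 5}",
    "n_initial_points: 4",
    "acquisition: {kind: EI, xi: 0.01}",
    "seed: 1"
  ), path)
  cfg <- load_config(path)
  expect_identical(dim_names(cfg$space), c("Acid", "Indicator"))
  expect_equal(cfg$space$dims[[1]]$low, 30)
  expect_equal(cfg$space$dims[[1]]$high, 85)
  expect_equal(cfg$space$dims[[2]]$low, 5)
  expect_equal(cfg$space$dims[[2]]$high, 40)
  expect_identical(cfg$n_initial_points, 4L)
  expect_identical(cfg$acq$kind, "EI")

  out <- withr::local_tempfile(fileext = ".yaml")
  con <- list(constraint_sum_equals(c("Acid", "Indicator"), 100, 2),
              constraint_value_restriction("Indicator", seq(5, 40, 5)))
  save_config(cfg$space, out, constraints = con, n_initial_points = 6,
              acq = acq_spec("LCB", kappa = 2.5), seed = 9)
  cfg2 <- load_config(out)
  expect_identical(space_to_list(cfg2$space), space_to_list(cfg$space))
  expect_identical(cfg2$n_initial_points, 6L)
  expect_identical(cfg2$acq$kind, "LCB")
  expect_equal(cfg2$acq$kappa, 2.5)
  expect_length(cfg2$constraints, 2L)
  expect_true(satisfies(cfg2$constraints, list(80, 20), cfg2$space))
  expect_false(satisfies(cfg2$constraints, list(80, 21), cfg2$space))
})

test_that("a config without dimensions is rejected with the offending key", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("n_initial_points: 4", path)
  expect_error(load_config(path), "dimensions")
  expect_error(load_config("does-not-exist.yaml"), "not found")
  path2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("dimensions:",
               "  - {name: s, kind: categorical, categories: [a, b]}"), path2)
  expect_error(load_config(path2), "only contain categorical")
})

test_that("session asks match a library-level run with the same seed", {
  dir <- withr::local_tempdir()
  session_init(dir, color_space(), n_initial_points = 4, seed = 42)
  ref <- bo_optimizer(color_space(), n_initial_points = 4, seed = 42)
  g <- synth_color_grid()
  for (i in 1:4) {
    got <- cli_ask(dir, quiet = TRUE)[[1]]
    want <- ask(ref)
    expect_equal(unname(unlist(got)), unname(unlist(want)), tolerance = 1e-9)
    x <- round_to_grid(want, ref$space)
    y <- color_ph_score(g, x)
    cli_tell(dir, unlist(x), y, quiet = TRUE)
    tell(ref, x, y)
  }
  # 5th ask is model-based and still matches
  got5 <- cli_ask(dir, quiet = TRUE)[[1]]
  want5 <- ask(ref)
  expect_equal(unname(unlist(got5)), unname(unlist(want5)), tolerance = 1e-9)
})

test_that("asking twice without telling repeats the suggestion; batch asks print n recipes", {
  dir <- withr::local_tempdir()
  session_init(dir, color_space(), n_initial_points = 4, seed = 7)
  a <- cli_ask(dir, quiet = TRUE)
  b <- cli_ask(dir, quiet = TRUE)
  expect_identical(a, b)
  out <- capture.output(pts <- cli_ask(dir, n = 3, strategy = "cl_min"))
  expect_length(pts, 3L)
  expect_length(grep("^suggestion", out), 3L)
})

test_that("telling appends exactly one validated row; errors leave the log untouched", {
  dir <- withr::local_tempdir()
  session_init(dir, color_space(), n_initial_points = 4, seed = 1)
  r <- cli_tell(dir, c(80, 35), 50.8, quiet = TRUE)
  log <- read.csv(file.path(dir, "log.csv"))
  expect_equal(nrow(log), 1L)
  expect_equal(log$Acid, 80)
  expect_equal(log$y, 50.8)
  expect_equal(r$best_y, 50.8)

  expect_error(cli_tell(dir, c(80, 35), "abc", quiet = TRUE), "finite")
  expect_error(cli_tell(dir, c(200, 35), 1, quiet = TRUE), "outside")
  expect_equal(nrow(read.csv(file.path(dir, "log.csv"))), 1L)
  cli_tell(dir, c(50, 20), 12.5, quiet = TRUE)
  expect_equal(nrow(read.csv(file.path(dir, "log.csv"))), 2L)
})

test_that("reports require the initial design and export a reloadable result", {
  dir <- withr::local_tempdir()
  session_init(dir, color_space(), n_initial_points = 4, seed = 5)
  g <- synth_color_grid()
  expect_error(cli_report(dir, quiet = TRUE), "initial-design")
  for (i in 1:8) {
    x <- round_to_grid(cli_ask(dir, quiet = TRUE)[[1]], color_space())
    cli_tell(dir, unlist(x), color_ph_score(g, x), quiet = TRUE)
  }
  out <- capture.output(rep1 <- cli_report(dir))
  expect_true(any(grepl("expected minimum", out)))
  expect_true(any(grepl("\\+/-", out)))
  expect_length(rep1$trace, 8L)
  expect_true(file.exists(file.path(dir, "result.json")))
  expect_true(file.exists(file.path(dir, "partial_dependence_Acid.csv")))

  # deterministic given the log
  rep2 <- cli_report(dir, quiet = TRUE)
  expect_equal(rep1$expected_min, rep2$expected_min)
  expect_equal(rep1$trace, rep2$trace)

  # JSON round-trip restores the observations and best
  back <- result_from_json(file.path(dir, "result.json"))
  expect_equal(back$observations, rep1$result$observations)
  expect_equal(back$best_y, rep1$result$best_y)
  expect_equal(unlist(back$best_x), unlist(rep1$result$best_x))
})

test_that("replaying the log reconstructs the same next suggestion", {
  dir <- withr::local_tempdir()
  session_init(dir, color_space(), n_initial_points = 2, seed = 3)
  g <- synth_color_grid()
  for (i in 1:3) {
    x <- round_to_grid(cli_ask(dir, quiet = TRUE)[[1]], color_space())
    cli_tell(dir, unlist(x), color_ph_score(g, x), quiet = TRUE)
  }
  next1 <- cli_ask(dir, quiet = TRUE)
  # wipe derived artifacts; the config + log are the state of record
  file.remove(file.path(dir, "pending.csv"))
  next2 <- cli_ask(dir, quiet = TRUE)
  expect_identical(next1, next2)
})

test_that("benchmarks run from the registered system or a plate CSV", {
  b <- cli_benchmark("color_ph", budget = 5, reps = 2, seed = 2, quiet = TRUE)
  expect_equal(dim(b$traces), c(5L, 2L))
  expect_error(cli_benchmark("no_such_system", quiet = TRUE),
               "registered")
  expect_error(cli_benchmark("color_ph", budget = 2, reps = 1, quiet = TRUE),
               "at least")

  csv <- withr::local_tempfile(fileext = ".csv")
  grid_to_csv(synth_color_grid(), csv)
  b2 <- cli_benchmark(csv, budget = 5, reps = 2, seed = 2, quiet = TRUE)
  expect_equal(b2$traces, b$traces)
})
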