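quad_space <- function() search_space(dim_real("x", 0, 1))

test_that("creation queues an LHS initial design and fits no model", {
  sp <- color_space()
  opt <- bo_optimizer(sp, n_initial_points = 4, seed = 1)
  expect_length(opt$queue, 4L)
  expect_true(lhs_stratified(sp, opt$queue))
  expect_null(opt$model)
  expect_length(opt$models, 0L)
  expect_error(bo_optimizer(sp, n_initial_points = 0), ">= 1")
  opt2 <- bo_optimizer(sp, n_initial_points = 4, seed = 1)
  expect_identical(opt$queue, opt2$queue)
})

test_that("the initial design is served before any surrogate is fitted", {
  sp <- color_space()
  opt <- bo_optimizer(sp, n_initial_points = 4, seed = 2)
  served <- list()
  for (i in 1:4) {
    x <- ask(opt)
    expect_length(opt$models, 0L)  # no fit while the design is being served
    served[[i]] <- x
    tell(opt, x, as.numeric(100 - i))
  }
  expect_true(lhs_stratified(sp, served))
  expect_true(all(opt$origins == "initial"))
  # the 4th tell completes the initial phase and triggers the first fit
  expect_length(opt$models, 1L)
})

test_that("asking is idempotent until the next tell", {
  sp <- color_space()
  opt <- bo_optimizer(sp, n_initial_points = 2, seed = 3)
  expect_identical(ask(opt), ask(opt))
  tell(opt, ask(opt), 10)
  x2 <- ask(opt)
  expect_identical(x2, ask(opt))
  tell(opt, x2, 9)
  # model phase: still idempotent
  x3 <- ask(opt)
  expect_identical(x3, ask(opt))
})

test_that("telling tracks the running minimum and validates inputs", {
  sp <- color_space()
  opt <- bo_optimizer(sp, n_initial_points = 4, seed = 1)
  r <- tell(opt, list(80, 35), 50.8)
  expect_equal(nrow(r$observations), 1L)
  expect_equal(r$best_y, 50.8)
  expect_equal(unname(unlist(r$best_x)), c(80, 35))
  r <- tell(opt, list(50, 20), 30.0)
  expect_equal(r$best_y, 30.0)
  r <- tell(opt, list(60, 25), 40.0)
  expect_equal(r$best_y, 30.0)   # a worse y does not update the best
  expect_error(tell(opt, list(200, 35), 1), "outside")
  expect_error(tell(opt, list(50, 20), NaN), "finite")
  expect_error(tell(opt, list(50, 20), Inf), "finite")
})

test_that("model-phase suggestions maximize the acquisition over random candidates", {
  sp <- color_space()
  grid <- synth_color_grid()
  opt <- bo_optimizer(sp, n_initial_points = 4, seed = 5)
  for (i in 1:4) {
    x <- round_to_grid(ask(opt), sp)
    tell(opt, x, color_ph_score(grid, x))
  }
  x5 <- ask(opt)
  m <- opt$model
  expect_false(is.null(m))
  got <- ei_at(m, sp, x5, min(opt$ys))
  set.seed(777)
  rand <- sample_space(sp, 1000)
  pr <- gp_predict(m, encode_points(sp, rand))
  expect_gte(got,
             max(expected_improvement(pr$mean, pr$std_model, min(opt$ys),
                                      0.01)) - 1e-6)
})

test_that("batch asks reduce to ask at n = 1 and leave no side effects", {
  sp <- color_space()
  opt1 <- bo_optimizer(sp, n_initial_points = 4, seed = 7)
  opt2 <- bo_optimizer(sp, n_initial_points = 4, seed = 7)
  expect_identical(ask_batch(opt1, 1)[[1]], ask(opt2))

  opt <- bo_optimizer(sp, n_initial_points = 2, seed = 8)
  for (i in 1:2) { x <- ask(opt); tell(opt, x, i + 10) }
  n_before <- length(opt$xs)
  batch <- ask_batch(opt, 3)
  expect_length(batch, 3L)
  expect_identical(length(opt$xs), n_before)
  expect_error(ask_batch(opt, 0), ">= 1")
})

test_that("constant-liar batches return pairwise-distinct suggestions", {
  sp <- color_space()
  grid <- synth_color_grid()
  for (s in 1:6) {
    opt <- bo_optimizer(sp, n_initial_points = 4, seed = 100 + s)
    for (i in 1:4) {
      x <- round_to_grid(ask(opt), sp)
      tell(opt, x, color_ph_score(grid, x))
    }
    batch <- ask_batch(opt, 3, strategy = "cl_min")
    U <- encode_points(sp, batch)
    d <- as.matrix(dist(U))
    expect_true(all(d[upper.tri(d)] > 0))
  }
})

test_that("expected_min locates the minimum of a noiseless quadratic", {
  sp <- quad_space()
  opt <- bo_optimizer(sp, n_initial_points = 12, seed = 9)
  r <- NULL
  for (i in 1:12) {
    x <- ask(opt)
    r <- tell(opt, x, (x$x - 0.3)^2)
  }
  em <- expected_min(r)
  expect_lt(abs(em$x$x - 0.3), 0.05)
  expect_lt(abs(em$mean), 0.01)
  # minimality over the observed starts
  mus <- gp_predict(r$model, encode_points(sp, r$xs))$mean
  expect_lte(em$mean, min(mus) + 1e-9)
  # the noise-inclusive std is never smaller
  em_noise <- expected_min(r, include_noise = TRUE)
  expect_gte(em_noise$std, em$std)
})

test_that("convergence traces are running minima", {
  sp <- color_space()
  opt <- bo_optimizer(sp, n_initial_points = 4, seed = 1)
  tell(opt, list(80, 35), 50.8)
  tell(opt, list(50, 20), 30.0)
  r <- tell(opt, list(60, 25), 40.0)
  expect_equal(convergence_trace(r), c(50.8, 30.0, 30.0))

  opt1 <- bo_optimizer(sp, n_initial_points = 4, seed = 1)
  r1 <- tell(opt1, list(40, 10), 5)
  expect_equal(convergence_trace(r1), 5)

  set.seed(33)
  for (k in 1:10) {
    ys <- rnorm(8)
    o <- bo_optimizer(sp, n_initial_points = 10, seed = k)
    r <- NULL
    for (y in ys) r <- tell(o, list(runif(1, 30, 85), runif(1, 5, 40)), y)
    tr <- convergence_trace(r)
    expect_length(tr, 8L)
    expect_true(all(diff(tr) <= 0))
  }
})

test_that("partial dependence has the right shape and recovers additive structure", {
  sp <- search_space(dim_real("x1", 0, 1), dim_real("x2", 0, 1))
  f <- function(x) sin(2 * pi * x)          # additive component on x1
  g <- function(x) 2 * (x - 0.5)^2
  opt <- bo_optimizer(sp, n_initial_points = 40, seed = 10)
  r <- NULL
  for (i in 1:40) {
    x <- ask(opt)
    r <- tell(opt, x, f(x$x1) + g(x$x2))
  }
  pd <- partial_dependence(r, "x1", grid_size = 15, n_background = 40)
  expect_equal(nrow(pd), 15L)
  expect_named(pd, c("x1", "mean", "std"))
  expect_gt(cor(pd$mean, f(pd$x1)), 0.95)

  pd2 <- partial_dependence(r, c("x1", "x2"), grid_size = 6,
                            n_background = 20)
  expect_equal(nrow(pd2), 36L)
  expect_error(partial_dependence(r, "nope"), "unknown dimension")
})

test_that("a flat response yields a flat dependence profile", {
  sp <- search_space(dim_real("x1", 0, 1), dim_real("x2", 0, 1))
  opt <- bo_optimizer(sp, n_initial_points = 8, seed = 11)
  r <- NULL
  for (i in 1:8) r <- tell(opt, ask(opt), 7)
  pd <- partial_dependence(r, "x1", grid_size = 10, n_background = 20)
  expect_lt(diff(range(pd$mean)), 1e-6)
})

test_that("the whole loop replays identically from the told data", {
  sp <- color_space()
  grid <- synth_color_grid()
  run <- function() {
    opt <- bo_optimizer(sp, n_initial_points = 4, seed = 13)
    xs <- list()
    for (i in 1:6) {
      x <- round_to_grid(ask(opt), sp)
      xs[[i]] <- x
      tell(opt, x, color_ph_score(grid, x))
    }
    xs
  }
  expect_identical(run(), run())
})

test_that("manual observations are accepted and labelled", {
  sp <- color_space()
  opt <- bo_optimizer(sp, n_initial_points = 2, seed = 14)
  for (i in 1:2) tell(opt, ask(opt), i)
  ask(opt)
  r <- tell(opt, list(42.5, 12.5), 0.5)  # never suggested
  expect_identical(r$observations$origin[3], "manual")
})
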