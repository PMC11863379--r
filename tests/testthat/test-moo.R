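test_that("dominance follows the strict Pareto definition", {
  expect_true(dominates(c(1, 1), c(2, 2)))
  expect_false(dominates(c(1, 2), c(2, 1)))
  expect_false(dominates(c(2, 1), c(1, 2)))
  expect_false(dominates(c(1, 1), c(1, 1)))
  expect_true(dominates(c(1, 2), c(1, 3)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "length")
})

test_that("dominance is irreflexive and transitive on random vectors", {
  set.seed(41)
  for (k in 1:200) {
    a <- rnorm(3); b <- rnorm(3); c <- rnorm(3)
    expect_false(dominates(a, a))
    if (dominates(a, b) && dominates(b, c)) expect_true(dominates(a, c))
  }
})

test_that("non-dominated sorting reproduces the textbook example", {
  objs <- rbind(c(1, 4), c(2, 2), c(4, 1), c(3, 3))
  fronts <- non_dominated_sort(objs)
  expect_length(fronts, 2L)
  expect_setequal(fronts[[1]], c(1L, 2L, 3L))
  expect_identical(fronts[[2]], 4L)
  expect_error(non_dominated_sort(matrix(numeric(0), 0, 2)), "empty")
})

test_that("single-objective sorting groups equal values in ascending order", {
  objs <- matrix(c(3, 1, 2, 1, 3), ncol = 1)
  fronts <- non_dominated_sort(objs)
  expect_length(fronts, 3L)
  expect_setequal(fronts[[1]], c(2L, 4L))
  expect_identical(fronts[[2]], 3L)
  expect_setequal(fronts[[3]], c(1L, 5L))
})

test_that("sorting agrees with the brute-force dominance oracle", {
  for (s in 1:20) {
    set.seed(400 + s)
    objs <- matrix(rnorm(20 * 3), ncol = 3)
    expect_identical(lapply(non_dominated_sort(objs), sort),
                     brute_force_fronts(objs))
  }
})

test_that("crowding distance rewards boundary and isolated points", {
  expect_identical(crowding_distance(rbind(c(1, 2))), Inf)
  expect_identical(crowding_distance(rbind(c(1, 2), c(2, 1))), c(Inf, Inf))
  # three evenly spaced points on a line: interior gap = 0.5 + 0.5
  d <- crowding_distance(rbind(c(0, 2), c(1, 1), c(2, 0)))
  expect_identical(d[c(1, 3)], c(Inf, Inf))
  expect_equal(d[2], 1.0)
  # permutation invariance
  objs <- rbind(c(0, 4), c(1, 2.5), c(2, 1.5), c(3, 1), c(4, 0.8))
  d0 <- crowding_distance(objs)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(crowding_distance(objs[perm, ]), d0[perm])
  # a zero-range objective contributes nothing
  dz <- crowding_distance(rbind(c(0, 1), c(1, 1), c(2, 1)))
  expect_equal(dz[2], 0.5)
})

toy_evaluator <- function(p) c(p$x^2, (p$x - 1)^2)
toy_space <- function() search_space(dim_real("x", -1, 2))

test_that("one generation of evolution preserves size, bounds and determinism", {
  sp <- toy_space()
  set.seed(51)
  init <- lhs_design(sp, 12)
  pop <- list(U = encode_points(sp, init),
              objectives = t(vapply(init, toy_evaluator, numeric(2))))
  set.seed(1); nxt1 <- evolve(pop, sp, toy_evaluator)
  set.seed(1); nxt2 <- evolve(pop, sp, toy_evaluator)
  expect_identical(nxt1, nxt2)
  expect_identical(nrow(nxt1$U), 12L)
  expect_true(all(nxt1$U >= 0 & nxt1$U <= 1))
  expect_error(
    evolve(pop, sp, toy_evaluator,
           constraints = list(constraint_value_exclusion("x", 0))),
    "does not support constraints")
})

test_that("hypervolume grows across elitist generations", {
  # Crowding-based truncation of an over-full first front can shed slivers
  # of hypervolume (a property of the algorithm, not a defect), so each step
  # is allowed a 0.1% relative slack; the run as a whole must improve.
  sp <- toy_space()
  ref <- c(4.5, 4.5)  # dominates every feasible objective pair on [-1, 2]
  ok <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    set.seed(600 + s)
    init <- lhs_design(sp, 12)
    pop <- list(U = encode_points(sp, init),
                objectives = t(vapply(init, toy_evaluator, numeric(2))))
    hv0 <- hypervolume_2d(pop$objectives, ref)
    hv <- hv0
    monotone <- TRUE
    for (g in 1:8) {
      pop <- evolve(pop, sp, toy_evaluator)
      hv_new <- hypervolume_2d(pop$objectives, ref)
      if (hv_new < hv * (1 - 1e-3)) monotone <- FALSE
      hv <- hv_new
    }
    if (monotone && hv >= hv0) ok <- ok + 1L
  }
  expect_gte(ok, 0.9 * n_seeds)
})

test_that("pareto_suggest recovers the closed-form Pareto set of the toy problem", {
  front <- pareto_suggest(toy_evaluator, toy_space(), pop_size = 40,
                          generations = 50, seed = 1)
  expect_lte(nrow(front), 40L)
  frac_in <- mean(front$x >= -0.02 & front$x <= 1.02)
  expect_gte(frac_in, 0.95)
  # mutual non-dominance, re-checked with dominates()
  O <- as.matrix(front[, c("obj_1", "obj_2")])
  for (i in seq_len(nrow(O))) {
    for (j in seq_len(nrow(O))) {
      if (i != j) expect_false(dominates(O[i, ], O[j, ]))
    }
  }
})

test_that("multi-objective interface rejects unsupported setups", {
  expect_error(pareto_suggest(function(p) p$x^2, toy_space(), pop_size = 8,
                              generations = 1, seed = 1),
               "at least 2 objectives")
  expect_error(pareto_suggest(toy_evaluator, toy_space(), pop_size = 7,
                              generations = 1, seed = 1), "even")
  expect_error(
    pareto_suggest(toy_evaluator, toy_space(), pop_size = 8, generations = 1,
                   seed = 1,
                   constraints = list(constraint_value_exclusion("x", 0))),
    "does not support constraints")
  # deterministic given the seed
  f1 <- pareto_suggest(toy_evaluator, toy_space(), pop_size = 8,
                       generations = 3, seed = 4)
  f2 <- pareto_suggest(toy_evaluator, toy_space(), pop_size = 8,
                       generations = 3, seed = 4)
  expect_identical(f1, f2)
})
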