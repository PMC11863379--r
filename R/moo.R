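#' Pareto dominance (minimization)
#'
#' `a` dominates `b` iff `a` is no worse in every objective and strictly
#' better in at least one.
#'
#' @param a,b Numeric objective vectors of equal length (all minimized).
#' @return Logical.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) stop("objective vectors differ in length",
                                   call. = FALSE)
  all(a <= b) && any(a < b)
}

#' Fast non-dominated sorting
#'
#' Partitions a population into Pareto fronts: front 1 holds all
#' non-dominated individuals; front k holds those non-dominated once fronts
#' `< k` are removed.
#'
#' @param objectives Numeric matrix, one row per individual, one column per
#'   objective (all minimized).
#' @return List of integer vectors (row indices), one per front.
#' @export
non_dominated_sort <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0L) stop("empty population", call. = FALSE)
  dominated_by <- vector("list", n)  # who i dominates
  n_dom <- integer(n)                # how many dominate i
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(objectives[i, ], objectives[j, ])) {
        dominated_by[[i]] <- c(dominated_by[[i]], j)
      } else if (dominates(objectives[j, ], objectives[i, ])) {
        n_dom[i] <- n_dom[i] + 1L
      }
    }
  }
  fronts <- list()
  current <- which(n_dom == 0L)
  while (length(current) > 0L) {
    fronts[[length(fronts) + 1L]] <- current
    nxt <- integer(0)
    for (i in current) {
      for (j in dominated_by[[i]]) {
        n_dom[j] <- n_dom[j] - 1L
        if (n_dom[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- sort(nxt)
  }
  fronts
}

#' Crowding distance within one front
#'
#' Per objective the front is sorted; boundary individuals get infinite
#' distance, interior ones accumulate the mean distance to their two
#' neighbours, normalized by the objective's range (so three evenly spaced
#' points on a 2-objective line give the interior point 0.5 + 0.5 = 1).
#' Objectives with zero range contribute nothing. Selection behaviour is
#' identical to the conventional neighbour-span form, which is exactly twice
#' this value.
#'
#' @param objectives Numeric matrix of the front's objective values.
#' @return Numeric vector of distances (may be `Inf`).
#' @export
crowding_distance <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0L) return(numeric(0))
  d <- numeric(n)
  if (n <= 2L) return(rep(Inf, n))
  for (m in seq_len(ncol(objectives))) {
    o <- objectives[, m]
    ord <- order(o)
    rng <- o[ord[n]] - o[ord[1]]
    d[ord[c(1, n)]] <- Inf
    if (rng > 0) {
      for (k in 2:(n - 1)) {
        d[ord[k]] <- d[ord[k]] + (o[ord[k + 1]] - o[ord[k - 1]]) / (2 * rng)
      }
    }
  }
  d
}

# rank (front index) and crowding for a whole population
rank_and_crowd <- function(objectives) {
  fronts <- non_dominated_sort(objectives)
  n <- nrow(as.matrix(objectives))
  rank <- integer(n); crowd <- numeric(n)
  for (f in seq_along(fronts)) {
    idx <- fronts[[f]]
    rank[idx] <- f
    crowd[idx] <- crowding_distance(as.matrix(objectives)[idx, , drop = FALSE])
  }
  list(rank = rank, crowding = crowd, fronts = fronts)
}

# binary tournament on (rank asc, crowding desc)
tournament_pick <- function(rank, crowd) {
  n <- length(rank)
  i <- sample.int(n, 1L); j <- sample.int(n, 1L)
  if (rank[i] < rank[j]) return(i)
  if (rank[j] < rank[i]) return(j)
  if (crowd[i] >= crowd[j]) i else j
}

# simulated binary crossover of two unit-coordinate parents (numeric coords)
sbx_pair <- function(p1, p2, eta_c, p_c) {
  c1 <- p1; c2 <- p2
  if (stats::runif(1) < p_c) {
    for (k in seq_along(p1)) {
      if (stats::runif(1) > 0.5 || abs(p1[k] - p2[k]) < 1e-14) next
      u <- stats::runif(1)
      beta <- if (u <= 0.5) (2 * u)^(1 / (eta_c + 1)) else
        (1 / (2 * (1 - u)))^(1 / (eta_c + 1))
      c1[k] <- 0.5 * ((1 + beta) * p1[k] + (1 - beta) * p2[k])
      c2[k] <- 0.5 * ((1 - beta) * p1[k] + (1 + beta) * p2[k])
    }
  }
  list(pmin(pmax(c1, 0), 1), pmin(pmax(c2, 0), 1))
}

# polynomial mutation in [0, 1]
poly_mutate <- function(x, eta_m, p_m) {
  for (k in seq_along(x)) {
    if (stats::runif(1) >= p_m) next
    u <- stats::runif(1)
    delta <- if (u < 0.5) (2 * u)^(1 / (eta_m + 1)) - 1 else
      1 - (2 * (1 - u))^(1 / (eta_m + 1))
    x[k] <- min(max(x[k] + delta, 0), 1)
  }
  x
}

# variation for mixed spaces: SBX/polynomial on numeric coords, uniform
# block swap + category resampling on one-hot blocks
numeric_coord_index <- function(space) {
  idx <- logical(space$encoded_width)
  j <- 1L
  for (d in space$dims) {
    if (d$kind == "categorical") {
      j <- j + length(d$categories)
    } else {
      idx[j] <- TRUE
      j <- j + 1L
    }
  }
  idx
}

cat_blocks <- function(space) {
  blocks <- list()
  j <- 1L
  for (d in space$dims) {
    if (d$kind == "categorical") {
      blocks[[length(blocks) + 1L]] <- j:(j + length(d$categories) - 1L)
      j <- j + length(d$categories)
    } else j <- j + 1L
  }
  blocks
}

make_children <- function(P, rank, crowd, space, params) {
  n <- nrow(P)
  num_idx <- which(numeric_coord_index(space))
  blocks <- cat_blocks(space)
  p_m <- params$p_m %||% (1 / length(space$dims))
  C <- P
  i <- 1L
  while (i <= n) {
    a <- tournament_pick(rank, crowd)
    b <- tournament_pick(rank, crowd)
    p1 <- P[a, ]; p2 <- P[b, ]
    ch <- sbx_pair(p1[num_idx], p2[num_idx], params$eta_c, params$p_c)
    c1 <- p1; c2 <- p2
    c1[num_idx] <- ch[[1]]; c2[num_idx] <- ch[[2]]
    for (blk in blocks) {        # uniform crossover per categorical block
      if (stats::runif(1) < 0.5) {
        tmp <- c1[blk]; c1[blk] <- c2[blk]; c2[blk] <- tmp
      }
    }
    c1[num_idx] <- poly_mutate(c1[num_idx], params$eta_m, p_m)
    c2[num_idx] <- poly_mutate(c2[num_idx], params$eta_m, p_m)
    for (blk in blocks) {        # resample-category mutation
      if (stats::runif(1) < p_m) {
        c1[blk] <- 0; c1[sample(blk, 1L)] <- 1
      }
      if (stats::runif(1) < p_m) {
        c2[blk] <- 0; c2[sample(blk, 1L)] <- 1
      }
    }
    C[i, ] <- c1
    if (i + 1L <= n) C[i + 1L, ] <- c2
    i <- i + 2L
  }
  C
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One elitist NSGA-II generation
#'
#' Binary tournament selection on (rank, crowding distance), simulated binary
#' crossover and polynomial mutation in unit coordinates (uniform block
#' crossover and category resampling for categorical factors), then
#' environmental selection of the best `N` from parents plus children.
#' Operator defaults follow the canonical published values
#' (`eta_c = 15`, `p_c = 0.9`, `eta_m = 20`, `p_m = 1/d`).
#'
#' Constrained multi-objective optimization is not supported and raises an
#' error.
#'
#' @param population List with `U` (unit-coordinate matrix) and `objectives`
#'   (matrix, rows aligned with `U`).
#' @param space A `search_space`.
#' @param evaluator Function mapping a recipe to a numeric objective vector.
#' @param params List of operator parameters (`eta_c`, `p_c`, `eta_m`, `p_m`).
#' @param constraints Must be `NULL`.
#' @return Population list (`U`, `objectives`) of the same size.
#' @export
evolve <- function(population, space, evaluator,
                   params = list(eta_c = 15, p_c = 0.9, eta_m = 20, p_m = NULL),
                   constraints = NULL) {
  if (!is.null(constraints) && length(constraints) > 0L) {
    stop("multi-objective optimization does not support constraints",
         call. = FALSE)
  }
  P <- population$U
  O <- as.matrix(population$objectives)
  n <- nrow(P)
  if (n < 4L || n %% 2L != 0L) stop("population size must be even and >= 4",
                                    call. = FALSE)
  rc <- rank_and_crowd(O)
  C <- make_children(P, rc$rank, rc$crowding, space, params)
  CO <- t(apply(C, 1, function(u) evaluator(from_unit(space, u))))
  if (ncol(O) == 1L) CO <- matrix(CO, ncol = 1L)
  allU <- rbind(P, C)
  allO <- rbind(O, CO)
  rc2 <- rank_and_crowd(allO)
  ord <- order(rc2$rank, -rc2$crowding)
  sel <- ord[seq_len(n)]
  list(U = allU[sel, , drop = FALSE], objectives = allO[sel, , drop = FALSE])
}

#' Multi-objective suggestion via NSGA-II
#'
#' Runs an LHS-initialized NSGA-II over the space against a vector-valued
#' evaluator (e.g. the predictive means of per-objective surrogates, or a
#' benchmark model system) and returns the final non-dominated front.
#'
#' @param evaluator Function: recipe -> numeric vector of `m >= 2` objectives
#'   (all minimized).
#' @param space A `search_space`.
#' @param pop_size Even population size >= 4 (default 40).
#' @param generations Number of generations >= 1 (default 50).
#' @param seed Integer seed.
#' @param params NSGA-II operator parameters (see [evolve()]).
#' @param constraints Must be `NULL` (documented limitation).
#' @return A `pareto_front`: data.frame of recipes with one `obj_k` column
#'   per objective, mutually non-dominated.
#' @export
pareto_suggest <- function(evaluator, space, pop_size = 40, generations = 50,
                           seed = 1L,
                           params = list(eta_c = 15, p_c = 0.9, eta_m = 20,
                                         p_m = NULL),
                           constraints = NULL) {
  if (!is.null(constraints) && length(constraints) > 0L) {
    stop("multi-objective optimization does not support constraints",
         call. = FALSE)
  }
  if (pop_size < 4L || pop_size %% 2L != 0L) {
    stop("pop_size must be even and >= 4", call. = FALSE)
  }
  if (generations < 1L) stop("generations must be >= 1", call. = FALSE)
  withr::with_seed(derive_seed(seed, 31L), {
    init <- lhs_design(space, pop_size)
    U <- encode_points(space, init)
    m <- length(as.numeric(evaluator(init[[1]])))
    if (m < 2L) {
      stop("need at least 2 objectives; use the single-objective optimizer",
           call. = FALSE)
    }
    O <- t(vapply(init, function(p) as.numeric(evaluator(p)), numeric(m)))
    pop <- list(U = U, objectives = O)
    for (g in seq_len(generations)) {
      pop <- evolve(pop, space, evaluator, params)
    }
    idx <- non_dominated_sort(pop$objectives)[[1]]
    recipes <- lapply(idx, function(i) from_unit(space, pop$U[i, ]))
    df <- observations_df(space, recipes, rep(NA_real_, length(idx)),
                          rep("pareto", length(idx)))
    df$y <- NULL; df$origin <- NULL; df$iteration <- NULL
    for (m in seq_len(ncol(pop$objectives))) {
      df[[paste0("obj_", m)]] <- pop$objectives[idx, m]
    }
    structure(df, class = c("pareto_front", "data.frame"))
  })
}
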