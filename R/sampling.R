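#' Uniform sampling of feasible recipes
#'
#' Draws `n` independent uniform points in the (unit-cube encoded) space,
#' decoded to recipes, rejection-sampling against any constraints. Uses R's
#' global RNG; call `set.seed()` (or run inside an optimizer, which manages
#' its own seeded streams) for reproducibility.
#'
#' @param space A `search_space`.
#' @param n Number of recipes (>= 1).
#' @param constraints Optional constraint list (see [satisfies()]).
#' @return List of `n` recipes.
#' @export
sample_space <- function(space, n, constraints = NULL) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (!is.null(constraints)) check_constraint_names(constraints, space)
  out <- vector("list", n)
  got <- 0L
  proposed <- 0L
  max_proposals <- 1e6
  while (got < n) {
    batch <- max(n - got, 64L)
    u <- matrix(stats::runif(batch * space$encoded_width),
                nrow = batch, ncol = space$encoded_width)
    for (r in seq_len(batch)) {
      proposed <- proposed + 1L
      p <- from_unit(space, u[r, ])
      if (satisfies(constraints, p, space)) {
        got <- got + 1L
        out[[got]] <- p
        if (got == n) break
      }
      if (proposed >= max_proposals && got / proposed < 1e-4) {
        stop("infeasible constraint region: acceptance rate below 1e-4",
             call. = FALSE)
      }
    }
  }
  out
}

#' Latin-hypercube design over a space
#'
#' Space-filling initial design: for each numeric dimension, `[0, 1]` is cut
#' into `n` equal strata and exactly one point is drawn uniformly within each
#' stratum, with an independent random stratum permutation per dimension
#' (via [lhs::randomLHS()]). Categorical dimensions receive a shuffled
#' balanced multiset of their categories. Deterministic given the RNG seed.
#'
#' @param space A `search_space`.
#' @param n Number of design points (>= 1).
#' @return List of `n` recipes.
#' @export
lhs_design <- function(space, n) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  kinds <- vapply(space$dims, `[[`, "", "kind")
  n_num <- sum(kinds != "categorical")
  U <- lhs::randomLHS(n, max(n_num, 1L))
  out <- vector("list", n)
  vals <- vector("list", length(space$dims))
  j <- 1L
  for (i in seq_along(space$dims)) {
    d <- space$dims[[i]]
    if (d$kind == "categorical") {
      pool <- rep(d$categories, length.out = n)
      vals[[i]] <- sample(pool, n)
    } else {
      v <- d$low + U[, j] * (d$high - d$low)
      if (d$kind == "integer") v <- pmin(pmax(round_half_away(v), d$low), d$high)
      vals[[i]] <- v
      j <- j + 1L
    }
  }
  for (r in seq_len(n)) {
    rec <- lapply(vals, `[[`, r)
    names(rec) <- dim_names(space)
    out[[r]] <- rec
  }
  out
}

#' Encode a list of recipes as a matrix of unit coordinates
#'
#' @param space A `search_space`.
#' @param points List of recipes.
#' @return `length(points) x encoded_width` numeric matrix.
#' @export
encode_points <- function(space, points) {
  do.call(rbind, lapply(points, function(p) to_unit(space, p)))
}
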