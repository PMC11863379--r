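#' Define a single design-space dimension
#'
#' A dimension is one controllable factor of the experiment: a continuous
#' quantity (`dim_real`), a discrete count (`dim_integer`), or a choice among
#' labels (`dim_categorical`). Numeric dimensions carry inclusive bounds in
#' the original experimental units and an optional `grid_step`, the resolution
#' at which recipes can actually be prepared (e.g. a pipetting step of 5).
#'
#' @param name Factor name (unique within a space).
#' @param low,high Inclusive numeric bounds, `low < high`.
#' @param grid_step Optional positive snap resolution; must divide
#'   `high - low` to within 1e-9.
#' @param categories Character vector of unique labels (categorical only).
#' @return An object of class `labopt_dimension`.
#' @examples
#' dim_real("acid", 30, 85, grid_step = 5)
#' dim_categorical("solvent", c("EtOH", "MeOH", "iPrOH"))
#' @export
dim_real <- function(name, low, high, grid_step = NULL) {
  new_dimension(name, "real", low = low, high = high, grid_step = grid_step)
}

#' @rdname dim_real
#' @export
dim_integer <- function(name, low, high, grid_step = NULL) {
  if (low != round(low) || high != round(high)) {
    stop("integer dimension '", name, "' needs integer bounds", call. = FALSE)
  }
  new_dimension(name, "integer", low = low, high = high, grid_step = grid_step)
}

#' @rdname dim_real
#' @export
dim_categorical <- function(name, categories) {
  new_dimension(name, "categorical", categories = categories)
}

new_dimension <- function(name, kind, low = NULL, high = NULL,
                          categories = NULL, grid_step = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  kind <- match.arg(kind, c("real", "integer", "categorical"))
  if (kind == "categorical") {
    categories <- as.character(categories)
    if (length(categories) == 0L) {
      stop("categorical dimension '", name, "' needs at least one category",
           call. = FALSE)
    }
    if (anyDuplicated(categories)) {
      stop("categories of '", name, "' must be unique", call. = FALSE)
    }
    d <- list(name = name, kind = kind, categories = categories)
  } else {
    low <- as.numeric(low); high <- as.numeric(high)
    if (!is.finite(low) || !is.finite(high) || low >= high) {
      stop("dimension '", name, "' needs finite bounds with low < high",
           call. = FALSE)
    }
    if (!is.null(grid_step)) {
      grid_step <- as.numeric(grid_step)
      if (!is.finite(grid_step) || grid_step <= 0) {
        stop("grid_step of '", name, "' must be positive", call. = FALSE)
      }
      k <- (high - low) / grid_step
      if (abs(k - round(k)) > 1e-9) {
        stop("grid_step of '", name, "' must divide high - low", call. = FALSE)
      }
    }
    d <- list(name = name, kind = kind, low = low, high = high,
              grid_step = grid_step)
  }
  structure(d, class = "labopt_dimension")
}

#' Build a mixed-type design space
#'
#' Assembles ordered dimensions into a search space and computes the width of
#' its unit-cube encoding (1 coordinate per numeric dimension, one one-hot
#' block per categorical dimension). Spaces made only of categorical factors
#' are not supported and raise an error.
#'
#' Numeric dimensions may also be given as shorthand vectors
#' `c(low, high)` or lists `list(low, high, name)`.
#'
#' @param ... Dimensions (`labopt_dimension` objects or numeric shorthands),
#'   or a single list of them.
#' @return An object of class `search_space` with elements `dims` and
#'   `encoded_width`.
#' @examples
#' search_space(dim_real("Acid", 30, 85), dim_real("Indicator", 5, 40))
#' @export
search_space <- function(...) {
  dims <- list(...)
  if (length(dims) == 1L && is.list(dims[[1]]) &&
      !inherits(dims[[1]], "labopt_dimension")) {
    dims <- dims[[1]]
  }
  if (length(dims) == 0L) stop("a search space needs at least one dimension",
                               call. = FALSE)
  dims <- lapply(seq_along(dims), function(i) {
    d <- dims[[i]]
    if (inherits(d, "labopt_dimension")) return(d)
    if (is.numeric(d) && length(d) >= 2L) {
      nm <- if (length(d) >= 3L && !is.null(names(d))) names(d)[3] else NULL
      return(dim_real(paste0("x", i), d[1], d[2]))
    }
    if (is.list(d) && length(d) >= 2L && is.numeric(d[[1]])) {
      nm <- if (length(d) >= 3L) as.character(d[[3]]) else paste0("x", i)
      return(dim_real(nm, d[[1]], d[[2]]))
    }
    stop("cannot interpret element ", i, " as a dimension", call. = FALSE)
  })
  nms <- vapply(dims, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("dimension names must be unique", call. = FALSE)
  kinds <- vapply(dims, `[[`, "", "kind")
  if (all(kinds == "categorical")) {
    stop("design spaces that only contain categorical factors are not ",
         "supported", call. = FALSE)
  }
  width <- sum(vapply(dims, function(d) {
    if (d$kind == "categorical") length(d$categories) else 1L
  }, integer(1)))
  structure(list(dims = dims, encoded_width = as.integer(width)),
            class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat("<search_space> ", length(x$dims), " dimensions, encoded width ",
      x$encoded_width, "\n", sep = "")
  for (d in x$dims) {
    if (d$kind == "categorical") {
      cat("  ", d$name, " [categorical]: ",
          paste(d$categories, collapse = ", "), "\n", sep = "")
    } else {
      cat("  ", d$name, " [", d$kind, "]: ", d$low, " to ", d$high,
        if (!is.null(d$grid_step)) paste0(", step ", d$grid_step) else "",
        "\n", sep = "")
    }
  }
  invisible(x)
}

#' Names of a space's dimensions, in order
#'
#' @param space A `search_space`.
#' @return Character vector.
#' @export
dim_names <- function(space) vapply(space$dims, `[[`, "", "name")

#' Coerce a value vector to a recipe in a space
#'
#' A recipe holds one entry per dimension, in dimension order, in original
#' units (numbers for numeric dimensions, labels for categorical ones).
#' Accepts a list, a named list (reordered by name), or an atomic vector.
#'
#' @param space A `search_space`.
#' @param x Values for each dimension.
#' @return A named list of length `length(space$dims)`.
#' @export
as_recipe <- function(space, x) {
  nd <- length(space$dims)
  nms <- dim_names(space)
  if (is.list(x) && !is.null(names(x)) && all(nms %in% names(x))) {
    x <- x[nms]
  }
  if (!is.list(x)) x <- as.list(x)
  if (length(x) != nd) {
    stop("recipe has ", length(x), " entries; space has ", nd, " dimensions",
         call. = FALSE)
  }
  names(x) <- nms
  for (i in seq_len(nd)) {
    d <- space$dims[[i]]
    v <- x[[i]]
    if (d$kind == "categorical") {
      v <- as.character(v)
      if (!(v %in% d$categories)) {
        stop("value '", v, "' is not a category of dimension '", d$name, "'",
             call. = FALSE)
      }
    } else {
      v <- as.numeric(v)
      if (!is.finite(v)) stop("non-finite value for dimension '", d$name, "'",
                              call. = FALSE)
      if (v < d$low - 1e-12 || v > d$high + 1e-12) {
        stop("value ", v, " of dimension '", d$name, "' is outside [",
             d$low, ", ", d$high, "]", call. = FALSE)
      }
      v <- min(max(v, d$low), d$high)
      if (d$kind == "integer") {
        if (abs(v - round(v)) > 1e-9) {
          stop("dimension '", d$name, "' is integer; got ", v, call. = FALSE)
        }
        v <- round(v)
      }
    }
    x[[i]] <- v
  }
  x
}

#' Map a recipe to unit-cube coordinates
#'
#' Numeric dimensions are rescaled linearly to `[0, 1]` via
#' `(x - low) / (high - low)`; categorical dimensions become one-hot blocks.
#'
#' @param space A `search_space`.
#' @param point A recipe (see [as_recipe()]).
#' @return Numeric vector of length `space$encoded_width`.
#' @export
to_unit <- function(space, point) {
  point <- as_recipe(space, point)
  out <- numeric(0)
  for (i in seq_along(space$dims)) {
    d <- space$dims[[i]]
    if (d$kind == "categorical") {
      block <- as.numeric(d$categories == point[[i]])
      out <- c(out, block)
    } else {
      out <- c(out, (point[[i]] - d$low) / (d$high - d$low))
    }
  }
  out
}

#' Decode unit-cube coordinates into a recipe
#'
#' Inverse of [to_unit()]. Integer dimensions are rounded to the nearest
#' integer (ties half away from zero); categorical blocks decode as the
#' argmax, ties resolved to the lowest category index.
#'
#' @param space A `search_space`.
#' @param coords Numeric vector of length `space$encoded_width` in `[0, 1]`.
#' @return A recipe (named list).
#' @export
from_unit <- function(space, coords) {
  if (length(coords) != space$encoded_width) {
    stop("expected ", space$encoded_width, " coordinates, got ",
         length(coords), call. = FALSE)
  }
  out <- vector("list", length(space$dims))
  j <- 1L
  for (i in seq_along(space$dims)) {
    d <- space$dims[[i]]
    if (d$kind == "categorical") {
      k <- length(d$categories)
      block <- coords[j:(j + k - 1L)]
      out[[i]] <- d$categories[which.max(block)]
      j <- j + k
    } else {
      v <- d$low + min(max(coords[j], 0), 1) * (d$high - d$low)
      if (d$kind == "integer") v <- round_half_away(v)
      out[[i]] <- min(max(v, d$low), d$high)
      j <- j + 1L
    }
  }
  names(out) <- dim_names(space)
  out
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Snap a recipe to the preparation grid
#'
#' Each numeric entry whose dimension has a `grid_step` is snapped to the
#' nearest `low + k * grid_step` (ties rounded half away from zero) and
#' clamped to the bounds. Dimensions without a step, and categorical entries,
#' pass through unchanged. Lab recipes can often only be pipetted at a fixed
#' resolution, so suggestions are rounded to the nearest feasible multiple
#' before being run.
#'
#' @param point A recipe.
#' @param space A `search_space`.
#' @return The snapped recipe.
#' @examples
#' sp <- search_space(dim_real("Acid", 30, 85, grid_step = 5),
#'                    dim_real("Indicator", 5, 40, grid_step = 5))
#' round_to_grid(list(79, 36), sp)  # -> 80, 35
#' @export
round_to_grid <- function(point, space) {
  point <- as_recipe(space, point)
  for (i in seq_along(space$dims)) {
    d <- space$dims[[i]]
    if (d$kind == "categorical" || is.null(d$grid_step)) next
    k <- round_half_away((point[[i]] - d$low) / d$grid_step)
    v <- d$low + k * d$grid_step
    point[[i]] <- min(max(v, d$low), d$high)
  }
  point
}
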