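#' Design-space constraints
#'
#' Constraints restrict which recipes are considered feasible when sampling
#' candidates and when suggesting experiments. Three kinds are supported:
#'
#' * `constraint_sum_equals`: the named numeric factors must sum to `total`
#'   within `tolerance` (mixture designs, e.g. component fractions summing
#'   to 100).
#' * `constraint_value_exclusion`: a factor must not take any of the
#'   `forbidden` values.
#' * `constraint_value_restriction`: a factor may only take values in
#'   `allowed`.
#'
#' @param dim_names Names of the factors the constraint applies to.
#' @param total Required sum (sum_equals).
#' @param tolerance Non-negative slack on the sum; default 1e-6.
#' @param dim_name Name of the single factor (exclusion/restriction).
#' @param forbidden,allowed Values compared exactly for categorical factors
#'   and within 1e-9 for numeric ones.
#' @return An object of class `labopt_constraint`.
#' @export
constraint_sum_equals <- function(dim_names, total, tolerance = 1e-6) {
  stopifnot(length(dim_names) >= 2L, is.finite(total), tolerance >= 0)
  structure(list(kind = "sum_equals", dim_names = as.character(dim_names),
                 total = as.numeric(total), tolerance = as.numeric(tolerance)),
            class = "labopt_constraint")
}

#' @rdname constraint_sum_equals
#' @export
constraint_value_exclusion <- function(dim_name, forbidden) {
  stopifnot(length(dim_name) == 1L, length(forbidden) >= 1L)
  structure(list(kind = "value_exclusion", dim_names = as.character(dim_name),
                 forbidden = forbidden),
            class = "labopt_constraint")
}

#' @rdname constraint_sum_equals
#' @export
constraint_value_restriction <- function(dim_name, allowed) {
  stopifnot(length(dim_name) == 1L, length(allowed) >= 1L)
  structure(list(kind = "value_restriction", dim_names = as.character(dim_name),
                 allowed = allowed),
            class = "labopt_constraint")
}

check_constraint_names <- function(constraints, space) {
  nms <- dim_names(space)
  for (con in constraints) {
    bad <- setdiff(con$dim_names, nms)
    if (length(bad)) {
      stop("constraint references unknown dimension(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

value_matches <- function(value, set) {
  if (is.numeric(value)) {
    any(abs(as.numeric(set) - value) <= 1e-9)
  } else {
    as.character(value) %in% as.character(set)
  }
}

#' Test whether a recipe satisfies a set of constraints
#'
#' @param constraints A list of `labopt_constraint` objects (or a single one);
#'   `NULL` means unconstrained.
#' @param point A recipe.
#' @param space The `search_space` the recipe lives in.
#' @return `TRUE` iff every constraint holds.
#' @export
satisfies <- function(constraints, point, space) {
  if (is.null(constraints) || length(constraints) == 0L) return(TRUE)
  if (inherits(constraints, "labopt_constraint")) constraints <- list(constraints)
  check_constraint_names(constraints, space)
  point <- as_recipe(space, point)
  for (con in constraints) {
    ok <- switch(con$kind,
      sum_equals = {
        s <- sum(vapply(con$dim_names, function(nm) as.numeric(point[[nm]]),
                        numeric(1)))
        abs(s - con$total) <= con$tolerance
      },
      value_exclusion = !value_matches(point[[con$dim_names]], con$forbidden),
      value_restriction = value_matches(point[[con$dim_names]], con$allowed),
      stop("unknown constraint kind: ", con$kind, call. = FALSE)
    )
    if (!ok) return(FALSE)
  }
  TRUE
}
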