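# ---- space / constraint <-> plain-list (YAML/JSON) serialization ----

#' Convert a space to/from its plain-list (YAML/JSON) form
#'
#' @param space A `search_space`.
#' @param lst A list with a `dimensions` element, as produced by
#'   `space_to_list` or read from a YAML/JSON config.
#' @return `space_to_list` a plain list; `space_from_list` a `search_space`.
#' @export
space_to_list <- function(space) {
  list(dimensions = lapply(space$dims, function(d) {
    out <- list(name = d$name, kind = d$kind)
    if (d$kind == "categorical") {
      out$categories <- as.list(d$categories)
    } else {
      out$low <- d$low; out$high <- d$high
      if (!is.null(d$grid_step)) out$grid_step <- d$grid_step
    }
    out
  }))
}

#' @rdname space_to_list
#' @export
space_from_list <- function(lst) {
  dims <- lst$dimensions
  if (is.null(dims)) stop("config is missing required key: dimensions",
                          call. = FALSE)
  search_space(lapply(dims, function(d) {
    kind <- d$kind %||% "real"
    switch(kind,
      real = dim_real(d$name, d$low, d$high, d$grid_step),
      integer = dim_integer(d$name, d$low, d$high, d$grid_step),
      categorical = dim_categorical(d$name, unlist(d$categories)),
      stop("unknown dimension kind: ", kind, call. = FALSE))
  }))
}

constraints_to_list <- function(constraints) {
  if (is.null(constraints)) return(list())
  lapply(constraints, function(con) {
    out <- list(kind = con$kind)
    switch(con$kind,
      sum_equals = {
        out$dim_names <- as.list(con$dim_names)
        out$total <- con$total
        out$tolerance <- con$tolerance
      },
      value_exclusion = {
        out$dim_name <- con$dim_names
        out$forbidden <- as.list(con$forbidden)
      },
      value_restriction = {
        out$dim_name <- con$dim_names
        out$allowed <- as.list(con$allowed)
      })
    out
  })
}

constraints_from_list <- function(lst) {
  if (is.null(lst) || length(lst) == 0L) return(NULL)
  lapply(lst, function(con) {
    kind <- con$kind %||% stop("constraint without a kind", call. = FALSE)
    switch(kind,
      sum_equals = constraint_sum_equals(unlist(con$dim_names), con$total,
                                         con$tolerance %||% 1e-6),
      value_exclusion = constraint_value_exclusion(con$dim_name,
                                                   unlist(con$forbidden)),
      value_restriction = constraint_value_restriction(con$dim_name,
                                                       unlist(con$allowed)),
      stop("unknown constraint kind: ", kind, call. = FALSE))
  })
}

#' Load an optimization configuration from YAML
#'
#' Schema:
#' ```yaml
#' dimensions:
#'   - {name: Acid, kind: real, low: 30, high: 85, grid_step: 5}
#'   - {name: Indicator, kind: real, low: 5, high: 40, grid_step: 5}
#' constraints: []
#' n_initial_points: 4
#' acquisition: {kind: EI, xi: 0.01}
#' seed: 1
#' ```
#'
#' @param path YAML file.
#' @return List with `space`, `constraints`, `n_initial_points`, `acq`,
#'   `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  missing <- setdiff("dimensions", names(cfg))
  if (length(missing)) {
    stop("config is missing required key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  space <- space_from_list(cfg)
  constraints <- constraints_from_list(cfg$constraints)
  if (!is.null(constraints)) check_constraint_names(constraints, space)
  acq_cfg <- cfg$acquisition %||% list()
  acq <- acq_spec(kind = acq_cfg$kind %||% "EI",
                  xi = acq_cfg$xi %||% 0.01,
                  kappa = acq_cfg$kappa %||% 1.96)
  list(
    space = space,
    constraints = constraints,
    n_initial_points = as.integer(cfg$n_initial_points %||% 4L),
    acq = acq,
    seed = as.integer(cfg$seed %||% 1L)
  )
}

#' Save an optimization configuration to YAML
#'
#' @param space A `search_space`.
#' @param path Output YAML file.
#' @param constraints Optional constraint list.
#' @param n_initial_points,seed Optimizer settings.
#' @param acq An [acq_spec()].
#' @export
save_config <- function(space, path, constraints = NULL,
                        n_initial_points = 4, acq = acq_spec(), seed = 1L) {
  cfg <- space_to_list(space)
  cfg$constraints <- constraints_to_list(constraints)
  cfg$n_initial_points <- as.integer(n_initial_points)
  cfg$acquisition <- list(kind = acq$kind, xi = acq$xi, kappa = acq$kappa)
  cfg$seed <- as.integer(seed)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
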