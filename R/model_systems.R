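#' CIELAB color
#'
#' @param L Lightness, 0-100.
#' @param a Green-red axis.
#' @param b Blue-yellow axis.
#' @return Object of class `lab_color`.
#' @export
lab_color <- function(L, a, b) {
  v <- c(L = as.numeric(L), a = as.numeric(a), b = as.numeric(b))
  if (any(!is.finite(v))) stop("non-finite color components", call. = FALSE)
  if (v[["L"]] < 0 || v[["L"]] > 100) stop("L must be in [0, 100]", call. = FALSE)
  structure(as.list(v), class = "lab_color")
}

#' Color difference Delta-E (CIE76)
#'
#' Euclidean distance in CIELAB space,
#' `sqrt((dL)^2 + (da)^2 + (db)^2)` — a proxy for the perceived difference
#' between two colors. Zero iff the colors are identical; symmetric.
#'
#' @param c1,c2 `lab_color` objects.
#' @return Non-negative number.
#' @export
delta_e <- function(c1, c2) {
  stopifnot(inherits(c1, "lab_color"), inherits(c2, "lab_color"))
  sqrt((c1$L - c2$L)^2 + (c1$a - c2$a)^2 + (c1$b - c2$b)^2)
}

# default universal-indicator palette: (pH, Lab) anchors, red -> violet.
# Synthetic stand-in colors; approximate hues of a wide-range indicator.
default_anchor_palette <- function() {
  data.frame(
    pH = c(3, 5, 6, 7, 8.5, 10, 11),
    L = c(54, 67, 92, 60, 55, 40, 35),
    a = c(75, 43, -12, -55, -35, 10, 45),
    b = c(55, 70, 85, 40, -15, -50, -45)
  )
}

lab_at_ph <- function(palette, ph) {
  ph <- min(max(ph, palette$pH[1]), palette$pH[nrow(palette)])
  i <- findInterval(ph, palette$pH, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(palette) - 1L)
  w <- (ph - palette$pH[i]) / (palette$pH[i + 1] - palette$pH[i])
  lab_color(
    palette$L[i] + w * (palette$L[i + 1] - palette$L[i]),
    palette$a[i] + w * (palette$a[i + 1] - palette$a[i]),
    palette$b[i] + w * (palette$b[i + 1] - palette$b[i])
  )
}

#' Synthetic universal pH-indicator color plate
#'
#' Deterministically generates a 96-well (12 x 8) plate of CIELAB colors on
#' the grid acid = 30, 35, ..., 85 % by indicator = 5, 10, ..., 40 uL,
#' emulating a wide-range buffer series mixed with a universal pH indicator:
#'
#' * the acid fraction sets the pH through a sigmoid titration curve
#'   `pH = p_lo + (p_hi - p_lo) / (1 + exp(s * (acid - mid)))`;
#' * the pH sets the hue by piecewise-linear interpolation between the
#'   anchor colors of the indicator palette (red at low pH through green to
#'   violet at high pH);
#' * the indicator volume v scales the color saturation: a and b are
#'   multiplied by `v / 40` and lightness fades towards 100 (colorless) as
#'   `v` approaches 0.
#'
#' This is a synthetic stand-in for a measured plate: the acid-to-pH mapping
#' of a real buffer series is not modelled, only its qualitative structure.
#' The target color is the generated color at `(target_acid,
#' target_indicator)`, so the optimum lies exactly on the plate grid with a
#' score of 0 by construction. Measured plate data with the same layout can
#' be loaded instead via [grid_from_csv()].
#'
#' @param target_acid,target_indicator Grid well defining the target color
#'   (defaults 50 % and 30 uL).
#' @param palette Anchor palette: data.frame with columns `pH`, `L`, `a`,
#'   `b`, strictly increasing pH.
#' @param ph_low,ph_high Asymptotic pH values of the titration curve.
#' @param steepness,midpoint Sigmoid slope (per acid fraction) and midpoint
#'   (acid fraction).
#' @return Object of class `color_grid`: the well table (`wells`), `target`
#'   color, `optimum_well`, and the matching `search_space` (grid step 5).
#' @export
synth_color_grid <- function(target_acid = 50, target_indicator = 30,
                             palette = default_anchor_palette(),
                             ph_low = 3, ph_high = 11,
                             steepness = 10, midpoint = 0.575) {
  if (nrow(palette) < 4L) stop("palette needs at least 4 anchors", call. = FALSE)
  if (any(diff(palette$pH) <= 0)) stop("anchor pH values must be increasing",
                                       call. = FALSE)
  acid_levels <- seq(30, 85, by = 5)
  indicator_levels <- seq(5, 40, by = 5)
  if (!(target_acid %in% acid_levels) ||
      !(target_indicator %in% indicator_levels)) {
    stop("target must be a plate well", call. = FALSE)
  }
  wells <- expand.grid(acid = acid_levels, indicator = indicator_levels,
                       KEEP.OUT.ATTRS = FALSE)
  lab <- t(mapply(function(acid, v) {
    ph <- ph_low + (ph_high - ph_low) /
      (1 + exp(steepness * (acid / 100 - midpoint)))
    base <- lab_at_ph(palette, ph)
    sat <- v / 40
    c(L = 100 - (100 - base$L) * sat, a = base$a * sat, b = base$b * sat)
  }, wells$acid, wells$indicator))
  wells$L <- lab[, "L"]; wells$a <- lab[, "a"]; wells$b <- lab[, "b"]
  new_color_grid(wells, target_acid, target_indicator)
}

new_color_grid <- function(wells, target_acid, target_indicator) {
  stopifnot(nrow(wells) == 96L)
  ti <- which(abs(wells$acid - target_acid) < 1e-9 &
                abs(wells$indicator - target_indicator) < 1e-9)
  if (length(ti) != 1L) stop("target well not found in grid", call. = FALSE)
  target <- lab_color(wells$L[ti], wells$a[ti], wells$b[ti])
  space <- search_space(
    dim_real("acid", 30, 85, grid_step = 5),
    dim_real("indicator", 5, 40, grid_step = 5)
  )
  structure(list(
    wells = wells,
    target = target,
    optimum_well = c(acid = target_acid, indicator = target_indicator),
    space = space
  ), class = "color_grid")
}

#' @export
print.color_grid <- function(x, ...) {
  cat("<color_grid> 96 wells (acid 30-85% x indicator 5-40 uL, step 5); ",
      "target at acid ", x$optimum_well[["acid"]], "%, indicator ",
      x$optimum_well[["indicator"]], " uL\n", sep = "")
  invisible(x)
}

#' Total prepared volume of a color-plate recipe
#'
#' Each well is prepared by diluting the indicator with water to 40 uL and
#' adding 200 uL of the acid/base buffer mixture, so every valid recipe has
#' a total volume of 240 uL. Errors if the recipe cannot be prepared that
#' way (indicator volume above 40 uL).
#'
#' @param recipe A recipe on the color-plate space (acid %, indicator uL).
#' @return Total volume in uL (always 240 for a valid recipe).
#' @export
recipe_volume <- function(recipe) {
  recipe <- unlist(recipe, use.names = FALSE)
  indicator <- as.numeric(recipe[2])
  if (!is.finite(indicator) || indicator < 0 || indicator > 40) {
    stop("indicator volume must be within [0, 40] uL", call. = FALSE)
  }
  indicator_solution <- 40   # indicator topped up with water to 40 uL
  acid_base <- 200           # fixed buffer volume
  indicator_solution + acid_base
}

#' Score a recipe against the color plate
#'
#' The recipe is snapped to the plate grid (step 5, matching how suggested
#' recipes are rounded before being run), its well color looked up, and the
#' CIE76 Delta-E to the target color returned. The 240 uL recipe volume is
#' validated via [recipe_volume()].
#'
#' @param grid A `color_grid`.
#' @param recipe Recipe (acid %, indicator uL) within the space bounds.
#' @return Delta-E score (>= 0; 0 at the target well).
#' @export
color_ph_score <- function(grid, recipe) {
  stopifnot(inherits(grid, "color_grid"))
  r <- round_to_grid(as_recipe(grid$space, recipe), grid$space)
  recipe_volume(r)
  i <- which(abs(grid$wells$acid - r$acid) < 1e-9 &
               abs(grid$wells$indicator - r$indicator) < 1e-9)
  if (length(i) != 1L) stop("recipe does not round to a plate well", call. = FALSE)
  delta_e(lab_color(grid$wells$L[i], grid$wells$a[i], grid$wells$b[i]),
          grid$target)
}

#' Noise specification for a model system
#'
#' @param kind `"zero"` (no noise), `"constant"` (additive Gaussian with
#'   standard deviation `size` in score units), or `"proportional"`
#'   (Gaussian with standard deviation `size * |truth|`).
#' @param size Non-negative noise size; must be 0 for kind `"zero"`.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("zero", "constant", "proportional"), size = 0) {
  kind <- match.arg(kind)
  if (size < 0) stop("noise size must be >= 0", call. = FALSE)
  if (kind == "zero" && size != 0) stop("zero noise has size 0", call. = FALSE)
  if (kind != "zero" && size == 0) kind <- "zero"
  structure(list(kind = kind, size = size), class = "noise_spec")
}

#' Benchmark model system
#'
#' Packages a truth function over a search space with a noise model, so full
#' optimization campaigns can be simulated without physical experiments.
#'
#' @param truth Function: recipe -> finite score.
#' @param space The `search_space` the truth is defined on.
#' @param noise A [noise_spec()] (default: no noise).
#' @param known_min Optional list `(x, score)` with the known optimum.
#' @param name Optional display name.
#' @return Object of class `model_system`.
#' @export
model_system <- function(truth, space, noise = noise_spec("zero"),
                         known_min = NULL, name = "model_system") {
  stopifnot(is.function(truth), inherits(space, "search_space"),
            inherits(noise, "noise_spec"))
  structure(list(truth = truth, space = space, noise = noise,
                 known_min = known_min, name = name),
            class = "model_system")
}

#' The synthetic color-plate model system
#'
#' Wraps [synth_color_grid()] into a ready-to-benchmark [model_system()]
#' whose truth is the Delta-E score to the target color; the known minimum
#' is the target well with score 0.
#'
#' @param noise A [noise_spec()].
#' @param grid Optionally a pre-built `color_grid` (e.g. loaded from CSV).
#' @return A `model_system`.
#' @export
color_ph_system <- function(noise = noise_spec("zero"),
                            grid = synth_color_grid()) {
  model_system(
    truth = function(recipe) color_ph_score(grid, recipe),
    space = grid$space,
    noise = noise,
    known_min = list(x = as.list(grid$optimum_well), score = 0),
    name = "color_ph"
  )
}

#' Simulate one experiment on a model system
#'
#' Evaluates the truth function and adds noise per the system's noise spec
#' (drawn from R's RNG; seed the stream for reproducibility). Proportional
#' noise scales with the absolute truth value, so a perfect score stays
#' exactly 0.
#'
#' @param system A `model_system`.
#' @param recipe Recipe within the system's space.
#' @return Noisy score.
#' @export
get_score <- function(system, recipe) {
  stopifnot(inherits(system, "model_system"))
  recipe <- as_recipe(system$space, recipe)
  y <- system$truth(recipe)
  if (!is.finite(y)) stop("truth function returned a non-finite score",
                          call. = FALSE)
  eps <- switch(system$noise$kind,
    zero = 0,
    constant = stats::rnorm(1, 0, system$noise$size),
    proportional = if (y == 0) 0 else stats::rnorm(1, 0, system$noise$size * abs(y))
  )
  y + eps
}

#' Write / read a color plate as CSV
#'
#' Plain-text interchange for plate data: columns `acid`, `indicator`, `L`,
#' `a`, `b`, one row per well. A measured plate with the same 96-well layout
#' can be loaded in place of the synthetic grid.
#'
#' @param grid A `color_grid`.
#' @param path CSV path.
#' @param target_acid,target_indicator Well defining the target color on load.
#' @return `grid_from_csv` returns a `color_grid`.
#' @export
grid_to_csv <- function(grid, path) {
  stopifnot(inherits(grid, "color_grid"))
  utils::write.csv(grid$wells[, c("acid", "indicator", "L", "a", "b")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname grid_to_csv
#' @export
grid_from_csv <- function(path, target_acid = 50, target_indicator = 30) {
  wells <- utils::read.csv(path)
  need <- c("acid", "indicator", "L", "a", "b")
  miss <- setdiff(need, names(wells))
  if (length(miss)) stop("grid CSV is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(wells) != 96L) stop("grid CSV must have 96 rows, got ", nrow(wells),
                               call. = FALSE)
  new_color_grid(wells, target_acid, target_indicator)
}
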