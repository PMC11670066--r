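#' Cubic approximation of the fertilization-distance curve
#'
#' A cubic in nearest-gravid-neighbour distance `nn` on the percent scale,
#' `F(nn) = c3 nn^3 + c2 nn^2 + c1 nn + c0`, clamped to [0, 100] where the
#' polynomial leaves its natural range. `F0 = F(0) = c0` is the maximum
#' theoretical fertilization success at zero separation. The defaults are
#' the reference curve for the studied *Acropora hyacinthus* population
#' (see [reference_fit()]), whose cubic tail goes slightly negative beyond
#' ~23 m and is clamped.
#'
#' @param c3,c2,c1,c0 Cubic coefficients (percent scale).
#' @param nn_max Upper end of the range (m) the curve was fitted over.
#' @return An object of class `allee_curve`.
#' @export
allee_curve <- function(c3 = -0.00222, c2 = 0.1458, c1 = -3.44, c0 = 30,
                        nn_max = 20) {
  structure(list(c3 = c3, c2 = c2, c1 = c1, c0 = c0, F0 = c0,
                 valid_range = c(0, nn_max)),
            class = "allee_curve")
}

#' @export
print.allee_curve <- function(x, ...) {
  cat(sprintf("fertilization-distance cubic: F(nn) = %.5g nn^3 + %.5g nn^2 + %.5g nn + %.5g\n",
              x$c3, x$c2, x$c1, x$c0))
  cat(sprintf("F0 = %.4g%%; fitted over [%g, %g] m; clamped to [0, 100]\n",
              x$F0, x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Evaluate the fertilization-distance curve
#'
#' @param curve An [allee_curve()].
#' @param nn Nearest-neighbour distances (m), >= 0.
#' @return Predicted fertilization success in percent, clamped to [0, 100].
#' @export
eval_curve <- function(curve, nn) {
  stopifnot(inherits(curve, "allee_curve"))
  if (any(nn < 0)) stop("nn must be >= 0", call. = FALSE)
  pmin(pmax(curve$c3 * nn^3 + curve$c2 * nn^2 + curve$c1 * nn + curve$c0,
            0), 100)
}

#' Cubic approximation to a fitted fertilization model
#'
#' Evaluates the fitted beta-binomial mean curve (in percent) for one night
#' over an evenly spaced nearest-neighbour grid and fits a cubic by
#' ordinary least squares. The cubic makes the fertilization-potential
#' metric usable without carrying the full model around.
#'
#' @param fit A `bb_fit` whose model contains the `nn` term.
#' @param night Night the curve represents (default `"n1"`).
#' @param grid `c(min, max, step)` in metres.
#' @return An [allee_curve()] with `F0` = the cubic at `nn = 0`.
#' @export
fit_cubic <- function(fit, night = "n1", grid = c(0, 20, 0.1)) {
  stopifnot(inherits(fit, "bb_fit"))
  if (!"nn" %in% names(fit$coefficients))
    stop("fit has no nearest-neighbour (nn) term", call. = FALSE)
  nn <- seq(grid[1], grid[2], by = grid[3])
  y <- 100 * predict_mean(fit, data.frame(nn = nn, night = night))
  co <- stats::coef(stats::lm(y ~ nn + I(nn^2) + I(nn^3)))
  allee_curve(c3 = unname(co[4]), c2 = unname(co[3]), c1 = unname(co[2]),
              c0 = unname(co[1]), nn_max = grid[2])
}

#' Site-level fertilization potential
#'
#' The mean, across colonies, of each colony's predicted fertilization
#' success at its nearest-gravid-neighbour distance expressed as a fraction
#' of the maximum achievable at zero separation (`F0`), times 100. A site
#' whose colonies all sit at `nn = 0` scores 100%; isolation pulls the
#' metric down — the site-level summary of the Allee effect.
#'
#' `fertilization_potential()` is generic: pass an [allee_curve()] (the
#' default route) or a fitted `bb_fit` to evaluate the model mean directly
#' without the cubic approximation.
#'
#' @param object An `allee_curve` or `bb_fit`.
#' @param nn_values Per-colony nearest-neighbour distances (m), >= 0.
#' @param ... Passed to methods (`night` for the `bb_fit` method).
#' @return List of class `potential_result`: `per_colony` (named fractions
#'   in [0, 1]), `n_colonies`, `F0`, `fertilization_potential` (percent).
#' @export
fertilization_potential <- function(object, nn_values, ...) {
  UseMethod("fertilization_potential")
}

#' @rdname fertilization_potential
#' @export
fertilization_potential.allee_curve <- function(object, nn_values, ...) {
  stopifnot(length(nn_values) >= 1)
  if (object$F0 <= 0)
    stop("undefined metric: F0 is not positive", call. = FALSE)
  frac <- pmin(eval_curve(object, nn_values) / object$F0, 1)
  make_potential(frac, object$F0, nn_values)
}

#' @rdname fertilization_potential
#' @param night Night at which the model mean is evaluated.
#' @export
fertilization_potential.bb_fit <- function(object, nn_values, night = "n1",
                                           ...) {
  stopifnot(length(nn_values) >= 1)
  if (any(nn_values < 0)) stop("nn must be >= 0", call. = FALSE)
  f0 <- predict_mean(object, data.frame(nn = 0, night = night))
  if (f0 <= 0) stop("undefined metric: F0 is not positive", call. = FALSE)
  mu <- predict_mean(object, data.frame(nn = nn_values, night = night))
  make_potential(pmin(mu / f0, 1), 100 * f0, nn_values)
}

make_potential <- function(frac, F0, nn_values) {
  names(frac) <- names(nn_values)
  structure(list(per_colony = frac,
                 n_colonies = length(frac),
                 F0 = F0,
                 fertilization_potential = 100 * mean(frac)),
            class = "potential_result")
}

#' @export
print.potential_result <- function(x, ...) {
  cat(sprintf("fertilization potential: %.1f%% (C = %d colonies, F0 = %.3g%%)\n",
              x$fertilization_potential, x$n_colonies, x$F0))
  invisible(x)
}

#' Threshold-based Allee metric
#'
#' An alternative site summary: the percentage of colonies whose predicted
#' fertilization success meets a chosen threshold.
#'
#' @param curve An [allee_curve()].
#' @param nn_values Per-colony nearest-neighbour distances (m).
#' @param threshold Percent, in (0, 100).
#' @return Percent of colonies at or above the threshold.
#' @export
threshold_metric <- function(curve, nn_values, threshold) {
  stopifnot(threshold > 0, threshold < 100, length(nn_values) >= 1)
  100 * mean(eval_curve(curve, nn_values) >= threshold)
}
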