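#' Sneddon indentation force for a conical/pyramidal tip
#'
#' Forward contact-mechanics model: the force required to indent an elastic
#' half-space to depth \eqn{\delta} with a sharp conical indenter of
#' half-angle \eqn{\alpha},
#' \deqn{F = \frac{2}{\pi} \tan(\alpha) \frac{E}{1 - \nu^2} \delta^2,}
#' in nanonewtons when \eqn{E} is in kPa and \eqn{\delta} in micrometres
#' (kPa um^2 = nN, so no conversion factor appears).
#'
#' @param modulus Young's modulus E in kPa, positive.
#' @param delta Indentation depth(s) in micrometres, non-negative.
#' @param params \code{\link{cantilever_params}} supplying the tip
#'   half-angle and Poisson's ratio.
#' @param form Prefactor convention: \code{"tan"} (default) for the
#'   standard conical form \eqn{(2/\pi)\tan\alpha}; \code{"inv-tan"} for
#'   the alternative reading \eqn{2/(\pi\tan\alpha)}.
#' @return Force(s) in nN.
#' @examples
#' p <- cantilever_params()
#' sneddon_force(1, 1, p)   # ~0.2758 nN at E = 1 kPa, delta = 1 um
#' @export
sneddon_force <- function(modulus, delta, params = cantilever_params(),
                          form = c("tan", "inv-tan")) {
  if (!is.numeric(modulus) || length(modulus) != 1L || modulus <= 0) {
    stop("modulus must be a single positive value (kPa)")
  }
  if (any(delta < 0)) stop("delta must be non-negative")
  sneddon_coef(modulus, params, form) * delta^2
}

#' Fit the Sneddon model to an indentation curve
#'
#' Estimates Young's modulus by least squares of force against indentation
#' squared, through the origin (contact-point removal already pins
#' \eqn{F = 0} at \eqn{\delta = 0}). The slope has the closed form
#' \eqn{\hat{c} = \sum F_i \delta_i^2 / \sum \delta_i^4}, and
#' \eqn{\hat{E} = \hat{c} \cdot (\pi/2) \cot(\alpha) (1 - \nu^2)} for the
#' standard prefactor convention.
#'
#' This is the package's central model fit; the returned object supports
#' \code{print}, \code{summary}, \code{coef}, \code{predict}, \code{plot},
#' \code{residuals} and \code{simulate} methods.
#'
#' @param curve An \code{\link{indentation_curve}}.
#' @param params \code{\link{cantilever_params}}.
#' @param delta_max Indentation depths above this (um) are excluded from
#'   the fit. Default 1.5.
#' @param form Prefactor convention, see \code{\link{sneddon_force}}.
#' @return An object of class \code{sneddon_fit} with components
#'   \code{modulus} (kPa), \code{r_squared}, \code{n_points},
#'   \code{delta_range} (um), \code{fitted}, \code{residuals}, the data
#'   used, \code{params} and \code{meta}.
#' @examples
#' p <- cantilever_params()
#' delta <- seq(0, 1.5, length.out = 50)
#' crv <- indentation_curve(delta, sneddon_force(5, delta, p), 0, 0)
#' fit <- fit_modulus(crv, p)
#' coef(fit)   # 5 kPa
#' @export
fit_modulus <- function(curve, params = cantilever_params(), delta_max = 1.5,
                        form = c("tan", "inv-tan")) {
  stopifnot(inherits(curve, "indentation_curve"),
            inherits(params, "cantilever_params"))
  form <- match.arg(form)
  keep <- curve$delta <= delta_max
  delta <- curve$delta[keep]
  force <- curve$force[keep]
  if (length(delta) < 8L) {
    stop("need at least 8 points with delta <= delta_max, got ", length(delta))
  }
  if (diff(range(delta)) < 1e-12) {
    stop("degenerate indentation range: all delta equal")
  }
  slope <- sum(force * delta^2) / sum(delta^4)
  if (!is.finite(slope) || slope <= 0) {
    stop("non-physical modulus: fitted slope is not positive")
  }
  unit_coef <- sneddon_coef(1, params, form)   # prefactor at E = 1 kPa
  modulus <- slope / unit_coef
  fitted <- slope * delta^2
  resid <- force - fitted
  ss_tot <- sum((force - mean(force))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - sum(resid^2) / ss_tot)) else 1
  structure(
    list(modulus = modulus, r_squared = r2, n_points = length(delta),
         delta_range = range(delta), delta = delta, force = force,
         fitted = fitted, residuals = resid, params = params, form = form,
         meta = curve$meta),
    class = "sneddon_fit"
  )
}

#' @export
print.sneddon_fit <- function(x, ...) {
  cat("Sneddon indentation fit\n")
  cat(sprintf("  Young's modulus : %.4g kPa\n", x$modulus))
  cat(sprintf("  R-squared       : %.4f\n", x$r_squared))
  cat(sprintf("  points          : %d (delta %.3g-%.3g um)\n",
              x$n_points, x$delta_range[1], x$delta_range[2]))
  invisible(x)
}

#' @export
summary.sneddon_fit <- function(object, ...) {
  out <- list(
    modulus = object$modulus,
    r_squared = object$r_squared,
    n_points = object$n_points,
    delta_range = object$delta_range,
    max_force = max(object$force),
    rmse = sqrt(mean(object$residuals^2)),
    params = object$params,
    meta = object$meta
  )
  class(out) <- "summary.sneddon_fit"
  out
}

#' @export
print.summary.sneddon_fit <- function(x, ...) {
  cat("Sneddon indentation fit\n")
  if (!is.null(x$meta)) {
    cat(sprintf("  cell %s (%s, %s, %s), curve %d/3\n", x$meta$cell_id,
                x$meta$cell_type, x$meta$condition, x$meta$age,
                x$meta$curve_index))
  }
  cat(sprintf("  Young's modulus : %.4g kPa\n", x$modulus))
  cat(sprintf("  R-squared       : %.4f   RMSE: %.3g nN\n",
              x$r_squared, x$rmse))
  cat(sprintf("  %d points, delta %.3g-%.3g um, F max %.3g nN\n",
              x$n_points, x$delta_range[1], x$delta_range[2], x$max_force))
  invisible(x)
}

#' @export
coef.sneddon_fit <- function(object, ...) {
  c(modulus_kPa = object$modulus)
}

#' @export
residuals.sneddon_fit <- function(object, ...) object$residuals

#' Predict force at given indentation depths
#'
#' @param object A \code{sneddon_fit}.
#' @param newdata Optional numeric vector of indentation depths (um);
#'   defaults to the depths used in the fit.
#' @param ... Ignored.
#' @return Predicted forces in nN.
#' @export
predict.sneddon_fit <- function(object, newdata = NULL, ...) {
  delta <- if (is.null(newdata)) object$delta else newdata
  if (any(delta < 0)) stop("delta must be non-negative")
  sneddon_force(object$modulus, delta, object$params, form = object$form)
}

#' Plot an indentation fit
#'
#' Force-indentation data with the fitted Sneddon curve overlaid.
#'
#' @param x A \code{sneddon_fit}.
#' @param ... Passed to \code{plot.default}.
#' @export
plot.sneddon_fit <- function(x, ...) {
  graphics::plot(x$delta, x$force, xlab = expression(delta ~ (mu * m)),
                 ylab = "F (nN)", pch = 16, cex = 0.5,
                 main = sprintf("Sneddon fit: E = %.3g kPa, R2 = %.3f",
                                x$modulus, x$r_squared), ...)
  dd <- seq(0, max(x$delta), length.out = 200)
  graphics::lines(dd, predict(x, dd), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Simulate indentation curves from a fitted model
#'
#' Draws new indentation curves at the fitted modulus with Gaussian force
#' noise matched to the residual RMSE of the fit.
#'
#' @param object A \code{sneddon_fit}.
#' @param nsim Number of curves to simulate.
#' @param seed Optional RNG seed.
#' @param ... Ignored.
#' @return A list of \code{\link{indentation_curve}} objects.
#' @export
simulate.sneddon_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  rmse <- sqrt(mean(object$residuals^2))
  lapply(seq_len(nsim), function(i) {
    f <- predict(object) + stats::rnorm(object$n_points, 0, rmse)
    indentation_curve(object$delta, f, 0, 0, meta = object$meta)
  })
}
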