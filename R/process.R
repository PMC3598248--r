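#' Remove the pre-contact baseline from an approach curve
#'
#' Fits a straight line by least squares to the first \code{pre_fraction} of
#' samples (assumed pre-contact) and subtracts it from the whole deflection
#' trace, so that the pre-contact deflection has mean approximately zero and
#' no linear drift. This removes the optical-lever offset and slope that are
#' always present in raw deflection signals.
#'
#' @param curve A \code{\link{raw_force_curve}}.
#' @param pre_fraction Fraction of samples (from the start of the ramp)
#'   assumed to be pre-contact. Default 0.2. At least 4 samples must fall in
#'   this window.
#' @return The detrended \code{raw_force_curve}.
#' @export
detrend_baseline <- function(curve, pre_fraction = 0.2) {
  stopifnot(inherits(curve, "raw_force_curve"))
  n <- length(curve$z)
  n_pre <- floor(pre_fraction * n)
  if (n_pre < 4L) {
    stop("too few pre-contact samples for baseline fit: pre_fraction * n = ",
         n_pre, " < 4")
  }
  detrend_first_n(curve, n_pre)
}

# baseline fit over the first n_pre samples
detrend_first_n <- function(curve, n_pre) {
  zi <- curve$z[seq_len(n_pre)]
  di <- curve$deflection[seq_len(n_pre)]
  fit <- stats::lm.fit(cbind(1, zi), di)
  base <- fit$coefficients[1] + fit$coefficients[2] * curve$z
  raw_force_curve(curve$z, curve$deflection - base, curve$meta)
}

# Sneddon prefactor C such that F = C * delta^2 (nN with kPa, um units).
# form = "tan": C = (2/pi) tan(alpha) E / (1 - nu^2)  (standard conical form)
# form = "inv-tan": C = 2 / (pi tan(alpha)) * E / (1 - nu^2)
sneddon_coef <- function(modulus, params, form = c("tan", "inv-tan")) {
  form <- match.arg(form)
  a <- params$tip_half_angle * pi / 180
  geom <- if (form == "tan") (2 / pi) * tan(a) else 2 / (pi * tan(a))
  geom * modulus / (1 - params$poisson_ratio^2)
}

# Exact solution of the implicit per-sample deflection equation
#   K * d = C * (s - d)^2,  0 <= d <= s,
# where s = z - z0 is piezo travel past contact and K the spring constant in
# nN/um. Quadratic in d; the stable (small) root is
#   d = 2 C s^2 / (2 C s + K + sqrt(K^2 + 4 C s K)).
bending_deflection <- function(s, coef, k_nN_um) {
  s <- pmax(s, 0)
  2 * coef * s^2 / (2 * coef * s + k_nN_um + sqrt(k_nN_um^2 + 4 * coef * s * k_nN_um))
}

# Piecewise SSE of (baseline before z0) + (baseline + Sneddon bending after
# z0) with the modulus profiled out by the closed-form origin fit. The
# baseline is either a flat level (for detrended curves) or a least-squares
# line (for raw curves, where the optical-lever slope is still present and
# continues underneath the contact response). Returns Inf for candidates
# with no usable post-contact response.
contact_sse <- function(z, d, z0, k_nN_um, baseline = "flat") {
  pre <- z <= z0
  n_pre <- sum(pre)
  if (baseline == "line" && n_pre >= 4L) {
    cf <- stats::lm.fit(cbind(1, z[pre]), d[pre])$coefficients
  } else {
    cf <- c(if (n_pre > 0) mean(d[pre]) else 0, 0)
  }
  base <- cf[1] + cf[2] * z
  d0 <- cf[1] + cf[2] * z0
  s <- z[!pre] - z0
  db <- d[!pre] - base[!pre]
  delta <- s - db
  ok <- delta > 0
  if (sum(ok) < 4L) return(list(sse = Inf, coef = NA_real_, d0 = d0))
  f <- k_nN_um * db[ok]
  slope <- sum(f * delta[ok]^2) / sum(delta[ok]^4)
  if (!is.finite(slope) || slope <= 0) {
    return(list(sse = Inf, coef = NA_real_, d0 = d0))
  }
  pred <- bending_deflection(s, slope, k_nN_um)
  sse <- sum((d[pre] - base[pre])^2) + sum((db - pred)^2)
  list(sse = sse, coef = slope, d0 = d0)
}

#' Locate the tip--sample contact point
#'
#' Scans candidate contact positions along the ramp, modelling the curve as
#' a flat baseline before contact and a Sneddon-form response (modulus free,
#' fitted in closed form) after it, and picks the position minimizing the
#' total squared error. The search runs on a coarse-to-fine grid of sample
#' indices and finishes with a continuous 1-D refinement of z0 between
#' neighbouring samples, so the estimate is not locked to the sampling grid.
#' Ties on the index grid resolve toward the smaller index.
#'
#' The curve should be baseline-detrended first
#' (\code{\link{detrend_baseline}}).
#'
#' @param curve A detrended \code{\link{raw_force_curve}}.
#' @param params \code{\link{cantilever_params}}.
#' @param min_post_contact_samples Minimum samples that must remain after
#'   the contact point (default 8).
#' @param contact_improvement_factor The piecewise model must reduce the SSE
#'   of the best all-baseline model by at least this factor, otherwise a
#'   "no contact detected" error is raised. Default 2.
#' @param baseline Pre-contact baseline model: \code{"flat"} (default, for
#'   detrended curves) or \code{"line"} (free slope, for raw curves whose
#'   optical-lever ramp has not been removed).
#' @return An object of class \code{contact_estimate} with fields
#'   \code{contact_index} (last pre-contact sample, 0 if contact precedes
#'   the ramp start), \code{contact_z}, \code{contact_deflection} and
#'   \code{fit_sse}.
#' @export
find_contact_point <- function(curve, params,
                               min_post_contact_samples = 8L,
                               contact_improvement_factor = 2,
                               baseline = c("flat", "line")) {
  stopifnot(inherits(curve, "raw_force_curve"),
            inherits(params, "cantilever_params"))
  baseline <- match.arg(baseline)
  z <- curve$z
  d <- curve$deflection
  n <- length(z)
  k <- spring_nN_per_um(params)
  i_max <- n - min_post_contact_samples
  if (i_max < 1L) stop("curve too short for contact detection")

  # all-baseline reference model over the whole trace
  if (baseline == "line") {
    cf0 <- stats::lm.fit(cbind(1, z), d)$coefficients
    sse_null <- sum((d - cf0[1] - cf0[2] * z)^2)
  } else {
    sse_null <- sum((d - mean(d))^2)
  }

  # coarse pass over sample indices (candidate z0 just below z[i]),
  # index 0 = contact at or before the first sample
  stride <- max(1L, i_max %/% 128L)
  cand <- unique(c(0L, seq.int(1L, i_max, by = stride), i_max))
  eps <- min(diff(z)) * 1e-6
  sse_at <- function(i) {
    z0 <- if (i == 0L) z[1] - eps else z[i]
    contact_sse(z, d, z0, k, baseline)$sse
  }
  sse_coarse <- vapply(cand, sse_at, numeric(1))
  best <- cand[which.min(sse_coarse)]

  # fine pass around the coarse winner
  if (stride > 1L) {
    lo <- max(0L, best - stride)
    hi <- min(i_max, best + stride)
    cand2 <- seq.int(lo, hi)
    sse_fine <- vapply(cand2, sse_at, numeric(1))
    best <- cand2[which.min(sse_fine)]
    sse_best <- min(sse_fine)
  } else {
    sse_best <- min(sse_coarse)
  }

  if (!is.finite(sse_best) ||
      (sse_null > 0 && sse_null / max(sse_best, .Machine$double.xmin) <
         contact_improvement_factor && sse_best > n * 1e-24)) {
    stop("no contact detected: piecewise model does not improve over baseline")
  }

  # continuous refinement of z0 between neighbouring samples
  lo_z <- z[max(best - 1L, 1L)]
  hi_z <- z[min(best + 2L, n)]
  if (best == 0L) lo_z <- z[1] - eps
  opt <- stats::optimize(function(z0) contact_sse(z, d, z0, k, baseline)$sse,
                         interval = c(lo_z, hi_z), tol = 1e-10)
  z0 <- opt$minimum
  res <- contact_sse(z, d, z0, k, baseline)
  # keep the grid solution if refinement did not help (flat/noisy objective)
  if (!is.finite(res$sse) || res$sse > sse_best) {
    z0 <- if (best == 0L) z[1] - eps else z[best]
    res <- contact_sse(z, d, z0, k, baseline)
  }
  structure(
    list(contact_index = sum(z <= z0),
         contact_z = z0,
         contact_deflection = res$d0,
         fit_sse = res$sse),
    class = "contact_estimate"
  )
}

#' @export
print.contact_estimate <- function(x, ...) {
  cat(sprintf(
    "Contact estimate: z0 = %.5g um (sample %d), d0 = %.3g um, SSE = %.3g\n",
    x$contact_z, x$contact_index, x$contact_deflection, x$fit_sse))
  invisible(x)
}

#' Convert a raw curve to an indentation-force curve
#'
#' For samples at and after the contact point, the applied force is
#' \eqn{F = 1000 k (d - d_0)} nN and the tip--sample indentation is
#' \eqn{\delta = (z - z_0) - (d - d_0)} um (piezo travel past contact minus
#' the cantilever's own bending -- the standard soft-sample correction).
#' Samples with negative indentation are dropped and the curve is truncated
#' at \code{delta_max}.
#'
#' @param curve A detrended \code{\link{raw_force_curve}}.
#' @param contact A \code{contact_estimate} from
#'   \code{\link{find_contact_point}}.
#' @param params \code{\link{cantilever_params}}.
#' @param delta_max Maximum indentation retained, um. Default 1.5, the ramp
#'   depth used for cochlear explants.
#' @param min_points Minimum surviving samples (default 8); fewer is an
#'   error.
#' @return An \code{\link{indentation_curve}}.
#' @export
to_indentation <- function(curve, contact, params, delta_max = 1.5,
                           min_points = 8L) {
  stopifnot(inherits(curve, "raw_force_curve"),
            inherits(contact, "contact_estimate"),
            inherits(params, "cantilever_params"))
  z0 <- contact$contact_z
  d0 <- contact$contact_deflection
  if (z0 > max(curve$z)) stop("contact point lies beyond the ramp")
  post <- curve$z >= z0
  s <- curve$z[post] - z0
  db <- curve$deflection[post] - d0
  delta <- s - db
  force <- spring_nN_per_um(params) * db
  keep <- delta >= 0 & delta <= delta_max
  if (sum(keep) < min_points) {
    stop("too few post-contact samples with usable indentation: ",
         sum(keep), " < ", min_points)
  }
  if (max(delta[keep]) <= 1e-9) {
    stop("no indentation range: sample behaves as a rigid surface ",
         "(deflection tracks piezo travel)")
  }
  ord <- order(delta[keep])
  indentation_curve(delta[keep][ord], force[keep][ord],
                    contact_z = z0, contact_deflection = d0,
                    meta = curve$meta)
}

#' Process a raw curve end to end
#'
#' Convenience wrapper: locate the contact point on the raw curve (with the
#' baseline slope free, so early contact cannot contaminate the detrend),
#' detrend using only pre-contact samples, re-detect the contact on the
#' detrended curve, and convert to an indentation curve.
#'
#' @inheritParams find_contact_point
#' @inheritParams to_indentation
#' @param pre_fraction Passed to \code{\link{detrend_baseline}} for the
#'   first pass.
#' @return An \code{\link{indentation_curve}}.
#' @export
process_curve <- function(curve, params, pre_fraction = 0.2, delta_max = 1.5,
                          min_post_contact_samples = 8L,
                          contact_improvement_factor = 2) {
  # first pass: locate contact on the raw curve with a free-slope baseline,
  # so an early contact inside the nominal pre_fraction window cannot
  # contaminate the detrend
  ct0 <- find_contact_point(curve, params,
                            min_post_contact_samples = min_post_contact_samples,
                            contact_improvement_factor = contact_improvement_factor,
                            baseline = "line")
  n_pre <- sum(curve$z < ct0$contact_z - 2 * mean(diff(curve$z)))
  det <- if (n_pre >= 4L) detrend_first_n(curve, n_pre) else
    detrend_baseline(curve, pre_fraction = pre_fraction)
  ct <- find_contact_point(det, params,
                           min_post_contact_samples = min_post_contact_samples,
                           contact_improvement_factor = contact_improvement_factor)
  to_indentation(det, ct, params, delta_max = delta_max,
                 min_points = min_post_contact_samples)
}
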