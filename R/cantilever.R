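#' Cantilever and tip parameters
#'
#' Bundles the probe calibration constants needed to convert cantilever
#' deflection to force and to evaluate the Sneddon contact model: the
#' cantilever spring constant, the tip half-angle of the pyramidal/conical
#' indenter, and the Poisson's ratio assumed for the sample.
#'
#' Internal unit conventions used throughout the package: lengths and
#' deflections in micrometres, forces in nanonewtons, moduli in kilopascals,
#' spring constants in N/m (1 N/m = 1000 nN/um). With these, kPa * um^2 = nN,
#' so the Sneddon expression carries no hidden conversion factor.
#'
#' @param spring_constant Cantilever stiffness in N/m. Default 0.03, the
#'   nominal value for soft gold-coated silicon-nitride probes.
#' @param tip_half_angle Tip (face) half-angle in degrees, strictly between
#'   0 and 90. Default 18.
#' @param poisson_ratio Sample Poisson's ratio, in [0, 0.5]. Default 0.5
#'   (incompressible soft tissue).
#' @return An object of class \code{cantilever_params}.
#' @examples
#' cantilever_params()
#' cantilever_params(spring_constant = 0.06, tip_half_angle = 20)
#' @export
cantilever_params <- function(spring_constant = 0.03,
                              tip_half_angle = 18,
                              poisson_ratio = 0.5) {
  if (!is.numeric(spring_constant) || length(spring_constant) != 1L ||
      !is.finite(spring_constant) || spring_constant <= 0) {
    stop("spring_constant must be a single positive number (N/m)")
  }
  if (!is.numeric(tip_half_angle) || length(tip_half_angle) != 1L ||
      !is.finite(tip_half_angle) ||
      tip_half_angle <= 0 || tip_half_angle >= 90) {
    stop("tip_half_angle must lie strictly between 0 and 90 degrees")
  }
  if (!is.numeric(poisson_ratio) || length(poisson_ratio) != 1L ||
      !is.finite(poisson_ratio) ||
      poisson_ratio < 0 || poisson_ratio > 0.5 + 1e-12) {
    stop("poisson_ratio must lie in [0, 0.5]")
  }
  structure(
    list(spring_constant = spring_constant,
         tip_half_angle = tip_half_angle,
         poisson_ratio = poisson_ratio),
    class = "cantilever_params"
  )
}

#' @export
print.cantilever_params <- function(x, ...) {
  cat("Cantilever parameters\n")
  cat(sprintf("  spring constant k : %.4g N/m (%.4g nN/um)\n",
              x$spring_constant, 1000 * x$spring_constant))
  cat(sprintf("  tip half-angle    : %.4g deg\n", x$tip_half_angle))
  cat(sprintf("  Poisson ratio     : %.4g\n", x$poisson_ratio))
  invisible(x)
}

# spring constant in nN/um
spring_nN_per_um <- function(params) 1000 * params$spring_constant
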