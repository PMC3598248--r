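#' Curve metadata
#'
#' Acquisition metadata attached to a single AFM approach curve: which cell
#' it came from, the cell type, the experimental condition, developmental
#' stage, cochlear region, and the index of the curve within the triplet
#' acquired per cell.
#'
#' @param cell_id Character identifier for the probed cell.
#' @param cell_type One of "OHC", "PC", "IHC", "other" (outer hair cell,
#'   pillar cell, inner hair cell).
#' @param condition One of "control", "hypothyroid", "T3", "rT3",
#'   "latrunculinA", "vehicle".
#' @param age Developmental stage label, e.g. "E16", "P0", "P3", "P5".
#' @param region Cochlear region, "base" or "apex".
#' @param curve_index Integer 1--3: three force-distance curves are taken at
#'   the centre of each identified cell.
#' @return An object of class \code{curve_meta}.
#' @export
curve_meta <- function(cell_id, cell_type = "OHC", condition = "control",
                       age = "P0", region = "base", curve_index = 1L) {
  cell_types <- c("OHC", "PC", "IHC", "other")
  conditions <- c("control", "hypothyroid", "T3", "rT3",
                  "latrunculinA", "vehicle")
  regions <- c("base", "apex")
  if (missing(cell_id) || !is.character(cell_id) || length(cell_id) != 1L ||
      is.na(cell_id) || !nzchar(cell_id)) {
    stop("cell_id must be a non-empty string")
  }
  if (!cell_type %in% cell_types) {
    stop("cell_type must be one of: ", paste(cell_types, collapse = ", "))
  }
  if (!condition %in% conditions) {
    stop("condition must be one of: ", paste(conditions, collapse = ", "))
  }
  if (!region %in% regions) stop("region must be 'base' or 'apex'")
  ci <- suppressWarnings(as.integer(curve_index))
  if (is.na(ci) || length(curve_index) != 1L || !ci %in% 1:3) {
    stop("curve_index must be 1, 2 or 3 (three curves per cell)")
  }
  structure(
    list(cell_id = cell_id, cell_type = cell_type, condition = condition,
         age = age, region = region, curve_index = ci),
    class = "curve_meta"
  )
}

#' Raw AFM approach curve
#'
#' A single approach ramp: piezo z-positions (increasing toward the sample)
#' and the matching cantilever deflections, with acquisition metadata. This
#' is the raw object produced by the instrument (or the simulator) before
#' baseline correction and contact-point detection.
#'
#' @param z Numeric vector of piezo positions in micrometres, strictly
#'   increasing, length at least 16.
#' @param deflection Numeric vector of cantilever deflections in
#'   micrometres, same length as \code{z}.
#' @param meta A \code{\link{curve_meta}} object.
#' @return An object of class \code{raw_force_curve}.
#' @seealso \code{\link{read_curve}}, \code{\link{detrend_baseline}},
#'   \code{\link{simulate_raw_curve}}
#' @export
raw_force_curve <- function(z, deflection, meta) {
  if (!is.numeric(z) || !is.numeric(deflection)) {
    stop("z and deflection must be numeric vectors")
  }
  if (length(z) != length(deflection)) {
    stop("length mismatch: z has ", length(z), " samples but deflection has ",
         length(deflection))
  }
  if (length(z) < 16L) {
    stop("curve too short: need at least 16 samples, got ", length(z))
  }
  if (anyNA(z) || anyNA(deflection)) stop("z and deflection must be finite")
  if (any(diff(z) <= 0)) {
    stop("z must be strictly increasing (monotonic approach ramp)")
  }
  if (!inherits(meta, "curve_meta")) {
    stop("meta must be a curve_meta object")
  }
  structure(
    list(z = as.numeric(z), deflection = as.numeric(deflection), meta = meta),
    class = "raw_force_curve"
  )
}

#' @export
print.raw_force_curve <- function(x, ...) {
  cat(sprintf("Raw AFM approach curve: %d samples, z in [%.4g, %.4g] um\n",
              length(x$z), min(x$z), max(x$z)))
  m <- x$meta
  cat(sprintf("  cell %s (%s, %s, %s, %s), curve %d/3\n",
              m$cell_id, m$cell_type, m$condition, m$age, m$region,
              m$curve_index))
  invisible(x)
}

#' Indentation-force curve
#'
#' The post-contact portion of an approach curve expressed as tip--sample
#' indentation depth against applied force; the domain of the Sneddon fit.
#' Produced by \code{\link{to_indentation}} from a raw curve and a contact
#' estimate.
#'
#' @param delta Indentation depths in micrometres, non-negative.
#' @param force Applied forces in nanonewtons, same length as \code{delta}.
#' @param contact_z Piezo position of the contact point, micrometres.
#' @param contact_deflection Deflection at the contact point, micrometres.
#' @param meta Optional \code{curve_meta} carried over from the raw curve.
#' @return An object of class \code{indentation_curve}.
#' @export
indentation_curve <- function(delta, force, contact_z, contact_deflection,
                              meta = NULL) {
  if (length(delta) != length(force)) {
    stop("delta and force must have the same length")
  }
  if (any(delta < -1e-12)) stop("delta must be non-negative")
  structure(
    list(delta = as.numeric(delta), force = as.numeric(force),
         contact_z = contact_z, contact_deflection = contact_deflection,
         meta = meta),
    class = "indentation_curve"
  )
}

#' @export
print.indentation_curve <- function(x, ...) {
  cat(sprintf(
    "Indentation curve: %d samples, delta in [%.4g, %.4g] um, F max %.4g nN\n",
    length(x$delta), min(x$delta), max(x$delta), max(x$force)))
  cat(sprintf("  contact at z0 = %.4g um\n", x$contact_z))
  invisible(x)
}
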