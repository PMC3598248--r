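# deterministic child-seed derivation: polynomial rolling hash mod a prime
# below 2^31, so datasets are reproducible regardless of generation order
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 17
  for (p in parts) h <- (h * 31 + (as.numeric(p) %% 2147483629)) %% 2147483629
  as.integer(h)
}

#' Simulate one raw AFM approach curve
#'
#' Synthesizes the deflection trace an AFM records while ramping the piezo
#' toward an elastic sample of known Young's modulus. Pre-contact, the
#' deflection follows a linear optical baseline; past the contact offset,
#' the cantilever bending \eqn{d_b} satisfies the implicit force balance
#' \deqn{1000\,k\,d_b = F_{Sneddon}(E,\ (z - z_0) - d_b),}
#' i.e. the indentation fed to the contact model is piezo travel minus the
#' cantilever's own bending (solved exactly per sample). Gaussian noise of
#' standard deviation \code{noise_sd} is then added to the deflection.
#'
#' @param true_modulus Ground-truth Young's modulus, kPa.
#' @param params \code{\link{cantilever_params}}.
#' @param contact_offset Piezo position of first contact, um; must lie
#'   inside the ramp.
#' @param baseline_slope Linear baseline slope (deflection per z,
#'   dimensionless). Default 0.
#' @param noise_sd Deflection noise standard deviation, um. Default 0.
#' @param n_samples Samples per ramp, at least 64. Default 1024.
#' @param ramp Ramp extent, um. Default 3 (the ramp size used for cochlear
#'   explants).
#' @param seed Integer RNG seed for the noise.
#' @param meta Optional \code{\link{curve_meta}}; a generic one is attached
#'   if omitted.
#' @return A list with \code{curve} (a \code{\link{raw_force_curve}}) and
#'   \code{manifest} (ground truth: true_modulus, contact_offset,
#'   baseline_slope, noise_sd, seed).
#' @export
simulate_raw_curve <- function(true_modulus, params = cantilever_params(),
                               contact_offset = 0.5, baseline_slope = 0,
                               noise_sd = 0, n_samples = 1024L, ramp = 3,
                               seed = 1L, meta = NULL) {
  if (true_modulus <= 0) stop("true_modulus must be positive (kPa)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (n_samples < 64L) stop("need at least 64 samples per ramp")
  if (contact_offset >= ramp || contact_offset < 0) {
    stop("contact_offset must lie inside the ramp [0, ", ramp, ")")
  }
  z <- seq(0, ramp, length.out = n_samples)
  coef <- sneddon_coef(true_modulus, params)
  k <- spring_nN_per_um(params)
  bend <- bending_deflection(z - contact_offset, coef, k)
  d <- baseline_slope * z + bend
  if (noise_sd > 0) {
    set.seed(seed)
    d <- d + stats::rnorm(n_samples, 0, noise_sd)
  }
  if (is.null(meta)) meta <- curve_meta("sim_cell")
  list(
    curve = raw_force_curve(z, d, meta),
    manifest = list(true_modulus = true_modulus,
                    contact_offset = contact_offset,
                    baseline_slope = baseline_slope,
                    noise_sd = noise_sd, seed = seed)
  )
}

#' Describe a synthetic AFM experiment
#'
#' Holds the design of a multi-group AFM study: per-group ground-truth
#' moduli, group sizes, and the acquisition settings shared by all curves.
#' Defaults mirror the acquisition used for cochlear explants: 10 cells per
#' group, 3 curves per cell, 3-um ramps.
#'
#' @param groups Data frame with columns \code{condition},
#'   \code{cell_type}, \code{age}, \code{true_modulus} (kPa) and optionally
#'   \code{sem} (kPa): when \code{cell_sd} is NULL, the between-cell sd for
#'   a group is taken as \code{sem * sqrt(n_cells)} so the emulated group
#'   reproduces a reported mean +/- s.e.m.
#' @param n_cells Cells per group. Default 10.
#' @param curves_per_cell Curves per cell. Default 3.
#' @param cell_sd Between-cell modulus sd in kPa (scalar), or NULL to
#'   derive it from the groups' \code{sem} column (0 when absent).
#' @param ramp Ramp extent in um. Default 3.
#' @param n_samples Samples per ramp. Default 1024.
#' @param noise_sd Deflection noise sd, um. Default 0.002 (2 nm, a typical
#'   optical-lever noise floor).
#' @param baseline_slope Baseline slope. Default 0.005.
#' @param contact_offset_range Range (um) from which each curve's contact
#'   offset is drawn uniformly. Default c(0.4, 0.6).
#' @param seed Master seed; all per-curve seeds derive from it.
#' @return An object of class \code{experiment_design}.
#' @export
experiment_design <- function(groups, n_cells = 10L, curves_per_cell = 3L,
                              cell_sd = NULL, ramp = 3, n_samples = 1024L,
                              noise_sd = 0.002, baseline_slope = 0.005,
                              contact_offset_range = c(0.4, 0.6),
                              seed = 1L) {
  need <- c("condition", "cell_type", "age", "true_modulus")
  if (!all(need %in% names(groups))) {
    stop("groups must have columns: ", paste(need, collapse = ", "))
  }
  if (any(groups$true_modulus <= 0)) stop("true_modulus must be positive")
  if (n_cells < 1L || curves_per_cell < 1L || curves_per_cell > 3L) {
    stop("need n_cells >= 1 and curves_per_cell in 1..3")
  }
  if (is.null(cell_sd)) {
    cell_sd <- if ("sem" %in% names(groups)) {
      groups$sem * sqrt(n_cells)
    } else rep(0, nrow(groups))
  } else {
    cell_sd <- rep(cell_sd, length.out = nrow(groups))
  }
  if (any(cell_sd < 0)) stop("cell_sd must be non-negative")
  structure(
    list(groups = as.data.frame(groups), n_cells = as.integer(n_cells),
         curves_per_cell = as.integer(curves_per_cell), cell_sd = cell_sd,
         ramp = ramp, n_samples = as.integer(n_samples),
         noise_sd = noise_sd, baseline_slope = baseline_slope,
         contact_offset_range = contact_offset_range,
         seed = as.integer(seed)),
    class = "experiment_design"
  )
}

#' Simulate a full AFM experiment
#'
#' Draws per-cell ground-truth moduli Normal(true_modulus, cell_sd)
#' truncated at zero, synthesizes every approach curve with
#' \code{\link{simulate_raw_curve}}, and (optionally) writes the dataset
#' directory with a ground-truth manifest. Per-curve seeds derive
#' deterministically from the design seed, so regeneration is bit-exact and
#' independent of generation order.
#'
#' @param design An \code{\link{experiment_design}}.
#' @param params \code{\link{cantilever_params}}.
#' @param dir Optional output directory; when given, the dataset (curve
#'   CSVs, sidecars, \code{dataset.json} with manifest) is written there.
#' @return A list with \code{curves} (list of raw curves) and
#'   \code{manifest} (one record per curve: ids, group truth, cell truth,
#'   per-curve generation parameters).
#' @export
simulate_experiment <- function(design, params = cantilever_params(),
                                dir = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  curves <- list()
  manifest <- list()
  for (g in seq_len(nrow(design$groups))) {
    grp <- design$groups[g, ]
    sd_g <- design$cell_sd[g]
    for (ci in seq_len(design$n_cells)) {
      cell_seed <- derive_seed(design$seed, g, ci)
      set.seed(cell_seed)
      cell_E <- if (sd_g > 0) {
        repeat {
          e <- stats::rnorm(1, grp$true_modulus, sd_g)
          if (e > 0) break
        }
        e
      } else grp$true_modulus
      cell_id <- sprintf("g%d_%s_%s_cell%02d", g, grp$condition,
                         grp$cell_type, ci)
      for (k in seq_len(design$curves_per_cell)) {
        curve_seed <- derive_seed(design$seed, g, ci, k)
        set.seed(curve_seed)
        offset <- stats::runif(1, design$contact_offset_range[1],
                               design$contact_offset_range[2])
        meta <- curve_meta(cell_id = cell_id, cell_type = grp$cell_type,
                          condition = grp$condition, age = grp$age,
                          curve_index = k)
        sim <- simulate_raw_curve(
          true_modulus = cell_E, params = params, contact_offset = offset,
          baseline_slope = design$baseline_slope,
          noise_sd = design$noise_sd, n_samples = design$n_samples,
          ramp = design$ramp, seed = derive_seed(curve_seed, 7L),
          meta = meta)
        curves[[length(curves) + 1L]] <- sim$curve
        manifest[[length(manifest) + 1L]] <- c(
          list(cell_id = cell_id, condition = grp$condition,
               cell_type = grp$cell_type, age = grp$age, curve_index = k,
               group_modulus = grp$true_modulus, cell_modulus = cell_E),
          sim$manifest["contact_offset"],
          list(baseline_slope = design$baseline_slope,
               noise_sd = design$noise_sd, seed = sim$manifest$seed))
      }
    }
  }
  if (!is.null(dir)) write_dataset(curves, dir, manifest = manifest)
  list(curves = curves, manifest = manifest)
}

#' Simulate a gel-lane densitometry profile
#'
#' Sum of Gaussian bands with specified analytic areas on a linear
#' background, plus optional Gaussian noise. Band windows default to
#' centre +/- 5 sigma and must not overlap.
#'
#' @param band_specs Named list of bands, each \code{c(center, width,
#'   area)}: Gaussian centre and sd in position units, analytic area in
#'   intensity*position units.
#' @param background \code{c(offset, slope)} of the linear background.
#' @param noise_sd Intensity noise sd. Default 0.
#' @param length Number of profile points. Default 600.
#' @param seed RNG seed for the noise.
#' @return A \code{\link{lane_profile}} with one window per band.
#' @export
simulate_gel_profile <- function(band_specs, background = c(0, 0),
                                 noise_sd = 0, length = 600L, seed = 1L) {
  positions <- seq_len(length) - 1
  intensity <- background[1] + background[2] * positions
  windows <- list()
  for (nm in names(band_specs)) {
    b <- band_specs[[nm]]
    center <- b[1]; width <- b[2]; area <- b[3]
    if (width <= 0) stop("band width must be positive")
    if (center < 0 || center > max(positions)) {
      stop("band '", nm, "' centre lies outside the profile")
    }
    intensity <- intensity +
      area / (width * sqrt(2 * pi)) * exp(-(positions - center)^2 / (2 * width^2))
    windows[[nm]] <- c(max(0, center - 5 * width),
                       min(max(positions), center + 5 * width))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    intensity <- intensity + stats::rnorm(length, 0, noise_sd)
  }
  intensity <- pmax(intensity, 0)
  lane_profile(positions, intensity, windows)
}

#' Simulate a piecewise-constant fluorescence image patch
#'
#' Emulates a projected confocal z-stack across adjacent cell regions:
#' each region occupies a vertical stripe of constant mean intensity, with
#' optional Gaussian pixel noise, and is annotated with a centred 2-um
#' line-scan window.
#'
#' @param region_means Named numeric vector: mean intensity per region
#'   (regions are laid out left to right in order).
#' @param pixel_size Pixel edge in um. Default 0.1.
#' @param region_width Width of each region stripe, um. Default 3 (must be
#'   at least 2 to hold a 2-um window).
#' @param height Patch height, um. Default 4.
#' @param noise_sd Pixel noise sd. Default 0.
#' @param seed RNG seed.
#' @return A list with \code{image} (matrix), \code{pixel_size}, and
#'   \code{windows}: one \code{c(x0, x1, y0, y1)} per region, 2 um wide,
#'   centred in the region.
#' @export
simulate_line_scan_patch <- function(region_means, pixel_size = 0.1,
                                     region_width = 3, height = 4,
                                     noise_sd = 0, seed = 1L) {
  if (region_width < 2) {
    stop("region_width must be at least 2 um to hold a 2-um window")
  }
  n_reg <- length(region_means)
  ncol_reg <- round(region_width / pixel_size)
  nrow_px <- round(height / pixel_size)
  img <- matrix(rep(region_means, each = nrow_px * ncol_reg),
                nrow = nrow_px)
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(base::length(img), 0, noise_sd),
                        nrow = nrow_px)
  }
  windows <- lapply(seq_len(n_reg), function(i) {
    xc <- (i - 0.5) * region_width
    c(xc - 1, xc + 1, 0, height)
  })
  names(windows) <- names(region_means)
  list(image = img, pixel_size = pixel_size, windows = windows)
}

#' Simulate a qPCR Ct table
#'
#' The reference gene has Ct = \code{base_ct} in every sample; a target
#' gene with fold change f (relative to control) amplifies earlier by
#' log2(f) cycles: Ct = base_ct - log2(f) + noise.
#'
#' @param fold_changes Data frame with columns \code{gene},
#'   \code{condition}, \code{fold} (positive; control condition rows may be
#'   omitted and default to fold 1).
#' @param conditions Character vector of conditions to generate (first is
#'   the control).
#' @param base_ct Baseline threshold cycle. Default 20.
#' @param n_replicates Biological replicates per condition. Default 3.
#' @param noise_sd Ct noise sd, cycles. Default 0.
#' @param reference_gene Name of the reference gene. Default "GAPDH".
#' @param seed RNG seed.
#' @return A \code{\link{ct_table}}.
#' @export
simulate_ct_table <- function(fold_changes,
                              conditions = c("control", "hypothyroid"),
                              base_ct = 20, n_replicates = 3L, noise_sd = 0,
                              reference_gene = "GAPDH", seed = 1L) {
  if (any(fold_changes$fold <= 0)) stop("fold changes must be positive")
  genes <- unique(fold_changes$gene)
  set.seed(seed)
  rows <- list()
  for (cond in conditions) {
    for (r in seq_len(n_replicates)) {
      sid <- sprintf("%s_rep%d", cond, r)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, condition = cond, gene = reference_gene,
        ct = base_ct, stringsAsFactors = FALSE)
      for (g in genes) {
        hit <- fold_changes$gene == g & fold_changes$condition == cond
        fold <- if (any(hit)) fold_changes$fold[hit][1] else 1
        ct <- base_ct - log2(fold) +
          if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, condition = cond, gene = g, ct = ct,
          stringsAsFactors = FALSE)
      }
    }
  }
  ct_table(do.call(rbind, rows), reference_gene = reference_gene)
}
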