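#' Microtubule density per micron of cell width
#'
#' Electron-micrograph microtubule counts are taken at fixed depths (2, 4
#' and 6 um) below the lumenal surface of pillar cells; dividing by the cell
#' width controls for cell-size differences between conditions.
#'
#' @param counts Named numeric vector of microtubule counts; names are the
#'   depths in um, a subset of \code{c("2", "4", "6")}.
#' @param cell_width Cell width in um, positive.
#' @return Named numeric vector of densities (microtubules per um width) at
#'   the same depths.
#' @examples
#' microtubule_density(c(`2` = 30, `4` = 24, `6` = 18), cell_width = 5)
#' @export
microtubule_density <- function(counts, cell_width) {
  if (!is.numeric(cell_width) || length(cell_width) != 1L ||
      !is.finite(cell_width) || cell_width <= 0) {
    stop("cell_width must be a single positive value (um)")
  }
  if (is.null(names(counts)) ||
      !all(names(counts) %in% c("2", "4", "6"))) {
    stop("counts must be named by depth, with depths among 2, 4, 6 um")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  counts / cell_width
}

#' Cell width-to-length aspect ratio
#'
#' Outer hair cells in hypothyroid cochleae are shorter and wider than
#' controls; the width:length ratio quantifies this shape change.
#'
#' @param width,length Cell width and length in um, both positive.
#' @return The dimensionless ratio width/length.
#' @examples
#' aspect_ratio(5, 20)  # 0.25
#' @export
aspect_ratio <- function(width, length) {
  if (any(!is.finite(width)) || any(!is.finite(length)) ||
      any(width <= 0) || any(length <= 0)) {
    stop("width and length must be positive")
  }
  width / length
}

#' Mean fluorescence intensity in a 2-um line-scan window
#'
#' Averages pixel intensities of a projected z-stack over an axis-aligned
#' rectangular window whose extent along the scan (x) axis is 2 um, placed
#' at the lumenal surface of the cell of interest. Pixels are included when
#' their centre falls inside the window.
#'
#' @param image Numeric matrix of pixel intensities (rows = y, cols = x).
#' @param window Numeric vector \code{c(x0, x1, y0, y1)} in um; the scan
#'   axis is x and \code{x1 - x0} must equal 2 um to within half a pixel.
#' @param pixel_size Pixel edge length in um.
#' @return Mean intensity (arbitrary units) over the window.
#' @export
line_scan_intensity <- function(image, window, pixel_size) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix")
  }
  if (length(window) != 4L) stop("window must be c(x0, x1, y0, y1) in um")
  x0 <- window[1]; x1 <- window[2]; y0 <- window[3]; y1 <- window[4]
  if (abs((x1 - x0) - 2) > pixel_size / 2) {
    stop("window extent along the scan axis must be 2 um (got ",
         signif(x1 - x0, 4), " um)")
  }
  w_um <- ncol(image) * pixel_size
  h_um <- nrow(image) * pixel_size
  if (x0 < 0 || y0 < 0 || x1 > w_um + 1e-9 || y1 > h_um + 1e-9) {
    stop("window extends outside the image (image is ",
         signif(w_um, 4), " x ", signif(h_um, 4), " um)")
  }
  xc <- (seq_len(ncol(image)) - 0.5) * pixel_size
  yc <- (seq_len(nrow(image)) - 0.5) * pixel_size
  cols <- xc >= x0 & xc <= x1
  rows <- yc >= y0 & yc <= y1
  if (!any(cols) || !any(rows)) stop("window contains no pixel centres")
  mean(image[rows, cols])
}

#' Background-subtracted band area of a gel-lane profile
#'
#' Area under the intensity profile over a band window after subtracting a
#' straight-line baseline drawn between the window endpoints (the gel-lane
#' analogue of the ImageJ Gel Analysis baseline), integrated by the
#' trapezoid rule.
#'
#' @param positions,intensity Numeric vectors describing the lane profile.
#' @param window Numeric \code{c(start, end)} in profile position units.
#' @return The background-subtracted band area.
#' @export
band_area <- function(positions, intensity, window) {
  if (length(positions) != length(intensity)) {
    stop("positions and intensity must have the same length")
  }
  if (window[1] >= window[2]) stop("band window must have start < end")
  idx <- which(positions >= window[1] & positions <= window[2])
  if (length(idx) < 3L) stop("band window covers too few profile points")
  x <- positions[idx]
  y <- intensity[idx]
  n <- length(x)
  base <- y[1] + (y[n] - y[1]) * (x - x[1]) / (x[n] - x[1])
  yc <- y - base
  sum(diff(x) * (yc[-1] + yc[-n]) / 2)
}

#' Relative density of a gel band
#'
#' Densitometric ratio of a target band (e.g. phosphorylated Cofilin) to a
#' loading-control band (e.g. beta-actin): each band's area is
#' background-subtracted with a linear baseline between its window
#' endpoints, then the ratio target/reference is returned.
#'
#' @param target,reference Lists with elements \code{positions},
#'   \code{intensity} and \code{window} (as accepted by
#'   \code{\link{band_area}}); typically both refer to the same lane
#'   profile with different windows, see \code{\link{lane_profile}}.
#' @return The relative density (dimensionless, A.U./A.U.).
#' @export
lane_relative_density <- function(target, reference) {
  at <- band_area(target$positions, target$intensity, target$window)
  ar <- band_area(reference$positions, reference$intensity, reference$window)
  if (ar <= 0) stop("non-positive reference band area: cannot normalize")
  if (at <= 0) stop("non-positive target band area")
  at / ar
}

#' Gel-lane profile container
#'
#' @param positions Positions along the lane, arbitrary length units.
#' @param intensity Non-negative intensities, same length.
#' @param band_windows Named list of \code{c(start, end)} windows, one per
#'   band; windows must lie within the profile and not overlap.
#' @return An object of class \code{lane_profile}. Use
#'   \code{\link{lane_band}} to extract one band for
#'   \code{\link{lane_relative_density}}.
#' @export
lane_profile <- function(positions, intensity, band_windows = list()) {
  if (length(positions) != length(intensity)) {
    stop("positions and intensity must have the same length")
  }
  if (any(intensity < 0)) stop("intensity must be non-negative")
  if (length(band_windows)) {
    rng <- range(positions)
    ord <- order(vapply(band_windows, `[`, numeric(1), 1))
    w <- band_windows[ord]
    for (bw in w) {
      if (bw[1] >= bw[2] || bw[1] < rng[1] || bw[2] > rng[2]) {
        stop("band window out of profile range or inverted")
      }
    }
    if (length(w) > 1L) {
      for (i in seq_len(length(w) - 1L)) {
        if (w[[i]][2] > w[[i + 1L]][1]) stop("band windows overlap")
      }
    }
  }
  structure(list(positions = as.numeric(positions),
                 intensity = as.numeric(intensity),
                 band_windows = band_windows),
            class = "lane_profile")
}

#' Extract one band of a lane profile
#'
#' @param profile A \code{\link{lane_profile}}.
#' @param band Name (or index) of the band window.
#' @return A list with \code{positions}, \code{intensity}, \code{window}
#'   suitable for \code{\link{lane_relative_density}}.
#' @export
lane_band <- function(profile, band) {
  stopifnot(inherits(profile, "lane_profile"))
  w <- profile$band_windows[[band]]
  if (is.null(w)) stop("no band window named '", band, "'")
  list(positions = profile$positions, intensity = profile$intensity,
       window = w)
}

#' qPCR Ct table
#'
#' Long-format table of qPCR threshold cycles with a designated reference
#' (housekeeping) gene; every sample must carry a Ct for the reference.
#'
#' @param rows Data frame with columns \code{sample_id}, \code{condition},
#'   \code{gene}, \code{ct} (cycles, in (0, 45)).
#' @param reference_gene Name of the normalization gene (e.g. "GAPDH").
#' @return An object of class \code{ct_table} (a data frame with the
#'   reference gene stored as an attribute).
#' @export
ct_table <- function(rows, reference_gene = "GAPDH") {
  need <- c("sample_id", "condition", "gene", "ct")
  if (!all(need %in% names(rows))) {
    stop("rows must have columns: ", paste(need, collapse = ", "))
  }
  if (any(rows$ct <= 0 | rows$ct >= 45)) {
    stop("ct values must lie in (0, 45) cycles")
  }
  samples <- unique(rows$sample_id)
  has_ref <- vapply(samples, function(s) {
    any(rows$gene[rows$sample_id == s] == reference_gene)
  }, logical(1))
  if (!all(has_ref)) {
    stop("reference gene '", reference_gene, "' missing for sample(s): ",
         paste(samples[!has_ref], collapse = ", "))
  }
  structure(as.data.frame(rows), reference_gene = reference_gene,
            class = c("ct_table", "data.frame"))
}

#' Delta-delta-Ct fold change
#'
#' Relative expression of \code{gene} in \code{treated} vs \code{control}
#' after normalization to the table's reference gene: per sample,
#' \eqn{\Delta Ct = Ct_{gene} - Ct_{ref}}; then
#' \eqn{\Delta\Delta Ct = \overline{\Delta Ct}_{treated} -
#' \overline{\Delta Ct}_{control}} and the fold change is
#' \eqn{2^{-\Delta\Delta Ct}} (amplification efficiency fixed at 2).
#'
#' @param table A \code{\link{ct_table}}.
#' @param gene Target gene name.
#' @param treated,control Condition labels to compare.
#' @return The fold change (dimensionless).
#' @export
ddct_fold_change <- function(table, gene, treated, control) {
  stopifnot(inherits(table, "ct_table"))
  ref <- attr(table, "reference_gene")
  dct_for <- function(cond) {
    sub <- table[table$condition == cond, , drop = FALSE]
    if (nrow(sub) == 0L) stop("condition '", cond, "' absent from Ct table")
    samples <- unique(sub$sample_id)
    dct <- vapply(samples, function(s) {
      g <- sub$ct[sub$sample_id == s & sub$gene == gene]
      r <- sub$ct[sub$sample_id == s & sub$gene == ref]
      if (length(g) != 1L) {
        stop("gene '", gene, "' missing (or duplicated) for sample ", s)
      }
      g - mean(r)
    }, numeric(1))
    mean(dct)
  }
  ddct <- dct_for(treated) - dct_for(control)
  2^(-ddct)
}
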