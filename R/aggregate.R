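#' Average the curve fits of one cell
#'
#' Three force-distance curves are acquired at the centre of each cell; the
#' cell's modulus is the arithmetic mean of the per-curve moduli. Curves
#' discarded upstream (e.g. by the R-squared quality gate) simply reduce the
#' number averaged; a single surviving fit is accepted with a warning.
#'
#' @param fits List of \code{sneddon_fit} objects from one cell (1--3).
#' @return A one-row data frame (class \code{cell_record}) with columns
#'   \code{cell_id}, \code{cell_type}, \code{condition}, \code{age},
#'   \code{n_curves}, \code{cell_modulus_kPa}, plus the per-curve moduli as
#'   an attribute \code{"moduli"}.
#' @examples
#' # three fitted curves of one cell averaging to 5 kPa
#' @export
aggregate_cell <- function(fits) {
  if (length(fits) == 0L) stop("no fits to aggregate")
  if (length(fits) > 3L) stop("at most 3 curves per cell, got ", length(fits))
  if (!all(vapply(fits, inherits, logical(1), "sneddon_fit"))) {
    stop("fits must be sneddon_fit objects")
  }
  metas <- lapply(fits, `[[`, "meta")
  if (any(vapply(metas, is.null, logical(1)))) {
    stop("fits lack cell metadata; cannot aggregate")
  }
  ids <- vapply(metas, `[[`, character(1), "cell_id")
  if (length(unique(ids)) != 1L) {
    stop("fits come from different cells: ",
         paste(unique(ids), collapse = ", "))
  }
  moduli <- vapply(fits, `[[`, numeric(1), "modulus")
  if (any(moduli <= 0)) stop("all moduli must be positive")
  if (length(moduli) == 1L) {
    warning("cell ", ids[1], ": only one surviving curve fit")
  }
  m <- metas[[1]]
  rec <- data.frame(cell_id = m$cell_id, cell_type = m$cell_type,
                    condition = m$condition, age = m$age,
                    n_curves = length(moduli),
                    cell_modulus_kPa = mean(moduli),
                    stringsAsFactors = FALSE)
  attr(rec, "moduli") <- moduli
  class(rec) <- c("cell_record", "data.frame")
  rec
}

#' Summarize a group of cells
#'
#' The group descriptor reported for each (condition, cell type, age)
#' combination: mean cell modulus and its standard error (sample sd over
#' the square root of the cell count), over typically 10 cells per group.
#'
#' @param cells List of \code{cell_record}s (or a data frame of them)
#'   sharing condition, cell_type and age; at least 2 cells.
#' @return A one-row data frame (class \code{group_summary}) with columns
#'   \code{condition}, \code{cell_type}, \code{age}, \code{n_cells},
#'   \code{mean_kPa}, \code{sem_kPa}, plus attribute \code{"cell_moduli"}.
#' @export
aggregate_group <- function(cells) {
  if (inherits(cells, "data.frame")) {
    df <- cells
  } else {
    if (length(cells) == 0L) stop("no cells to aggregate")
    df <- do.call(rbind, lapply(cells, as.data.frame))
  }
  if (nrow(df) < 2L) {
    stop("need at least 2 cells for a group summary, got ", nrow(df))
  }
  key <- unique(df[c("condition", "cell_type", "age")])
  if (nrow(key) != 1L) {
    stop("heterogeneous grouping keys: cells must share condition, ",
         "cell_type and age")
  }
  x <- df$cell_modulus_kPa
  ms <- mean_sem(x)
  out <- data.frame(condition = key$condition, cell_type = key$cell_type,
                    age = key$age, n_cells = length(x),
                    mean_kPa = ms[["mean"]], sem_kPa = ms[["sem"]],
                    stringsAsFactors = FALSE)
  attr(out, "cell_moduli") <- x
  class(out) <- c("group_summary", "data.frame")
  out
}
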