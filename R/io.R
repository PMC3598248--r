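#' Read a raw force curve from disk
#'
#' Curves are stored as two-column CSV files with header
#' \code{z_um,deflection_um} (dot decimal separator) plus a JSON sidecar
#' \code{<name>.meta.json} holding the \code{\link{curve_meta}} fields.
#'
#' @param path Path to the curve CSV file.
#' @return A validated \code{\link{raw_force_curve}}.
#' @seealso \code{\link{write_curve}}
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("curve file not found: ", path)
  header <- readLines(path, n = 1L)
  if (!identical(trimws(header), "z_um,deflection_um")) {
    stop("malformed header in ", path,
         ": expected 'z_um,deflection_um', got '", header, "'")
  }
  df <- utils::read.csv(path, colClasses = "numeric")
  mpath <- meta_path_for(path)
  if (!file.exists(mpath)) stop("missing metadata sidecar: ", mpath)
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  meta <- curve_meta(cell_id = m$cell_id, cell_type = m$cell_type,
                     condition = m$condition, age = m$age,
                     region = m$region, curve_index = m$curve_index)
  raw_force_curve(df$z_um, df$deflection_um, meta)
}

#' Write a raw force curve to disk
#'
#' Writes the CSV + JSON sidecar pair read back by \code{\link{read_curve}};
#' the round trip reproduces \code{z}, \code{deflection} and the metadata to
#' full double precision.
#'
#' @param curve A \code{\link{raw_force_curve}}.
#' @param path Destination CSV path; the sidecar is written next to it.
#' @return \code{path}, invisibly.
#' @export
write_curve <- function(curve, path) {
  if (!inherits(curve, "raw_force_curve")) {
    stop("curve must be a raw_force_curve")
  }
  m <- curve$meta   # re-validate before touching the filesystem
  do.call(curve_meta, unclass(m))
  lines <- c("z_um,deflection_um",
             paste(format_full(curve$z), format_full(curve$deflection),
                   sep = ","))
  writeLines(lines, path)
  jsonlite::write_json(unclass(curve$meta), meta_path_for(path),
                       auto_unbox = TRUE)
  invisible(path)
}

meta_path_for <- function(path) sub("\\.csv$", "", path) |> paste0(".meta.json")

# full round-trip precision, C locale decimal point
format_full <- function(x) formatC(x, format = "g", digits = 17)

#' Write a dataset of curves with an index
#'
#' A dataset is a directory of curve CSV/sidecar pairs plus a
#' \code{dataset.json} index listing the curve files and, for synthetic
#' data, the ground-truth manifest.
#'
#' @param curves List of \code{\link{raw_force_curve}} objects.
#' @param dir Output directory (created if needed).
#' @param manifest Optional list of ground-truth records (one per curve)
#'   stored alongside the index.
#' @return The dataset directory, invisibly.
#' @export
write_dataset <- function(curves, dir, manifest = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(curves))
  for (i in seq_along(curves)) {
    m <- curves[[i]]$meta
    files[i] <- sprintf("%s_curve%d.csv", m$cell_id, m$curve_index)
    write_curve(curves[[i]], file.path(dir, files[i]))
  }
  index <- list(n_curves = length(curves), files = files)
  if (!is.null(manifest)) index$manifest <- manifest
  jsonlite::write_json(index, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset of curves
#'
#' @param dir Dataset directory containing \code{dataset.json}.
#' @return A list with elements \code{curves} (list of raw curves) and
#'   \code{manifest} (ground truth, or NULL).
#' @export
read_dataset <- function(dir) {
  idx_path <- file.path(dir, "dataset.json")
  if (!file.exists(idx_path)) stop("no dataset index found at: ", idx_path)
  index <- jsonlite::read_json(idx_path, simplifyVector = TRUE)
  curves <- lapply(file.path(dir, index$files), read_curve)
  list(curves = curves, manifest = index$manifest)
}

#' Export group summaries as CSV
#'
#' @param summaries A data frame of group summaries as returned by
#'   \code{\link{aggregate_group}} (rows) or \code{\link{fit_dataset}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_group_table <- function(summaries, path) {
  cols <- c("condition", "cell_type", "age", "n_cells", "mean_kPa", "sem_kPa")
  missing_cols <- setdiff(cols, names(summaries))
  if (length(missing_cols)) {
    stop("summary table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(summaries[cols], path, row.names = FALSE)
  invisible(path)
}
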