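#' Fit every curve of a dataset and aggregate to cells and groups
#'
#' Runs the full modulus pipeline over a set of raw curves: baseline
#' detrend, contact-point detection, conversion to indentation, Sneddon
#' fit, then per-cell averaging and per-group mean +/- s.e.m. Curves whose
#' fit falls below the R-squared quality threshold are discarded (logged
#' via \code{message}); cells with no surviving curve are dropped with a
#' warning.
#'
#' @param curves A list of \code{\link{raw_force_curve}} objects, or a
#'   dataset directory path readable by \code{\link{read_dataset}}.
#' @param params \code{\link{cantilever_params}}.
#' @param pre_fraction,delta_max,min_post_contact_samples,contact_improvement_factor
#'   Processing settings, see \code{\link{process_curve}}.
#' @param r2_threshold Curves with fit R-squared below this are discarded.
#'   Default 0.8.
#' @param verbose Emit a \code{message} per discarded curve. Default TRUE.
#' @return A list with data frames \code{per_curve}, \code{per_cell},
#'   \code{per_group}, and \code{discards} (curve-level log).
#' @export
fit_dataset <- function(curves, params = cantilever_params(),
                        pre_fraction = 0.2, delta_max = 1.5,
                        min_post_contact_samples = 8L,
                        contact_improvement_factor = 2,
                        r2_threshold = 0.8, verbose = TRUE) {
  if (is.character(curves)) curves <- read_dataset(curves)$curves
  per_curve <- list()
  discards <- list()
  fits_by_cell <- list()
  for (i in seq_along(curves)) {
    crv <- curves[[i]]
    m <- crv$meta
    tag <- sprintf("%s/curve%d", m$cell_id, m$curve_index)
    fit <- tryCatch({
      ind <- process_curve(crv, params, pre_fraction = pre_fraction,
                           delta_max = delta_max,
                           min_post_contact_samples = min_post_contact_samples,
                           contact_improvement_factor = contact_improvement_factor)
      fit_modulus(ind, params, delta_max = delta_max)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      discards[[length(discards) + 1L]] <- data.frame(
        curve = tag, reason = conditionMessage(fit),
        stringsAsFactors = FALSE)
      if (verbose) message("discarded ", tag, ": ", conditionMessage(fit))
      next
    }
    if (fit$r_squared < r2_threshold) {
      discards[[length(discards) + 1L]] <- data.frame(
        curve = tag,
        reason = sprintf("R-squared %.3f below threshold %.3f",
                         fit$r_squared, r2_threshold),
        stringsAsFactors = FALSE)
      if (verbose) message("discarded ", tag, ": low R-squared")
      next
    }
    per_curve[[length(per_curve) + 1L]] <- data.frame(
      cell_id = m$cell_id, cell_type = m$cell_type, condition = m$condition,
      age = m$age, curve_index = m$curve_index, modulus_kPa = fit$modulus,
      r_squared = fit$r_squared, n_points = fit$n_points,
      stringsAsFactors = FALSE)
    fits_by_cell[[m$cell_id]] <- c(fits_by_cell[[m$cell_id]], list(fit))
  }
  if (length(per_curve) == 0L) stop("no curves survived fitting")
  per_curve <- do.call(rbind, per_curve)

  per_cell <- do.call(rbind, lapply(names(fits_by_cell), function(id) {
    as.data.frame(suppressWarnings(aggregate_cell(fits_by_cell[[id]])))
  }))

  keys <- unique(per_cell[c("condition", "cell_type", "age")])
  per_group <- do.call(rbind, lapply(seq_len(nrow(keys)), function(j) {
    sel <- per_cell$condition == keys$condition[j] &
      per_cell$cell_type == keys$cell_type[j] & per_cell$age == keys$age[j]
    as.data.frame(aggregate_group(per_cell[sel, , drop = FALSE]))
  }))

  list(per_curve = per_curve, per_cell = per_cell, per_group = per_group,
       discards = if (length(discards)) do.call(rbind, discards) else
         data.frame(curve = character(), reason = character()))
}

#' Compare group summaries pairwise with Welch's t-test
#'
#' Juxtaposes pairs of group summaries sharing cell type and age (e.g.
#' control vs hypothyroid, untreated vs Latrunculin A), reporting the mean
#' difference, Welch's t on the underlying per-cell moduli, and the usual
#' significance annotation (* < 0.05, ** < 0.01, *** < 0.001; annotation
#' only, never a filter).
#'
#' @param summaries List of \code{group_summary} objects (each carrying its
#'   per-cell moduli as the \code{"cell_moduli"} attribute), at least 2,
#'   all sharing cell_type and age.
#' @return A data frame with one row per pair: the two conditions, means,
#'   difference, Welch t, dof, p-value and annotation.
#' @export
report_compare <- function(summaries) {
  if (length(summaries) < 2L) {
    stop("need at least 2 group summaries to compare")
  }
  ct <- unique(vapply(summaries, function(s) s$cell_type, character(1)))
  age <- unique(vapply(summaries, function(s) s$age, character(1)))
  if (length(ct) != 1L || length(age) != 1L) {
    stop("summaries must share cell_type and age")
  }
  pairs <- utils::combn(length(summaries), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- summaries[[pairs[1, j]]]
    b <- summaries[[pairs[2, j]]]
    xa <- attr(a, "cell_moduli")
    xb <- attr(b, "cell_moduli")
    if (is.null(xa) || is.null(xb)) {
      stop("summaries must carry per-cell moduli for testing")
    }
    tt <- welch_t(xa, xb)
    data.frame(cell_type = ct, age = age,
               condition_a = a$condition, condition_b = b$condition,
               mean_a_kPa = a$mean_kPa, mean_b_kPa = b$mean_kPa,
               difference_kPa = a$mean_kPa - b$mean_kPa,
               t = tt$statistic, dof = tt$dof, p_value = tt$p_value,
               signif = trimws(significance_stars(tt$p_value)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the end-to-end pipeline from a configuration
#'
#' Orchestrates simulate -> fit -> aggregate -> compare -> write. The
#' configuration is a named list (or a YAML file path) with components:
#' \describe{
#'   \item{design}{arguments for \code{\link{experiment_design}}, with
#'     \code{groups} as a data frame or list of rows.}
#'   \item{cantilever}{arguments for \code{\link{cantilever_params}}
#'     (optional).}
#'   \item{processing}{optional settings: \code{pre_fraction},
#'     \code{delta_max}, \code{min_post_contact_samples},
#'     \code{contact_improvement_factor}, \code{r2_threshold}.}
#'   \item{dataset}{alternatively, a directory of existing curves to fit
#'     instead of simulating.}
#'   \item{out_dir}{output directory for the CSV tables (optional).}
#' }
#' All randomness flows from \code{design$seed}; a rerun with the same
#' config writes byte-identical tables.
#'
#' @param config Named list or path to a YAML config file.
#' @return Invisibly, a list with the fitted tables (\code{per_curve},
#'   \code{per_cell}, \code{per_group}, \code{discards}), the pairwise
#'   \code{comparisons}, and \code{truth} (recovered vs ground-truth group
#'   means, when the data were simulated).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  params <- do.call(cantilever_params, config$cantilever %||% list())
  proc <- config$processing %||% list()

  if (!is.null(config$dataset)) {
    if (!dir.exists(config$dataset)) {
      stop("dataset directory not found: ", config$dataset)
    }
    ds <- read_dataset(config$dataset)
    curves <- ds$curves
    manifest <- ds$manifest
  } else if (!is.null(config$design)) {
    dargs <- config$design
    if (!is.data.frame(dargs$groups)) {
      dargs$groups <- do.call(rbind, lapply(dargs$groups, as.data.frame))
    }
    design <- do.call(experiment_design, dargs)
    sim <- simulate_experiment(design, params,
                               dir = config$out_dir %||% NULL)
    curves <- sim$curves
    manifest <- sim$manifest
  } else {
    stop("config must provide either a 'design' or a 'dataset' entry")
  }

  res <- fit_dataset(
    curves, params,
    pre_fraction = proc$pre_fraction %||% 0.2,
    delta_max = proc$delta_max %||% 1.5,
    min_post_contact_samples = proc$min_post_contact_samples %||% 8L,
    contact_improvement_factor = proc$contact_improvement_factor %||% 2,
    r2_threshold = proc$r2_threshold %||% 0.8,
    verbose = !isFALSE(config$verbose))

  # pairwise comparisons within each (cell_type, age) stratum
  pg <- res$per_group
  comparisons <- NULL
  strata <- unique(pg[c("cell_type", "age")])
  for (j in seq_len(nrow(strata))) {
    sel <- which(pg$cell_type == strata$cell_type[j] &
                   pg$age == strata$age[j])
    if (length(sel) < 2L) next
    sums <- lapply(sel, function(i) {
      s <- pg[i, , drop = FALSE]
      cm <- res$per_cell$cell_modulus_kPa[
        res$per_cell$condition == s$condition &
          res$per_cell$cell_type == s$cell_type &
          res$per_cell$age == s$age]
      attr(s, "cell_moduli") <- cm
      class(s) <- c("group_summary", "data.frame")
      s
    })
    comparisons <- rbind(comparisons, report_compare(sums))
  }

  truth <- NULL
  if (!is.null(manifest)) {
    md <- if (is.data.frame(manifest)) manifest else
      do.call(rbind, lapply(manifest, function(m) {
        as.data.frame(m[c("condition", "cell_type", "age", "group_modulus")])
      }))
    tr <- unique(md[c("condition", "cell_type", "age", "group_modulus")])
    truth <- merge(pg, tr, by = c("condition", "cell_type", "age"))
    truth$error_kPa <- truth$mean_kPa - truth$group_modulus
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$per_curve,
                     file.path(config$out_dir, "per_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(res$per_cell,
                     file.path(config$out_dir, "per_cell.csv"),
                     row.names = FALSE)
    write_group_table(res$per_group,
                      file.path(config$out_dir, "per_group.csv"))
    if (!is.null(comparisons)) {
      utils::write.csv(comparisons,
                       file.path(config$out_dir, "comparisons.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(res$discards,
                     file.path(config$out_dir, "discards.csv"),
                     row.names = FALSE)
  }

  invisible(c(res, list(comparisons = comparisons, truth = truth)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
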