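#' Persist a boundary case to disk
#'
#' Two dialects are supported.  `"csv"` writes a dependency-light triplet
#' `<stem>.ilm.csv`, `<stem>.rpe.csv`, `<stem>.bm.csv` (plain depth grids,
#' no header) plus `<stem>.meta.json` holding the geometry and identity
#' fields.  `"rds"` writes the object natively.
#'
#' @param case a [layer_boundaries] object.
#' @param path output path: the stem for `"csv"`, the file for `"rds"`.
#' @param dialect `"csv"` or `"rds"`.
#' @return `path`, invisibly.
#' @export
save_case <- function(case, path, dialect = c("csv", "rds")) {
  stopifnot(inherits(case, "layer_boundaries"))
  dialect <- match.arg(dialect)
  if (dialect == "rds") {
    saveRDS(case, path)
    return(invisible(path))
  }
  for (k in c("ilm", "rpe", "bm"))
    utils::write.table(case[[paste0("b_", k)]],
                       paste0(path, ".", k, ".csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  meta <- case[c("n_ascan", "n_bscan", "n_axial", "spacing_x_mm",
                 "spacing_y_mm", "fovea_xy", "case_id", "label")]
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_grid_csv <- function(f) {
  if (!file.exists(f))
    stop(sprintf("boundary grid file missing: '%s'", f), call. = FALSE)
  as.matrix(utils::read.table(f, sep = ",", header = FALSE))
}

#' Load a boundary case from disk
#'
#' Inverse of [save_case()].  The returned object is re-validated through
#' [layer_boundaries()], so boundary-order violations in the stored data
#' raise unless `repair = TRUE`.
#'
#' @inheritParams save_case
#' @param repair clamp `b_rpe` into `[b_ilm, b_bm]` instead of failing.
#' @return A [layer_boundaries] object.
#' @export
load_case <- function(path, dialect = c("csv", "rds"), repair = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "rds") {
    if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
    case <- readRDS(path)
    return(layer_boundaries(case$b_ilm, case$b_rpe, case$b_bm, case$n_axial,
                            case$spacing_x_mm, case$spacing_y_mm,
                            case$fovea_xy, case$case_id, case$label,
                            repair = repair))
  }
  mf <- paste0(path, ".meta.json")
  if (!file.exists(mf))
    stop(sprintf("metadata file missing: '%s'", mf), call. = FALSE)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  need <- c("n_axial", "spacing_x_mm", "spacing_y_mm", "fovea_xy")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop(sprintf("metadata key(s) missing from '%s': %s", mf,
                 paste(miss, collapse = ", ")), call. = FALSE)
  layer_boundaries(read_grid_csv(paste0(path, ".ilm.csv")),
                   read_grid_csv(paste0(path, ".rpe.csv")),
                   read_grid_csv(paste0(path, ".bm.csv")),
                   meta$n_axial, meta$spacing_x_mm, meta$spacing_y_mm,
                   meta$fovea_xy,
                   case_id = if (is.null(meta$case_id)) basename(path) else meta$case_id,
                   label = if (is.null(meta$label)) "UNKNOWN" else meta$label,
                   repair = repair)
}

#' Write a feature table to CSV
#'
#' One row per feature vector: `arrangement`, `case_id`, `label`, then the
#' feature columns `f_001 .. f_NNN` (direction-major, lag-ascending order as
#' produced by [build_feature_vector()]).  All rows must share one length.
#'
#' @param table data frame as returned by [extract_features()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
save_features <- function(table, path) {
  stopifnot(is.data.frame(table))
  meta_cols <- c("arrangement", "case_id", "label")
  if (nrow(table) && !all(meta_cols %in% names(table)))
    stop("feature table must have arrangement, case_id, label columns",
         call. = FALSE)
  fcols <- grep("^f_\\d+$", names(table), value = TRUE)
  if (nrow(table) && !length(fcols))
    stop("feature table has no f_NNN columns", call. = FALSE)
  utils::write.csv(table[c(meta_cols, fcols)], path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Read a feature table written by [save_features()]
#' @param path CSV path.
#' @return A data frame with `arrangement`, `case_id`, `label` and `f_NNN`
#'   columns.
#' @export
load_features <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(arrangement = "character",
                                        case_id = "character",
                                        label = "character"))
  tab
}

#' Write an evaluation report to JSON
#'
#' Serializes the protocol record, the per-repetition metric table, the
#' per-fold confusion counts and the aggregate rows of an `amd_eval` object.
#'
#' @param report an `amd_eval` object from [svm_repeated_cv()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_report <- function(report, path) {
  stopifnot(inherits(report, "amd_eval"))
  out <- list(protocol = report$protocol,
              per_repetition = report$per_repetition,
              per_fold = report$per_fold,
              aggregates = report$aggregates)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read an evaluation report written by [save_report()]
#' @param path JSON path.
#' @return An `amd_eval` object (without the raw per-case scores).
#' @export
load_report <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(protocol = x$protocol,
                 per_repetition = as.data.frame(x$per_repetition),
                 per_fold = as.data.frame(x$per_fold),
                 aggregates = as.data.frame(x$aggregates)),
            class = "amd_eval")
}
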