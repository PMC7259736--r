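#' Bundle detection histories and covariates for model fitting
#'
#' Assembles the per-unit data the sampler consumes: one three-count
#' detection history per site-stage-year unit (after first-visit
#' filtering), the unit's stage, year and site labels, and the
#' standardized design matrix.
#'
#' @param y n x 3 binary matrix of detection histories.
#' @param stage Character/factor of annual-cycle stages, length n.
#' @param year Year of each unit, length n.
#' @param site Site identifier of each unit, length n.
#' @param X Standardized design matrix from [build_design()] (or `NULL`
#'   for an intercept-only analysis).
#' @return Object of class `occu_data`.
#' @export
occu_data <- function(y, stage, year, site, X = NULL) {
  y <- as.matrix(y)
  stopifnot(ncol(y) == 3, all(y %in% c(0, 1)),
            length(stage) == nrow(y), length(year) == nrow(y),
            length(site) == nrow(y), all(stage %in% stage_levels()))
  if (is.null(X)) X <- matrix(numeric(0), nrow = nrow(y), ncol = 0)
  stopifnot(is.matrix(X), nrow(X) == nrow(y))
  if (ncol(X) > 0 && is.null(colnames(X))) {
    stop("design matrix columns must be named")
  }
  present <- stage_levels()[stage_levels() %in% unique(stage)]
  structure(list(
    y = matrix(as.integer(y), ncol = 3),
    stage = factor(stage, levels = present),
    year = factor(year),
    site = factor(site),
    X = X,
    n = nrow(y)
  ), class = "occu_data")
}

#' Build an `occu_data` object from survey records
#'
#' Convenience wrapper: takes validated, first-visit-filtered survey
#' records for a single radius class and an aligned design matrix.
#'
#' @param records Survey-record data frame (one row per unit).
#' @param X Design matrix with rows aligned to `records`, or `NULL`.
#' @return An [occu_data()] object.
#' @export
as_occu_data <- function(records, X = NULL) {
  stopifnot(is.data.frame(records),
            all(c("site_id", "year", "stage", "count1", "count2", "count3")
                %in% names(records)))
  if (length(unique(records$radius_class)) > 1) {
    stop("records mix radius classes; fit one model per radius")
  }
  occu_data(as.matrix(records[, c("count1", "count2", "count3")]),
            records$stage, records$year, records$site_id, X)
}

#' @export
print.occu_data <- function(x, ...) {
  cat("occu_data:", x$n, "detection-history units\n")
  cat("  stages:", paste(levels(x$stage), collapse = ", "), "\n")
  cat("  years:", paste(levels(x$year), collapse = ", "),
      " sites:", nlevels(x$site), "\n")
  cat("  covariates:", if (ncol(x$X)) paste(colnames(x$X), collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
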