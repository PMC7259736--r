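#' Radius classes used for scoring detections
#'
#' Detections were scored twice per count: within 100 m of the point, and at
#' an unlimited ("infinite") radius, as far as observable.
#'
#' @return Character vector of the two radius-class labels.
#' @export
radius_levels <- function() c("within_100m", "infinite")

.survey_cols <- c("site_id", "year", "date", "count1", "count2", "count3",
                  "radius_class")

#' Read a survey-record CSV
#'
#' Reads and validates a table of point-count survey records.  Required
#' columns: `site_id`, `year`, `date` (ISO-8601), `count1..count3` (binary
#' detection outcome of each sequential ten-minute count) and
#' `radius_class`.  A `stage` column is optional; when absent, stages are
#' derived from the dates via [assign_stage()].
#'
#' @param path Path to a UTF-8 CSV file.
#' @param windows Stage-window table from [stage_windows()]; required when
#'   the file lacks a `stage` column.
#' @return Validated data frame of survey records (see [validate_surveys()]).
#' @export
read_surveys <- function(path, windows = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(.survey_cols, names(df))
  if (length(missing)) {
    stop("survey CSV is missing required columns: ",
         paste(missing, collapse = ", "))
  }
  df$date <- as.Date(df$date)
  if (is.null(df$stage)) {
    if (is.null(windows)) windows <- stage_windows(sort(unique(df$year)))
    df$stage <- assign_stage(df$date, windows)
  }
  validate_surveys(df)
}

#' Validate survey records
#'
#' Checks structural invariants of a survey-record table: binary counts,
#' known radius classes, parseable dates, and cross-radius consistency — a
#' bird detected within 100 m on a given count must also be a detection at
#' infinite radius for the same visit, because both outcomes are scored
#' from the same physical count.
#'
#' @param df Data frame with the columns listed in [read_surveys()], plus
#'   `stage`.
#' @return The validated data frame, with `date` as `Date` and counts as
#'   integers, invisibly classed as validated.
#' @export
validate_surveys <- function(df) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(c(.survey_cols, "stage"), names(df))
  if (length(missing)) {
    stop("survey table is missing columns: ", paste(missing, collapse = ", "))
  }
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable survey dates")
  cnt <- as.matrix(df[, c("count1", "count2", "count3")])
  if (anyNA(cnt) || !all(cnt %in% c(0L, 1L))) {
    stop("counts must be binary 0/1 with no missing values")
  }
  if (!all(df$radius_class %in% radius_levels())) {
    stop("radius_class must be one of: ", paste(radius_levels(), collapse = ", "))
  }
  if (!all(df$stage %in% stage_levels())) {
    stop("stage must be one of: ", paste(stage_levels(), collapse = ", "))
  }
  bad <- check_radius_consistency(df)
  if (nrow(bad)) {
    stop("radius inconsistency: detection within 100 m without detection at ",
         "infinite radius for the same visit (", nrow(bad), " visit(s), e.g. ",
         "site ", bad$site_id[1], " on ", format(bad$date[1]), ")")
  }
  df
}

#' Find visits that violate cross-radius consistency
#'
#' For visits scored at both radii, flags any count where the within-100 m
#' outcome is 1 but the infinite-radius outcome is 0.
#'
#' @param df Survey data frame containing both radius classes.
#' @return Data frame of offending visits (zero rows when consistent).
#' @export
check_radius_consistency <- function(df) {
  near <- df[df$radius_class == "within_100m", ]
  far  <- df[df$radius_class == "infinite", ]
  if (!nrow(near) || !nrow(far)) return(df[0, ])
  key <- function(x) paste(x$site_id, x$year, format(as.Date(x$date)), sep = "|")
  m <- match(key(near), key(far))
  have <- !is.na(m)
  nc <- as.matrix(near[have, c("count1", "count2", "count3")])
  fc <- as.matrix(far[m[have], c("count1", "count2", "count3")])
  bad <- rowSums(nc == 1 & fc == 0) > 0
  near[have, ][bad, , drop = FALSE]
}

#' Keep only the first visit per site-stage-year unit
#'
#' When a point was surveyed more than once within the same stage and year,
#' only the first visit (the first set of three ten-minute counts) enters
#' the occupancy analysis, so that each site-stage-year-radius unit
#' contributes exactly one detection history.  Ties on date are broken by
#' stable input order.  The operation is idempotent.
#'
#' @param df Validated survey data frame.
#' @return Data frame with one row per (site, year, stage, radius class).
#' @export
first_visit_filter <- function(df) {
  stopifnot(is.data.frame(df))
  unit <- paste(df$site_id, df$year, df$stage, df$radius_class, sep = "|")
  ord <- order(unit, as.Date(df$date), seq_len(nrow(df)))
  keep_sorted <- !duplicated(unit[ord])
  out <- df[ord[keep_sorted], , drop = FALSE]
  out[order(match(rownames(out), rownames(df))), , drop = FALSE]
}

#' Naive occurrence metrics for detection histories
#'
#' Uncorrected summaries of a detection history: `naive_occurrence` is 1 if
#' the species was detected on at least one of the three counts, and
#' `proportion_detected` is the number of counts with a detection divided
#' by 3 — the "proportion of survey time with >= 1 detection" variable used
#' by earlier cone-crop occurrence models.
#'
#' @param h Either a length-3 binary vector (one history) or a matrix/data
#'   frame with three columns, one row per history.
#' @return Data frame with columns `naive_occurrence` and
#'   `proportion_detected`.
#' @examples
#' naive_metrics(c(1, 0, 1))  # detected on 2 of 3 counts
#' @export
naive_metrics <- function(h) {
  if (is.null(dim(h))) h <- matrix(h, nrow = 1)
  h <- as.matrix(h)
  stopifnot(ncol(h) == 3, all(h %in% c(0, 1)))
  k <- rowSums(h)
  data.frame(naive_occurrence = as.integer(k > 0),
             proportion_detected = k / 3)
}

#' Tally surveys by annual-cycle stage
#'
#' Counts surveys per stage and overall, either from raw survey records
#' (one row per survey) or from a survey schedule that carries an
#' `n_surveys` column of per-cell sample sizes.
#'
#' @param df Data frame with a `stage` column and, optionally, `n_surveys`.
#' @return List with `by_stage` (named integer vector over the five stages)
#'   and `total`.
#' @export
tally_surveys <- function(df) {
  stopifnot(is.data.frame(df))
  if (!nrow(df)) {
    by_stage <- setNames(integer(length(stage_levels())), stage_levels())
    return(list(by_stage = by_stage, total = 0L))
  }
  stopifnot("stage" %in% names(df), all(df$stage %in% stage_levels()))
  n <- if ("n_surveys" %in% names(df)) as.integer(df$n_surveys) else
    rep(1L, nrow(df))
  by_stage <- vapply(stage_levels(), function(s) sum(n[df$stage == s]), 0L)
  list(by_stage = by_stage, total = sum(by_stage))
}
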