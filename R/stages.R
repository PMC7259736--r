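#' Stages of the Clark's nutcracker annual cycle
#'
#' The analysis divides each survey year into five behaviourally defined
#' stages: breeding (nest building through last nestling observed), early
#' summer, late summer (immature-seed predation), fall seed harvest
#' (mature-seed harvest and caching) and post-harvest (no mature cones
#' remaining).
#'
#' @return Character vector of the five stage names, in annual order.
#' @export
stage_levels <- function() {
  c("breeding", "early_summer", "late_summer", "fall_harvest", "post_harvest")
}

# default month-day boundaries; early/late-summer and harvest boundaries are
# phenological and therefore year-specific config in real use
.default_boundaries <- list(
  breeding     = c("03-05", "06-15"),
  early_summer = c("06-16", "07-11"),
  late_summer  = c("07-12", "08-11"),
  fall_harvest = c("08-12", "09-28"),
  post_harvest = c("09-29", "11-30")
)

#' Stage windows for one or more survey years
#'
#' Builds the table of date windows delimiting each annual-cycle stage.
#' The breeding window is fixed by observed nesting phenology (5 March to
#' 15 June); the remaining boundaries track whitebark pine cone phenology
#' and may be overridden per year.
#'
#' @param years Integer vector of survey years.
#' @param boundaries Named list overriding the default month-day boundaries;
#'   each element is `c(start, end)` in `"mm-dd"` form, named by stage.
#'   Windows must be non-overlapping and in annual order.
#' @return A data frame with columns `year`, `stage`, `start`, `end`
#'   (`Date` columns), one row per year x stage.
#' @examples
#' stage_windows(2011)
#' @export
stage_windows <- function(years, boundaries = NULL) {
  stopifnot(is.numeric(years), length(years) >= 1)
  b <- .default_boundaries
  if (!is.null(boundaries)) {
    stopifnot(is.list(boundaries), all(names(boundaries) %in% stage_levels()))
    b[names(boundaries)] <- boundaries
  }
  out <- do.call(rbind, lapply(as.integer(years), function(y) {
    data.frame(
      year  = y,
      stage = stage_levels(),
      start = as.Date(paste0(y, "-", vapply(b[stage_levels()], `[`, "", 1L))),
      end   = as.Date(paste0(y, "-", vapply(b[stage_levels()], `[`, "", 2L)))
    )
  }))
  rownames(out) <- NULL
  # windows must be ordered and non-overlapping within each year
  for (y in unique(out$year)) {
    w <- out[out$year == y, ]
    if (any(w$end < w$start) || any(diff(as.numeric(w$start)) <= 0) ||
        any(w$start[-1] <= w$end[-nrow(w)])) {
      stop("stage windows for year ", y, " overlap or are out of order")
    }
  }
  out
}

#' Assign survey dates to annual-cycle stages
#'
#' Maps each calendar date to the unique stage whose window contains it.
#' Dates falling outside all windows (e.g. mid-winter) are rejected: surveys
#' were only conducted within the annual cycle the model describes.
#'
#' @param dates `Date` vector (or strings coercible via ISO-8601).
#' @param windows Window table from [stage_windows()] covering the years of
#'   `dates`.
#' @return Character vector of stage names, same length as `dates`.
#' @examples
#' w <- stage_windows(2011)
#' assign_stage(as.Date(c("2011-03-10", "2011-06-16")), w)
#' @export
assign_stage <- function(dates, windows) {
  dates <- as.Date(dates)
  stopifnot(!anyNA(dates), is.data.frame(windows),
            all(c("year", "stage", "start", "end") %in% names(windows)))
  yrs <- as.integer(format(dates, "%Y"))
  out <- character(length(dates))
  for (i in seq_along(dates)) {
    w <- windows[windows$year == yrs[i] &
                   windows$start <= dates[i] & windows$end >= dates[i], ]
    if (nrow(w) == 0L) {
      stop("date ", format(dates[i]),
           " falls outside all stage windows for year ", yrs[i])
    }
    if (nrow(w) > 1L) {
      stop("date ", format(dates[i]), " matches multiple stage windows")
    }
    out[i] <- w$stage
  }
  out
}
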