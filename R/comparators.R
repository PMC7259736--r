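#' Cone-production index used by earlier occurrence models
#'
#' The squared logarithm of cone density per hectare, the predictor both
#' published comparator models use.  The log base is configurable because
#' the original reports do not state it; the natural log is the default.
#'
#' @param cones_per_ha Strictly positive cone densities.
#' @param base `"natural"` or `"log10"`.
#' @return The index `log(cones)^2`.
#' @export
cone_index <- function(cones_per_ha, base = c("natural", "log10")) {
  base <- match.arg(base)
  stopifnot(all(cones_per_ha > 0))
  l <- if (base == "natural") log(cones_per_ha) else log10(cones_per_ha)
  l^2
}

#' McKinney et al. linear occurrence model
#'
#' The published linear regression `y = -0.449 + 0.019 x` predicting the
#' proportion of survey time with a nutcracker detection from the
#' cone-production index `x`.  Being linear, predictions fall outside
#' `[0, 1]` at the extremes; they are returned unclipped by default so
#' the raw model can be examined, with optional clipping.
#'
#' @param x Cone-production index (>= 0), see [cone_index()].
#' @param clip Clip predictions into `[0, 1]`.
#' @return Predicted occurrence proportion.
#' @examples
#' mckinney_predict(0)  # the intercept, -0.449
#' @export
mckinney_predict <- function(x, clip = FALSE) {
  stopifnot(all(x >= 0))
  y <- -0.449 + 0.019 * x
  if (clip) pmin(pmax(y, 0), 1) else y
}

#' Barringer et al. beta-regression occurrence model
#'
#' The published beta-regression mean model
#' `y = exp(-1.5165 + 0.03883 x) / (1 + exp(-1.5165 + 0.03883 x))`,
#' i.e. the inverse logit of a linear function of the cone-production
#' index; predictions lie strictly inside (0, 1) and increase with `x`.
#'
#' @param x Cone-production index (>= 0), see [cone_index()].
#' @return Predicted occurrence proportion in (0, 1).
#' @export
barringer_predict <- function(x) {
  stopifnot(all(x >= 0))
  plogis(-1.5165 + 0.03883 * x)
}

#' Filter surveys to the comparator studies' parameters
#'
#' The published comparator models were built on a narrower design, so
#' the comparison only uses surveys matching it: infinite-radius surveys,
#' whitebark pine cone density > 0, survey dates 15 July - 15 September,
#' and (when a `cone_count_date` column is present) a cone count made on
#' the survey date.
#'
#' @param df Survey data frame with columns `radius_class`, `date`,
#'   `cone_density`, and optionally `cone_count_date`.
#' @param window Month-day bounds of the seasonal filter.
#' @return The filtered data frame.
#' @export
comparator_filter <- function(df, window = c("07-15", "09-15")) {
  stopifnot(is.data.frame(df),
            all(c("radius_class", "date", "cone_density") %in% names(df)))
  d <- as.Date(df$date)
  md <- format(d, "%m-%d")
  keep <- df$radius_class == "infinite" &
    df$cone_density > 0 &
    md >= window[1] & md <= window[2]
  if ("cone_count_date" %in% names(df)) {
    keep <- keep & !is.na(df$cone_count_date) &
      as.Date(df$cone_count_date) == d
  }
  df[keep, , drop = FALSE]
}

#' Compare observed and model-predicted occurrence proportions
#'
#' The published-model comparison: Spearman rank correlation between
#' observed proportions of survey time with a detection and a comparator
#' model's predictions, plus a one-tailed paired Wilcoxon signed-rank
#' test of whether the comparator underpredicts (alternative: observed
#' greater than predicted).  Zero differences are dropped and ties take
#' mid-ranks, the standard treatment.
#'
#' @param observed,predicted Paired numeric vectors, length >= 5.
#' @return List with `rho`, `rho_p`, `W` (signed-rank statistic), `W_p`,
#'   `n`, and `note` (set when the signed-rank test is undefined because
#'   all differences are zero).
#' @export
compare_observed_predicted <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted),
            length(observed) == length(predicted))
  if (length(observed) < 5) stop("need at least 5 pairs")
  ct <- suppressWarnings(
    cor.test(observed, predicted, method = "spearman", exact = FALSE)
  )
  d <- observed - predicted
  if (all(d == 0)) {
    return(list(rho = unname(ct$estimate), rho_p = ct$p.value,
                W = NA_real_, W_p = NA_real_, n = length(observed),
                note = "signed-rank test undefined: all differences zero"))
  }
  wt <- suppressWarnings(
    wilcox.test(observed, predicted, paired = TRUE, alternative = "greater")
  )
  list(rho = unname(ct$estimate), rho_p = ct$p.value,
       W = unname(wt$statistic), W_p = wt$p.value,
       n = length(observed), note = NULL)
}
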