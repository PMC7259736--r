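#' Posterior occurrence-probability curve over a covariate grid
#'
#' Evaluates the model-averaged posterior of the occurrence probability
#' along a grid of one covariate, holding all other covariates at their
#' observed means (or at supplied conditioning values).  For each
#' posterior draw the linear predictor is assembled from that draw's
#' intercept, coefficients and — under cross-product selection — its
#' sampled model's inclusion pattern, then inverse-logit transformed;
#' the curve reports the pointwise posterior mean and central 95%
#' credible bounds.  Predictions are at the population level: random
#' effects are set to their mean of zero.  When the grid covariate is the
#' magnitude member of a zero-inflated pair, the curve describes the
#' covariate-present state (absence indicator 0) and the grid must be
#' strictly positive.
#'
#' @param fit An `occu_fit`.
#' @param stage Stage to predict for (must be present in the fit).
#' @param var Design-matrix column to vary.
#' @param grid Grid in original covariate units; default: `n_grid` points
#'   spanning the observed range.  Grids outside the observed range are
#'   allowed but flagged with a warning.
#' @param n_grid Number of default grid points.
#' @param conditioning Named list of original-unit values at which to hold
#'   other covariates; for a zero-inflated covariate, the value 0 selects
#'   the absent state.
#' @return Object of class `prediction_curve`: data frame with columns
#'   `value` (original units), `value_std`, `mean`, `lower`, `upper`.
#' @export
predict_psi <- function(fit, stage, var, grid = NULL, n_grid = 200,
                        conditioning = list()) {
  stopifnot(inherits(fit, "occu_fit"))
  meta <- fit$meta
  X <- meta$X
  if (!stage %in% meta$stages) stop("stage '", stage, "' not in the fit")
  if (!var %in% colnames(X)) stop("unknown covariate '", var, "'")
  if (length(conditioning) &&
      !all(names(conditioning) %in% colnames(X))) {
    stop("conditioning references unknown covariates: ",
         paste(setdiff(names(conditioning), colnames(X)), collapse = ", "))
  }
  s <- match(stage, meta$stages)
  ctr <- attr(X, "center"); scl <- attr(X, "scale")
  zi_pairs <- attr(X, "zi_pairs")

  std <- function(col, value) (value - ctr[[col]]) / scl[[col]]
  orig <- function(col, value_std) value_std * scl[[col]] + ctr[[col]]

  if (is.null(grid)) {
    rng <- range(orig(var, X[, var]))
    grid <- seq(rng[1], rng[2], length.out = n_grid)
  }
  obs_rng <- range(orig(var, X[, var]))
  if (min(grid) < obs_rng[1] - 1e-9 || max(grid) > obs_rng[2] + 1e-9) {
    warning("grid extends beyond the observed covariate range (extrapolation)")
  }
  grid_std <- std(var, grid)

  # standardized value of every other column under the conditioning record
  base_vals <- colMeans(X)
  for (nm in names(conditioning)) {
    val <- conditioning[[nm]]
    if (nm %in% names(zi_pairs)) {
      pr <- zi_pairs[[nm]]
      if (val == 0) {
        base_vals[pr[1]] <- 1; base_vals[pr[2]] <- 0
      } else {
        base_vals[pr[1]] <- 0; base_vals[pr[2]] <- std(pr[2], val)
      }
    } else {
      base_vals[nm] <- std(nm, val)
    }
  }
  if (var %in% unlist(zi_pairs)) {
    # curve in the covariate-present state
    pair <- zi_pairs[[which(vapply(zi_pairs, function(p) var %in% p, TRUE))]]
    base_vals[pair[1]] <- 0
  }

  pars <- posterior_matrix(fit)
  model_draws <- attr(pars, "model")
  incl_draws <- attr(pars, "incl")
  ndraw <- nrow(pars)
  alpha <- pars[, paste0("alpha[", stage, "]")]

  terms <- colnames(X)[meta$ua[, s]]
  lin <- matrix(alpha, ndraw, length(grid))
  for (tr in terms) {
    b <- pars[, paste0("beta[", tr, ",", stage, "]")]
    act <- rep(TRUE, ndraw)
    if (meta$mode == "models") {
      act <- meta$incl_list[[s]][model_draws[, s], tr]
    } else if (meta$mode == "screen") {
      g <- which(vapply(meta$groups, function(gr) {
        match(tr, colnames(X)) %in% gr
      }, TRUE))
      act <- incl_draws[, g] == 1L
    }
    b <- b * act
    if (tr == var) {
      lin <- lin + outer(b, grid_std)
    } else {
      lin <- lin + b * base_vals[[tr]]
    }
  }
  psi <- plogis(lin)
  out <- data.frame(
    value = grid, value_std = grid_std,
    mean = colMeans(psi),
    lower = apply(psi, 2, quantile, 0.025),
    upper = apply(psi, 2, quantile, 0.975)
  )
  class(out) <- c("prediction_curve", "data.frame")
  attr(out, "stage") <- stage
  attr(out, "var") <- var
  attr(out, "conditioning") <- base_vals
  out
}

#' Smallest covariate value reaching a target occurrence probability
#'
#' Scans a prediction curve for the smallest covariate value at which the
#' posterior-mean occurrence probability reaches the target, linearly
#' interpolating between the bracketing grid points.  The curve is
#' expected to be monotone over the searched segment; if it is not, the
#' smallest crossing is returned with a warning.
#'
#' @param curve A [predict_psi()] curve (or any data frame with `value`
#'   and `mean` columns).
#' @param target Target probability in (0, 1), e.g. 0.75.
#' @return The threshold covariate value (original units), or `NA` when
#'   the curve never reaches the target.
#' @examples
#' curve <- data.frame(value = c(10000, 20000), mean = c(0.6, 0.8))
#' threshold_area(curve, 0.75)  # 17500
#' @export
threshold_area <- function(curve, target) {
  stopifnot(is.data.frame(curve), all(c("value", "mean") %in% names(curve)))
  if (!is.numeric(target) || length(target) != 1 || target <= 0 || target >= 1) {
    stop("target must be a probability strictly between 0 and 1")
  }
  m <- curve$mean; v <- curve$value
  stopifnot(!is.unsorted(v))
  hits <- which(m >= target)
  if (!length(hits)) return(NA_real_)
  first <- hits[1]
  if (any(diff(m) < -1e-9)) {
    warning("curve is not monotone; returning the smallest crossing")
  }
  if (first == 1) return(v[1])
  # linear interpolation between the bracketing grid points
  v[first - 1] + (target - m[first - 1]) / (m[first] - m[first - 1]) *
    (v[first] - v[first - 1])
}
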