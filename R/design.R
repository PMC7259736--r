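#' Z-score standardization
#'
#' Centers and scales a numeric vector to mean 0 and sample standard
#' deviation 1 (denominator n - 1).  All occurrence and detection
#' covariates enter the models standardized so that coefficients are
#' comparable across covariates and the diffuse priors are sensible.
#'
#' @param x Numeric vector, length >= 2, non-constant.
#' @return Standardized vector with attributes `center` and `scale`.
#' @examples
#' zscore(c(1, 2, 3))
#' @export
zscore <- function(x) {
  stopifnot(is.numeric(x))
  if (length(x) < 2L) stop("zscore needs at least two values")
  if (anyNA(x) || any(!is.finite(x))) stop("zscore input must be finite")
  s <- sd(x)
  if (s == 0) stop("zscore input is constant")
  out <- (x - mean(x)) / s
  attr(out, "center") <- mean(x)
  attr(out, "scale") <- s
  out
}

#' Decompose a zero-inflated covariate into absence and magnitude terms
#'
#' Extremely zero-inflated habitat covariates (cone density, importance
#' values) enter the occurrence model as a pair: a binary absence indicator
#' (1 = absent, matching the published coding "cones present = 0, cones
#' absent = 1") and a continuous magnitude term standardized over the
#' strictly positive values only, set to 0 wherever the covariate is zero.
#' The pair lets the model's intercept shift with presence/absence while
#' the magnitude term measures the effect of "how much, given present";
#' the magnitude contribution vanishes identically at absent sites.
#'
#' @param x Non-negative numeric vector.
#' @return List with `absence` (0/1 vector, 1 = absent), `magnitude`
#'   (standardized-over-positives vector, 0 at absent entries; `NA` when no
#'   positive values exist), `magnitude_defined` (logical), and `center`,
#'   `scale` of the positive part.
#' @examples
#' decompose_zero_inflated(c(0, 10, 20))
#' @export
decompose_zero_inflated <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (any(x < 0)) stop("zero-inflated covariates must be non-negative")
  absence <- as.numeric(x == 0)
  pos <- x > 0
  if (!any(pos)) {
    return(list(absence = absence, magnitude = rep(NA_real_, length(x)),
                magnitude_defined = FALSE, center = NA_real_, scale = NA_real_))
  }
  if (sum(pos) == 1L || sd(x[pos]) == 0) {
    # a single (or constant) positive value carries no magnitude contrast
    mag <- rep(0, length(x))
    ctr <- mean(x[pos]); scl <- NA_real_
  } else {
    z <- zscore(x[pos])
    mag <- rep(0, length(x))
    mag[pos] <- as.numeric(z)
    ctr <- attr(z, "center"); scl <- attr(z, "scale")
  }
  list(absence = absence, magnitude = mag, magnitude_defined = TRUE,
       center = ctr, scale = scl)
}

#' Build a standardized design matrix for occurrence covariates
#'
#' Assembles the covariate columns used by the occupancy model: plain
#' continuous covariates are z-scored; zero-inflated covariates are
#' expanded into their (absence, magnitude) column pair via
#' [decompose_zero_inflated()].  Standardization metadata is kept as
#' attributes so prediction grids specified in original units can be mapped
#' onto the model scale.
#'
#' @param covs Data frame of covariate values, rows aligned with the
#'   detection-history units.
#' @param continuous Character vector of plain continuous covariate names.
#' @param zero_inflated Character vector of zero-inflated covariate names;
#'   each contributes columns `<name>_absent` and `<name>`.
#' @return Numeric matrix with attributes `center`, `scale` (named per
#'   column) and `zi_pairs` (named list mapping each zero-inflated
#'   covariate to its column pair).
#' @export
build_design <- function(covs, continuous = character(),
                         zero_inflated = character()) {
  stopifnot(is.data.frame(covs),
            all(c(continuous, zero_inflated) %in% names(covs)))
  cols <- list(); ctr <- c(); scl <- c(); zi_pairs <- list()
  for (v in continuous) {
    z <- zscore(covs[[v]])
    cols[[v]] <- as.numeric(z)
    ctr[v] <- attr(z, "center"); scl[v] <- attr(z, "scale")
  }
  for (v in zero_inflated) {
    d <- decompose_zero_inflated(covs[[v]])
    if (!d$magnitude_defined) {
      stop("zero-inflated covariate '", v, "' has no positive values")
    }
    ab <- paste0(v, "_absent")
    cols[[ab]] <- d$absence
    cols[[v]] <- d$magnitude
    ctr[ab] <- 0; scl[ab] <- 1
    ctr[v] <- d$center; scl[v] <- if (is.na(d$scale)) 1 else d$scale
    zi_pairs[[v]] <- c(ab, v)
  }
  if (!length(cols)) {
    X <- matrix(numeric(0), nrow = nrow(covs), ncol = 0)
  } else {
    X <- do.call(cbind, cols)
    colnames(X) <- names(cols)
  }
  attr(X, "center") <- ctr
  attr(X, "scale") <- scl
  attr(X, "zi_pairs") <- zi_pairs
  X
}

#' Select design-matrix columns, keeping standardization metadata
#'
#' Plain `[` subsetting drops the `center`/`scale`/`zi_pairs` attributes a
#' [build_design()] matrix carries; this helper keeps them consistent with
#' the selected columns.  A zero-inflated pair must be kept or dropped
#' together.
#'
#' @param X A [build_design()] matrix.
#' @param cols Character vector of columns to keep.
#' @return The column-subset matrix with updated metadata attributes.
#' @export
design_subset <- function(X, cols) {
  stopifnot(is.matrix(X), all(cols %in% colnames(X)))
  zi <- attr(X, "zi_pairs")
  zi_keep <- list()
  for (v in names(zi)) {
    pr <- zi[[v]]
    if (xor(pr[1] %in% cols, pr[2] %in% cols)) {
      stop("zero-inflated pair (", paste(pr, collapse = ", "),
           ") must be selected together")
    }
    if (all(pr %in% cols)) zi_keep[[v]] <- pr
  }
  out <- X[, cols, drop = FALSE]
  attr(out, "center") <- attr(X, "center")[cols]
  attr(out, "scale") <- attr(X, "scale")[cols]
  attr(out, "zi_pairs") <- zi_keep
  out
}
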