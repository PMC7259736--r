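# split-Rhat and effective sample size, computed per parameter across chains

.split_chains <- function(mat_list) {
  out <- list()
  for (m in mat_list) {
    h <- floor(nrow(m) / 2)
    out <- c(out, list(m[seq_len(h), , drop = FALSE],
                       m[h + seq_len(h), , drop = FALSE]))
  }
  out
}

.rhat_one <- function(draws) {
  # draws: iterations x chains (already split)
  m <- ncol(draws); n <- nrow(draws)
  cm <- colMeans(draws)
  if (sd(as.vector(draws)) == 0) return(NA_real_)
  B <- n * var(cm)
  W <- mean(apply(draws, 2, var))
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.ess_one <- function(draws) {
  # Geyer initial-positive-sequence estimator, averaged autocovariances
  m <- ncol(draws); n <- nrow(draws)
  if (sd(as.vector(draws)) == 0) return(NA_real_)
  acov <- sapply(seq_len(m), function(c) {
    x <- draws[, c] - mean(draws[, c])
    out <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE,
                      type = "covariance", demean = FALSE)$acf[, 1, 1]
    out
  })
  acov <- rowMeans(acov)
  var_plus <- acov[1] * n / (n - 1)
  rho <- 1 - (acov[1] - acov[-1]) / var_plus
  # sum paired autocorrelations while the pair sums stay positive
  tau <- 1
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  max(m * n / tau, 1)
}

#' Convergence diagnostics for an occupancy fit
#'
#' Split-Rhat (each chain halved, between/within variance ratio) and an
#' effective-sample-size estimate per stored parameter; parameters with
#' split-Rhat above the threshold are flagged as non-converged, replacing
#' the visual chain inspection used in interactive work.
#'
#' @param fit An `occu_fit`.
#' @param threshold Flagging threshold on split-Rhat.
#' @return Data frame with columns `parameter`, `rhat`, `ess`, `flagged`;
#'   attribute `available` is `FALSE` (with all-NA columns) when the fit
#'   has a single chain, for which between-chain diagnostics are undefined.
#' @export
convergence_diagnostics <- function(fit, threshold = 1.1) {
  stopifnot(inherits(fit, "occu_fit"))
  mats <- lapply(fit$chains, `[[`, "params")
  pn <- colnames(mats[[1]])
  if (length(mats) < 2) {
    out <- data.frame(parameter = pn, rhat = NA_real_, ess = NA_real_,
                      flagged = NA)
    attr(out, "available") <- FALSE
    return(out)
  }
  halves <- .split_chains(mats)
  rhat <- vapply(seq_along(pn), function(j) {
    .rhat_one(sapply(halves, function(h) h[, j]))
  }, 0)
  ess <- vapply(seq_along(pn), function(j) {
    .ess_one(sapply(mats, function(m) m[, j]))
  }, 0)
  out <- data.frame(parameter = pn, rhat = rhat, ess = ess,
                    flagged = is.na(rhat) | rhat > threshold)
  attr(out, "available") <- TRUE
  out
}
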