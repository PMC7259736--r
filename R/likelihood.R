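#' Marginal likelihood of one detection history
#'
#' The single-season occupancy likelihood of a three-count detection
#' history `h` for one survey unit, with the latent occupancy state
#' marginalized out: an occupied unit (probability `psi`) yields
#' independent Bernoulli counts with per-count detection probabilities
#' `p`; an unoccupied unit yields the all-zero history with certainty.
#'
#' \deqn{L(h) = \psi \prod_t p_t^{h_t}(1-p_t)^{1-h_t} +
#'   (1-\psi)\,[h = (0,0,0)]}
#'
#' Summed over the 8 possible histories this is exactly 1 for any valid
#' `(psi, p)`.  The marginal form is used for oracle checks and for the
#' goodness-of-fit expected frequencies; the sampler itself augments the
#' latent state.
#'
#' @param psi Occupancy (use) probability in `[0, 1]`.
#' @param p Detection probability: scalar or length-3 vector in `[0, 1]`.
#' @param h Length-3 binary detection history.
#' @return The likelihood, a probability.
#' @examples
#' unit_likelihood(0.5, 0.5, c(0, 0, 0))  # 0.5625
#' @export
unit_likelihood <- function(psi, p, h) {
  stopifnot(length(psi) == 1, psi >= 0, psi <= 1,
            length(h) == 3, all(h %in% c(0, 1)),
            all(p >= 0), all(p <= 1), length(p) %in% c(1L, 3L))
  p <- rep_len(p, 3L)
  cond <- prod(p^h * (1 - p)^(1 - h))
  psi * cond + (1 - psi) * as.numeric(all(h == 0))
}

# the 8 possible histories, ordered by binary code 000, 001, ..., 111
# (cell index of a history h = 4*h1 + 2*h2 + h3 + 1)
.history_cells <- function() {
  cbind(c1 = rep(0:1, each = 4),
        c2 = rep(rep(0:1, each = 2), 2),
        c3 = rep(0:1, 4))
}

# P(h_c | psi_i, p_i) for all units i and cells c; psi, p length-n vectors
.cell_probs <- function(psi, p) {
  H <- .history_cells()
  k <- rowSums(H)                         # detections per cell
  out <- outer(psi, rep(1, 8)) * outer(p, k, `^`) *
    outer(1 - p, 3 - k, `^`)
  out[, 1] <- out[, 1] + (1 - psi)        # all-zero cell absorbs 1 - psi
  out
}
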