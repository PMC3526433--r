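# -------------------------------------------------------------------------
# Kimura (1980) two-parameter substitution model, equal base frequencies.
#
# Parameterized by the expected transition/transversion ratio
# R = alpha / (2 beta) (each base has one transition target at rate alpha
# and two transversion targets at rate beta each). The rate matrix is
# normalized to one expected substitution per unit branch length:
#   alpha + 2 beta = 1  =>  beta = 1 / (2R + 2), alpha = R / (R + 1).
# Closed-form transition probabilities (base order A, C, G, T; transitions
# A<->G and C<->T):
#   P_same(t) = 1/4 + 1/4 e1 + 1/2 e2
#   P_ti(t)   = 1/4 + 1/4 e1 - 1/2 e2
#   P_tv(t)   = 1/4 - 1/4 e1            (per transversion target)
# with e1 = exp(-4 beta t), e2 = exp(-2 (alpha + beta) t).
# -------------------------------------------------------------------------

k80_rates <- function(tstv = 2) {
  if (!is.numeric(tstv) || tstv <= 0) stop("tstv must be > 0")
  beta <- 1 / (2 * tstv + 2)
  list(alpha = tstv / (tstv + 1), beta = beta)
}

# psame, pti, ptv for a vector of branch lengths; rows = edges
k80_probs <- function(t, tstv = 2) {
  r <- k80_rates(tstv)
  e1 <- exp(-4 * r$beta * t)
  e2 <- exp(-2 * (r$alpha + r$beta) * t)
  cbind(psame = 0.25 + 0.25 * e1 + 0.5 * e2,
        pti   = 0.25 + 0.25 * e1 - 0.5 * e2,
        ptv   = 0.25 - 0.25 * e1)
}

#' K80 transition probability matrix
#'
#' Closed-form transition probabilities of the Kimura (1980) model for a
#' branch of length `t` expected substitutions per site, with equal base
#' frequencies and expected transition/transversion ratio `tstv`.
#'
#' @param t Branch length (expected substitutions/site), `t >= 0`.
#' @param tstv Expected transition/transversion ratio (default 2).
#' @return A 4x4 row-stochastic matrix with dimnames `A, C, G, T`;
#'   `P(0)` is the identity and `P(t)` tends to uniform 1/4 as `t` grows.
#' @export
k80_transition_matrix <- function(t, tstv = 2) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("branch length t must be a single non-negative number")
  }
  pr <- k80_probs(t, tstv)
  ps <- pr[1, "psame"]; pi_ <- pr[1, "pti"]; pv <- pr[1, "ptv"]
  bases <- c("A", "C", "G", "T")
  m <- matrix(pv, 4, 4, dimnames = list(bases, bases))
  diag(m) <- ps
  # transitions: A<->G, C<->T
  m["A", "G"] <- m["G", "A"] <- m["C", "T"] <- m["T", "C"] <- pi_
  m
}

#' Default inheritance-probability grid
#'
#' The candidate inheritance probabilities evaluated when a new
#' reticulation edge is scored: `{0.05, 0.10, ..., 0.50}` by default.
#'
#' @param from,to,by Grid specification; all values must lie strictly in
#'   (0, 1).
#' @return Ascending numeric vector.
#' @export
gamma_grid <- function(from = 0.05, to = 0.5, by = 0.05) {
  g <- seq(from, to, by = by)
  if (any(g <= 0 | g >= 1)) stop("grid values must lie strictly in (0, 1)")
  g
}
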