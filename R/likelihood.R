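# MSORD likelihood: open within-primary sub-model over availability windows
# [a, d] (single entry, single exit per primary), latent states P (present),
# E (temporary emigrant) and dead between primaries, conditional on first
# encounter.

# availability-window masses: pent_a * prod(phi[a..d-1]) * (1 - phi[d]),
# with no departure factor when d == J.  Returns a list of (a, d, mass).
window_masses <- function(pent, phi) {
  pent <- unname(pent); phi <- unname(phi)
  J <- length(pent)
  out <- vector("list", J * (J + 1) / 2); k <- 0L
  for (a in seq_len(J)) {
    running <- pent[a]
    for (d in a:J) {
      mass <- if (d < J) running * (1 - phi[d]) else running
      k <- k + 1L
      out[[k]] <- c(a = a, d = d, mass = mass)
      if (d < J) running <- running * phi[d]
    }
  }
  out
}

# vectorised within-primary emission probabilities for an n x J 0/1 matrix
wpp_all <- function(X, pent, phi, p) {
  J <- length(p); n <- nrow(X)
  if (length(pent) != J || length(phi) != max(J - 1, 0))
    stop_msord("pent/phi/p lengths inconsistent")
  if (abs(sum(pent) - 1) > 1e-8) stop_msord("pent must sum to 1")
  wins <- window_masses(pent, phi)
  has <- rowSums(X) > 0
  lo <- max.col(X, "first"); hi <- max.col(X, "last")
  lo[!has] <- J; hi[!has] <- 1L

  interior <- all(p > 0 & p < 1)
  if (interior) {
    # cumulative row log-emissions allow O(1) window sums
    logM <- X * rep(log(p), each = n) + (1 - X) * rep(log(1 - p), each = n)
    A <- matrix(0, n, J + 1)
    acc <- numeric(n)
    for (j in seq_len(J)) { acc <- acc + logM[, j]; A[, j + 1] <- acc }
  } else {
    M <- X * rep(p, each = n) + (1 - X) * rep(1 - p, each = n)
  }
  res <- numeric(n)
  for (w in wins) {
    a <- w[["a"]]; d <- w[["d"]]; mass <- w[["mass"]]
    if (mass == 0) next
    allowed <- (a <= lo) & (d >= hi)
    if (!any(allowed)) next
    E <- if (interior) exp(A[, d + 1] - A[, a]) else {
      block <- M[, a:d, drop = FALSE]
      apply(block, 1, prod)
    }
    res <- res + mass * E * allowed
  }
  res
}

#' Within-primary detection-vector probability
#'
#' Probability of a secondary detection vector for an animal present (state P)
#' during a primary period, under the open within-primary sub-model: the
#' animal enters the study area once at occasion `a` with probability
#' `pent[a]`, persists occasion-to-occasion with probabilities `phi`, leaves
#' once, and is detected independently with probabilities `p` while available.
#' The probability sums over every availability window compatible with the
#' observed detections; over all `2^J` detection vectors the probabilities
#' sum to 1.
#'
#' @param omega 0/1 detection vector of length J.
#' @param pent entry probabilities, length J, summing to 1.
#' @param phi persistence probabilities, length J - 1.
#' @param p detection probabilities, length J.
#' @return The probability of `omega` given presence.
#' @export
within_primary_prob <- function(omega, pent, phi, p) {
  omega <- as.numeric(omega)
  if (length(omega) != length(p)) stop_msord("omega and p lengths differ")
  if (!all(omega %in% c(0, 1))) stop_msord("omega must be a 0/1 vector")
  wpp_all(matrix(omega, 1), pent, phi, p)[1]
}

#' Probability of at least one detection within a primary period
#'
#' `pstar = 1 - P(all-zero detection vector | present)`; the detectability
#' that converts counts of distinct individuals into marked abundance by
#' Horvitz-Thompson (`N_m = n / pstar`).
#'
#' @inheritParams within_primary_prob
#' @return The per-primary detection probability `pstar`.
#' @export
pstar <- function(pent, phi, p) {
  1 - within_primary_prob(rep(0, length(p)), pent, phi, p)
}

# coerce/validate a natural-scale parameter list against a design
msord_params <- function(params, design) {
  T <- design$n_primary; J <- design$n_secondary
  as_list <- function(x, len_t) {
    if (is.list(x)) x
    else if (is.matrix(x)) lapply(seq_len(T), function(t) x[t, seq_len(len_t[t])])
    else lapply(seq_len(T), function(t) rep_len(x, len_t[t]))
  }
  p <- as_list(params$p, J)
  phi <- as_list(params$phi %||% 1, pmax(J - 1, 0))
  pent <- if (is.list(params$pent)) params$pent
  else if (is.matrix(params$pent)) lapply(seq_len(T), function(t) params$pent[t, seq_len(J[t])])
  else if (is.null(params$pent)) lapply(seq_len(T), function(t) c(1, rep(0, J[t] - 1)))
  else lapply(seq_len(T), function(t) rep_len(params$pent, J[t]))
  for (t in seq_len(T)) {
    check_prob(p[[t]], "p"); check_prob(pent[[t]], "pent")
    if (J[t] > 1) check_prob(phi[[t]], "phi")
    if (abs(sum(pent[[t]]) - 1) > 1e-6)
      stop_msord("pent for primary ", t, " must sum to 1")
  }
  S <- if (T > 1) check_prob(rep_len(params$S %||% 1, T - 1), "S") else numeric(0)
  psiPE <- if (T > 1) check_prob(rep_len(params$psiPE %||% 0, T - 1), "psiPE") else numeric(0)
  psiEE <- if (T > 1) check_prob(rep_len(params$psiEE %||% 0, T - 1), "psiEE") else numeric(0)
  list(S = S, p = p, pent = pent, phi = phi, psiPE = psiPE, psiEE = psiEE)
}

# core forward recursion; X already validated, params in msord_params() form.
# returns per-history log-probabilities
msord_history_loglik <- function(X, params, design) {
  T <- design$n_primary; n <- nrow(X)
  wt <- vector("list", T); det <- matrix(FALSE, n, T); pst <- numeric(T)
  for (t in seq_len(T)) {
    Xt <- X[, design_cols(design, t), drop = FALSE]
    wt[[t]] <- wpp_all(Xt, params$pent[[t]], params$phi[[t]], params$p[[t]])
    det[, t] <- rowSums(Xt) > 0
    pst[t] <- pstar(params$pent[[t]], params$phi[[t]], params$p[[t]])
  }
  if (any(rowSums(det) == 0)) stop_msord("all-zero capture histories are not allowed")
  f <- max.col(det, "first")
  ll <- numeric(n); aP <- aE <- aD <- numeric(n)
  for (t in seq_len(T)) {
    st <- f == t
    if (any(st)) {
      if (pst[t] <= 0) { ll[st] <- -Inf } else {
        ll[st] <- log(wt[[t]][st]) - log(pst[t])
      }
      aP[st] <- 1; aE[st] <- 0; aD[st] <- 0
    }
    act <- f < t
    if (any(act)) {
      S_ <- params$S[t - 1]; pe <- params$psiPE[t - 1]; ee <- params$psiEE[t - 1]
      nP <- (aP * (1 - pe) + aE * (1 - ee)) * S_
      nE <- (aP * pe + aE * ee) * S_
      nD <- aD + (aP + aE) * (1 - S_)
      eED <- as.numeric(!det[, t])
      bP <- nP * wt[[t]]; bE <- nE * eED; bD <- nD * eED
      tot <- bP + bE + bD
      zero <- act & tot <= 0
      pos <- act & tot > 0
      ll[zero] <- -Inf
      ll[pos] <- ll[pos] + log(tot[pos])
      aP[pos] <- bP[pos] / tot[pos]
      aE[pos] <- bE[pos] / tot[pos]
      aD[pos] <- bD[pos] / tot[pos]
    }
  }
  ll
}

#' Log-likelihood of a single MSORD capture history
#'
#' Conditional on first encounter: the primary period of first detection
#' contributes its within-primary probability divided by `pstar` (the animal
#' is known present and detected there); each later inter-primary interval
#' applies apparent survival `S` then the Markov transition between the
#' observable (P) and emigrant (E) states; each later primary emits the
#' within-primary probability in state P and the all-zero vector with
#' probability 1 in states E and dead.
#'
#' @param history 0/1 vector over all secondary occasions (>= 1 detection).
#' @param params natural-scale parameter list with elements `S` (length T - 1
#'   or scalar), `p`, `pent`, `phi` (scalar, matrix, or per-primary lists) and
#'   `psiPE`, `psiEE` (length T - 1 or scalar).
#' @param design a [study_design()].
#' @return The log-probability of the history.
#' @export
history_loglik <- function(history, params, design) {
  X <- matrix(as.numeric(history), 1)
  if (ncol(X) != design$n_occasions) stop_msord("history length does not match design")
  if (sum(X) == 0) stop_msord("history has no detections")
  msord_history_loglik(X, msord_params(params, design), design)[1]
}

#' Total MSORD log-likelihood of a capture matrix
#'
#' Sum of per-history conditional log-likelihoods, optionally weighted
#' (frequency weights; used for collapsed duplicate histories and data
#' cloning).
#'
#' @param data a [capture_matrix()].
#' @param params natural-scale parameters (see [history_loglik()]).
#' @param weights optional per-history weights.
#' @return Total log-likelihood with attribute `"per_history"`.
#' @export
msord_loglik <- function(data, params, weights = NULL) {
  design <- design_of(data)
  weights <- weights %||% rep(1, nrow(data))
  ll <- msord_history_loglik(unclass(data), msord_params(params, design), design)
  if (any(!is.finite(ll))) {
    bad <- which(!is.finite(ll))[1]
    warning("non-finite likelihood for history ", bad, call. = FALSE)
  }
  structure(sum(weights * ll), per_history = ll)
}
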