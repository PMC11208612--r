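#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logL + 2K + 2K(K + 1) / (ess - K - 1)`.  The effective sample
#' size `ess` is, by this package's convention, the number of capture
#' histories.
#'
#' @param logL maximised log-likelihood.
#' @param K number of estimated parameters.
#' @param ess effective sample size (> K + 1).
#' @return The AICc value.
#' @export
aicc <- function(logL, K, ess) {
  if (ess <= K + 1) stop_msord("AICc undefined: ess must exceed K + 1")
  -2 * logL + 2 * K + 2 * K * (K + 1) / (ess - K - 1)
}

#' Quasi-likelihood AICc under overdispersion
#'
#' Replaces `-2 logL` by `-2 logL / c_hat` and counts one extra parameter for
#' the estimated overdispersion factor.
#'
#' @inheritParams aicc
#' @param c_hat variance-inflation factor (capped below at 1).
#' @return The QAICc value.
#' @export
qaicc <- function(logL, K, ess, c_hat) {
  c_hat <- max(c_hat, 1)
  K2 <- K + 1
  if (ess <= K2 + 1) stop_msord("QAICc undefined: ess must exceed K + 2")
  -2 * logL / c_hat + 2 * K2 + 2 * K2 * (K2 + 1) / (ess - K2 - 1)
}

#' Rank fitted models by information criterion
#'
#' Computes delta-AICc against the best model and Akaike weights
#' `w_i = exp(-delta_i / 2) / sum(exp(-delta / 2))`, and flags the candidate
#' set within 2 criterion units of the best model (the model-averaging
#' window).  All fits must be to the same data (matched history counts).
#'
#' @param fits list of [fit_msord()] / [fit_popan()] results (optionally named).
#' @return data.frame of class `model_rank_table`, sorted by criterion, with
#'   columns `model`, `K`, `AICc`, `delta`, `weight`, `in_window`.
#' @export
rank_models <- function(fits) {
  if (inherits(fits, "msord_fit") || inherits(fits, "popan_fit")) fits <- list(fits)
  if (!length(fits)) stop_msord("no fits to rank")
  n <- vapply(fits, `[[`, numeric(1), "n_histories")
  if (length(unique(n)) > 1)
    stop_msord("fits are on different datasets (history counts differ)")
  crit <- vapply(fits, `[[`, numeric(1), "AICc")
  K <- vapply(fits, `[[`, numeric(1), "K")
  nm <- names(fits) %||% vapply(fits, function(f) format(f$structure), character(1))
  nm[!nzchar(nm)] <- vapply(fits[!nzchar(nm)], function(f) format(f$structure), character(1))
  delta <- crit - min(crit)
  w <- exp(-delta / 2); w <- w / sum(w)
  out <- data.frame(model = nm, K = K, AICc = crit, delta = delta,
                    weight = w, in_window = delta <= 2)
  out <- out[order(out$AICc), ]
  rownames(out) <- NULL
  class(out) <- c("model_rank_table", "data.frame")
  attr(out, "fits") <- fits[order(crit)]
  out
}

#' @export
print.model_rank_table <- function(x, ...) {
  cat("Model ranking (", nrow(x), "models )\n")
  print(data.frame(model = x$model, K = x$K, AICc = round(x$AICc, 1),
                   delta = round(x$delta, 1), weight = round(x$weight, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Weighted average of per-model estimates
#'
#' Weight-renormalised average with the unconditional SE combining
#' within-model variance and between-model spread:
#' `se = sqrt(sum(w_i * (se_i^2 + (est_i - avg)^2)))`.
#'
#' @param est,se numeric vectors of per-model estimates and SEs.
#' @param weights model weights (renormalised internally).
#' @return list with `estimate` and `se`.
#' @export
average_estimates <- function(est, se, weights) {
  w <- weights / sum(weights)
  avg <- sum(w * est)
  list(estimate = avg, se = sqrt(sum(w * (se^2 + (est - avg)^2))))
}

#' Model-average natural-scale estimates over the 2-unit window
#'
#' Averages natural-scale parameter estimates across the fits within 2
#' criterion units of the best model, using renormalised Akaike weights; a
#' single-model window is the identity.  All fits must report the same
#' parameter set (identical structures up to the parameters shared).
#'
#' @param fits list of [fit_msord()] results (the window set), or a
#'   `model_rank_table` from which the window is taken.
#' @return data.frame `parameter`, `estimate`, `se` (unconditional).
#' @export
model_average <- function(fits) {
  if (inherits(fits, "model_rank_table")) {
    tab <- fits
    fits <- attr(tab, "fits")[tab$in_window]
    weights <- tab$weight[tab$in_window]
  } else {
    tab <- rank_models(fits)
    fits <- attr(tab, "fits")[tab$in_window]
    weights <- tab$weight[tab$in_window]
  }
  if (length(fits) == 1) {
    nat <- fits[[1]]$natural
    return(data.frame(parameter = nat$parameter, estimate = nat$estimate,
                      se = nat$se))
  }
  pn <- lapply(fits, function(f) f$natural$parameter)
  common <- Reduce(intersect, pn)
  if (!length(common))
    stop_msord("fits share no reporting parameters; cannot average")
  rows <- lapply(common, function(nm) {
    est <- vapply(fits, function(f) f$natural$estimate[f$natural$parameter == nm], numeric(1))
    se <- vapply(fits, function(f) f$natural$se[f$natural$parameter == nm], numeric(1))
    av <- average_estimates(est, se, weights)
    data.frame(parameter = nm, estimate = av$estimate, se = av$se)
  })
  do.call(rbind, rows)
}
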