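# Jolly-Seber POPAN super-population likelihood on pooled seasonal occasions.

popan_prep <- function(params, T) {
  list(
    N = params$N,
    pent = {
      pe <- params$pent
      if (length(pe) != T) stop_msord("pent must have length T")
      if (abs(sum(pe) - 1) > 1e-6) stop_msord("pent must sum to 1")
      pe
    },
    S = rep_len(params$S, T - 1),
    p = rep_len(params$p, T))
}

#' POPAN log-likelihood
#'
#' Full Schwarz-Arnason likelihood on pooled occasions: animals enter the
#' population at occasion `b` with probability `pent[b]`, survive intervals
#' with probabilities `S`, and are detected with probabilities `p`.  The
#' likelihood multiplies each observed history's probability (entry before or
#' at first detection, survival through last detection, and never-seen-again
#' tail) by the binomial term for the `N - D` super-population members never
#' detected, `D` being the number of distinct animals observed.
#'
#' @param pooled a `pooled_matrix` (see [pool_primaries()]) or 0/1 matrix with
#'   T >= 2 occasion columns.
#' @param params list with `N` (super-population size, >= number observed),
#'   `pent` (length T, sums to 1), `S` (length T - 1 or scalar), `p` (length T
#'   or scalar).
#' @return Total log-likelihood.
#' @export
popan_loglik <- function(pooled, params) {
  X <- unclass(as.matrix(pooled))
  T <- ncol(X); D <- nrow(X)
  if (T < 2) stop_msord("POPAN needs >= 2 occasions")
  pp <- popan_prep(params, T)
  if (pp$N < D) stop_msord("N below the number of distinct animals observed")
  # collapse duplicate histories into counts
  key <- apply(X, 1, paste, collapse = "")
  cnt <- c(table(key))
  X <- X[match(names(cnt), key), , drop = FALSE]
  with(pp, {
    # zeta[b]: P(never detected | enters at b); chi[l]: P(never seen after l)
    zeta <- numeric(T); zeta[T] <- 1 - p[T]
    if (T > 1) for (b in (T - 1):1)
      zeta[b] <- (1 - p[b]) * ((1 - S[b]) + S[b] * zeta[b + 1])
    chi <- numeric(T); chi[T] <- 1
    if (T > 1) for (l in (T - 1):1)
      chi[l] <- (1 - S[l]) + S[l] * zeta[l + 1]
    P0 <- sum(pent * zeta)

    ll_hist <- vapply(seq_len(nrow(X)), function(i) {
      x <- X[i, ]
      f <- which(x == 1)[1]; l <- max(which(x == 1))
      # entry at b <= f, alive and undetected b..f-1
      entry <- 0
      for (b in seq_len(f)) {
        pr <- pent[b]
        if (b < f) pr <- pr * prod((1 - p[b:(f - 1)]) * S[b:(f - 1)])
        entry <- entry + pr
      }
      mid <- prod(ifelse(x[f:l] == 1, p[f:l], 1 - p[f:l]))
      surv <- if (l > f) prod(S[f:(l - 1)]) else 1
      log(entry) + log(mid) + log(surv) + log(chi[l])
    }, numeric(1))
    lgamma(N + 1) - lgamma(N - D + 1) - lgamma(D + 1) +
      (N - D) * log(P0) + sum(cnt * ll_hist)
  })
}

#' Specify a POPAN model structure
#'
#' Variation over pooled occasions for each parameter: `"constant"` (`.`) or
#' `"season"` (by occasion / interval).
#'
#' @param p,S,pent `"constant"` or `"season"`.
#' @return An object of class `popan_structure`.
#' @export
popan_structure <- function(p = "constant", S = "constant", pent = "constant") {
  norm <- function(x) {
    if (x %in% c(".", "constant")) "constant"
    else if (x %in% c("season", "t", "time")) "season"
    else stop_msord("POPAN variation must be 'constant' or 'season'")
  }
  structure(list(p = norm(p), S = norm(S), pent = norm(pent)),
            class = "popan_structure")
}

#' @export
format.popan_structure <- function(x, ...) {
  sh <- function(v) if (v == "constant") "." else "season"
  sprintf("p(%s) S(%s) pent(%s)", sh(x$p), sh(x$S), sh(x$pent))
}

#' @export
print.popan_structure <- function(x, ...) {
  cat("POPAN structure:", format(x), "\n"); invisible(x)
}

#' Fit a POPAN (Jolly-Seber super-population) model
#'
#' Maximum likelihood over the super-population size `N` (log link offset by
#' the observed count), entry proportions (multinomial logit) and logit-scaled
#' survival and detection.  Known Jolly-Seber confounding under full time
#' variation of all parameters (entry/detection at the boundary occasions) is
#' flagged.  An optional `c_hat > 1` switches ranking to QAICc and inflates
#' reported SEs by `sqrt(c_hat)`.
#'
#' @param pooled a `pooled_matrix` (see [pool_primaries()]).
#' @param structure a [popan_structure()] or string such as
#'   `"p(season) S(.) pent(.)"`.
#' @param fixed optional named list fixing parameters at known values
#'   (e.g. `list(S = 1, pent = c(1, 0))`); fixed blocks are removed from the
#'   free parameter vector.
#' @param c_hat overdispersion factor (>= 1) for QAICc and SE inflation.
#' @param n_restarts,seed,ess,control as in [fit_msord()].
#' @return An object of class `popan_fit` with `N_super`, `se_N_super` and
#'   log-normal CI among its elements.
#' @export
fit_popan <- function(pooled, structure = popan_structure(), fixed = list(),
                      c_hat = 1, n_restarts = 3, seed = 1, ess = NULL,
                      control = list()) {
  if (is.character(structure)) {
    toks <- regmatches(structure, gregexpr("[A-Za-z]+\\(([^)]*)\\)", structure))[[1]]
    gv <- function(nm) {
      hit <- toks[grepl(paste0("^", nm, "\\("), toks, ignore.case = TRUE)]
      if (!length(hit)) "." else sub("^[A-Za-z]+\\(([^)]*)\\)$", "\\1", hit[1])
    }
    structure <- popan_structure(p = gv("p"), S = gv("S"), pent = gv("pent"))
  }
  X <- unclass(as.matrix(pooled))
  T <- ncol(X); D <- nrow(X)
  if (T < 2) stop_msord("POPAN needs >= 2 occasions")
  if (c_hat < 1) c_hat <- 1

  if (structure$p == "season" && structure$S == "season" &&
      structure$pent == "season")
    warning("fully time-varying POPAN: boundary entry/detection parameters ",
            "are confounded (non-identifiable structure)", call. = FALSE)

  blocks <- list(logN = "logNminusD")
  if (!"p" %in% names(fixed))
    blocks$p <- if (structure$p == "season") paste0("p_", seq_len(T)) else "p"
  if (!"S" %in% names(fixed))
    blocks$S <- if (structure$S == "season") paste0("S_", seq_len(T - 1)) else "S"
  if (!"pent" %in% names(fixed))
    blocks$pent <- if (structure$pent == "season") paste0("pent_", 2:T) else "pent"
  parnames <- unlist(blocks, use.names = FALSE)
  K_free <- length(parnames)

  expand <- function(theta) {
    ix <- split(seq_along(theta), rep(names(blocks), lengths(blocks)))
    N <- unname(D + exp(theta[ix$logN]))
    p <- if ("p" %in% names(fixed)) rep_len(fixed$p, T)
         else rep_len(unname(invlogit(theta[ix$p])), T)
    S <- if ("S" %in% names(fixed)) rep_len(fixed$S, T - 1)
         else rep_len(unname(invlogit(theta[ix$S])), T - 1)
    pent <- if ("pent" %in% names(fixed)) fixed$pent
    else if (structure$pent == "season") softmax1(unname(theta[ix$pent]))
    else softmax1(rep(theta[ix$pent], T - 1))  # one shared entry cell, occ 1 as reference
    list(N = N, p = p, S = S, pent = pent)
  }
  negll <- function(theta) {
    v <- tryCatch(-popan_loglik(X, expand(theta)), error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }

  start <- stats::setNames(numeric(K_free), parnames)
  start[1] <- log(max(D * 0.5, 1))
  if (!is.null(blocks$p)) start[blocks$p] <- logit(0.5)
  if (!is.null(blocks$S)) start[blocks$S] <- logit(0.85)
  ctrl <- utils::modifyList(list(maxit = 1000, reltol = 1e-12), control)
  fits <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    th0 <- start
    if (r > 1) { set.seed(derive_seed(seed, 100 + r)); th0 <- th0 + stats::rnorm(K_free, sd = 0.5) }
    fits[[r]] <- tryCatch(stats::optim(th0, negll, method = "BFGS", control = ctrl),
                          error = function(e) list(value = Inf, convergence = 99L))
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  theta <- stats::setNames(best$par, parnames)
  converged <- is.finite(best$value) && best$convergence == 0L

  H <- tryCatch(stats::optimHess(theta, negll,
                                 control = list(ndeps = rep(1e-4, K_free))),
                error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  vcov_ok <- !is.null(V) && all(is.finite(diag(V))) && all(diag(V) >= 0)
  if (!vcov_ok) V <- matrix(NA_real_, K_free, K_free)
  dimnames(V) <- list(parnames, parnames)

  pars <- expand(theta)
  logLik <- popan_loglik(X, pars)
  # delta method: dN/dtheta1 = exp(theta1) = N - D; inflate by sqrt(c_hat)
  se_N <- if (vcov_ok) (pars$N - D) * sqrt(V[1, 1]) * sqrt(c_hat) else NA_real_
  ess <- ess %||% D
  K_crit <- if (c_hat > 1) K_free + 1 else K_free
  crit <- if (c_hat > 1) qaicc(logLik, K_free, ess, c_hat) else aicc(logLik, K_free, ess)
  ci <- if (is.finite(se_N)) lognormal_ci(pars$N, se_N) else c(low = NA, high = NA)

  structure(list(
    call = match.call(), structure = structure, fixed = fixed, T = T, D = D,
    par = theta, vcov_link = V, vcov_ok = vcov_ok, params = pars,
    logLik = logLik, K = K_free, K_crit = K_crit, ess = ess, c_hat = c_hat,
    AICc = crit, criterion = if (c_hat > 1) "QAICc" else "AICc",
    N_super = pars$N, se_N_super = se_N, ci_N_super = ci,
    convergence = converged, boundary = any(abs(theta[-1]) > 8),
    n_histories = D, optim = best, seed = seed
  ), class = "popan_fit")
}

#' @export
print.popan_fit <- function(x, ...) {
  cat("POPAN fit:", format(x$structure), "\n")
  cat(sprintf("  %d animals observed over %d occasions; logLik %.3f; %s %.3f\n",
              x$D, x$T, x$logLik, x$criterion, x$AICc))
  cat(sprintf("  N_super (marked) = %.1f (SE %.2f, 95%% CI %.0f-%.0f)\n",
              x$N_super, x$se_N_super, x$ci_N_super[1], x$ci_N_super[2]))
  if (!x$convergence) cat("  WARNING: optimisation did not converge\n")
  invisible(x)
}

#' @export
summary.popan_fit <- function(object, ...) object

#' @export
coef.popan_fit <- function(object, ...) {
  c(N_super = object$N_super, p = object$params$p, S = object$params$S,
    pent = object$params$pent)
}

#' @export
vcov.popan_fit <- function(object, ...) object$vcov_link

#' @export
logLik.popan_fit <- function(object, ...) {
  structure(object$logLik, df = object$K, nobs = object$D, class = "logLik")
}
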