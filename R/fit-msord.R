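#' Fit a multi-state open robust design model
#'
#' Maximum-likelihood fit of the MSORD to robust-design capture histories,
#' conditional on first encounter.  Probabilities are estimated on the logit
#' scale (entry vectors on the multinomial-logit scale, first occasion as
#' reference) by quasi-Newton optimisation with finite-difference gradients
#' and multiple jittered restarts; standard errors come from the inverse
#' Hessian, propagated through the links by the delta method.  The emigration
#' regime is imposed structurally: `random` shares a single transition
#' parameter per interval (`psiPE == psiEE`), `none` fixes both at 0.
#'
#' The fit carries derived quantities: per-primary marked abundance
#' `N_m = n_t / pstar_t` with delta-method SEs (with and without the
#' Horvitz-Thompson binomial component), transition complements, and expected
#' residence time (secondary occasions present per primary).
#'
#' @param data a [capture_matrix()].
#' @param structure an [msord_structure()] or a structure string such as
#'   `"S(.) p(.) pent(season.day) phi(season.day) psi(Markovian)"`.
#' @param weights optional frequency weights per history (data cloning,
#'   collapsed duplicates).
#' @param start optional link-scale start vector.
#' @param n_restarts number of jittered restarts (>= 1).
#' @param seed integer seed controlling the restart jitter; fits are
#'   deterministic given data, structure and seed.
#' @param ess effective sample size for AICc (default: number of capture
#'   histories, counting frequency weights).
#' @param control passed to [stats::optim()] (`reltol` defaults to 1e-10).
#' @return An object of class `msord_fit`.
#' @seealso [derive_abundance()], [derived_transitions()], [residence_time()]
#' @export
fit_msord <- function(data, structure, weights = NULL, start = NULL,
                      n_restarts = 3, seed = 1, ess = NULL, control = list()) {
  if (is.character(structure)) structure <- msord_structure(structure)
  if (!inherits(structure, "msord_structure")) stop_msord("invalid structure")
  design <- design_of(data)
  if (nrow(data) < 1) stop_msord("no capture histories to fit")
  w0 <- weights %||% rep(1, nrow(data))

  # collapse duplicate histories into frequency weights
  key <- apply(unclass(data), 1, paste, collapse = "")
  agg <- rowsum(w0, key)
  X <- unclass(data)[match(rownames(agg), key), , drop = FALSE]
  w <- as.numeric(agg)

  map <- msord_par_map(structure, design)
  parnames <- unlist(map, use.names = FALSE)
  K <- length(parnames)
  negll <- function(theta) {
    pl <- expand_msord(theta, structure, design)
    ll <- msord_history_loglik(X, pl, design)
    v <- -sum(w * ll)
    if (!is.finite(v)) 1e10 else v
  }

  base_start <- start %||% msord_start(structure, design)
  if (length(base_start) != K) stop_msord("start vector must have length ", K)
  ctrl <- utils::modifyList(list(maxit = 1000, reltol = 1e-8), control)
  fits <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    th0 <- base_start
    if (r > 1) {
      set.seed(derive_seed(seed, r))
      th0 <- th0 + stats::rnorm(K, sd = 0.7)
    }
    fits[[r]] <- tryCatch(
      stats::optim(th0, negll, method = "BFGS", control = ctrl),
      error = function(e) list(value = Inf, convergence = 99L))
  }
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  converged <- is.finite(best$value) && best$convergence == 0L
  theta <- stats::setNames(best$par, parnames)
  boundary <- any(abs(theta) > 8)

  H <- tryCatch(stats::optimHess(theta, negll,
                                 control = list(ndeps = rep(1e-4, K))),
                error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) < 0)) {
    vcov_ok <- FALSE
    V <- matrix(NA_real_, K, K)
  } else vcov_ok <- TRUE
  dimnames(V) <- list(parnames, parnames)

  # natural-scale estimates with delta-method SEs
  natf <- function(th) flatten_msord(expand_msord(th, structure, design), design)
  nat <- natf(theta)
  G <- num_jacobian(natf, theta)
  se_nat <- if (vcov_ok) sqrt(pmax(rowSums((G %*% V) * G), 0)) else rep(NA_real_, length(nat))
  natural <- data.frame(parameter = names(nat), estimate = unname(nat),
                        se = unname(se_nat), row.names = NULL)

  params <- expand_msord(theta, structure, design)
  ll <- msord_history_loglik(X, params, design)
  logLik <- sum(w * ll)
  ess <- ess %||% sum(w0)

  fit <- structure(list(
    call = match.call(), structure = structure, design = design,
    data = capture_matrix(X, design, ids = paste0("h", seq_len(nrow(X)))),
    weights = w, n_histories = sum(w0), par = theta, vcov_link = V,
    vcov_ok = vcov_ok, natural = natural, params = params,
    logLik = logLik, K = K, ess = ess,
    AICc = aicc(logLik, K, ess),
    convergence = converged, boundary = boundary,
    optim = best, n_restarts = n_restarts, seed = seed
  ), class = "msord_fit")
  fit$derived <- msord_derived(fit)
  if (!converged) warning("MSORD fit did not converge after ", n_restarts,
                          " restart(s)", call. = FALSE)
  fit
}

# flatten natural-scale parameters to a named vector (delta-method target)
flatten_msord <- function(pl, design) {
  T <- design$n_primary
  out <- c(
    if (T > 1) stats::setNames(pl$S, paste0("S_", seq_len(T - 1))),
    unlist(lapply(seq_len(T), function(t)
      stats::setNames(pl$p[[t]], paste0("p_", t, ".", seq_along(pl$p[[t]]))))),
    unlist(lapply(seq_len(T), function(t)
      stats::setNames(pl$pent[[t]], paste0("pent_", t, ".", seq_along(pl$pent[[t]]))))),
    unlist(lapply(seq_len(T), function(t)
      if (length(pl$phi[[t]]))
        stats::setNames(pl$phi[[t]], paste0("phi_", t, ".", seq_along(pl$phi[[t]]))))),
    if (T > 1) stats::setNames(pl$psiPE, paste0("psiPE_", seq_len(T - 1))),
    if (T > 1) stats::setNames(pl$psiEE, paste0("psiEE_", seq_len(T - 1))))
  out
}

num_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  G <- matrix(0, length(f0), length(x), dimnames = list(names(f0), names(x)))
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- x[k] + h
    xm <- x; xm[k] <- x[k] - h
    G[, k] <- (f(xp) - f(xm)) / (2 * h)
  }
  G
}

# derived per-primary quantities computed once at fit time
msord_derived <- function(fit) {
  design <- fit$design; T <- design$n_primary
  X <- unclass(fit$data); w <- fit$weights
  n_t <- vapply(seq_len(T), function(t)
    sum(w * (rowSums(X[, design_cols(design, t), drop = FALSE]) > 0)), numeric(1))
  pst_fun <- function(th) {
    pl <- expand_msord(th, fit$structure, design)
    vapply(seq_len(T), function(t)
      pstar(pl$pent[[t]], pl$phi[[t]], pl$p[[t]]), numeric(1))
  }
  pst <- pst_fun(fit$par)
  Gp <- num_jacobian(pst_fun, fit$par)
  var_pst <- if (fit$vcov_ok) pmax(rowSums((Gp %*% fit$vcov_link) * Gp), 0)
             else rep(NA_real_, T)
  undef <- pst < 1e-8
  N_m <- ifelse(undef, NA_real_, n_t / pst)
  var_model <- (n_t / pst^2)^2 * var_pst
  var_ht <- n_t * (1 - pst) / pst^2
  abundance <- data.frame(
    period = design$labels, n = n_t, pstar = pst, se_pstar = sqrt(var_pst),
    N_m = N_m,
    se_N_m = sqrt(var_model + var_ht),
    se_N_m_model = sqrt(var_model),
    flagged = undef)

  pl <- fit$params
  residence <- vapply(seq_len(T), function(t) {
    wins <- window_masses(pl$pent[[t]], pl$phi[[t]])
    sum(vapply(wins, function(wn) wn[["mass"]] * (wn[["d"]] - wn[["a"]] + 1), numeric(1)))
  }, numeric(1))
  names(residence) <- design$labels

  transitions <- NULL
  if (T > 1 && fit$structure$emigration != "none") {
    nat <- fit$natural
    get_se <- function(nm) {
      i <- match(nm, nat$parameter)
      ifelse(is.na(i), NA_real_, nat$se[i])
    }
    iv <- seq_len(T - 1)
    transitions <- data.frame(
      interval = paste(design$labels[iv], design$labels[iv + 1], sep = " -> "),
      psiPE = pl$psiPE, se_psiPE = get_se(paste0("psiPE_", iv)),
      psiEE = pl$psiEE, se_psiEE = get_se(paste0("psiEE_", iv)),
      psiPP = 1 - pl$psiPE, psiEP = 1 - pl$psiEE)
    transitions$se_psiPP <- transitions$se_psiPE
    transitions$se_psiEP <- transitions$se_psiEE
  }
  list(abundance = abundance, residence = residence, transitions = transitions)
}

#' Derived marked abundance per primary period
#'
#' Horvitz-Thompson estimates `N_m = n_t / pstar_t`, where `n_t` is the number
#' of distinct individuals detected in primary `t` and `pstar_t` the fitted
#' probability of at least one detection for an animal present.  The default
#' SE combines the delta-method variance of `pstar` with the binomial
#' Horvitz-Thompson component `n_t (1 - pstar) / pstar^2`; the model-only
#' variant (`se_N_m_model`) is reported alongside.
#'
#' @param fit an [fit_msord()] result.
#' @return data.frame with columns `period`, `n`, `pstar`, `N_m`, `se_N_m`,
#'   `se_N_m_model`, `flagged` (near-zero `pstar`).
#' @export
derive_abundance <- function(fit) {
  stopifnot(inherits(fit, "msord_fit"))
  fit$derived$abundance
}

#' Derived transition complements
#'
#' Transition probabilities out of each state sum to 1, so the return and
#' stay-present probabilities follow by subtraction: `psiPP = 1 - psiPE`,
#' `psiEP = 1 - psiEE`; their delta-method SEs equal the source SEs.
#'
#' @param fit an [fit_msord()] result with emigration regime other than `none`.
#' @return data.frame per inter-primary interval.
#' @export
derived_transitions <- function(fit) {
  stopifnot(inherits(fit, "msord_fit"))
  if (is.null(fit$derived$transitions))
    stop_msord("no transition parameters (emigration = none)")
  fit$derived$transitions
}

#' Expected residence time per primary period
#'
#' Expected number of secondary occasions an animal spends available within a
#' primary, `E(d - a + 1)` under the fitted entry/persistence window
#' distribution.
#'
#' @param fit an [fit_msord()] result.
#' @return Named numeric vector, one expectation per primary period.
#' @export
residence_time <- function(fit) {
  stopifnot(inherits(fit, "msord_fit"))
  fit$derived$residence
}

#' @export
print.msord_fit <- function(x, ...) {
  cat("MSORD fit:", format(x$structure), "\n")
  cat(sprintf("  %d histories, %d parameters, logLik %.3f, AICc %.3f\n",
              x$n_histories, x$K, x$logLik, x$AICc))
  if (!x$convergence) cat("  WARNING: optimisation did not converge\n")
  if (x$boundary) cat("  note: boundary estimate(s) on the link scale\n")
  invisible(x)
}

#' @export
summary.msord_fit <- function(object, ...) {
  out <- list(structure = format(object$structure), K = object$K,
              logLik = object$logLik, AICc = object$AICc,
              convergence = object$convergence, boundary = object$boundary,
              natural = object$natural, abundance = object$derived$abundance,
              transitions = object$derived$transitions,
              residence = object$derived$residence)
  class(out) <- "summary.msord_fit"
  out
}

#' @export
print.summary.msord_fit <- function(x, ...) {
  cat("MSORD fit:", x$structure, "\n")
  cat(sprintf("logLik %.3f on %d parameters; AICc %.3f\n", x$logLik, x$K, x$AICc))
  cat("\nDerived marked abundance:\n")
  print(x$abundance, digits = 4, row.names = FALSE)
  if (!is.null(x$transitions)) {
    cat("\nTransitions (temporary emigration):\n")
    print(x$transitions, digits = 3, row.names = FALSE)
  }
  cat("\nExpected residence time (secondary occasions):\n")
  print(round(x$residence, 2))
  invisible(x)
}

#' @export
coef.msord_fit <- function(object, type = c("natural", "link"), ...) {
  type <- match.arg(type)
  if (type == "link") object$par
  else stats::setNames(object$natural$estimate, object$natural$parameter)
}

#' @export
vcov.msord_fit <- function(object, ...) object$vcov_link

#' @export
logLik.msord_fit <- function(object, ...) {
  structure(object$logLik, df = object$K, nobs = object$n_histories,
            class = "logLik")
}

#' @export
plot.msord_fit <- function(x, ...) {
  ab <- x$derived$abundance
  ci <- t(mapply(lognormal_ci, ab$N_m, ab$se_N_m))
  idx <- seq_len(nrow(ab))
  graphics::plot(idx, ab$N_m, ylim = range(0, ci, na.rm = TRUE), xaxt = "n",
                 xlab = "primary period", ylab = expression(hat(N)[m]),
                 pch = 19, ...)
  graphics::axis(1, at = idx, labels = ab$period, las = 2, cex.axis = 0.8)
  graphics::arrows(idx, ci[, 1], idx, ci[, 2], angle = 90, code = 3, length = 0.04)
  invisible(x)
}

#' @export
simulate.msord_fit <- function(object, nsim = 1, seed = NULL,
                               n_individuals = NULL, ...) {
  n <- n_individuals %||% object$n_histories
  out <- lapply(seq_len(nsim), function(k)
    simulate_msord(object$params, object$design, n,
                   seed = derive_seed(seed %||% 1, k))$data)
  if (nsim == 1) out[[1]] else out
}
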