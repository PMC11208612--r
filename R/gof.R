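# goodness-of-fit: per-primary CJS deviance c-hat, RELEASE-style contingency
# tests, and data-cloning identifiability checks.

# m-array cell probabilities under time-varying CJS (phi length T-1, p length
# T; p[1] unused)
cjs_cell_probs <- function(phi, p) {
  T <- length(p)
  pi <- matrix(0, T - 1, T)
  for (i in seq_len(T - 1)) {
    for (j in (i + 1):T) {
      surv <- prod(phi[i:(j - 1)])
      miss <- if (j > i + 1) prod(1 - p[(i + 1):(j - 1)]) else 1
      pi[i, j] <- surv * miss * p[j]
    }
  }
  pi
}

cjs_marray_loglik <- function(ma, phi, p) {
  pi <- cjs_cell_probs(phi, p)
  chi <- 1 - rowSums(pi)
  ll <- 0
  for (i in seq_along(ma$releases)) {
    for (j in seq_len(ncol(ma$m))) if (ma$m[i, j] > 0) ll <- ll + ma$m[i, j] * log(pi[i, j])
    if (ma$never[i] > 0) ll <- ll + ma$never[i] * log(max(chi[i], 1e-300))
  }
  ll
}

#' Fit a fully time-varying Cormack-Jolly-Seber model
#'
#' Conditional (on first release) CJS maximum likelihood via the reduced
#' m-array multinomial, with deviance measured against the saturated
#' multinomial.  Used per primary period to compute the overdispersion factor
#' `c_hat = deviance / df`.  The terminal `phi * p` product is confounded, so
#' the identifiable parameter count is `2(T - 1) - 1`.
#'
#' @param x 0/1 detection matrix (individuals x occasions, >= 3 occasions);
#'   all-zero rows are dropped.
#' @param n_restarts,seed optimisation controls.
#' @return An object of class `cjs_fit`: `phi`, `p`, `logLik`, `deviance`,
#'   `df`, `c_hat`, `m_array`, `K`.
#' @export
cjs_fit <- function(x, n_restarts = 2, seed = 1) {
  x <- unclass(as.matrix(x))
  x <- x[rowSums(x) > 0, , drop = FALSE]
  T <- ncol(x)
  if (T < 3) stop_msord("time-varying CJS needs >= 3 occasions")
  ma <- m_array(x)
  npar <- 2 * (T - 1)   # phi_1..T-1, p_2..T (one confounded pair)
  negll <- function(theta) {
    phi <- invlogit(theta[seq_len(T - 1)])
    p <- c(0, invlogit(theta[T:(2 * T - 2)]))
    v <- -cjs_marray_loglik(ma, phi, p)
    if (!is.finite(v)) 1e10 else v
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    th0 <- rep(logit(0.6), npar)
    if (r > 1) { set.seed(derive_seed(seed, 200 + r)); th0 <- th0 + stats::rnorm(npar, sd = 0.8) }
    f <- tryCatch(stats::optim(th0, negll, method = "BFGS",
                               control = list(maxit = 500, reltol = 1e-12)),
                  error = function(e) list(value = Inf))
    if (is.null(best) || f$value < best$value) best <- f
  }
  phi <- invlogit(best$par[seq_len(T - 1)])
  p <- c(NA, invlogit(best$par[T:(2 * T - 2)]))
  ll_fit <- -best$value

  # saturated multinomial per release cohort
  ll_sat <- 0; cells <- 0L; rows_used <- 0L
  for (i in seq_along(ma$releases)) {
    R <- ma$releases[i]
    if (R == 0) next
    counts <- c(ma$m[i, ], ma$never[i])
    pr <- counts / R
    ll_sat <- ll_sat + sum(counts[counts > 0] * log(pr[counts > 0]))
    cells <- cells + (T - i + 1L)   # (T - i) recapture cells + never cell
    rows_used <- rows_used + 1L
  }
  deviance <- max(2 * (ll_sat - ll_fit), 0)
  K_ident <- 2 * (T - 1) - 1
  df <- max((cells - rows_used) - K_ident, 0L)
  structure(list(phi = phi, p = p, logLik = ll_fit, deviance = deviance,
                 df = df, c_hat = if (df > 0) deviance / df else NA_real_,
                 m_array = ma, K = K_ident, n = nrow(x), T = T),
            class = "cjs_fit")
}

#' @export
print.cjs_fit <- function(x, ...) {
  cat(sprintf("time-varying CJS: %d animals, %d occasions; deviance %.2f on %d df (c-hat %.2f)\n",
              x$n, x$T, x$deviance, x$df, x$c_hat))
  invisible(x)
}

#' Combine chi-square components into a global c-hat
#'
#' The global overdispersion factor is the ratio of summed components,
#' `sum(chisq) / sum(df)` -- not the mean of per-component ratios.
#'
#' @param chisq,df numeric vectors of per-component chi-square values and
#'   degrees of freedom.
#' @return The pooled `c_hat`.
#' @export
global_c_hat <- function(chisq, df) {
  if (sum(df) <= 0) stop_msord("no degrees of freedom to pool")
  sum(chisq) / sum(df)
}

#' Per-primary CJS deviance c-hat and its global pool
#'
#' Runs a fully time-varying CJS model on the secondary occasions of each
#' primary period (animals detected in that primary) and reports
#' `c_hat = deviance / df` per primary; the global factor pools components as
#' `sum(deviance) / sum(df)`.  Primaries with zero residual df are excluded
#' with a warning.
#'
#' @param data a [capture_matrix()].
#' @return data.frame of class `gof_report` with one row per usable primary
#'   and attributes `global_chisq`, `global_df`, `global_c_hat`.
#' @export
median_c_hat <- function(data) {
  design <- design_of(data)
  rows <- list()
  for (t in seq_len(design$n_primary)) {
    Xt <- unclass(data)[, design_cols(design, t), drop = FALSE]
    Xt <- Xt[rowSums(Xt) > 0, , drop = FALSE]
    if (ncol(Xt) < 3 || nrow(Xt) < 2) next
    ft <- tryCatch(cjs_fit(Xt), error = function(e) NULL)
    if (is.null(ft)) next
    if (ft$df == 0) {
      warning("primary ", design$labels[t], " has zero residual df; excluded",
              call. = FALSE)
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      period = design$labels[t], n = ft$n, deviance = ft$deviance,
      df = ft$df, c_hat = ft$c_hat)
  }
  if (!length(rows)) stop_msord("no primary period yields a usable CJS fit")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "global_chisq") <- sum(out$deviance)
  attr(out, "global_df") <- sum(out$df)
  attr(out, "global_c_hat") <- global_c_hat(out$deviance, out$df)
  class(out) <- c("gof_report", "data.frame")
  out
}

#' @export
print.gof_report <- function(x, ...) {
  cat("Per-primary CJS goodness of fit:\n")
  print(data.frame(period = x$period, n = x$n, deviance = round(x$deviance, 2),
                   df = x$df, c_hat = round(x$c_hat, 2)), row.names = FALSE)
  cat(sprintf("Global: chisq %.1f on %d df; c-hat = %.2f\n",
              attr(x, "global_chisq"), attr(x, "global_df"),
              attr(x, "global_c_hat")))
  invisible(x)
}

pearson_chisq <- function(tab, min_expected = 2) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NULL)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < min_expected)) return(NULL)
  list(chisq = sum((tab - expected)^2 / expected),
       df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

#' RELEASE-style contingency tests on pooled occasions
#'
#' Component contingency tests for the assumptions of equal catchability and
#' equal survival, built from seen/not-seen pooled histories:
#'
#' * **TEST 2** (capture heterogeneity): for each interval, among animals
#'   detected at least once up to occasion i and at least once from i + 1 on,
#'   a 2x2 table of capture at i versus capture at i + 1; under homogeneous
#'   detection the two are independent.
#' * **TEST 3** (survival heterogeneity): for each occasion, among animals
#'   detected at i, a 2x2 table of newly-versus-previously encountered against
#'   ever-detected-again versus not; under equal survival and detection, fate
#'   is independent of capture history.
#'
#' Sub-tables with any expected count below `min_expected` (or an empty
#' margin) are dropped; chi-square components and df are summed over the
#' retained tables.
#'
#' @param pooled a `pooled_matrix` (or 0/1 matrix, >= 3 occasions).
#' @param min_expected minimum expected cell count for a sub-table to enter.
#' @return An object of class `release_tests`: lists `test2` and `test3`,
#'   each with `chisq`, `df`, `c_hat`, `n_tables`.
#' @export
release_tests <- function(pooled, min_expected = 2) {
  X <- unclass(as.matrix(pooled))
  T <- ncol(X)
  if (T < 3) stop_msord("component tests need >= 3 pooled occasions")
  first <- max.col(X, "first")

  t2 <- list(); t3 <- list()
  for (i in seq_len(T - 1)) {
    seen_before <- rowSums(X[, seq_len(i), drop = FALSE]) > 0
    seen_after <- rowSums(X[, (i + 1):T, drop = FALSE]) > 0
    sel <- seen_before & seen_after
    if (sum(sel) >= 4) {
      tab <- table(factor(X[sel, i], levels = 0:1),
                   factor(X[sel, i + 1], levels = 0:1))
      r <- pearson_chisq(unclass(tab), min_expected)
      if (!is.null(r)) t2[[length(t2) + 1]] <- r
    }
  }
  for (i in 2:(T - 1)) {
    sel <- X[, i] == 1
    if (sum(sel) >= 4) {
      new <- first[sel] == i
      again <- rowSums(X[sel, (i + 1):T, drop = FALSE]) > 0
      tab <- table(factor(new, levels = c(TRUE, FALSE)),
                   factor(again, levels = c(TRUE, FALSE)))
      r <- pearson_chisq(unclass(tab), min_expected)
      if (!is.null(r)) t3[[length(t3) + 1]] <- r
    }
  }
  sum_up <- function(lst) {
    chisq <- sum(vapply(lst, `[[`, numeric(1), "chisq"))
    df <- sum(vapply(lst, `[[`, numeric(1), "df"))
    list(chisq = chisq, df = df,
         c_hat = if (df > 0) chisq / df else NA_real_,
         n_tables = length(lst))
  }
  structure(list(test2 = sum_up(t2), test3 = sum_up(t3)),
            class = "release_tests")
}

#' @export
print.release_tests <- function(x, ...) {
  f <- function(nm, r) cat(sprintf(
    "%s: chisq %.2f on %d df (%d tables); c-hat %.2f\n",
    nm, r$chisq, r$df, r$n_tables, r$c_hat))
  f("TEST 2 (capture)", x$test2)
  f("TEST 3 (survival)", x$test3)
  invisible(x)
}

#' Data-cloning identifiability diagnostic
#'
#' Refits the model on the dataset replicated `K_clones` times (frequency
#' weights).  Cloning multiplies the likelihood information by `K`, so point
#' estimates are unchanged and the standard error of every estimable
#' parameter shrinks by `1 / sqrt(K)`; parameters whose SE ratio departs from
#' that scaling (or whose estimate moves) are flagged non-estimable.  Both the
#' `1 / sqrt(K)` (information arithmetic, the pass criterion) and `1 / K`
#' reference lines are reported.
#'
#' @param data a [capture_matrix()].
#' @param structure an [msord_structure()] (or string).
#' @param K_clones number of clones (>= 2).
#' @param tol relative tolerance on `ratio * sqrt(K) - 1` for the estimable
#'   verdict.
#' @param ... passed to [fit_msord()].
#' @return An object of class `data_cloning`: per-parameter table with link
#'   estimates and SEs before/after cloning, the SE ratio, both reference
#'   values, and the `estimable` flag.
#' @export
data_cloning <- function(data, structure, K_clones = 100, tol = 0.25, ...) {
  if (K_clones < 2) stop_msord("K_clones must be >= 2")
  dots <- list(...)
  fit0 <- do.call(fit_msord, c(list(data, structure), dots))
  se0 <- sqrt(diag(fit0$vcov_link))
  dots[c("weights", "start", "n_restarts")] <- NULL
  fitK <- do.call(fit_msord, c(list(data, structure,
                                    weights = rep(K_clones, nrow(data)),
                                    start = fit0$par, n_restarts = 1), dots))
  seK <- sqrt(diag(fitK$vcov_link))
  ratio <- seK / se0
  expected <- 1 / sqrt(K_clones)
  est_shift <- abs(fitK$par - fit0$par)
  estimable <- is.finite(ratio) & abs(ratio / expected - 1) < tol &
    est_shift < 0.05
  out <- data.frame(parameter = names(fit0$par),
                    estimate = unname(fit0$par),
                    estimate_cloned = unname(fitK$par),
                    se = unname(se0), se_cloned = unname(seK),
                    ratio = unname(ratio),
                    expected_sqrtK = expected, expected_K = 1 / K_clones,
                    estimable = unname(estimable))
  structure(list(table = out, K_clones = K_clones,
                 fit = fit0, fit_cloned = fitK), class = "data_cloning")
}

#' @export
print.data_cloning <- function(x, ...) {
  cat("Data cloning x", x$K_clones, "(SE scaling check; pass line 1/sqrt(K))\n")
  print(transform(x$table, ratio = round(ratio, 4), se = signif(se, 3),
                  se_cloned = signif(se_cloned, 3)), row.names = FALSE)
  if (!all(x$table$estimable))
    cat("Flagged non-estimable:",
        paste(x$table$parameter[!x$table$estimable], collapse = ", "), "\n")
  invisible(x)
}
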