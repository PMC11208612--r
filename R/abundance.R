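#' Scale marked abundance to total abundance
#'
#' Dividing the estimated abundance of marked (distinctive) animals by the
#' mark rate gives total abundance: `N_total = N_m / theta`.
#'
#' @param N_m estimated marked abundance (>= 0).
#' @param theta mark rate in (0, 1].
#' @return Unrounded total abundance (reporting layers round to integers).
#' @export
total_abundance <- function(N_m, theta) {
  if (any(theta <= 0) || any(theta > 1)) stop_msord("theta must lie in (0, 1]")
  if (any(N_m < 0)) stop_msord("N_m must be non-negative")
  N_m / theta
}

#' Delta-method SE of total abundance
#'
#' Combines the relative variance of the marked-abundance estimate with the
#' binomial variance of the mark rate:
#' `SE = sqrt(N_total^2 * (se_N_m^2 / N_m^2 + (1 - theta) / (n * theta)))`,
#' where `n` is the sample size behind the binomial term -- here the number of
#' distinct individuals identified in the period being scaled.
#'
#' @param N_m,se_N_m marked abundance and its SE.
#' @param theta mark rate in (0, 1).
#' @param n sample size for the binomial mark-rate term (> 0).
#' @return Unrounded SE of total abundance.
#' @export
total_abundance_se <- function(N_m, se_N_m, theta, n) {
  if (any(n <= 0)) stop_msord("n must be positive")
  if (any(theta <= 0) || any(theta >= 1)) stop_msord("theta must lie in (0, 1)")
  N_total <- N_m / theta
  sqrt(N_total^2 * (se_N_m^2 / N_m^2 + (1 - theta) / (n * theta)))
}

#' Log-normal 95% confidence interval for an abundance estimate
#'
#' `C = exp(z * sqrt(log(1 + (se / N)^2)))`; the interval is `(N / C, N * C)`,
#' geometrically symmetric about the estimate (`low * high = N^2`).
#'
#' @param N abundance estimate (> 0).
#' @param se its standard error (>= 0).
#' @param z normal quantile, fixed at 1.96 by convention.
#' @return Named numeric `c(low, high)`.
#' @export
lognormal_ci <- function(N, se, z = 1.96) {
  if (any(N <= 0)) stop_msord("N must be positive")
  if (any(se < 0)) stop_msord("se must be non-negative")
  C <- exp(z * sqrt(log(1 + (se / N)^2)))
  c(low = N / C, high = N * C)
}

#' Per-period abundance table (marked and total)
#'
#' Applies the scaling chain per primary period: total abundance, its
#' delta-method SE using that period's count of identified individuals, and
#' log-normal 95% CIs.  All computation is on unrounded values; rounded
#' presentation columns (`N_total` to integers, SE to one decimal) are included
#' alongside, and the presentation CI is recomputed from the rounded
#' `(N_total, SE)` pair so printed tables are internally reproducible.
#'
#' @param per_period data.frame with columns `period`, `n` (distinct
#'   individuals identified), `N_m`, `se_N_m`.
#' @param theta scalar mark rate, or a `mark_rate` object.
#' @return data.frame of class `abundance_table` with unrounded columns
#'   (`N_total`, `se_N_total`, `ci_low`, `ci_high`) and rounded presentation
#'   columns (`N_total_r`, `se_r`, `ci_low_r`, `ci_high_r`).
#' @export
abundance_table <- function(per_period, theta) {
  if (inherits(theta, "mark_rate")) theta <- theta$theta
  need <- c("period", "n", "N_m", "se_N_m")
  if (!all(need %in% names(per_period)))
    stop_msord("per_period needs columns: ", paste(need, collapse = ", "))
  N_tot <- total_abundance(per_period$N_m, theta)
  se <- total_abundance_se(per_period$N_m, per_period$se_N_m, theta, per_period$n)
  ci <- t(mapply(lognormal_ci, N_tot, se))
  Nr <- round(N_tot); ser <- round(se, 1)
  cir <- t(mapply(lognormal_ci, Nr, ser))
  out <- data.frame(period = per_period$period, n = per_period$n,
                    N_m = per_period$N_m, se_N_m = per_period$se_N_m,
                    N_total = N_tot, se_N_total = se,
                    ci_low = ci[, 1], ci_high = ci[, 2],
                    N_total_r = Nr, se_r = ser,
                    ci_low_r = round(cir[, 1]), ci_high_r = round(cir[, 2]))
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("Total abundance by primary period (marked abundance / mark rate):\n")
  show <- data.frame(period = x$period, n = x$n,
                     N_m = sprintf("%.0f (%.1f)", x$N_m, x$se_N_m),
                     N_total = sprintf("%d (%.1f, %d-%d)", x$N_total_r, x$se_r,
                                       x$ci_low_r, x$ci_high_r))
  print(show, row.names = FALSE)
  invisible(x)
}
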