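#' Run the full capture-recapture analysis from one configuration
#'
#' Orchestrates the analysis end to end: load (or simulate) capture
#' histories, estimate or fix the mark rate, fit the MSORD model suite and
#' rank by AICc, derive per-primary marked abundance from the best model and
#' scale to total abundance, pool occasions and fit the POPAN suite (QAICc
#' when a c-hat adjustment is active), compute goodness-of-fit, and
#' optionally run the data-cloning identifiability screen (models whose
#' parameters fail the cloning scaling are dropped from the ranking).
#' Deterministic given the config's seed.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   * `design`: `n_primary`, `n_secondary`, optional `labels`;
#'   * `data`: either `inp` / `csv` (a file path) or `simulate`
#'     (`truth` parameter list and `n_individuals`);
#'   * `theta`: a fixed mark rate, or `sightings` (CSV path) to estimate it;
#'   * `msord_models`: structure strings (default: the study's six-model
#'     suite, see [msord_model_suite()]);
#'   * `popan_models`: POPAN structure strings (default the four
#'     constant/season combinations of `p` and `S`);
#'   * `c_hat_adjust`: logical, apply the global c-hat to POPAN ranking;
#'   * `data_cloning`: number of clones for the identifiability screen
#'     (0 = off);
#'   * `seed`: integer; `outdir`: optional directory for CSV artifacts.
#' @return An object of class `analysis_report`.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop_msord("stage '", name, "' failed: ", conditionMessage(e)))
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  design <- stage("design", do.call(study_design, config$design))

  data <- stage("data", {
    dc <- config$data
    if (!is.null(dc$inp)) read_inp(dc$inp, design)
    else if (!is.null(dc$csv)) read_captures_csv(dc$csv, design)
    else if (!is.null(dc$simulate))
      simulate_msord(dc$simulate$truth, design, dc$simulate$n_individuals,
                     seed = derive_seed(seed, 1))$data
    else stop_msord("config$data must supply 'inp', 'csv' or 'simulate'")
  })

  theta <- stage("mark_rate", {
    tc <- config$theta
    if (is.numeric(tc)) new_mark_rate(tc, NA_real_, NA_integer_, "fixed")
    else {
      s <- if (is.character(tc$sightings)) read_sightings_csv(tc$sightings)
           else tc$sightings
      combine_mark_rates(theta1(s), theta2(s))
    }
  })

  suite <- config$msord_models %||% msord_model_suite()
  clone_k <- config$data_cloning %||% 0

  msord_fits <- stage("msord_suite", {
    fits <- list()
    for (m in suite) {
      f <- tryCatch(
        suppressWarnings(fit_msord(data, m, seed = derive_seed(seed, 2),
                                   n_restarts = config$n_restarts %||% 2)),
        error = function(e) NULL)
      if (is.null(f) || !f$convergence) {
        message("  model dropped (no convergence): ", m)
        next
      }
      if (clone_k >= 2) {
        dc <- data_cloning(data, m, K_clones = clone_k,
                           seed = derive_seed(seed, 3),
                           n_restarts = 1)
        if (!all(dc$table$estimable)) {
          message("  model dropped (non-estimable parameters): ", m)
          next
        }
      }
      fits[[m]] <- f
    }
    if (!length(fits)) stop_msord("no MSORD model converged")
    fits
  })
  msord_rank <- rank_models(msord_fits)
  best <- attr(msord_rank, "fits")[[1]]

  abundance <- stage("abundance", {
    ab <- derive_abundance(best)
    abundance_table(data.frame(period = ab$period, n = ab$n, N_m = ab$N_m,
                               se_N_m = ab$se_N_m), theta)
  })

  gof <- stage("gof", {
    pooled <- pool_primaries(data)
    list(median_c_hat = tryCatch(median_c_hat(data), error = function(e) NULL),
         release = tryCatch(release_tests(pooled), error = function(e) NULL))
  })
  c_hat <- if (isTRUE(config$c_hat_adjust) && !is.null(gof$median_c_hat))
    max(attr(gof$median_c_hat, "global_c_hat"), 1) else 1
  if (c_hat > 3)
    warning("global c-hat ", round(c_hat, 2),
            " > 3 suggests structural inadequacy", call. = FALSE)

  popan_out <- stage("popan_suite", {
    pooled <- pool_primaries(data)
    specs <- config$popan_models %||%
      c("p(season) S(.) pent(.)", "p(.) S(.) pent(.)",
        "p(season) S(season) pent(.)", "p(.) S(.) pent(season)")
    fits <- list()
    for (m in specs) {
      f <- tryCatch(suppressWarnings(
        fit_popan(pooled, m, c_hat = c_hat, seed = derive_seed(seed, 4),
                  n_restarts = config$n_restarts %||% 2)),
        error = function(e) NULL)
      if (!is.null(f) && f$convergence) fits[[m]] <- f
    }
    if (!length(fits)) stop_msord("no POPAN model converged")
    rank <- rank_models(fits)
    best_p <- attr(rank, "fits")[[1]]
    super <- data.frame(
      N_super_marked = best_p$N_super, se = best_p$se_N_super,
      ci_low = best_p$ci_N_super[1], ci_high = best_p$ci_N_super[2],
      N_super_total = total_abundance(best_p$N_super, theta$theta),
      se_total = total_abundance_se(best_p$N_super, best_p$se_N_super,
                                    theta$theta, best_p$D))
    list(rank = rank, best = best_p, super = super)
  })

  # internal consistency: the table's totals must equal the scaling law
  stopifnot(all(abs(abundance$N_total - abundance$N_m / theta$theta) < 1e-8))

  report <- structure(list(
    design = design, data = data, theta = theta,
    msord_rank = msord_rank, best_msord = best,
    abundance = abundance, transitions = best$derived$transitions,
    gof = gof, c_hat = c_hat,
    popan_rank = popan_out$rank, best_popan = popan_out$best,
    super_population = popan_out$super,
    provenance = list(seed = seed, config = config,
                      r_version = R.version.string, time = Sys.time())
  ), class = "analysis_report")

  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' The study's six-model MSORD suite
#'
#' Named preset of the structures compared in the two-year dolphin analysis;
#' the full crossing of variation specs and emigration regimes can be
#' enumerated with [msord_enumerate_suite()].
#'
#' @return character vector of structure strings.
#' @export
msord_model_suite <- function() {
  c("S(.) p(.) pent(season.day) phi(season.day) psi(Markovian)",
    "S(.) p(.) pent(season.day) phi(season) psi(Markovian)",
    "S(.) p(.) pent(season.day) phi(.) psi(Markovian)",
    "S(.) p(season) pent(.) phi(.) psi(Markovian)",
    "S(.) p(.) pent(season) phi(t) psi(Markovian)",
    "S(.) p(.) pent(.) phi(season) psi(Markovian)")
}

#' Enumerate an MSORD model suite programmatically
#'
#' All combinations of the supplied variation specs and emigration regimes.
#'
#' @param S,p,pent,phi character vectors of variation specs.
#' @param emigration character vector of emigration regimes.
#' @return character vector of structure strings.
#' @export
msord_enumerate_suite <- function(S = c("."), p = c(".", "season"),
                                  pent = c(".", "season", "season.day"),
                                  phi = c(".", "season", "season.day"),
                                  emigration = c("Markovian", "random", "none")) {
  g <- expand.grid(S = S, p = p, pent = pent, phi = phi, psi = emigration,
                   stringsAsFactors = FALSE)
  sprintf("S(%s) p(%s) pent(%s) phi(%s) psi(%s)",
          g$S, g$p, g$pent, g$phi, g$psi)
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$msord_rank, file.path(outdir, "msord_rank.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$abundance),
                   file.path(outdir, "abundance.csv"), row.names = FALSE)
  utils::write.csv(report$popan_rank, file.path(outdir, "popan_rank.csv"),
                   row.names = FALSE)
  utils::write.csv(report$super_population,
                   file.path(outdir, "super_population.csv"), row.names = FALSE)
  if (!is.null(report$transitions))
    utils::write.csv(report$transitions, file.path(outdir, "transitions.csv"),
                     row.names = FALSE)
  if (!is.null(report$gof$median_c_hat))
    utils::write.csv(as.data.frame(report$gof$median_c_hat),
                     file.path(outdir, "gof_c_hat.csv"), row.names = FALSE)
  invisible(outdir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Capture-recapture analysis report ==\n\n")
  print(x$theta); cat("\n")
  print(x$msord_rank); cat("\n")
  print(x$abundance); cat("\n")
  cat(sprintf("Super-population (marked): %.1f (SE %.2f); total: %.0f (SE %.1f)\n",
              x$super_population$N_super_marked, x$super_population$se,
              x$super_population$N_super_total, x$super_population$se_total))
  if (!is.null(x$gof$median_c_hat))
    cat(sprintf("Global c-hat: %.2f\n", attr(x$gof$median_c_hat, "global_c_hat")))
  invisible(x)
}

#' Summary statistics of survey effort and sighting histories
#'
#' Per-individual sighting frequencies, the mean number of occasions each
#' animal was photographed, the proportion detected on more than one
#' occasion, the cumulative discovery curve of new identifications by
#' occasion, and (when sightings are supplied with a `primary` column)
#' per-primary group counts and mean group sizes.
#'
#' @param data a [capture_matrix()].
#' @param sightings optional group-sightings data.frame with a `primary`
#'   column.
#' @return An object of class `summary_stats`.
#' @export
summary_statistics <- function(data, sightings = NULL) {
  X <- unclass(data)
  freq <- rowSums(X)
  first_occ <- max.col(X, "first")
  discovery <- cumsum(tabulate(first_occ, nbins = ncol(X)))
  out <- list(
    n_individuals = nrow(X),
    sighting_freq = table(freq),
    mean_sightings = mean(freq),
    se_mean_sightings = stats::sd(freq) / sqrt(length(freq)),
    prop_resighted = mean(freq > 1),
    discovery_curve = discovery)
  if (!is.null(sightings) && "primary" %in% names(sightings)) {
    out$groups_per_primary <- tapply(sightings$sighting_id, sightings$primary, length)
    out$mean_group_size <- tapply(sightings$group_size, sightings$primary, mean)
  }
  class(out) <- "summary_stats"
  out
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("%d individuals; mean sightings %.2f (SE %.2f); %.0f%% resighted\n",
              x$n_individuals, x$mean_sightings, x$se_mean_sightings,
              100 * x$prop_resighted))
  cat("Discovery curve ends at", utils::tail(x$discovery_curve, 1), "\n")
  invisible(x)
}
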