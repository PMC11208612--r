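#' Simulate capture histories under the MSORD generative model
#'
#' Individuals are seeded at the first primary period in the observable (P) or
#' emigrant (E) state; between primaries they survive with probability `S`
#' then move between states by the Markov transitions (`psiPE`, `psiEE`);
#' within a primary an animal in state P draws a single availability window
#' from the entry/persistence distribution (`pent`, `phi`) and is detected
#' independently with probability `p` on each occasion inside the window.
#' Animals never detected are retained in the truth but excluded from the
#' returned capture matrix (the conditional likelihood cannot see them).
#'
#' @param params natural-scale parameter list (`S`, `p`, `pent`, `phi`,
#'   `psiPE`, `psiEE`; scalars recycled, see [history_loglik()]).
#' @param design a [study_design()].
#' @param n_individuals number of animals to simulate.
#' @param seed integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @param init_p probability of starting in state P at the first primary;
#'   default is the stationary probability of the transition chain.
#' @return list with `data` (a [capture_matrix()] of detected animals) and
#'   `truth` (`params`, per-individual `states` (`"P"`/`"E"`/`"dead"`),
#'   `windows`, `detected` flags, `seed`).
#' @export
simulate_msord <- function(params, design, n_individuals, seed = 1,
                           init_p = NULL) {
  pl <- msord_params(params, design)
  T <- design$n_primary; J <- design$n_secondary
  if (n_individuals < 1) stop_msord("n_individuals must be >= 1")
  if (is.null(init_p)) {
    init_p <- if (T > 1) {
      pe <- pl$psiPE[1]; ee <- pl$psiEE[1]
      denom <- pe + 1 - ee
      if (denom > 0) (1 - ee) / denom else 1
    } else 1
  }
  set.seed(as.integer(seed) %% 2147483647L)
  det <- matrix(0L, n_individuals, design$n_occasions)
  states <- matrix("dead", n_individuals, T)
  windows <- array(NA_integer_, c(n_individuals, T, 2),
                   dimnames = list(NULL, NULL, c("a", "d")))
  for (i in seq_len(n_individuals)) {
    state <- if (stats::runif(1) < init_p) "P" else "E"
    for (t in seq_len(T)) {
      states[i, t] <- state
      if (state == "P") {
        a <- sample.int(J[t], 1, prob = pl$pent[[t]])
        d <- a
        while (d < J[t] && stats::runif(1) < pl$phi[[t]][d]) d <- d + 1
        windows[i, t, ] <- c(a, d)
        occ <- design_cols(design, t)[a:d]
        det[i, occ] <- stats::rbinom(d - a + 1, 1, pl$p[[t]][a:d])
      }
      if (t < T) {
        if (stats::runif(1) > pl$S[t]) { state <- "dead" }
        else if (state == "P") {
          state <- if (stats::runif(1) < pl$psiPE[t]) "E" else "P"
        } else if (state == "E") {
          state <- if (stats::runif(1) < pl$psiEE[t]) "E" else "P"
        }
        if (state == "dead") {
          if (t + 1 <= T) states[i, (t + 1):T] <- "dead"
          break
        }
      }
    }
  }
  detected <- rowSums(det) > 0
  data <- suppressWarnings(capture_matrix(det[detected, , drop = FALSE], design,
                                          ids = paste0("sim", which(detected))))
  list(data = data,
       truth = list(params = pl, states = states, windows = windows,
                    detected = detected, n_individuals = n_individuals,
                    seed = seed, init_p = init_p))
}

#' Simulate pooled histories under the POPAN model
#'
#' `N` super-population members enter at a multinomial(pent) occasion, survive
#' intervals with probability `S` and are detected with probability `p`;
#' animals never detected are counted in the truth.
#'
#' @param params list with `N`, `pent` (length T, sums to 1), `S`, `p`.
#' @param T number of pooled occasions.
#' @param seed integer seed.
#' @return list with `data` (a `pooled_matrix` of detected animals) and
#'   `truth`.
#' @export
simulate_popan <- function(params, T, seed = 1) {
  pp <- popan_prep(params, T)
  N <- round(pp$N)
  set.seed(as.integer(seed) %% 2147483647L)
  entry <- sample.int(T, N, replace = TRUE, prob = pp$pent)
  det <- matrix(0L, N, T)
  for (i in seq_len(N)) {
    t <- entry[i]
    repeat {
      det[i, t] <- stats::rbinom(1, 1, pp$p[t])
      if (t == T || stats::runif(1) > pp$S[t]) break
      t <- t + 1
    }
  }
  detected <- rowSums(det) > 0
  pooled <- structure(det[detected, , drop = FALSE],
                      design = study_design(rep(1, T)),
                      class = "pooled_matrix")
  rownames(pooled) <- paste0("sim", which(detected))
  colnames(pooled) <- paste0("occ", seq_len(T))
  list(data = pooled,
       truth = list(params = pp, entry = entry, detected = detected,
                    n_never_detected = sum(!detected), seed = seed))
}

#' Simulate group sightings for mark-rate estimation
#'
#' Group sizes are drawn from `size_dist`; the number of distinctive
#' individuals in each group is Binomial(size, theta), and the image tallies
#' are Binomial(images_total, theta) with `images_total` proportional to group
#' size.
#'
#' @param theta true mark rate in `[0, 1]`.
#' @param n_groups number of sightings.
#' @param size_dist function of `n` returning positive integer group sizes;
#'   the default draws sizes with mean about 30, matching coastal dolphin
#'   group sizes.
#' @param images_per_animal expected high-quality images per animal.
#' @param p_full_coverage probability a sighting achieves full photographic
#'   coverage.
#' @param seed integer seed.
#' @return data.frame of sightings (see [read_sightings_csv()] for columns).
#' @export
simulate_sightings <- function(theta, n_groups,
                               size_dist = function(n)
                                 pmax(1L, stats::rnbinom(n, mu = 30, size = 2)),
                               images_per_animal = 3,
                               p_full_coverage = 0.9, seed = 1) {
  check_prob(theta, "theta")
  set.seed(as.integer(seed) %% 2147483647L)
  size <- as.integer(size_dist(n_groups))
  if (any(size < 1)) stop_msord("group sizes must be positive")
  n_distinct <- stats::rbinom(n_groups, size, theta)
  images_total <- stats::rpois(n_groups, size * images_per_animal) + 1L
  images_distinct <- stats::rbinom(n_groups, images_total, theta)
  data.frame(sighting_id = paste0("g", seq_len(n_groups)),
             group_size = size, n_distinct = n_distinct,
             images_distinct = images_distinct, images_total = images_total,
             full_coverage = stats::runif(n_groups) < p_full_coverage)
}

#' Parameter-recovery experiment for the MSORD
#'
#' Simulates `n_reps` datasets at a known truth, fits the given structure to
#' each, and tabulates per-parameter bias, empirical spread, mean model SE and
#' 95% Wald coverage (intervals formed on the logit scale and transformed).
#' Probability parameters with constant variation (`S`, `p`, `phi`, `psiPE`,
#' `psiEE`) are compared; failed fits are counted and excluded.
#'
#' @param truth natural-scale parameter list (see [simulate_msord()]).
#' @param structure an [msord_structure()] to fit.
#' @param design a [study_design()].
#' @param n_individuals animals per replicate.
#' @param n_reps number of replicates (>= 2).
#' @param seed integer seed; the experiment is deterministic given the seed.
#' @param n_restarts restarts per fit (1 keeps the harness fast).
#' @return data.frame of class `recovery_table` with columns `parameter`,
#'   `truth`, `mean_est`, `bias`, `sd_emp`, `mean_se`, `coverage`; attribute
#'   `n_failed` counts non-converged replicates.
#' @export
recovery_experiment <- function(truth, structure, design, n_individuals,
                                n_reps, seed = 1, n_restarts = 1) {
  if (n_reps < 2) stop_msord("n_reps must be >= 2")
  if (is.character(structure)) structure <- msord_structure(structure)
  tl <- msord_params(truth, design)
  truth_scalar <- c(S = tl$S[1], p = tl$p[[1]][1], phi = tl$phi[[1]][1],
                    psiPE = tl$psiPE[1], psiEE = tl$psiEE[1], psi = tl$psiPE[1])
  res <- list(); n_failed <- 0L
  for (r in seq_len(n_reps)) {
    sim <- simulate_msord(truth, design, n_individuals,
                          seed = derive_seed(seed, r))
    fit <- tryCatch(
      suppressWarnings(fit_msord(sim$data, structure, n_restarts = n_restarts,
                                 seed = derive_seed(seed, 10000 + r))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$convergence || !fit$vcov_ok) {
      n_failed <- n_failed + 1L
      next
    }
    keep <- names(fit$par) %in% names(truth_scalar)
    se_link <- sqrt(diag(fit$vcov_link))[keep]
    est_link <- fit$par[keep]
    res[[length(res) + 1]] <- data.frame(
      rep = r, parameter = names(fit$par)[keep],
      estimate = invlogit(est_link),
      lcl = invlogit(est_link - 1.96 * se_link),
      ucl = invlogit(est_link + 1.96 * se_link))
  }
  if (!length(res)) stop_msord("all replicates failed to fit")
  all <- do.call(rbind, res)
  # natural-scale SE by delta method
  rows <- lapply(split(all, all$parameter), function(d) {
    tv <- truth_scalar[[d$parameter[1]]]
    data.frame(parameter = d$parameter[1], truth = tv,
               mean_est = mean(d$estimate), bias = mean(d$estimate) - tv,
               sd_emp = stats::sd(d$estimate),
               mean_se = mean((d$ucl - d$lcl) / (2 * 1.96)),
               coverage = mean(d$lcl <= tv & tv <= d$ucl),
               n_reps = nrow(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  class(out) <- c("recovery_table", "data.frame")
  out
}

#' @export
print.recovery_table <- function(x, ...) {
  cat("Parameter recovery over", x$n_reps[1] + attr(x, "n_failed"),
      "replicates (", attr(x, "n_failed"), "failed )\n")
  print(data.frame(parameter = x$parameter, truth = x$truth,
                   mean = round(x$mean_est, 4), bias = round(x$bias, 4),
                   sd = round(x$sd_emp, 4), coverage = round(x$coverage, 3)),
        row.names = FALSE)
  invisible(x)
}
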