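# fitting, derived quantities, emigration-regime constraints

study_truth <- list(S = 0.95, p = 0.3, pent = c(0.4, 0.2, 0.1, 0.1, 0.1, 0.1),
                    phi = 0.75, psiPE = 0.35, psiEE = 0.6)
const_structure <- "S(.) p(.) pent(.) phi(.) psi(Markovian)"

test_that("structure strings parse to the intended specification", {
  st <- msord_structure("S(.) p(.) pent(season.day) phi(season.day) psi(Markovian)")
  expect_equal(st$S, "constant")
  expect_equal(st$pent, "season.day")
  expect_equal(st$emigration, "Markovian")
  expect_equal(st$psi_time, "constant")
  st2 <- msord_structure("S(t) p(season) pent(season) phi(.) psi(random.t)")
  expect_equal(st2$S, "time")
  expect_equal(st2$p, "season")
  expect_equal(st2$emigration, "random")
  expect_equal(st2$psi_time, "time")
  # random emigration ties the transitions; none fixes them at zero
  d <- study_design(3, 4)
  th <- msord:::msord_start(msord_structure(emigration = "random"), d)
  pl <- msord:::expand_msord(th, msord_structure(emigration = "random"), d)
  expect_equal(pl$psiPE, pl$psiEE)
  pl0 <- msord:::expand_msord(msord:::msord_start(msord_structure(emigration = "none"), d),
                      msord_structure(emigration = "none"), d)
  expect_equal(pl0$psiPE, rep(0, 3))
  # parameter count for the study's best structure (8 x 6 design)
  d86 <- study_design(6, 8)
  expect_equal(msord:::msord_n_par(msord_structure(
    "S(.) p(.) pent(season.day) phi(season.day) psi(Markovian)"), d86),
    1 + 1 + 40 + 40 + 2)
})

test_that("estimates recover simulation truth on a moderate dataset", {
  d <- study_design(6, 8)
  sim <- simulate_msord(study_truth, d, 400, seed = 31)
  fit <- suppressWarnings(fit_msord(sim$data, const_structure, n_restarts = 1))
  expect_true(fit$convergence)
  est <- coef(fit)
  se <- fit$natural$se[match(names(est), fit$natural$parameter)]
  for (nm in c("S_1", "p_1.1", "psiPE_1", "psiEE_1")) {
    truth_val <- switch(substr(nm, 1, 3), "S_1" = 0.95, "p_1" = 0.3,
                        "psi" = if (nm == "psiPE_1") 0.35 else 0.6)
    expect_lt(abs(est[[nm]] - truth_val), 3 * se[match(nm, names(est))] + 1e-8)
  }
})

test_that("random-emigration fit equals the psi-tied Markovian likelihood and nests", {
  d <- study_design(4, 5)
  truth <- list(S = 0.93, p = 0.35, pent = c(0.5, 0.2, 0.15, 0.15), phi = 0.7,
                psiPE = 0.45, psiEE = 0.45)   # random-emigration truth
  sim <- simulate_msord(truth, d, 250, seed = 44)
  fit_r <- suppressWarnings(fit_msord(sim$data, "S(.) p(.) pent(.) phi(.) psi(random)",
                                      n_restarts = 2))
  # a Markovian model evaluated at the tied estimates gives the same likelihood
  st_m <- msord_structure(emigration = "Markovian")
  th_m <- c(fit_r$par[names(fit_r$par) != "psi"],
            psiPE = unname(fit_r$par[["psi"]]), psiEE = unname(fit_r$par[["psi"]]))
  pl <- msord:::expand_msord(th_m, st_m, d)
  expect_equal(as.numeric(msord_loglik(sim$data, pl)), fit_r$logLik,
               tolerance = 1e-8)
  # nesting: Markovian maximum cannot fall below the random maximum
  fit_m <- suppressWarnings(fit_msord(sim$data, "S(.) p(.) pent(.) phi(.) psi(Markovian)",
                                      start = th_m, n_restarts = 1))
  expect_gte(fit_m$logLik, fit_r$logLik - 1e-6)
})

test_that("no-emigration fit equals the single-state open robust design", {
  d <- study_design(4, 4)
  truth <- list(S = 0.9, p = 0.4, pent = c(0.55, 0.2, 0.15, 0.1), phi = 0.7,
                psiPE = 0, psiEE = 0)
  sim <- simulate_msord(truth, d, 200, seed = 47)
  fit0 <- suppressWarnings(fit_msord(sim$data, "S(.) p(.) pent(.) phi(.) psi(none)",
                                     n_restarts = 1))
  # direct single-state likelihood: no emigrant state at all
  pl <- fit0$params
  expect_equal(pl$psiPE, rep(0, 3))
  manual <- sum(msord:::msord_history_loglik(unclass(fit0$data), pl, d) * fit0$weights)
  expect_equal(fit0$logLik, manual, tolerance = 1e-10)
  expect_true(fit0$convergence)
})

test_that("derived abundance behaves as Horvitz-Thompson", {
  d <- study_design(3, 3)
  truth <- list(S = 1, p = 1, pent = c(1, 0, 0), phi = 1, psiPE = 0, psiEE = 0)
  sim <- simulate_msord(truth, d, 50, seed = 53)
  fit <- suppressWarnings(fit_msord(sim$data, "S(.) p(.) pent(.) phi(.) psi(none)",
                                    n_restarts = 1))
  ab <- derive_abundance(fit)
  # perfect detection: N_m equals the observed count in every primary
  expect_equal(ab$N_m, ab$n, tolerance = 1e-3)
  expect_false(any(ab$flagged))
})

test_that("marked abundance recovers the simulated number present", {
  d <- study_design(6, 4)
  truth <- list(S = 0.95, p = 0.3, pent = c(0.4, 0.2, 0.1, 0.1, 0.1, 0.1),
                phi = 0.75, psiPE = 0.35, psiEE = 0.6)
  reps <- lapply(1:8, function(r) {
    sim <- simulate_msord(truth, d, 250, seed = 700 + r)
    fit <- suppressWarnings(fit_msord(sim$data, const_structure, n_restarts = 1))
    ab <- derive_abundance(fit)
    true_present <- colSums(sim$truth$states == "P")
    cbind(est = ab$N_m, true = true_present, se = ab$se_N_m)
  })
  est <- rowMeans(sapply(reps, function(m) m[, "est"] / m[, "true"]))
  # N_m / (true animals in state P) should average to 1 within MC spread
  expect_true(all(abs(est - 1) < 0.15))
})

test_that("derived transitions are complements with matching SEs", {
  d <- study_design(6, 4)
  sim <- simulate_msord(list(S = 0.95, p = 0.35, pent = c(0.4, 0.2, 0.1, 0.1, 0.1, 0.1),
                             phi = 0.75, psiPE = 0.67, psiEE = 0.6), d, 300, seed = 59)
  fit <- suppressWarnings(fit_msord(sim$data, const_structure, n_restarts = 1))
  tr <- derived_transitions(fit)
  expect_equal(tr$psiPP, 1 - tr$psiPE)
  expect_equal(tr$psiEP, 1 - tr$psiEE)
  expect_equal(tr$se_psiPP, tr$se_psiPE)
  expect_equal(tr$psiPP + tr$psiPE, rep(1, nrow(tr)), tolerance = 1e-12)
  # the complement arithmetic itself (0.67 emigration -> 0.33 return)
  expect_equal(1 - 0.67, 0.33)
  fit_none <- suppressWarnings(fit_msord(sim$data, "S(.) p(.) pent(.) phi(.) psi(none)",
                                         n_restarts = 1))
  expect_error(derived_transitions(fit_none), "none")
})

test_that("fits are deterministic given data, structure and seed", {
  d <- study_design(4, 4)
  sim <- simulate_msord(list(S = 0.9, p = 0.4, pent = c(0.4, 0.3, 0.2, 0.1),
                             phi = 0.7, psiPE = 0.3, psiEE = 0.5), d, 120, seed = 61)
  f1 <- suppressWarnings(fit_msord(sim$data, const_structure, n_restarts = 2, seed = 5))
  f2 <- suppressWarnings(fit_msord(sim$data, const_structure, n_restarts = 2, seed = 5))
  expect_identical(f1$par, f2$par)
  expect_identical(f1$logLik, f2$logLik)
})

test_that("data cloning leaves estimates in place and scales SEs by 1/sqrt(K)", {
  d <- study_design(5, 5)
  sim <- simulate_msord(list(S = 0.92, p = 0.35, pent = c(0.4, 0.25, 0.15, 0.1, 0.1),
                             phi = 0.75, psiPE = 0.3, psiEE = 0.55), d, 250, seed = 67)
  K <- 25
  dc <- suppressWarnings(data_cloning(sim$data, const_structure, K_clones = K,
                                      n_restarts = 1))
  tab <- dc$table
  expect_true(all(abs(tab$estimate_cloned - tab$estimate) < 0.02))
  expect_true(all(abs(tab$ratio * sqrt(K) - 1) < 0.1))
  expect_true(all(tab$estimable))
  expect_equal(tab$expected_sqrtK[1], 1 / sqrt(K))
  expect_equal(tab$expected_K[1], 1 / K)
})
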