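# within-primary sub-model and the conditional MSORD history likelihood

test_that("within-primary probability: closed forms at simple designs", {
  expect_equal(within_primary_prob(1, pent = 1, phi = numeric(0), p = 0.4), 0.4)
  # always available across both occasions
  expect_equal(within_primary_prob(c(0, 0), pent = c(1, 0), phi = 1,
                                   p = c(0.3, 0.5)),
               0.7 * 0.5)
  # detection before entry is impossible
  expect_equal(within_primary_prob(c(1, 0), pent = c(0, 1), phi = 1,
                                   p = c(0.3, 0.5)), 0)
})

test_that("emission probabilities sum to 1 over all detection vectors (J <= 4)", {
  for (J in 2:4) for (k in 1:5) {
    set.seed(J * 100 + k)
    pent <- {x <- runif(J); x / sum(x)}
    phi <- runif(J - 1); p <- runif(J)
    om <- as.matrix(expand.grid(rep(list(0:1), J)))
    tot <- sum(apply(om, 1, within_primary_prob, pent = pent, phi = phi, p = p))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("within-primary probabilities match the enumeration oracle", {
  for (k in 1:10) {
    set.seed(k)
    J <- sample(2:4, 1)
    pent <- {x <- runif(J); x / sum(x)}
    phi <- runif(J - 1); p <- runif(J)
    om <- rbinom(J, 1, 0.5)
    expect_equal(within_primary_prob(om, pent, phi, p),
                 oracle_wpp(om, pent, phi, p), tolerance = 1e-12)
  }
})

test_that("pstar: boundaries, closed form, and internal consistency", {
  expect_equal(pstar(c(0.5, 0.5), 0.8, c(0, 0)), 0)
  # entry at occasion 1, perfect persistence: 1 - (1-p)^J
  expect_equal(pstar(c(1, 0, 0), c(1, 1), rep(0.3, 3)), 1 - 0.7^3)
  for (k in 1:5) {
    set.seed(50 + k)
    pent <- {x <- runif(3); x / sum(x)}
    phi <- runif(2); p <- runif(3)
    expect_equal(pstar(pent, phi, p),
                 1 - within_primary_prob(c(0, 0, 0), pent, phi, p))
  }
})

test_that("history likelihood matches hand expansions at T = 2, J = 1", {
  d <- study_design(1, 2)
  S <- 0.9; psi <- 0.3; p <- 0.4
  pars <- list(S = S, p = p, pent = 1, phi = 1, psiPE = psi, psiEE = 0.5)
  expect_equal(history_loglik(c(1, 0), pars, d),
               log(S * (psi + (1 - psi) * (1 - p)) + (1 - S)))
  expect_equal(history_loglik(c(1, 1), pars, d),
               log(S * (1 - psi) * p))
})

test_that("history likelihood equals the brute-force latent enumeration", {
  for (k in 1:12) {
    d <- study_design(2, 3)
    pars <- random_msord_params(d, seed = 300 + k)
    set.seed(400 + k)
    repeat {
      h <- rbinom(6, 1, 0.4)
      if (sum(h) > 0) break
    }
    expect_equal(history_loglik(h, pars, d),
                 log(oracle_history_prob(h, pars, d)), tolerance = 1e-10)
  }
})

test_that("total likelihood is additive and permutation-invariant", {
  d <- study_design(3, 3)
  pars <- random_msord_params(d, seed = 77)
  sim <- simulate_msord(pars, d, 40, seed = 78)
  x <- sim$data
  ll <- msord_loglik(x, pars)
  expect_equal(as.numeric(msord_loglik(x[1, , drop = FALSE], pars)),
               history_loglik(unclass(x)[1, ], pars, d))
  dup <- capture_matrix(rbind(unclass(x), unclass(x)), d,
                        ids = paste0("i", seq_len(2 * nrow(x))))
  expect_equal(as.numeric(msord_loglik(dup, pars)), 2 * as.numeric(ll))
  set.seed(79)
  perm <- sample(nrow(x))
  expect_equal(as.numeric(msord_loglik(x[perm, , drop = FALSE], pars)),
               as.numeric(ll))
})

test_that("degenerate inputs are rejected", {
  d <- study_design(2, 2)
  pars <- list(S = 0.9, p = 0.3, pent = c(0.6, 0.4), phi = 0.5,
               psiPE = 0.2, psiEE = 0.5)
  expect_error(history_loglik(c(0, 0, 0, 0), pars, d), "no detections")
  bad <- pars; bad$pent <- c(0.6, 0.6)
  expect_error(history_loglik(c(1, 0, 0, 0), bad, d), "sum to 1")
})

test_that("residence expectation matches enumeration for J = 4", {
  set.seed(91)
  pent <- {x <- runif(4); x / sum(x)}
  phi <- runif(3)
  # closed-form degenerate cases first
  expect_equal(oracle_residence(c(1, 0, 0, 0), c(1, 1, 1)), 4)
  expect_equal(oracle_residence(pent, c(0, 0, 0)), 1)
  d <- study_design(4, 2)
  pars <- list(S = 0.9, p = 0.4,
               pent = list(pent, pent), phi = list(phi, phi),
               psiPE = 0.3, psiEE = 0.5)
  sim <- simulate_msord(pars, d, 30, seed = 92)
  fit <- suppressWarnings(fit_msord(sim$data, "S(.) p(.) pent(.) phi(.) psi(none)",
                                    n_restarts = 1))
  rt <- residence_time(fit)
  expect_equal(unname(rt[1]),
               oracle_residence(fit$params$pent[[1]], fit$params$phi[[1]]),
               tolerance = 1e-10)
})
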