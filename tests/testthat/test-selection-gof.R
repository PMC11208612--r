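# information criteria, ranking, model averaging, GOF components

test_that("AICc and QAICc arithmetic", {
  logL <- -100; K <- 5; ess <- 50
  expect_equal(aicc(logL, K, ess), -2 * logL + 2 * K + 2 * K * (K + 1) / (ess - K - 1))
  # large-sample limit is plain AIC
  expect_equal(aicc(logL, K, 1e9), -2 * logL + 2 * K, tolerance = 1e-6)
  expect_error(aicc(logL, 49, 50), "ess")
  # c-hat = 1: QAICc differs from AICc only through the extra parameter
  expect_equal(qaicc(logL, K, ess, 1),
               aicc(logL, K + 1, ess) + 0, tolerance = 1e-12)
  expect_gt(qaicc(logL, K, ess, 1), aicc(logL, K, ess))
  # c-hat below 1 is capped
  expect_equal(qaicc(logL, K, ess, 0.4), qaicc(logL, K, ess, 1))
})

test_that("ranking reproduces the study's delta and behaves symmetrically", {
  mk <- function(A, K) structure(list(AICc = A, K = K, n_histories = 165,
                                      structure = msord_structure()),
                                 class = "msord_fit")
  tab <- rank_models(list(best = mk(3907.6, 69), third = mk(3964.7, 39)))
  expect_equal(tab$delta, c(0, 57.1))
  expect_equal(tab$weight[1], 1, tolerance = 1e-10)

  one <- rank_models(list(only = mk(100, 3)))
  expect_equal(one$weight, 1)

  tie <- rank_models(list(a = mk(100, 3), b = mk(100, 4)))
  expect_equal(tie$weight, c(0.5, 0.5))

  # weights invariant to a constant shift of all criteria
  sh <- rank_models(list(a = mk(350, 3), b = mk(351.2, 4), c = mk(360, 5)))
  sh2 <- rank_models(list(a = mk(50, 3), b = mk(51.2, 4), c = mk(60, 5)))
  expect_equal(sh$weight, sh2$weight)

  expect_error(rank_models(list(mk(1, 2), structure(list(AICc = 2, K = 2,
    n_histories = 99, structure = msord_structure()), class = "msord_fit"))),
    "different datasets")
})

test_that("model averaging weights estimates and widens SEs", {
  av <- average_estimates(c(0.9, 0.8), c(0.02, 0.03), c(0.5, 0.5))
  expect_equal(av$estimate, 0.85)
  expect_gte(av$se, 0.02)       # unconditional SE at least the smallest within-model SE
  # between-model spread contributes
  expect_gt(av$se, sqrt(0.5 * 0.02^2 + 0.5 * 0.03^2) - 1e-12)

  # single-model window is the identity
  d <- study_design(4, 3)
  sim <- simulate_msord(list(S = 0.9, p = 0.4, pent = c(0.4, 0.3, 0.2, 0.1),
                             phi = 0.7, psiPE = 0.3, psiEE = 0.5), d, 150, seed = 8)
  f <- suppressWarnings(fit_msord(sim$data, "S(.) p(.) pent(.) phi(.) psi(random)",
                                  n_restarts = 1))
  avf <- model_average(list(f))
  expect_equal(avf$estimate, f$natural$estimate)
})

test_that("CJS deviance is near zero under perfect detection and survival", {
  X <- matrix(1L, 40, 4)
  fit <- cjs_fit(X)
  expect_lt(fit$deviance, 1e-3)
})

test_that("CJS m-array likelihood equals the per-history conditional product", {
  set.seed(17)
  T <- 5
  X <- matrix(rbinom(60 * T, 1, 0.5), 60)
  X <- X[rowSums(X) > 0, ]
  phi <- runif(T - 1, 0.5, 0.95); p <- c(NA, runif(T - 1, 0.2, 0.8))
  ma <- m_array(X)
  impl <- msord:::cjs_marray_loglik(ma, phi, c(0, p[-1]))
  oracle <- oracle_cjs_loglik(X, phi, c(0, p[-1]))
  expect_equal(impl, oracle, tolerance = 1e-10)
})

test_that("CJS recovers phi and p on simulated data", {
  set.seed(23)
  T <- 6; n <- 600; phi_true <- 0.85; p_true <- 0.5
  X <- matrix(0L, n, T)
  X[, 1] <- 1L
  alive <- rep(TRUE, n)
  for (t in 2:T) {
    alive <- alive & runif(n) < phi_true
    X[, t] <- ifelse(alive, rbinom(n, 1, p_true), 0L)
  }
  fit <- cjs_fit(X)
  expect_lt(abs(mean(fit$phi[1:(T - 2)]) - phi_true), 0.05)
  expect_lt(abs(mean(fit$p[2:(T - 1)]) - p_true), 0.06)
})

test_that("global c-hat pools components as a ratio of sums", {
  expect_equal(global_c_hat(531, 384), 1.38, tolerance = 0.005)
  expect_equal(global_c_hat(49, 23), 2.13, tolerance = 0.005)
  # ratio of sums, not mean of ratios
  chisq <- c(10, 50); df <- c(10, 40)
  expect_equal(global_c_hat(chisq, df), 1.2)
  expect_false(isTRUE(all.equal(global_c_hat(chisq, df), mean(chisq / df))))
  expect_equal(global_c_hat(0, 12), 0)
})

test_that("per-primary c-hat report pools into the global ratio", {
  d <- study_design(6, 4)
  sim <- simulate_msord(list(S = 0.95, p = 0.35, pent = c(0.4, 0.2, 0.1, 0.1, 0.1, 0.1),
                             phi = 0.8, psiPE = 0.3, psiEE = 0.5), d, 250, seed = 29)
  g <- median_c_hat(sim$data)
  expect_equal(attr(g, "global_c_hat"),
               sum(g$deviance) / sum(g$df), tolerance = 1e-12)
  expect_equal(g$c_hat, g$deviance / g$df, tolerance = 1e-12)
})

test_that("contingency components: null calibration and zero table", {
  # a perfectly balanced 2x2 gives chi-square zero
  expect_equal(msord:::pearson_chisq(matrix(10, 2, 2))$chisq, 0)

  # null calibration: homogeneous CJS data give mean chi-square close to df
  set.seed(37)
  T <- 6
  stats <- replicate(60, {
    X <- matrix(0L, 150, T)
    entry <- sample.int(2, 150, replace = TRUE)
    for (i in 1:150) {
      alive <- TRUE
      for (t in entry[i]:T) {
        if (!alive) break
        X[i, t] <- rbinom(1, 1, 0.55)
        alive <- runif(1) < 0.9
      }
    }
    X <- X[rowSums(X) > 0, ]
    rt <- release_tests(X)
    c(rt$test2$chisq / max(rt$test2$df, 1), rt$test3$chisq / max(rt$test3$df, 1))
  })
  expect_lt(abs(mean(stats[1, ]) - 1), 0.35)
  expect_lt(abs(mean(stats[2, ]) - 1), 0.35)
})

test_that("latent detection heterogeneity inflates TEST 2", {
  set.seed(41)
  T <- 6
  mk <- function(hetero) {
    n <- 400
    p_i <- if (hetero) ifelse(runif(n) < 0.5, 0.15, 0.85) else rep(0.5, n)
    X <- matrix(rbinom(n * T, 1, rep(p_i, T)), n)
    X[rowSums(X) > 0, ]
  }
  null_c <- release_tests(mk(FALSE))$test2$c_hat
  het_c <- release_tests(mk(TRUE))$test2$c_hat
  expect_gt(het_c, 2 * null_c)
})
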