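# Independent brute-force oracles, written as plain enumerations so they can
# vouch for the recursion-based implementations.

# all availability windows [a, d] with their masses, by direct products
oracle_windows <- function(pent, phi) {
  J <- length(pent)
  out <- list()
  for (a in seq_len(J)) for (d in a:J) {
    mass <- pent[a]
    if (d > a) for (j in a:(d - 1)) mass <- mass * phi[j]
    if (d < J) mass <- mass * (1 - phi[d])
    out[[length(out) + 1]] <- list(a = a, d = d, mass = mass)
  }
  out
}

oracle_wpp <- function(omega, pent, phi, p) {
  dets <- which(omega == 1)
  total <- 0
  for (w in oracle_windows(pent, phi)) {
    if (length(dets) && (min(dets) < w$a || max(dets) > w$d)) next
    em <- 1
    for (j in w$a:w$d) em <- em * (if (omega[j] == 1) p[j] else 1 - p[j])
    total <- total + w$mass * em
  }
  total
}

oracle_pstar <- function(pent, phi, p) {
  1 - oracle_wpp(rep(0, length(p)), pent, phi, p)
}

# brute-force MSORD history probability: enumerate latent state sequences
# (P / E / dead) over the primaries from first detection on, and availability
# windows within every P primary; condition on detection in the first primary.
oracle_history_prob <- function(history, params, design) {
  T <- design$n_primary; J <- design$n_secondary
  occ0 <- c(0, cumsum(J))
  omega <- lapply(seq_len(T), function(t) history[(occ0[t] + 1):occ0[t + 1]])
  f <- which(vapply(omega, function(o) any(o == 1), logical(1)))[1]

  emit <- function(t, state) {
    if (state == "P") oracle_wpp(omega[[t]], params$pent[[t]], params$phi[[t]], params$p[[t]])
    else if (any(omega[[t]] == 1)) 0 else 1
  }
  trans <- function(t, from, to) {
    S <- params$S[t]; pe <- params$psiPE[t]; ee <- params$psiEE[t]
    if (from == "D") return(if (to == "D") 1 else 0)
    if (to == "D") return(1 - S)
    stay_e <- if (from == "P") pe else ee
    S * (if (to == "E") stay_e else 1 - stay_e)
  }
  recurse <- function(t, state, prob) {
    prob <- prob * emit(t, state)
    if (prob == 0 || t == T) return(prob)
    total <- 0
    for (nxt in c("P", "E", "D"))
      total <- total + recurse(t + 1, nxt, prob * trans(t, state, nxt))
    total
  }
  recurse(f, "P", 1) / oracle_pstar(params$pent[[f]], params$phi[[f]], params$p[[f]])
}

# conditional CJS likelihood computed history-by-history (not via the m-array)
oracle_cjs_loglik <- function(X, phi, p) {
  T <- ncol(X)
  chi <- numeric(T); chi[T] <- 1
  if (T > 1) for (t in (T - 1):1)
    chi[t] <- (1 - phi[t]) + phi[t] * (1 - p[t + 1]) * chi[t + 1]
  ll <- 0
  for (i in seq_len(nrow(X))) {
    caps <- which(X[i, ] == 1)
    if (length(caps) < 1) next
    for (k in seq_along(caps)[-1]) {
      ci <- caps[k - 1]; cj <- caps[k]
      seg <- prod(phi[ci:(cj - 1)])
      if (cj > ci + 1) seg <- seg * prod(1 - p[(ci + 1):(cj - 1)])
      ll <- ll + log(seg * p[cj])
    }
    ll <- ll + log(chi[caps[length(caps)]])
  }
  ll
}

# expected window length (residence) by direct enumeration over windows
oracle_residence <- function(pent, phi) {
  sum(vapply(oracle_windows(pent, phi),
             function(w) w$mass * (w$d - w$a + 1), numeric(1)))
}

# random valid MSORD parameter set for property tests
random_msord_params <- function(design, seed) {
  set.seed(seed)
  T <- design$n_primary; J <- design$n_secondary
  list(S = runif(max(T - 1, 1), 0.6, 0.99),
       p = lapply(seq_len(T), function(t) runif(J[t], 0.1, 0.9)),
       pent = lapply(seq_len(T), function(t) {
         x <- runif(J[t]); x / sum(x)
       }),
       phi = lapply(seq_len(T), function(t) runif(max(J[t] - 1, 0), 0.2, 0.95)),
       psiPE = runif(max(T - 1, 1), 0.1, 0.7),
       psiEE = runif(max(T - 1, 1), 0.2, 0.8))
}
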