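#' Specify an MSORD model structure
#'
#' Declares how each parameter varies and the temporary-emigration regime,
#' using the conventional shorthand: `.` = constant, `season` = one value per
#' primary period, `season.day` (for entry/persistence) or `season.survey`
#' (for detection) = one value per secondary occasion.  Emigration is
#' `Markovian` (`psiPE` and `psiEE` free), `random` (`psiPE == psiEE`,
#' a single shared parameter) or `none` (both fixed at 0).  Appending `.t` to
#' the emigration token (e.g. `psi(Markovian.t)`) lets the transition
#' probabilities vary by inter-primary interval.
#'
#' A whole structure can be given as one string in the field notation, e.g.
#' `msord_structure("S(.) p(.) pent(season.day) phi(season.day) psi(Markovian)")`.
#'
#' Identifiability bookkeeping: each within-primary entry vector `pent_t` sums
#' to 1 and so has `J_t - 1` free cells (multinomial-logit, first occasion as
#' reference); persistence has `J_t - 1` cells.  Under `season` variation the
#' free entry cells of a primary share one parameter, so entry is uniform over
#' occasions 2..J relative to occasion 1.
#'
#' @param S `"constant"` or `"time"` (per inter-primary interval).
#' @param p `"constant"`, `"season"`, or `"season.survey"`.
#' @param pent,phi `"constant"`, `"season"`, or `"season.day"`.
#' @param emigration `"Markovian"`, `"random"`, or `"none"`.
#' @param psi_time `"constant"` or `"time"`.
#' @return An object of class `msord_structure`.
#' @export
msord_structure <- function(S = "constant", p = "constant",
                            pent = "constant", phi = "constant",
                            emigration = "Markovian", psi_time = "constant") {
  if (length(S) == 1 && grepl("\\(", S) && missing(p)) {
    return(parse_msord_structure(S))
  }
  norm <- function(x, allowed, what) {
    lookup <- c("." = "constant", "t" = "time", "season.survey" = "season.day")
    if (x %in% names(lookup)) x <- unname(lookup[x])
    if (!x %in% allowed)
      stop_msord("'", what, "' must be one of: ", paste(allowed, collapse = ", "))
    x
  }
  S <- norm(S, c("constant", "time"), "S")
  p <- norm(p, c("constant", "season", "season.day"), "p")
  pent <- norm(pent, c("constant", "season", "season.day"), "pent")
  phi <- norm(phi, c("constant", "season", "season.day"), "phi")
  emigration <- match.arg(emigration, c("Markovian", "random", "none"))
  psi_time <- match.arg(psi_time, c("constant", "time"))
  structure(list(S = S, p = p, pent = pent, phi = phi,
                 emigration = emigration, psi_time = psi_time),
            class = "msord_structure")
}

parse_msord_structure <- function(spec) {
  toks <- regmatches(spec, gregexpr("[A-Za-z]+\\(([^)]*)\\)", spec))[[1]]
  if (!length(toks)) stop_msord("cannot parse model structure: ", spec)
  get <- function(name, default) {
    hit <- toks[grepl(paste0("^", name, "\\("), toks, ignore.case = TRUE)]
    if (!length(hit)) return(default)
    sub("^[A-Za-z]+\\(([^)]*)\\)$", "\\1", hit[1])
  }
  map_var <- function(x) switch(tolower(x),
    "." = "constant", "t" = "time", "season" = "season", "time" = "time",
    "season.day" = "season.day", "season.survey" = "season.day",
    stop_msord("unknown variation token: ", x))
  psi_raw <- get("psi", "Markovian")
  psi_time <- if (grepl("\\.t$", psi_raw)) "time" else "constant"
  emi <- sub("\\.t$", "", psi_raw)
  emi <- match.arg(tolower(emi), c("markovian", "random", "none"))
  emi <- c(markovian = "Markovian", random = "random", none = "none")[emi]
  s_var <- map_var(get("S", "."))
  msord_structure(
    S = if (s_var == "season") "time" else s_var,
    p = {v <- map_var(get("p", ".")); if (v == "time") "season" else v},
    pent = {v <- map_var(get("pent", ".")); if (v == "time") "season" else v},
    phi = {v <- map_var(get("phi", ".")); if (v == "time") "season" else v},
    emigration = unname(emi), psi_time = psi_time)
}

#' @export
print.msord_structure <- function(x, ...) {
  cat("MSORD structure:", format(x), "\n")
  invisible(x)
}

#' @export
format.msord_structure <- function(x, ...) {
  shorthand <- function(v, daytok) switch(v, constant = ".", time = "t",
                                          season = "season", season.day = daytok)
  psi <- if (x$emigration == "none") "none"
  else paste0(x$emigration, if (x$psi_time == "time") ".t" else "")
  sprintf("S(%s) p(%s) pent(%s) phi(%s) psi(%s)",
          shorthand(x$S, "t"), shorthand(x$p, "season.survey"),
          shorthand(x$pent, "season.day"), shorthand(x$phi, "season.day"), psi)
}

# --- parameter-vector bookkeeping -------------------------------------------

# number of free link-scale parameters per block and their names
msord_par_map <- function(structure, design) {
  T <- design$n_primary; J <- design$n_secondary
  blocks <- list()
  if (T > 1) {
    blocks$S <- switch(structure$S, constant = "S",
                       time = paste0("S_", seq_len(T - 1)))
  }
  blocks$p <- switch(structure$p,
    constant = "p",
    season = paste0("p_", seq_len(T)),
    season.day = unlist(lapply(seq_len(T), function(t) paste0("p_", t, ".", seq_len(J[t])))))
  pent_free <- J - 1L
  blocks$pent <- switch(structure$pent,
    constant = if (any(pent_free > 0)) "pent" else character(0),
    season = paste0("pent_", which(pent_free > 0)),
    season.day = unlist(lapply(seq_len(T), function(t)
      if (pent_free[t] > 0) paste0("pent_", t, ".", 1 + seq_len(pent_free[t])) else character(0))))
  blocks$phi <- switch(structure$phi,
    constant = if (any(J > 1)) "phi" else character(0),
    season = paste0("phi_", which(J > 1)),
    season.day = unlist(lapply(seq_len(T), function(t)
      if (J[t] > 1) paste0("phi_", t, ".", seq_len(J[t] - 1)) else character(0))))
  if (T > 1 && structure$emigration != "none") {
    nint <- if (structure$psi_time == "time") T - 1 else 1
    tag <- if (nint > 1) paste0("_", seq_len(nint)) else ""
    if (structure$emigration == "Markovian")
      blocks$psi <- c(paste0("psiPE", tag), paste0("psiEE", tag))
    else blocks$psi <- paste0("psi", tag)
  } else blocks$psi <- character(0)
  blocks
}

msord_n_par <- function(structure, design) {
  sum(lengths(msord_par_map(structure, design)))
}

# expand a link-scale parameter vector to natural-scale parameter lists
expand_msord <- function(theta, structure, design) {
  T <- design$n_primary; J <- design$n_secondary
  map <- msord_par_map(structure, design)
  ix <- split(seq_along(theta), rep(names(map), lengths(map)))
  take <- function(b) theta[ix[[b]]]

  S <- if (T > 1) {
    v <- invlogit(take("S"))
    if (structure$S == "constant") rep(v, T - 1) else v
  } else numeric(0)

  p_raw <- take("p")
  p <- switch(structure$p,
    constant = lapply(seq_len(T), function(t) rep(invlogit(p_raw), J[t])),
    season = lapply(seq_len(T), function(t) rep(invlogit(p_raw[t]), J[t])),
    season.day = {
      off <- c(0, cumsum(J))
      lapply(seq_len(T), function(t) invlogit(p_raw[(off[t] + 1):off[t + 1]]))
    })

  pent_raw <- take("pent")
  pent <- switch(structure$pent,
    constant = lapply(seq_len(T), function(t)
      if (J[t] > 1) softmax1(rep(pent_raw, J[t] - 1)) else 1),
    season = {
      idx <- cumsum(J > 1)
      lapply(seq_len(T), function(t)
        if (J[t] > 1) softmax1(rep(pent_raw[idx[t]], J[t] - 1)) else 1)
    },
    season.day = {
      off <- c(0, cumsum(J - 1))
      lapply(seq_len(T), function(t)
        if (J[t] > 1) softmax1(pent_raw[(off[t] + 1):off[t + 1]]) else 1)
    })

  phi_raw <- take("phi")
  phi <- switch(structure$phi,
    constant = lapply(seq_len(T), function(t) rep(invlogit(phi_raw), max(J[t] - 1, 0))),
    season = {
      idx <- cumsum(J > 1)
      lapply(seq_len(T), function(t)
        if (J[t] > 1) rep(invlogit(phi_raw[idx[t]]), J[t] - 1) else numeric(0))
    },
    season.day = {
      off <- c(0, cumsum(pmax(J - 1, 0)))
      lapply(seq_len(T), function(t)
        if (J[t] > 1) invlogit(phi_raw[(off[t] + 1):off[t + 1]]) else numeric(0))
    })

  if (T > 1) {
    nint <- T - 1
    if (structure$emigration == "none") {
      psiPE <- psiEE <- rep(0, nint)
    } else {
      ps <- invlogit(take("psi"))
      if (structure$emigration == "Markovian") {
        half <- length(ps) / 2
        psiPE <- rep_len(ps[seq_len(half)], nint)
        psiEE <- rep_len(ps[half + seq_len(half)], nint)
      } else {
        psiPE <- psiEE <- rep_len(ps, nint)
      }
    }
  } else psiPE <- psiEE <- numeric(0)

  list(S = S, p = p, pent = pent, phi = phi, psiPE = psiPE, psiEE = psiEE)
}

# default/jittered start values on the link scale
msord_start <- function(structure, design) {
  map <- msord_par_map(structure, design)
  unlist(lapply(names(map), function(b) {
    n <- length(map[[b]])
    stats::setNames(rep(switch(b, S = logit(0.9), p = logit(0.2),
                               pent = 0, phi = logit(0.6),
                               psi = logit(0.3)), n), map[[b]])
  }))
}
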