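#' Define a robust-design sampling layout
#'
#' A study design records the ordered primary periods (seasons) and the number
#' of secondary occasions (complete surveys) nested within each.  Occasions are
#' indexed 1-based and stored primary-major: the columns of a capture matrix
#' run secondary 1..J of primary 1, then secondary 1..J of primary 2, and so on.
#'
#' @param n_secondary integer vector, number of secondary occasions per primary
#'   period; a single value is recycled across `n_primary` primaries.
#' @param n_primary number of primary periods; defaults to `length(n_secondary)`.
#' @param labels optional character labels for the primary periods (e.g.
#'   `"Spring 2021"`); must be unique.
#' @param dates optional data.frame of calendar metadata (reporting only).
#' @return An object of class `study_design` with elements `n_primary`,
#'   `n_secondary` (vector of length `n_primary`), `labels`, `occasion_primary`
#'   (primary index of every occasion column) and `n_occasions`.
#' @examples
#' study_design(6, n_primary = 8)
#' @export
study_design <- function(n_secondary, n_primary = length(n_secondary),
                         labels = NULL, dates = NULL) {
  if (n_primary < 1) stop_msord("a design needs at least one primary period")
  n_secondary <- as.integer(rep_len(n_secondary, n_primary))
  if (any(n_secondary < 1)) stop_msord("every primary needs >= 1 secondary occasion")
  if (is.null(labels)) labels <- paste0("primary", seq_len(n_primary))
  if (anyDuplicated(labels)) stop_msord("primary labels must be unique")
  if (length(labels) != n_primary) stop_msord("one label per primary period")
  structure(list(
    n_primary = as.integer(n_primary),
    n_secondary = n_secondary,
    labels = as.character(labels),
    dates = dates,
    occasion_primary = rep(seq_len(n_primary), n_secondary),
    n_occasions = sum(n_secondary)
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Robust-design layout:", x$n_primary, "primary periods,",
      x$n_occasions, "secondary occasions\n")
  cat("  secondaries per primary:", paste(x$n_secondary, collapse = " "), "\n")
  invisible(x)
}

# column indices of primary t
design_cols <- function(design, t) {
  which(design$occasion_primary == t)
}
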