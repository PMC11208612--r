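#' Mark-rate estimation from group sightings
#'
#' Capture-recapture estimates from photo-identification relate only to the
#' distinctively marked fraction of a population.  The mark rate theta -- the
#' proportion of animals with individually identifiable marks -- is estimated
#' by two independent methods and the two estimates averaged before scaling
#' abundance:
#'
#' * **Method 1** ([theta1()]): among fully photographed groups larger than the
#'   size threshold, the proportion of high-quality images showing a distinct
#'   fin, `theta1 = sum(images_distinct) / sum(images_total)`.
#' * **Method 2** ([theta2()]): among fully photographed groups at or below the
#'   threshold (where field counts of group size are reliable), the proportion
#'   of individuals that are distinct, `theta2 = sum(n_distinct) / sum(group_size)`.
#'
#' Both use the binomial standard error `sqrt(theta * (1 - theta) / n)` with
#' `n` the pooled denominator.  Numerators and denominators are pooled across
#' sightings (a single ratio of totals, not a mean of per-sighting ratios).
#'
#' @param sightings data.frame of group sightings with columns `sighting_id`,
#'   `group_size`, `n_distinct`, `images_distinct`, `images_total`,
#'   `full_coverage` (logical: all animals in the group photographed).
#' @param threshold group-size cut between the two methods (default 20,
#'   inclusive for method 2).
#' @return A `mark_rate` object: list with `theta`, `se`, `n`, `method`, and
#'   for [combine_mark_rates()] the component estimates.
#' @name mark_rate
NULL

new_mark_rate <- function(theta, se, n, method, components = NULL) {
  structure(list(theta = theta, se = se, n = n, method = method,
                 components = components), class = "mark_rate")
}

#' @export
print.mark_rate <- function(x, ...) {
  cat(sprintf("Mark rate (%s): theta = %.4f (SE %.4f, n = %d)\n",
              x$method, x$theta, x$se, as.integer(x$n)))
  if (!is.null(x$components))
    for (cm in x$components)
      cat(sprintf("  component %s: %.4f (SE %.4f)\n", cm$method, cm$theta, cm$se))
  invisible(x)
}

binom_se <- function(theta, n) sqrt(theta * (1 - theta) / n)

#' @rdname mark_rate
#' @export
theta1 <- function(sightings, threshold = 20) {
  s <- partition_groups(sightings, threshold)$large
  if (!nrow(s)) stop_msord("no fully photographed groups above the size threshold")
  ntot <- sum(s$images_total)
  if (ntot <= 0) stop_msord("zero total images among qualifying sightings")
  th <- sum(s$images_distinct) / ntot
  new_mark_rate(th, binom_se(th, ntot), ntot, "images")
}

#' @rdname mark_rate
#' @export
theta2 <- function(sightings, threshold = 20) {
  s <- partition_groups(sightings, threshold)$small
  if (!nrow(s)) stop_msord("no fully photographed groups at or below the size threshold")
  n <- sum(s$group_size)
  th <- sum(s$n_distinct) / n
  new_mark_rate(th, binom_se(th, n), n, "groups")
}

#' Average independent mark-rate estimates
#'
#' The combined rate is the unweighted arithmetic mean of the component
#' estimates (component estimates are carried along for reporting).  A single
#' estimate is returned unchanged.
#'
#' @param ... `mark_rate` objects (or a single list of them).
#' @return A `mark_rate` with `method = "combined"`.
#' @export
combine_mark_rates <- function(...) {
  ests <- list(...)
  if (length(ests) == 1 && !inherits(ests[[1]], "mark_rate")) ests <- ests[[1]]
  if (!length(ests)) stop_msord("no mark-rate estimates to combine")
  if (!all(vapply(ests, inherits, logical(1), "mark_rate")))
    stop_msord("all inputs must be mark_rate objects")
  if (length(ests) == 1) return(ests[[1]])
  th <- mean(vapply(ests, `[[`, numeric(1), "theta"))
  # SE of an unweighted mean of independent estimates
  se <- sqrt(sum(vapply(ests, `[[`, numeric(1), "se")^2)) / length(ests)
  new_mark_rate(th, se, sum(vapply(ests, `[[`, numeric(1), "n")),
                "combined", components = ests)
}

#' Partition group sightings by size and photographic coverage
#'
#' Fully photographed groups are split at the size threshold: `large`
#' (size > threshold, used by method 1) and `small` (size <= threshold, used
#' by method 2); sightings without full photographic coverage are `excluded`
#' regardless of size.
#'
#' @inheritParams mark_rate
#' @return list of data.frames `large`, `small`, `excluded`.
#' @export
partition_groups <- function(sightings, threshold = 20) {
  full <- as.logical(sightings$full_coverage)
  list(large = sightings[full & sightings$group_size > threshold, , drop = FALSE],
       small = sightings[full & sightings$group_size <= threshold, , drop = FALSE],
       excluded = sightings[!full, , drop = FALSE])
}

#' Read a group-sightings CSV
#'
#' Columns: `sighting_id`, `group_size`, `n_distinct`, `images_distinct`,
#' `images_total`, `full_coverage`.
#'
#' @param path CSV file.
#' @return data.frame of sightings (validated).
#' @export
read_sightings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sighting_id", "group_size", "n_distinct", "images_distinct",
            "images_total", "full_coverage")
  if (!all(need %in% names(df)))
    stop_msord("sightings CSV needs columns: ", paste(need, collapse = ", "))
  if (any(df$n_distinct > df$group_size))
    stop_msord("n_distinct cannot exceed group_size")
  if (any(df$images_distinct > df$images_total))
    stop_msord("images_distinct cannot exceed images_total")
  df$full_coverage <- as.logical(df$full_coverage)
  df
}
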