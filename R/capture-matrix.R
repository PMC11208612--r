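#' Capture histories over a robust design
#'
#' A capture matrix holds binary detections, one row per identified individual
#' and one column per secondary occasion (primary-major column order, see
#' [study_design()]).  Every retained individual must be detected at least
#' once; conditional-likelihood models cannot use all-zero histories.
#'
#' @param detections 0/1 matrix, individuals x occasions.
#' @param design a [study_design()] whose occasion count matches `ncol(detections)`.
#' @param ids optional unique individual identifiers (default `rownames` or
#'   `ind1..indn`).
#' @param drop_empty drop all-zero rows with a warning instead of erroring.
#' @return An object of class `capture_matrix`: the detection matrix with
#'   attributes `design` and `ids`.
#' @export
capture_matrix <- function(detections, design, ids = NULL, drop_empty = TRUE) {
  detections <- as.matrix(detections)
  if (!all(detections %in% c(0, 1)))
    stop_msord("detections must contain only 0 and 1")
  if (ncol(detections) != design$n_occasions)
    stop_msord("detection matrix has ", ncol(detections),
               " columns but the design has ", design$n_occasions, " occasions")
  if (is.null(ids)) ids <- rownames(detections) %||% paste0("ind", seq_len(nrow(detections)))
  if (anyDuplicated(ids)) stop_msord("individual ids must be unique")
  empty <- rowSums(detections) == 0
  if (any(empty)) {
    if (!drop_empty) stop_msord(sum(empty), " individuals have no detections")
    warning(sum(empty), " individual(s) with zero detections dropped", call. = FALSE)
    detections <- detections[!empty, , drop = FALSE]
    ids <- ids[!empty]
  }
  storage.mode(detections) <- "integer"
  rownames(detections) <- ids
  colnames(detections) <- paste0("p", design$occasion_primary, ".s",
                                 unlist(lapply(design$n_secondary, seq_len)))
  structure(detections, design = design, ids = ids, class = "capture_matrix")
}

#' @export
print.capture_matrix <- function(x, ...) {
  d <- attr(x, "design")
  cat("Capture histories:", nrow(x), "individuals,", d$n_primary,
      "primary periods (", paste(d$n_secondary, collapse = "+"), "occasions )\n")
  cat("  total detections:", sum(x), "\n")
  invisible(x)
}

#' @export
summary.capture_matrix <- function(object, ...) {
  d <- attr(object, "design")
  per_primary <- vapply(seq_len(d$n_primary), function(t)
    sum(rowSums(object[, design_cols(d, t), drop = FALSE]) > 0), integer(1))
  out <- list(n_individuals = nrow(object),
              detections = sum(object),
              detected_per_primary = stats::setNames(per_primary, d$labels))
  class(out) <- "summary.capture_matrix"
  out
}

#' @export
print.summary.capture_matrix <- function(x, ...) {
  cat("Individuals:", x$n_individuals, " total detections:", x$detections, "\n")
  cat("Distinct individuals per primary period:\n")
  print(x$detected_per_primary)
  invisible(x)
}

design_of <- function(x) attr(x, "design")

#' @export
`[.capture_matrix` <- function(x, i, j, drop = FALSE) {
  if (!missing(j)) return(unclass(x)[i, j, drop = drop])
  out <- unclass(x)[i, , drop = FALSE]
  capture_matrix(out, attr(x, "design"), ids = rownames(out))
}

#' Read MARK-style `.inp` capture histories
#'
#' Parses the MARK input dialect: one history string over `{0,1}` per line,
#' an optional positive frequency, a terminating `;`, and `/* ... */` comments.
#' Frequencies greater than one are expanded to one row per individual;
#' negative frequencies (losses on capture) are rejected.
#'
#' @param path file to read.
#' @param design the [study_design()] the histories are laid out over.
#' @return A [capture_matrix()].
#' @examples
#' inp <- system.file("extdata", "synthetic_histories.inp", package = "msord")
#' read_inp(inp, study_design(6, n_primary = 8))
#' @export
read_inp <- function(path, design) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  # strip comments (non-greedy, may span lines)
  txt <- gsub("/\\*.*?\\*/", " ", txt, perl = TRUE)
  stmts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  if (length(stmts) && !grepl(";", txt, fixed = TRUE) && nzchar(trimws(txt)))
    stop_msord("no ';' statement terminator found in ", path)
  rows <- list(); ids <- character(0); k <- 0L
  for (s in stmts) {
    s <- trimws(s)
    if (!nzchar(s)) next
    parts <- strsplit(s, "\\s+")[[1]]
    hist <- parts[1]
    freq <- if (length(parts) >= 2) suppressWarnings(as.numeric(parts[2])) else 1
    if (is.na(freq) || freq != as.integer(freq))
      stop_msord("bad frequency in statement: ", s)
    if (freq < 0) stop_msord("negative frequencies (losses on capture) are not supported: ", s)
    if (grepl("[^01]", hist))
      stop_msord("history contains characters outside {0,1}: ", hist)
    if (nchar(hist) != design$n_occasions)
      stop_msord("history length ", nchar(hist), " does not match the design's ",
                 design$n_occasions, " occasions: ", hist)
    bits <- as.integer(strsplit(hist, "")[[1]])
    for (r in seq_len(freq)) {
      k <- k + 1L
      rows[[k]] <- bits
      ids[k] <- paste0("ind", k)
    }
  }
  det <- if (k) do.call(rbind, rows) else matrix(integer(0), 0, design$n_occasions)
  capture_matrix(det, design, ids = if (k) ids else character(0))
}

#' Write a capture matrix in MARK `.inp` format
#'
#' One line per individual (frequency 1), history unwrapped on a single line,
#' re-readable by [read_inp()] to an identical matrix.
#'
#' @param x a [capture_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_inp <- function(x, path) {
  d <- design_of(x)
  header <- sprintf("/* %d individuals, %d primary periods x (%s) secondary occasions */",
                    nrow(x), d$n_primary, paste(d$n_secondary, collapse = ","))
  lines <- c(header,
             if (nrow(x)) paste0(apply(unclass(x), 1, paste, collapse = ""), " 1;"))
  writeLines(lines, path)
  invisible(path)
}

#' Read long-format capture records from CSV
#'
#' The native tabular dialect: columns `individual_id`, `primary`, `secondary`,
#' `detected` (0/1).  Rows with `detected == 0` are allowed and ignored.
#'
#' @param path CSV file.
#' @param design the [study_design()].
#' @return A [capture_matrix()].
#' @export
read_captures_csv <- function(path, design) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "primary", "secondary", "detected")
  if (!all(need %in% names(df)))
    stop_msord("capture CSV needs columns: ", paste(need, collapse = ", "))
  df <- df[df$detected > 0, , drop = FALSE]
  ids <- sort(unique(df$individual_id))
  det <- matrix(0L, length(ids), design$n_occasions, dimnames = list(ids, NULL))
  occ0 <- c(0L, cumsum(design$n_secondary))
  bad <- df$primary < 1 | df$primary > design$n_primary |
    df$secondary < 1 | df$secondary > design$n_secondary[pmax(df$primary, 1)]
  if (any(bad)) stop_msord(sum(bad), " record(s) outside the design bounds")
  det[cbind(match(df$individual_id, ids), occ0[df$primary] + df$secondary)] <- 1L
  capture_matrix(det, design, ids = ids)
}

#' Filter graded photo-identification records
#'
#' Keeps records whose image quality and fin distinctiveness both pass: by
#' default excellent/good quality and the two highest distinctiveness grades
#' (D1, D2), the inclusion rule used to build mark-recapture histories from
#' graded dorsal-fin photographs.  Poor-quality images and weakly marked or
#' clean fins (D3, D4) are excluded.
#'
#' @param records data.frame with columns `individual_id`, `sighting_id`,
#'   `quality` (`excellent`/`good`/`poor`), `distinctiveness` (`D1`..`D4`),
#'   `primary`, `secondary`.
#' @param keep_quality,keep_distinctiveness grades to retain.
#' @return The retained records, with attribute `removed` giving counts of
#'   records removed per reason (`quality`, `distinctiveness`, `both`).
#' @export
filter_photo_records <- function(records,
                                 keep_quality = c("excellent", "good"),
                                 keep_distinctiveness = c("D1", "D2")) {
  qual_levels <- c("excellent", "good", "poor")
  dist_levels <- c("D1", "D2", "D3", "D4")
  bad_q <- !(records$quality %in% qual_levels)
  bad_d <- !(records$distinctiveness %in% dist_levels)
  if (any(bad_q | bad_d))
    stop_msord("unknown grade token in records: ",
               paste(utils::head(which(bad_q | bad_d), 5), collapse = ", "))
  fail_q <- !(records$quality %in% keep_quality)
  fail_d <- !(records$distinctiveness %in% keep_distinctiveness)
  keep <- !fail_q & !fail_d
  out <- records[keep, , drop = FALSE]
  attr(out, "removed") <- c(quality = sum(fail_q & !fail_d),
                            distinctiveness = sum(fail_d & !fail_q),
                            both = sum(fail_q & fail_d))
  out
}

#' Build a capture matrix from filtered photo records
#'
#' A cell is 1 iff the individual has at least one record in that
#' (primary, secondary) occasion.  Individuals are ordered by first detection
#' occasion, ties broken by id; records without an individual id
#' (unidentified fins) are dropped.
#'
#' @param records filtered photo records (see [filter_photo_records()]).
#' @param design the [study_design()].
#' @return A [capture_matrix()].
#' @export
build_capture_matrix <- function(records, design) {
  records <- records[!is.na(records$individual_id), , drop = FALSE]
  if (!nrow(records))
    return(capture_matrix(matrix(integer(0), 0, design$n_occasions), design,
                          ids = character(0)))
  bad <- records$primary < 1 | records$primary > design$n_primary |
    records$secondary < 1 |
    records$secondary > design$n_secondary[pmax(pmin(records$primary, design$n_primary), 1)]
  if (any(bad)) stop_msord(sum(bad), " record(s) outside the design bounds")
  occ0 <- c(0L, cumsum(design$n_secondary))
  occ <- occ0[records$primary] + records$secondary
  ids <- unique(records$individual_id)
  det <- matrix(0L, length(ids), design$n_occasions, dimnames = list(ids, NULL))
  det[cbind(match(records$individual_id, ids), occ)] <- 1L
  first <- apply(det, 1, function(r) which(r == 1)[1])
  ord <- order(first, ids)
  capture_matrix(det[ord, , drop = FALSE], design, ids = ids[ord])
}

#' Pool secondary occasions within primary periods
#'
#' Collapses a robust-design capture matrix to one seen/not-seen column per
#' primary period (the POPAN occasion structure): the pooled cell is 1 iff the
#' individual was detected on any secondary occasion of that primary.
#'
#' @param x a [capture_matrix()].
#' @return An object of class `pooled_matrix`: individuals x primaries 0/1
#'   matrix with attribute `design`.
#' @export
pool_primaries <- function(x) {
  d <- design_of(x)
  pooled <- vapply(seq_len(d$n_primary), function(t)
    as.integer(rowSums(x[, design_cols(d, t), drop = FALSE]) > 0),
    integer(nrow(x)))
  pooled <- matrix(pooled, nrow = nrow(x),
                   dimnames = list(rownames(x), d$labels))
  structure(pooled, design = d, class = "pooled_matrix")
}

#' @export
print.pooled_matrix <- function(x, ...) {
  cat("Pooled histories:", nrow(x), "individuals x", ncol(x), "primary occasions\n")
  invisible(x)
}

#' Reduced m-array of first recaptures
#'
#' For each release occasion i (all animals detected at i, including
#' re-releases), counts animals next detected at each later occasion j and
#' those never detected again.  Cohort totals are conserved:
#' `rowSums(m) + never == releases`.
#'
#' @param x a `pooled_matrix` (or any 0/1 matrix with >= 2 occasion columns).
#' @return An object of class `m_array`: list with `releases` (length T-1),
#'   `m` ((T-1) x T matrix, entries `m[i, j]` for j > i), `never` (length T-1).
#' @export
m_array <- function(x) {
  x <- unclass(as.matrix(x))
  T <- ncol(x)
  if (T < 2) stop_msord("an m-array needs at least 2 occasions")
  m <- matrix(0L, T - 1, T, dimnames = list(paste0("rel", seq_len(T - 1)),
                                            paste0("occ", seq_len(T))))
  releases <- integer(T - 1); never <- integer(T - 1)
  for (i in seq_len(T - 1)) {
    rel <- which(x[, i] == 1)
    releases[i] <- length(rel)
    for (r in rel) {
      nxt <- which(x[r, (i + 1):T] == 1)
      if (length(nxt)) m[i, i + nxt[1]] <- m[i, i + nxt[1]] + 1L
      else never[i] <- never[i] + 1L
    }
  }
  structure(list(releases = releases, m = m, never = never), class = "m_array")
}

#' @export
print.m_array <- function(x, ...) {
  cat("m-array (", length(x$releases), "release cohorts )\n")
  tab <- cbind(releases = x$releases, x$m[, -1, drop = FALSE], never = x$never)
  print(tab)
  invisible(x)
}
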