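test_that("read_inp parses histories, frequencies and comments", {
  d <- study_design(6, 1)
  f <- withr::local_tempfile(fileext = ".inp")
  writeLines(c("/* synthetic example */", "101000 1;", "010101 2;"), f)
  cm <- read_inp(f, d)
  expect_equal(nrow(cm), 3)
  expect_equal(unname(unclass(cm)[1, ]), c(1, 0, 1, 0, 0, 0))
  expect_equal(unclass(cm)[2, ], unclass(cm)[3, ], ignore_attr = TRUE)
})

test_that("read_inp rejects malformed input with informative errors", {
  d <- study_design(6, 1)
  f <- withr::local_tempfile(fileext = ".inp")
  writeLines("10100 1;", f)   # ragged length
  expect_error(read_inp(f, d), "length")
  writeLines("1012a0 1;", f)
  expect_error(read_inp(f, d), "outside \\{0,1\\}")
  writeLines("101000 1", f)   # no terminator
  expect_error(read_inp(f, d), ";")
  writeLines("101000 -1;", f) # loss on capture
  expect_error(read_inp(f, d), "negative")
})

test_that("write_inp / read_inp round-trips matrices, including 48 occasions", {
  for (spec in list(list(J = 6, T = 2, n = 5), list(J = 6, T = 8, n = 12))) {
    d <- study_design(spec$J, spec$T)
    set.seed(spec$n)
    det <- matrix(rbinom(spec$n * d$n_occasions, 1, 0.3), spec$n)
    det[rowSums(det) == 0, 1] <- 1L
    cm <- capture_matrix(det, d)
    f <- withr::local_tempfile(fileext = ".inp")
    write_inp(cm, f)
    # histories stay on one line each
    hist_lines <- grep("^[01]", readLines(f), value = TRUE)
    expect_true(all(nchar(sub(" .*", "", hist_lines)) == d$n_occasions))
    back <- read_inp(f, d)
    expect_equal(unclass(back), unclass(cm), ignore_attr = TRUE)
  }
})

test_that("empty matrix writes a header-only file", {
  d <- study_design(4, 2)
  cm <- capture_matrix(matrix(integer(0), 0, 8), d, ids = character(0))
  f <- withr::local_tempfile(fileext = ".inp")
  write_inp(cm, f)
  expect_match(readLines(f), "^/\\*")
  expect_length(readLines(f), 1)
})

test_that("photo-record filtering keeps good/excellent D1-D2 only", {
  rec <- data.frame(
    individual_id = c("a", "b", "c", "d", "e"),
    sighting_id = "s1",
    quality = c("good", "poor", "excellent", "good", "poor"),
    distinctiveness = c("D2", "D1", "D1", "D3", "D4"),
    primary = 1, secondary = 1)
  out <- filter_photo_records(rec)
  expect_equal(out$individual_id, c("a", "c"))
  expect_equal(attr(out, "removed"),
               c(quality = 1, distinctiveness = 1, both = 1))

  empty <- filter_photo_records(rec[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(sum(attr(empty, "removed")), 0)

  bad <- transform(rec, quality = c("good", "great", "poor", "good", "poor"))
  expect_error(filter_photo_records(bad), "unknown grade")
})

test_that("build_capture_matrix is idempotent per cell and bounds-checked", {
  d <- study_design(3, 2)
  rec <- data.frame(individual_id = c("x", "x", "y", "z"), sighting_id = "s",
                    quality = "good", distinctiveness = "D1",
                    primary = c(1, 1, 1, 2), secondary = c(2, 2, 1, 3))
  cm <- build_capture_matrix(rec, d)
  expect_equal(nrow(cm), 3)
  expect_equal(sum(cm), 3)             # duplicate record collapses to one 1
  expect_equal(rownames(cm)[1:2], c("y", "x"))  # ordered by first detection
  rec$secondary[4] <- 4
  expect_error(build_capture_matrix(rec, d), "outside the design")
})

test_that("pooling collapses secondaries and is monotone", {
  d <- study_design(6, 2)
  cm <- capture_matrix(rbind(c(1,0,1,0,0,0, 0,0,0,0,0,0),
                             c(0,1,0,0,0,0, 0,0,0,1,0,0)), d)
  pl <- pool_primaries(cm)
  expect_equal(unname(unclass(pl)), rbind(c(1L, 0L), c(1L, 1L)),
               ignore_attr = TRUE)

  # monotone: adding a detection never removes a pooled 1
  set.seed(42)
  det <- matrix(rbinom(20 * 12, 1, 0.2), 20); det[rowSums(det) == 0, 1] <- 1L
  cm1 <- capture_matrix(det, d)
  p1 <- unclass(pool_primaries(cm1))
  det2 <- det; det2[3, 8] <- 1L
  p2 <- unclass(pool_primaries(capture_matrix(det2, d)))
  expect_true(all(p2 >= p1))

  # pooled row sums equal the direct count of primaries with a detection
  direct <- vapply(seq_len(20), function(i)
    sum(vapply(1:2, function(t) any(det[i, ((t - 1) * 6 + 1):(t * 6)] == 1),
               logical(1))), numeric(1))
  expect_equal(unname(rowSums(p1)), direct)
})

test_that("m-array records first recaptures and conserves cohorts", {
  # histories {11, 10, 01}
  ma <- m_array(rbind(c(1, 1), c(1, 0), c(0, 1)))
  expect_equal(ma$releases, 2)
  expect_equal(ma$m[1, 2], 1L)
  expect_equal(ma$never, 1L)

  # seen at 1 and 3 of 3 contributes m_13, not m_12
  ma3 <- m_array(rbind(c(1, 0, 1)))
  expect_equal(ma3$m[1, 3], 1L)
  expect_equal(ma3$m[1, 2], 0L)

  expect_error(m_array(matrix(1, 3, 1)), "2 occasions")

  # conservation on simulated data
  set.seed(8)
  X <- matrix(rbinom(300, 1, 0.4), 60); X <- X[rowSums(X) > 0, ]
  ma <- m_array(X)
  expect_equal(unname(rowSums(ma$m) + ma$never), ma$releases)
})

test_that("long-format CSV reader matches a hand-built matrix", {
  d <- study_design(3, 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(individual_id = c("a", "a", "b"),
                       primary = c(1, 2, 1), secondary = c(1, 3, 2),
                       detected = 1), f, row.names = FALSE)
  cm <- read_captures_csv(f, d)
  expect_equal(unname(unclass(cm)),
               rbind(c(1L, 0L, 0L, 0L, 0L, 1L), c(0L, 1L, 0L, 0L, 0L, 0L)),
               ignore_attr = TRUE)
})

test_that("all-zero histories are dropped with a warning", {
  d <- study_design(2, 1)
  expect_warning(cm <- capture_matrix(rbind(c(1, 0), c(0, 0)), d), "dropped")
  expect_equal(nrow(cm), 1)
})
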