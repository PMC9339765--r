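test_that("construction and direct counts work on a hand-built dataset", {
  m <- matrix(1L, 3, 2)
  ds <- ds_from_matrix(m)
  expect_s3_class(ds, "detection_data")
  expect_equal(mln(ds)$mln, 3L)
  expect_equal(unname(plot_matrix(ds, "P")), m)
})

test_that("structural invariants are enforced with descriptive errors", {
  m <- matrix(1L, 2, 2)
  ds <- ds_from_matrix(m)

  bad <- ds
  bad$detections$detected[1] <- 2L
  expect_error(validate_detection_data(bad), "non-binary")

  bad <- ds
  bad$surveyors <- dplyr::bind_rows(bad$surveyors, bad$surveyors[1, ])
  expect_error(validate_detection_data(bad), "duplicate surveyor")

  bad <- ds
  bad$surveyors$experience[1] <- "guru"
  expect_error(validate_detection_data(bad), "expert")

  bad <- ds
  bad$occasions$surveyor_id[2] <- "S1"
  expect_error(validate_detection_data(bad), "at most once")

  bad <- ds
  bad$individuals$hibernaculum_id[2] <- bad$individuals$hibernaculum_id[1]
  expect_error(validate_detection_data(bad), "duplicate hibernaculum")

  bad <- ds
  bad$plots$area <- -5
  expect_error(validate_detection_data(bad), "area")

  # field data must not contain never-detected individuals
  bad <- ds
  bad$detections$detected <- 0L
  expect_error(validate_detection_data(bad), "never-detected")
})

test_that("CSV round-trip is bit-exact and errors name the offending cell", {
  set.seed(11)
  ds <- simulate_population(sim_config(seed = 11))
  dpath <- withr::local_tempfile(fileext = ".csv")
  spath <- withr::local_tempfile(fileext = ".csv")
  ppath <- withr::local_tempfile(fileext = ".csv")
  write_detections(ds, dpath, spath, ppath)
  ds2 <- read_detections(dpath, spath, ppath)

  for (p in ds$plots$plot_id) {
    m1 <- plot_matrix(ds, p)
    m2 <- plot_matrix(ds2, p)
    expect_identical(m2[rownames(m1), colnames(m1)], m1)
    # occasion order preserved
    expect_identical(colnames(m2), colnames(m1))
  }
  expect_identical(
    dplyr::arrange(ds2$individuals, hibernaculum_id),
    dplyr::arrange(ds$individuals, hibernaculum_id)
  )

  # corrupt one detection cell
  raw <- readLines(dpath)
  raw[2] <- sub(",1", ",2", raw[2])
  writeLines(raw, dpath)
  expect_error(read_detections(dpath, spath), "non-binary value '2'")
})

test_that("encounter-history (.inp) output matches the occasion order and round-trips", {
  m <- rbind(c(1, 0, 1, 0), c(0, 1, 1, 1))
  ds <- ds_from_matrix(m)
  path <- withr::local_tempfile(fileext = ".inp")
  write_inp(ds, path)
  lines <- grep(";", readLines(path), value = TRUE)
  expect_match(lines[1], "1010 1;", fixed = TRUE)
  expect_match(lines[2], "0111 1;", fixed = TRUE)

  ds_big <- simulate_population(sim_config(seed = 5))
  path2 <- withr::local_tempfile(fileext = ".inp")
  write_inp(ds_big, path2)
  # all history strings have the same (global) length, with '.' padding
  hist <- sub("^/\\* \\S+ \\*/ ([01.]+) .*$", "\\1",
              grep(";", readLines(path2), value = TRUE))
  expect_length(unique(nchar(hist)), 1)
  back <- read_inp(path2, surveyors = ds_big$surveyors)
  for (p in ds_big$plots$plot_id) {
    m1 <- plot_matrix(ds_big, p)
    m2 <- plot_matrix(back, p)
    expect_identical(m2[rownames(m1), colnames(m1)], m1)
  }
})

test_that("closure filtering drops lost individuals, reports the count, and is idempotent", {
  set.seed(2)
  m <- rand_capture_matrix(50, 4, 0.8)
  ds <- ds_from_matrix(m)
  expect_equal(attr(filter_closure(ds), "n_removed"), 0)
  expect_equal(mln(filter_closure(ds))$mln, mln(ds)$mln)

  n <- nrow(ds$individuals)
  ds$individuals$lost[seq_len(10)] <- TRUE
  f1 <- filter_closure(ds)
  expect_equal(attr(f1, "n_removed"), 10)
  expect_equal(nrow(f1$individuals), n - 10)
  f2 <- filter_closure(f1)
  expect_equal(attr(f2, "n_removed"), 0)
  expect_identical(f2$individuals, f1$individuals)

  # mln bounded by matrix rows; equality holds once data are field-like
  expect_lte(mln(f1)$mln, nrow(plot_matrix(f1, "P")))
  expect_equal(mln(f1)$mln, nrow(plot_matrix(f1, "P")))
})

test_that("mln handles perfect detection and unknown plots", {
  m <- matrix(1L, 100, 1)
  ds <- ds_from_matrix(m)
  expect_equal(mln(ds)$mln, 100)
  expect_error(mln(ds, "Z"), "unknown plot")
})
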