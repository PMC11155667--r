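# output files, TOML round trips and the tamper-evident lock report

fit_small <- function(seed = 5) {
  tt <- truth_table(data.frame(kind = "gaussian", amplitude = 2, center = 5,
                               width = 1.5),
                    grid = seq(0, 10, length.out = 60),
                    noise_sd = 0.01, seed = seed)
  s <- make_spectrum(tt)$spectrum
  pr <- project_from_truth(tt)
  list(project = pr, spectrum = s, result = fit(pr, s))
}

test_that("write_outputs emits the CSV/JSON set with expected headers", {
  f <- fit_small()
  base <- file.path(withr::local_tempdir(), "run1")
  paths <- write_outputs(f$result, f$spectrum, f$project, base)
  expect_true(all(file.exists(paths)))
  expect_length(paths, 4)
  fit_csv <- read.csv(paths[1], check.names = FALSE)
  expect_named(fit_csv, c("energy", "data", "fit", "gaussian_1", "residual"))
  err_csv <- read.csv(paths[2])
  expect_true(all(c("name", "value", "stderr") %in% names(err_csv)))
  expect_setequal(err_csv$name, f$result$params$name)
  cm <- read.csv(paths[3], check.names = FALSE)
  expect_identical(nrow(cm), ncol(cm) - 1L)           # square + label column
  expect_equal(diag(as.matrix(cm[, -1])), rep(1, nrow(cm)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # JSON reload equals the in-memory record
  rec <- jsonlite::fromJSON(paths[4], simplifyVector = FALSE)
  expect_equal(rec$results$goodness_of_fit$chi2, f$result$gof$chi2,
               tolerance = 1e-12)
  expect_equal(unlist(rec$data[[1]]$y), f$spectrum$y, tolerance = 1e-12)
  expect_identical(rec$schema_version, "1.0")
})

test_that("TOML writer/reader round-trips nested documents", {
  doc <- list(alpha = 1L, beta = 2.5, flag = TRUE, name = "He said \"hi\"\n",
              vec = c(1.5, -2.25, 1e-9), empty = list(),
              tab = list(x = "a#b", sub = list(deep = c(TRUE, FALSE))),
              arr = list(list(k = 1L), list(k = 2L)))
  txt <- toml_write(doc)
  back <- toml_read(txt)
  expect_identical(back$alpha, 1L)
  expect_identical(back$beta, 2.5)
  expect_identical(back$flag, TRUE)
  expect_identical(back$name, "He said \"hi\"\n")
  expect_identical(back$vec, c(1.5, -2.25, 1e-9))
  expect_identical(back$tab$x, "a#b")
  expect_identical(back$tab$sub$deep, c(TRUE, FALSE))
  expect_identical(back$arr[[2]]$k, 2L)
  # special floats
  expect_identical(toml_read("a = inf\nb = -inf")$b, -Inf)
  expect_error(toml_read("a = ["), class = "peakfitr_parse_error")
  expect_error(toml_read("just words"), class = "peakfitr_parse_error")
})

test_that("identical content yields identical lock IDs", {
  f <- fit_small()
  d <- withr::local_tempdir()
  l1 <- write_lock(f$project, f$spectrum, f$result, file.path(d, "a.lock"))
  Sys.sleep(1.1)  # different timestamp must not change the ID
  l2 <- write_lock(f$project, f$spectrum, f$result, file.path(d, "b.lock"))
  expect_identical(l1$id, l2$id)
  expect_match(l1$id, "^[0-9a-f]{64}$")
  expect_true(verify_lock(file.path(d, "a.lock"))$valid)
})

test_that("any single-value perturbation changes the ID and fails verification", {
  f <- fit_small()
  d <- withr::local_tempdir()
  write_lock(f$project, f$spectrum, f$result, file.path(d, "a.lock"))
  s2 <- f$spectrum
  s2$y[30] <- s2$y[30] + 1e-9
  l2 <- write_lock(f$project, s2, f$result, file.path(d, "b.lock"))
  expect_false(identical(verify_lock(file.path(d, "a.lock"))$stored_id, l2$id))
  # hand-edit a results value inside the file
  lines <- readLines(file.path(d, "a.lock"))
  i <- grep("^chi2 = ", lines)[1]
  lines[i] <- "chi2 = 0.123"
  writeLines(lines, file.path(d, "tampered.lock"))
  v <- verify_lock(file.path(d, "tampered.lock"))
  expect_false(v$valid)
  expect_false(identical(v$recomputed_id, v$stored_id))
})

test_that("verification is independent of key order and whitespace", {
  f <- fit_small()
  d <- withr::local_tempdir()
  write_lock(f$project, f$spectrum, f$result, file.path(d, "a.lock"))
  lines <- readLines(file.path(d, "a.lock"))
  # shuffle the top-level scalar keys and pad with blank/comment lines
  top_end <- grep("^\\[", lines)[1] - 1
  reordered <- c(rev(lines[1:top_end]), "", "# appended comment",
                 lines[(top_end + 1):length(lines)])
  writeLines(reordered, file.path(d, "b.lock"))
  expect_true(verify_lock(file.path(d, "b.lock"))$valid)
})

test_that("a truncated lock raises a parse error, not an invalid verdict", {
  f <- fit_small()
  d <- withr::local_tempdir()
  write_lock(f$project, f$spectrum, f$result, file.path(d, "a.lock"))
  lines <- readLines(file.path(d, "a.lock"))
  # cut the file in the middle of the data array: unterminated value
  i <- grep("^x = \\[", lines)[1]
  cut <- c(lines[1:(i - 1)], substr(lines[i], 1, 12))
  writeLines(cut, file.path(d, "trunc.lock"))
  expect_error(verify_lock(file.path(d, "trunc.lock")),
               class = "peakfitr_parse_error")
})

test_that("canonical form is byte-stable across write -> read -> write", {
  f <- fit_small()
  d <- withr::local_tempdir()
  write_lock(f$project, f$spectrum, f$result, file.path(d, "a.lock"))
  content1 <- toml_read(paste(readLines(file.path(d, "a.lock")), collapse = "\n"))
  txt1 <- toml_write(content1)
  content2 <- toml_read(txt1)
  expect_identical(toml_write(content2), txt1)
  expect_identical(peakfitr:::canonical_render(content1),
                   peakfitr:::canonical_render(content2))
})

test_that("the lock records a simultaneous fit including all spectra", {
  pair <- make_xas_pair(seed = 13)
  pr <- project_from_truth(pair$truths[[1]])
  sim <- fit_simultaneous(pr, pair$spectra)
  d <- withr::local_tempdir()
  lk <- write_lock(pr, pair$spectra, sim$joint, file.path(d, "joint.lock"))
  expect_length(lk$data, 2)
  expect_true(verify_lock(file.path(d, "joint.lock"))$valid)
})
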