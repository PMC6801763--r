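test_that("CSV and Sparky rows map to the documented peak fields", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("residue_id,residue_name,delta_h_ppm,delta_n_ppm,height",
               "12,GLY,8.251,110.42,1.0e6"), csv)
  pk <- read_peak_table(csv, "csv")
  expect_identical(pk$residue_id, 12L)
  expect_identical(pk$residue_name, "GLY")
  expect_equal(pk$delta_h, 8.251)
  expect_equal(pk$delta_n, 110.42)
  expect_equal(pk$height, 1e6)

  # Sparky convention: w1 = 15N, w2 = 1H; height optional
  sp <- tempfile(fileext = ".list")
  writeLines(c("Assignment w1 w2", "G12N-H 110.42 8.251"), sp)
  pk2 <- read_peak_table(sp, "sparky")
  expect_identical(pk2$residue_id, 12L)
  expect_identical(pk2$residue_name, "GLY")
  expect_equal(pk2$delta_h, 8.251)
  expect_equal(pk2$delta_n, 110.42)
  expect_true(is.na(pk2$height))
  # w1 override
  sp2 <- tempfile(fileext = ".list")
  writeLines("G12N-H 8.251 110.42", sp2)
  pk3 <- read_peak_table(sp2, "sparky", sparky_w1 = "h")
  expect_equal(pk3$delta_h, 8.251)
})

test_that("malformed and duplicate rows are rejected with useful messages", {
  dup <- tempfile(fileext = ".csv")
  writeLines(c("residue_id,residue_name,delta_h_ppm,delta_n_ppm,height",
               "12,GLY,8.251,110.42,", "12,GLY,8.30,110.50,"), dup)
  expect_error(read_peak_table(dup, "csv"), "duplicate residue_id.*12")

  bad <- tempfile(fileext = ".list")
  writeLines(c("G12N-H 110.42 8.251", "WAT 1 2"), bad)
  expect_error(read_peak_table(bad, "sparky"), "line 2")

  empty <- tempfile(fileext = ".csv")
  writeLines("residue_id,residue_name,delta_h_ppm,delta_n_ppm,height", empty)
  expect_error(read_peak_table(empty, "csv"), "empty")

  # out-of-window shifts warn but do not stop
  odd <- tempfile(fileext = ".csv")
  writeLines(c("residue_id,residue_name,delta_h_ppm,delta_n_ppm,height",
               "1,ALA,4.2,110.0,"), odd)
  expect_warning(read_peak_table(odd, "csv"), "1H shift outside")
})

test_that("peak lists round-trip bit-exactly through every dialect", {
  withr::with_seed(9, {
    peaks <- make_peaks(
      residue_id = sample(1:60, 15), delta_h = runif(15, 6.5, 10.5),
      delta_n = runif(15, 102, 132),
      height = ifelse(runif(15) < 0.3, NA_real_, runif(15, 1e5, 1e7)),
      residue_name = sample(c("GLY", "ALA", "THR", "TRP"), 15, replace = TRUE))
  })
  peaks <- peaks[order(peaks$residue_id), ]
  rownames(peaks) <- NULL
  for (dialect in c("csv", "tsv", "sparky")) {
    f <- tempfile()
    write_peak_table(peaks, f, dialect)
    back <- suppressWarnings(read_peak_table(f, dialect))
    rownames(back) <- NULL
    expect_identical(back$residue_id, peaks$residue_id)
    expect_identical(back$delta_h, peaks$delta_h)
    expect_identical(back$delta_n, peaks$delta_n)
    expect_identical(back$height, peaks$height)
    if (dialect != "sparky") {
      expect_identical(back$residue_name, peaks$residue_name)
    }
  }
})

test_that("load_titration derives concentrations and validates the schedule", {
  dir <- tempfile(); dir.create(dir)
  ratios <- seven_ratio_schedule
  files <- sprintf("p%d.csv", seq_along(ratios))
  for (i in seq_along(ratios)) {
    writeLines(c("residue_id,residue_name,delta_h_ppm,delta_n_ppm,height",
                 "1,GLY,8.0,110.0,", "2,ALA,8.5,118.0,"),
               file.path(dir, files[i]))
  }
  config <- list(label = "seven-point", protein_conc_mM = 0.78,
                 ratios = ratios, peak_files = files)
  yaml::write_yaml(config, file.path(dir, "cfg.yaml"))
  series <- load_titration(file.path(dir, "cfg.yaml"))
  expect_length(series$points, 7)
  expect_equal(vapply(series$points, `[[`, numeric(1), "ligand_conc"),
               c(0, 0.078, 0.156, 0.39, 0.78, 1.56, 3.12))

  # count mismatch
  cfg2 <- config; cfg2$peak_files <- files[1:6]
  yaml::write_yaml(cfg2, file.path(dir, "cfg2.yaml"))
  expect_error(load_titration(file.path(dir, "cfg2.yaml")),
               "6 peak file")
  # schedule must start at the free state and increase strictly
  cfg3 <- config; cfg3$ratios <- ratios + 0.1
  yaml::write_yaml(cfg3, file.path(dir, "cfg3.yaml"))
  expect_error(load_titration(file.path(dir, "cfg3.yaml")), "ratio 0")
  cfg4 <- config; cfg4$ratios <- c(0, 0.2, 0.1, 0.5, 1, 2, 4)
  yaml::write_yaml(cfg4, file.path(dir, "cfg4.yaml"))
  expect_error(load_titration(file.path(dir, "cfg4.yaml")),
               "strictly increasing")
})

test_that("CSP tables round-trip with missingness preserved, never as zero", {
  free <- make_peaks(1:3, c(8.0, 8.5, 9.0), c(110, 115, 120))
  mid <- make_peaks(1:3, c(8.03, 8.52, 9.0), c(110.2, 115.1, 120))
  last <- make_peaks(1:2, c(8.06, 8.55), c(110.4, 115.2))
  series <- make_series(c(0, 1, 3), 0.5, list(free, mid, last))
  prof <- build_profiles(series)
  f <- tempfile(fileext = ".csv")
  write_csp_table(prof, f)
  back <- read_csp_table(f)
  expect_identical(back$delta_delta, prof$delta_delta)
  expect_identical(back$flag, prof$flag)
  expect_identical(back$ratio, prof$ratio)
  # the gap is an explicit empty field in the file
  lines <- readLines(f)
  gap <- grep("^3,3,", lines, value = TRUE)
  expect_match(gap, ",,missing$")
  expect_error(write_csp_table(prof[0, ], tempfile()), "nrow")
})
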