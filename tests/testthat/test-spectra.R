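test_that("spectrum construction enforces the axis and metadata contract", {
  s <- spectrum1d(c(9, 5, 1), c(0.1, 1, 0.2), "S1", "M", "t1rho_short_a", 10)
  expect_s3_class(s, "spectrum1d")
  expect_true(all(diff(s$ppm) < 0))

  # ascending input is re-sorted into the descending convention
  s2 <- spectrum1d(c(1, 5, 9), c(0.2, 1, 0.1), "S1", "M", "t1rho_short_a", 10)
  expect_identical(s$ppm, s2$ppm)
  expect_identical(s$intensity, s2$intensity)

  expect_error(spectrum1d(c(9, 5, 1), c(0.1, 1), "S1", "M", "t1rho_short_a", 10),
               "same length")
  expect_error(spectrum1d(c(9, 1, 5), c(1, 1, 1), "S1", "M", "t1rho_short_a", 10),
               "monotone")
  expect_error(spectrum1d(c(9, 5, 1), c(0.1, NA, 0.2), "S1", "M",
                          "t1rho_short_a", 10), "finite")
  expect_error(spectrum1d(c(9, 5, 1), c(0.1, 1, 0.2), "S1", "M",
                          "t1rho_short_a", 50), "spin lock")
})

test_that("spectrum files round-trip and reject malformed content", {
  path <- tempfile(fileext = ".tsv")
  s <- spectrum1d(c(9, 5, 1), c(0.1, 1, 0.2), "S1", "PM", "t1rho_long", 200,
                  protein_id = "prot01", mix_id = "1")
  write_spectrum(s, path)
  r <- read_spectrum(path)
  expect_equal(r$ppm, s$ppm)
  expect_equal(r$intensity, s$intensity)
  expect_identical(r[c("sample_id", "role", "experiment", "spin_lock_ms",
                       "protein_id", "mix_id")],
                   s[c("sample_id", "role", "experiment", "spin_lock_ms",
                       "protein_id", "mix_id")])

  # ascending row order in the file gives the identical spectrum
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- rev(grep("^#", lines, invert = TRUE, value = TRUE))
  writeLines(c(hdr, body), path)
  expect_equal(read_spectrum(path)$intensity, s$intensity)

  # missing header field
  writeLines(c(hdr[-4], body), path)
  expect_error(read_spectrum(path), "spin_lock_ms")

  # non-numeric row names the line
  writeLines(c(hdr, body[1], "abc\tdef", body[-1]), path)
  expect_error(read_spectrum(path), "line 8")

  # invalid spin-lock delay
  writeLines(c(sub("200", "50", hdr), body), path)
  expect_error(read_spectrum(path), "spin lock")
})

test_that("measurement triples enforce delays and role consistency", {
  a <- toy_spectrum(experiment = "t1rho_short_a")
  b <- toy_spectrum(experiment = "t1rho_short_b")
  l <- toy_spectrum(experiment = "t1rho_long", spin_lock_ms = 200)
  m <- sample_measurement(a, l, b)
  expect_identical(m$long_delay_ms, 200)
  expect_error(sample_measurement(a, b, b), "long spectrum")
  expect_error(sample_measurement(a, l, l), "short replicates")
  expect_error(sample_measurement(a, l, b, role = "M", protein_id = "x"),
               "protein_id")
  expect_error(sample_measurement(a, l, b, role = "P", mix_id = "1"),
               "mix_id")
})

test_that("reference sets deduplicate and collapse conflicting types", {
  df <- data.frame(protein_id = c("Eno", "Eno"), metabolite_id = c("PEP", "PEP"),
                   type = c("catalytic", "regulatory"))
  rs <- reference_set(df)
  expect_equal(nrow(rs), 1L)
  expect_equal(rs$type, "both")

  # a 43-catalytic + 40-regulatory roster with 11 overlaps gives 72 uniques
  rows <- synthetic_reference_rows()
  path <- write_temp_csv(rows)
  rs <- read_reference_set(path)
  expect_equal(nrow(rs), 72L)
  expect_equal(sum(rs$type == "both"), 11L)
  # cardinality is invariant to row order and duplication
  rs2 <- read_reference_set(write_temp_csv(rows[rev(seq_len(nrow(rows))), ]))
  expect_equal(rs2, rs)
  rs3 <- read_reference_set(write_temp_csv(rbind(rows, rows)))
  expect_equal(nrow(rs3), 72L)

  expect_error(read_reference_set(write_temp_csv(
    data.frame(protein_id = "a", metabolite_id = "b", type = "unknown"))),
    "type label")

  # empty file parses to an empty set
  empty <- write_temp_csv(rows[0, ])
  expect_equal(nrow(read_reference_set(empty)), 0L)
})

test_that("similarity tables are validated on read", {
  ok <- data.frame(protein_id = c("Pta", "Zwf"), metabolite_id = c("TRP", "ATP"),
                   max_similarity = c(0.06, 0.60))
  tab <- read_similarity_table(write_temp_csv(ok))
  expect_equal(tab$max_similarity, c(0.06, 0.60))
  expect_error(read_similarity_table(write_temp_csv(
    data.frame(protein_id = "X", metabolite_id = "Y", max_similarity = 1.2))),
    "\\[0, 1\\]")
  expect_error(read_similarity_table(write_temp_csv(rbind(ok, ok[1, ]))),
    "duplicate")
})

test_that("interaction tables round-trip through the long CSV", {
  pv <- data.frame(protein_id = rep(c("p1", "p2"), 2),
                   metabolite_id = rep(c("m1", "m2"), each = 2),
                   delta_rf = c(0.30, NA, -0.02, 0.1805),
                   n_peaks_used = c(2L, 0L, 1L, 3L),
                   qc_flags = c("ok", "no_valid_peaks", "ok", "ok"))
  im <- build_matrix(pv, c("p1", "p2"), c("m1", "m2"))
  path <- tempfile(fileext = ".csv")
  write_interaction_table(im, path, cutoff = 0.18)
  long <- read.csv(path)
  expect_equal(nrow(long), 4L)
  expect_equal(sum(long$detected_at_cutoff), 2L)  # 0.30 and 0.1805 > 0.18
  expect_true(any(long$qc_flags == "no_valid_peaks" & long$delta_rf == ""
                  | is.na(long$delta_rf)))
  back <- read_interaction_table(path)
  expect_identical(back$delta_rf, im$delta_rf)  # full-precision round trip

  # full-roster screen dimensions: 29 x 55 yields 1,595 long rows
  prot <- sprintf("enz%02d", 1:29); met <- sprintf("met%02d", 1:55)
  big <- build_matrix(data.frame(protein_id = prot[1], metabolite_id = met[1],
                                 delta_rf = 0.2), prot, met)
  write_interaction_table(big, path)
  expect_equal(nrow(read.csv(path)), 1595L)
})
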