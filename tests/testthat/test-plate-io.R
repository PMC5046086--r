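test_that("plate datasets validate layout and series structure", {
  layout <- make_layout()
  sch <- c(0, 30, 60)
  series <- do.call(rbind, lapply(layout$well, function(w)
    data.frame(time_s = sch, well = w, a594 = c(0.5, 0.6, 0.7))))
  ds <- plate_dataset(layout, series)
  expect_s3_class(ds, "plate_dataset")
  expect_length(attr(ds, "wells_without_data"), 0)

  # well ids canonicalized case-insensitively
  lo2 <- layout; lo2$well[1] <- tolower(lo2$well[1])
  expect_equal(plate_dataset(lo2, series)$layout$well, layout$well)

  # standard without ph_value
  lo3 <- layout; lo3$ph_value[1] <- NA
  expect_error(plate_dataset(lo3, series), "ph_value")
  # unknown role
  lo4 <- layout; lo4$role[9] <- "mystery"
  expect_error(plate_dataset(lo4, series), "role")
  # series well absent from layout
  s2 <- rbind(series, data.frame(time_s = sch, well = "H12", a594 = 0.5))
  expect_error(plate_dataset(layout, s2), "absent from layout")
  # duplicate (time, well)
  s3 <- rbind(series, series[1, ])
  expect_error(plate_dataset(layout, s3), "duplicate")
  # non-monotone time
  s4 <- series; s4$time_s[2:3] <- c(60, 30)
  expect_error(plate_dataset(layout, s4), "strictly increasing")
  # missing control flagged as error only when required
  lo5 <- layout[layout$role != "control", ]
  s5 <- series[series$well %in% lo5$well, ]
  expect_error(plate_dataset(lo5, s5), "control")
  expect_s3_class(plate_dataset(lo5, s5, require_control = FALSE),
                  "plate_dataset")
  # layout wells with no readings are allowed but flagged
  s6 <- series[series$well != layout$well[9], ]
  expect_equal(attr(plate_dataset(layout, s6), "wells_without_data"),
               layout$well[9])
})

test_that("plate write/read round trip is lossless", {
  plan <- drift_plan(doses = c(0, 1), replicates = 2)
  ds <- simulate_drift_plate(plan, noise_sd = 0.003,
                             sampling = seq(0, 600, 30), seed = 9)
  lp <- tempfile(fileext = ".csv"); sp <- tempfile(fileext = ".csv")
  write_plate(ds, lp, sp)
  back <- read_plate(lp, sp)
  expect_equal(back$layout, ds$layout)
  expect_equal(back$series, ds$series)
  # reading twice yields identical structures
  expect_identical(read_plate(lp, sp), read_plate(lp, sp))
})

test_that("wide plate-reader exports convert to the long form", {
  wide <- data.frame(time_s = c(0, 30), A1 = c(0.1, 0.2), B2 = c(0.3, 0.4))
  long <- wide_to_long(wide)
  expect_equal(nrow(long), 4)
  expect_equal(long$a594[long$well == "B2"], c(0.3, 0.4))
  expect_error(wide_to_long(data.frame(t = 1:3)), "time column")
})

test_that("spectral-count tables construct, group, and round trip", {
  counts <- matrix(c(5L, 0L, 3L, 7L, 2L, 1L), nrow = 3,
                   dimnames = list(c("A", "B", "C"), c("m1", "f1")))
  tab <- spc_table(counts, c("matrix", "fluid"))
  expect_s3_class(tab, "spc_table")
  expect_equal(unname(tab$counts["B", "f1"]), 2L)

  # grouped accessions merge with counts summed
  tab2 <- spc_table(counts, c("matrix", "fluid"),
                    grouping = c(A = "AB", B = "AB"))
  expect_equal(nrow(tab2$counts), 2)
  expect_equal(unname(tab2$counts["AB", ]), c(5L, 9L))

  expect_error(spc_table(counts * -1L, c("matrix", "fluid")), "negative")
  expect_error(spc_table(counts + 0.5, c("matrix", "fluid")), "non-integer")
  expect_error(spc_table(counts[0, , drop = FALSE], character(0)), "empty")

  p <- tempfile(fileext = ".tsv")
  write_spectral_counts(tab, p)
  back <- read_spectral_counts(p)
  expect_equal(back$counts, tab$counts)
  expect_equal(back$groups, tab$groups)

  empty <- tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(read_spectral_counts(empty), "empty")
})

test_that("FASTA io upper-cases, strips terminal stops, rejects bad residues", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">p1 desc", "acdefg", ">p2", "MKLV*"), p)
  seqs <- read_fasta(p)
  expect_equal(unname(seqs), c("ACDEFG", "MKLV"))
  expect_equal(names(seqs), c("p1", "p2"))

  writeLines(c(">bad", "MK*LV"), p)
  expect_error(read_fasta(p), "internal stop")
  writeLines(c(">odd", "MKJLV"), p)
  expect_error(read_fasta(p), "illegal")
  expect_equal(unname(read_fasta(p, on_invalid = "mask")), "MKXLV")

  out <- tempfile(fileext = ".fa")
  long_seq <- c(widepep = strrep("ACDEFGHIKL", 13))
  write_fasta(long_seq, out)
  expect_equal(read_fasta(out), long_seq)
})

test_that("titration and EDS readers validate their invariants", {
  p <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = c(0, 10, 20), base_ul = c(0, 1, 3)), p,
            row.names = FALSE)
  expect_equal(read_titration(p)$base_ul, c(0, 1, 3))
  write.csv(data.frame(time_s = c(0, 10, 20), base_ul = c(0, 3, 1)), p,
            row.names = FALSE)
  expect_error(read_titration(p), "non-decreasing")

  write.csv(data.frame(sample_id = "s1", dose = "0", reading = 1,
                       mg = 0.05, ca = 0.15), p, row.names = FALSE)
  expect_equal(read_eds(p)$mg, 0.05)
  write.csv(data.frame(sample_id = "s1", dose = "0", reading = 1,
                       mg = 1.5, ca = 0.15), p, row.names = FALSE)
  expect_error(read_eds(p), "\\[0, 1\\]")
})
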