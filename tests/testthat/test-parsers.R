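test_that("detect_dialect identifies every emitted dialect uniquely", {
  dir <- withr::local_tempdir()
  an <- make_experiment_fixture("det", 1, 1, seed = 2,
                                duration = 0.2, interval = 0.01)
  pr <- make_experiment_fixture("detp", 1, 1, preparative = TRUE, seed = 2,
                                duration = 5, interval = 0.1)
  for (dl in c("waters-arw", "shimadzu-ascii", "agilent-csv")) {
    for (p in emit_dialect_files(an, dl, file.path(dir, dl))) {
      expect_identical(detect_dialect(p), dl)
    }
  }
  for (p in emit_dialect_files(pr, "akta-csv", file.path(dir, "akta"))) {
    expect_identical(detect_dialect(p), "akta-csv")
  }
})

test_that("empty or unrecognizable files raise an unsupported-format error", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(), empty)
  expect_error(detect_dialect(empty), "unsupported format")
  junk <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,c", "1,2,3"), junk)
  expect_error(detect_dialect(junk), "unsupported format")
})

test_that("AKTA sentinel beats the generic .csv fallback", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("UV,", "mL,mAU", "0.0,1.5", "0.5,2.5"), p)
  expect_identical(detect_dialect(p), "akta-csv")
})

test_that("waters-arw parses header metadata and the declared point grid", {
  # 3 min at 0.3 s sampling: 601 points by construction
  ex <- make_experiment_fixture("w", 1, 1, seed = 7)
  res <- emit_and_parse(ex, "waters-arw")
  run <- res$runs[[1]]
  expect_equal(nrow(run$table), 601)
  expect_identical(run$meta$sample, "inj_S1")
  expect_identical(run$meta$channel, "GFP")
  expect_identical(run$meta$instrument_kind, "hplc")
  expect_equal(run$meta$flow_rate, 0.5)
  expect_equal(run$table$time_min[1], 0)
})

test_that("waters-arw rejects missing header fields and bad data rows", {
  p <- withr::local_tempfile(fileext = ".arw")
  writeLines(c("SampleName\tOther", "A\tx", "0.0\t1.0"), p)
  expect_error(parse_waters_arw(p), "Channel")
  p2 <- withr::local_tempfile(fileext = ".arw")
  writeLines(c("SampleName\tChannel", "A\tGFP", "0.0\t1.0", "oops\t2.0"), p2)
  expect_error(parse_waters_arw(p2), "line 4")
})

test_that("shimadzu blocks reconstruct times from the declared interval", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("[Header]", "Sample Name\tmysample", "",
               "[LC Chromatogram(A)]", "Interval(msec)\t500",
               paste0("# of Points\t241"),
               format(seq_len(241))), p)
  runs <- parse_shimadzu_ascii(p)
  expect_length(runs, 1)
  tab <- runs[[1]]$table
  expect_equal(nrow(tab), 241)
  expect_equal(tab$time_min[1], 0)
  expect_equal(tab$time_min[241], 2, tolerance = 1e-12)  # 240 x 0.5 s
  expect_identical(runs[[1]]$meta$sample, "mysample")
  expect_identical(runs[[1]]$meta$channel, "A")
})

test_that("shimadzu multi-channel blocks share the sample name", {
  ex <- make_experiment_fixture("sh", 1, 2, seed = 9,
                                duration = 0.5, interval = 0.01)
  res <- emit_and_parse(ex, "shimadzu-ascii")
  expect_length(res$runs, 2)
  expect_identical(res$runs[[1]]$meta$sample, res$runs[[2]]$meta$sample)
  expect_false(identical(res$runs[[1]]$meta$channel,
                         res$runs[[2]]$meta$channel))
})

test_that("shimadzu point-count mismatch and zero-point blocks behave", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("[Header]", "Sample Name\ts", "",
               "[LC Chromatogram(A)]", "Interval(msec)\t500",
               "# of Points\t5", "1", "2"), p)
  expect_error(parse_shimadzu_ascii(p), "declares 5 points but contains 2")
  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("[Header]", "Sample Name\ts", "",
               "[LC Chromatogram(A)]", "Interval(msec)\t500",
               "# of Points\t0"), p2)
  runs <- parse_shimadzu_ascii(p2)
  expect_equal(nrow(runs[[1]]$table), 0)
  p3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("[Header]", "Sample Name\ts", "",
               "[LC Chromatogram(A)]", "# of Points\t0"), p3)
  expect_error(parse_shimadzu_ascii(p3), "Interval")
})

test_that("agilent CSV parses bare two-column data with absent metadata", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Time,Signal",
               paste(seq(0, 0.99, by = 0.01), seq_len(100), sep = ",")), p)
  run <- parse_agilent_csv(p)
  expect_equal(nrow(run$table), 100)
  expect_true(is.na(run$meta$channel))
  expect_true(is.na(run$meta$flow_rate))
  # resolve_metadata completes it from batch overrides
  meta <- resolve_metadata(run$meta,
                           meta_sources(batch = list(channel = "280 nm",
                                                     flow_rate = 1)))
  expect_identical(meta$channel, "280 nm")
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.0,1.0,9"), p3)
  expect_error(parse_agilent_csv(p3), "2 columns")
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.0,ok"), p4)
  expect_error(parse_agilent_csv(p4), "non-numeric")
})

test_that("akta CSV yields volume-axis groups and fraction intervals", {
  ex <- make_experiment_fixture("ak", 1, 2, preparative = TRUE, seed = 4)
  res <- emit_and_parse(ex, "akta-csv")
  run <- res$runs[[1]]
  expect_identical(attr(run$table, "x_unit"), "volume")
  expect_identical(run$meta$instrument_kind, "fplc")
  expect_equal(length(unique(run$table$channel)), 2)
  expect_length(run$fractions, 5)
  # boundary rule: consecutive marks abut; last fraction ends at trace end
  starts <- vapply(run$fractions, `[[`, numeric(1), "start")
  ends <- vapply(run$fractions, `[[`, numeric(1), "end")
  expect_equal(ends[-5], starts[-1])
  expect_equal(ends[5], max(run$table$volume_mL))
})

test_that("akta fraction boundary convention on a hand-written file", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("UV,,Fraction,",
               "mL,mAU,mL,",
               "8.0,1,8.0,F1",
               "8.5,2,8.5,F2",
               "9.0,3,,"), p)
  run <- parse_akta_csv(p)
  expect_length(run$fractions, 2)
  expect_equal(run$fractions[[1]]$start, 8.0)
  expect_equal(run$fractions[[1]]$end, 8.5)
  expect_equal(run$fractions[[2]]$end, 9.0)
  # no fraction pair -> empty fraction list
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("UV,", "mL,mAU", "0.0,1", "1.0,2"), p2)
  expect_length(parse_akta_csv(p2)$fractions, 0)
})

test_that("akta rejects odd column counts and non-monotone volumes", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("UV,,x", "mL,mAU,mL", "0,1,0"), p)
  expect_error(parse_akta_csv(p), "odd column count")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("UV,", "mL,mAU", "1.0,1", "0.5,2"), p2)
  expect_error(parse_akta_csv(p2), "non-monotone")
})

test_that("metadata precedence is file > per-file > batch > defaults db", {
  base <- run_meta(sample = "A", channel = "GFP", flow_rate = 0.5,
                   instrument_kind = "hplc", source_path = "f.arw",
                   dialect = "waters-arw")
  srcs <- meta_sources(per_file = list("f.arw" = list(flow_rate = 2)),
                       batch = list(flow_rate = 1),
                       defaults_db = list("waters-arw" =
                                            list(flow_rate = 0.3)))
  expect_equal(resolve_metadata(base, srcs)$flow_rate, 0.5)  # file wins
  base$flow_rate <- NA_real_
  expect_equal(resolve_metadata(base, srcs)$flow_rate, 2)    # per-file
  srcs$per_file <- list()
  expect_equal(resolve_metadata(base, srcs)$flow_rate, 1)    # batch
  srcs$batch <- list()
  expect_equal(resolve_metadata(base, srcs)$flow_rate, 0.3)  # defaults db
})

test_that("defaults database is read from its YAML file by dialect key", {
  db <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list("agilent-csv" = list(flow_rate = 0.3,
                                             channel = "280nm")), db)
  meta <- run_meta(sample = "A", instrument_kind = "hplc",
                   source_path = "x.csv", dialect = "agilent-csv")
  out <- resolve_metadata(meta, meta_sources(defaults_db = db))
  expect_equal(out$flow_rate, 0.3)
  expect_identical(out$channel, "280nm")
})

test_that("unresolvable flow rate errors non-interactively, prompts otherwise", {
  meta <- run_meta(sample = "A", channel = "GFP", instrument_kind = "hplc",
                   source_path = "x.csv", dialect = "agilent-csv")
  expect_error(resolve_metadata(meta, meta_sources()), "flow rate required")
  answered <- resolve_metadata(meta, meta_sources(), interactive = TRUE,
                               prompt = function(field, m) {
                                 if (field == "flow_rate") 0.75 else "UV"
                               })
  expect_equal(answered$flow_rate, 0.75)
  # preparative runs need no flow rate
  fplc <- run_meta(sample = "A", instrument_kind = "fplc",
                   source_path = "y.csv", dialect = "akta-csv")
  expect_silent(resolve_metadata(fplc, meta_sources()))
})

test_that("parsing preserves strictly increasing x order in every group", {
  ex <- make_experiment_fixture("mono", 2, 2, seed = 13,
                                duration = 0.3, interval = 0.01)
  for (dl in c("waters-arw", "shimadzu-ascii", "agilent-csv")) {
    for (run in emit_and_parse(ex, dl)$runs) {
      xs <- run$table$time_min
      expect_false(is.unsorted(xs, strictly = TRUE))
    }
  }
})
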