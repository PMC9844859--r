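test_that("add_volume is the elementwise product of time and flow rate", {
  tab <- random_tidy(3, n_groups = 2, n_pts = 10)
  out <- add_volume(tab, 0.5)
  # independent elementwise oracle
  for (i in seq_len(nrow(tab))) {
    expect_identical(out$volume_mL[i], tab$time_min[i] * 0.5)
  }
  expect_identical(out$time_min, tab$time_min)
  expect_equal(add_volume(simple_tidy(1, x = 2), 0.5)$volume_mL, 1.0)
  expect_equal(add_volume(simple_tidy(1, x = 0), 0.7)$volume_mL, 0)
  # linearity: doubling the flow rate doubles every volume
  expect_equal(add_volume(tab, 1.0)$volume_mL, 2 * out$volume_mL)
  expect_error(add_volume(tab, 0), "> 0")
  expect_error(add_volume(tab, -1), "> 0")
})

test_that("apply_scale multiplies raw signal only", {
  tab <- simple_tidy(c(1, 3))
  expect_identical(apply_scale(tab, 1), tab)
  expect_equal(apply_scale(tab, 2)$signal, c(2, 6))
  expect_error(apply_scale(tab, 0), "> 0")
})

test_that("normalize_range maps the in-range max to 1 over the whole trace", {
  tab <- simple_tidy(c(2, 4, 8, 6))
  out <- normalize_range(tab, range_start = 0, range_end = 3)
  expect_equal(out$signal_norm, c(0.25, 0.5, 1.0, 0.75))
  expect_identical(out$signal, tab$signal)   # raw column untouched
  # restricted range: out-of-range values may exceed 1
  out2 <- normalize_range(tab, range_start = 0, range_end = 1)
  expect_equal(out2$signal_norm, c(0.5, 1.0, 2.0, 1.5))
})

test_that("zero_min maps the range onto [0, 1] affinely", {
  tab <- simple_tidy(c(2, 4, 8, 6))
  out <- normalize_range(tab, range_start = 0, range_end = 3,
                         zero_min = TRUE)
  expect_equal(out$signal_norm, c(0, 1 / 3, 1, 2 / 3))
  expect_equal(min(out$signal_norm), 0)
  expect_equal(max(out$signal_norm), 1)
})

test_that("groups normalize independently of each other", {
  a <- data.frame(experiment = "E", sample = "A", channel = "c",
                  time_min = 0:3, signal = c(2, 4, 8, 6))
  b <- data.frame(experiment = "E", sample = "B", channel = "c",
                  time_min = 0:3, signal = c(1, 5, 2, 1))
  tab <- tidy_table(rbind(a, b), "time")
  out <- normalize_range(tab, range_start = 0, range_end = 3)
  b10 <- b; b10$signal <- b10$signal * 10
  out10 <- normalize_range(tidy_table(rbind(a, b10), "time"),
                           range_start = 0, range_end = 3)
  expect_equal(out10$signal_norm, out$signal_norm)
})

test_that("normalization is scale-invariant and idempotent", {
  for (seed in 1:10) {
    tab <- random_tidy(seed, n_groups = 3, n_pts = 12)
    rng <- range(tab$time_min)
    for (zero_min in c(FALSE, TRUE)) {
      base <- normalize_range(tab, range_start = rng[1], range_end = rng[2],
                              zero_min = zero_min)
      scaled <- normalize_range(apply_scale(tab, 7.3),
                                range_start = rng[1], range_end = rng[2],
                                zero_min = zero_min)
      expect_equal(scaled$signal_norm, base$signal_norm)
    }
    # idempotence (max-only): renormalizing the normalized signal is a no-op
    base <- normalize_range(tab, range_start = rng[1], range_end = rng[2])
    renorm <- as.data.frame(base)
    renorm$signal <- renorm$signal_norm
    renorm <- normalize_range(tidy_table(renorm, "time"),
                              range_start = rng[1], range_end = rng[2])
    expect_equal(renorm$signal_norm, base$signal_norm)
  }
})

test_that("degenerate traces raise named errors instead of NaN", {
  flat <- simple_tidy(c(5, 5, 5))
  expect_error(normalize_range(flat, range_start = 0, range_end = 2,
                               zero_min = TRUE), "flat over the range")
  zero <- simple_tidy(c(0, -2, 0))
  expect_error(normalize_range(zero, range_start = 0, range_end = 2),
               "not positive")
  expect_error(normalize_range(flat, range_start = 10, range_end = 11),
               "no points")
})

test_that("classify_run follows instrument kind and fractions", {
  hplc <- run_meta(sample = "A", channel = "c", flow_rate = 0.5,
                   instrument_kind = "hplc")
  fplc <- run_meta(sample = "B", instrument_kind = "fplc")
  fr <- list(fraction_record("A1", 0, 1))
  expect_identical(classify_run(hplc), "analytic")
  expect_identical(classify_run(fplc), "preparative")
  expect_identical(classify_run(fplc, list()), "preparative")  # kind wins
  expect_identical(classify_run(hplc, fr), "preparative")
})

test_that("assemble_experiment merges kinds and disambiguates samples", {
  an <- make_experiment_fixture("a", 2, 1, seed = 5,
                                duration = 0.2, interval = 0.01)
  pr <- make_experiment_fixture("p", 1, 1, preparative = TRUE, seed = 6,
                                duration = 6, interval = 0.2)
  dir <- withr::local_tempdir()
  runs <- c(emit_and_parse(an, "waters-arw", dir)$runs,
            emit_and_parse(pr, "akta-csv", dir)$runs)
  runs <- lapply(runs, function(r) {
    r$meta <- resolve_metadata(r$meta,
                               meta_sources(batch = list(flow_rate = 0.5)))
    r
  })
  ex <- assemble_experiment("mixed", runs)
  expect_s3_class(ex, "chrom_experiment")
  expect_gt(nrow(ex$analytic), 0)
  expect_gt(nrow(ex$preparative), 0)
  expect_length(ex$fractions, 5)
  expect_true(all(ex$analytic$experiment == "mixed"))
})

test_that("duplicate sample names across files get numeric suffixes", {
  mk_run <- function(path) {
    tab <- simple_tidy(c(1, 2), sample = "A")
    meta <- run_meta(sample = "A", channel = "ch1", flow_rate = 0.5,
                     instrument_kind = "hplc", source_path = path)
    list(table = tab, meta = meta, fractions = list())
  }
  ex <- assemble_experiment("dup", list(mk_run("f1.arw"), mk_run("f2.arw")))
  expect_setequal(unique(ex$analytic$sample), c("A", "A (2)"))
  # same file (multi-channel acquisition) keeps one shared name
  r1 <- mk_run("f1.arw"); r2 <- mk_run("f1.arw")
  r2$table$channel <- "ch2"; r2$meta$channel <- "ch2"
  ex2 <- assemble_experiment("dup2", list(r1, r2))
  expect_identical(unique(ex2$analytic$sample), "A")
})

test_that("assemble rejects empty input and reserved ids", {
  expect_error(assemble_experiment("x", list()), "nothing to assemble")
  run <- list(table = simple_tidy(1),
              meta = run_meta(sample = "A", channel = "c", flow_rate = 1,
                              instrument_kind = "hplc"),
              fractions = list())
  expect_error(assemble_experiment("a+b", list(run)), "reserved")
  expect_error(assemble_experiment("a?b", list(run)), "reserved")
})

test_that("combine_experiments joins ids with '+' and relabels samples", {
  e1 <- make_experiment_fixture("HPLC_Example_1", 1, 1, seed = 1,
                                duration = 0.2, interval = 0.01)
  e2 <- make_experiment_fixture("HPLC_Example_2", 1, 1, seed = 2,
                                duration = 0.2, interval = 0.01)
  comb <- combine_experiments(list(e1, e2))
  expect_identical(comb$id, "HPLC_Example_1+HPLC_Example_2")
  expect_setequal(unique(comb$analytic$sample),
                  c("HPLC_Example_1: inj_S1", "HPLC_Example_2: inj_S1"))
  expect_length(comb$fractions, 0)
  expect_error(combine_experiments(list(e1)), "at least 2")
  expect_error(combine_experiments(list(e1, e1)), "duplicate")
})

test_that("combining preparative experiments drops fraction fills", {
  p1 <- make_experiment_fixture("P1", 1, 1, preparative = TRUE, seed = 3,
                                duration = 6, interval = 0.2)
  p2 <- make_experiment_fixture("P2", 1, 1, preparative = TRUE, seed = 4,
                                duration = 6, interval = 0.2)
  comb <- combine_experiments(list(p1, p2))
  expect_length(comb$fractions, 0)
  expect_equal(length(unique(comb$preparative$sample)), 2)
})

test_that("peak_height reads the window maximum, preferring signal_norm", {
  spec <- sim_spec(duration = 2, interval = 0.005,
                   peaks = list(peak_spec(center = 1, height = 250,
                                          sigma = 0.05)))
  tab <- simulate_trace(spec)
  expect_equal(peak_height(tab, "sim", "signal", c(0.8, 1.2)), 250,
               tolerance = 1e-9)
  expect_equal(peak_height(tab, "sim", "signal", c(1.8, 2.0)), 0,
               tolerance = 1e-6)
  norm <- normalize_range(tab, range_start = 0.8, range_end = 1.2)
  expect_equal(peak_height(norm, "sim", "signal", c(0.8, 1.2)), 1.0)
  expect_error(peak_height(tab, "nope", "signal", c(0, 1)), "no points")
})

test_that("percent_bound reproduces the relative-binding heuristic", {
  # unbound peak four times the bound one -> about 20% bound
  expect_equal(percent_bound(0.25, 1.0), 20)
  expect_equal(percent_bound(0, 1), 0)
  expect_equal(percent_bound(3, 3), 50)
  expect_error(percent_bound(0, 0), "both")
  expect_error(percent_bound(-1, 1), "non-negative")
})
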