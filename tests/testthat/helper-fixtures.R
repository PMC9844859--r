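# Shared fixture builders; everything is generated in code at test time.

# Small random tidy table: n_groups traces on a shared or per-group grid.
random_tidy <- function(seed, n_groups = 2, n_pts = 5, shared_grid = TRUE,
                        x_unit = "time") {
  set.seed(seed)
  rows <- lapply(seq_len(n_groups), function(g) {
    if (shared_grid) {
      x <- seq(0, by = 0.1, length.out = n_pts)
    } else {
      x <- cumsum(round(stats::runif(n_pts, 0.01, 0.5), 3))
    }
    df <- data.frame(experiment = "E", sample = paste0("S", (g - 1) %/% 2 + 1),
                     channel = paste0("ch", (g - 1) %% 2 + 1),
                     signal = round(stats::rnorm(n_pts, 100, 30), 6),
                     stringsAsFactors = FALSE)
    df[[if (x_unit == "time") "time_min" else "volume_mL"]] <- x
    df
  })
  tidy_table(unique(do.call(rbind, rows)), x_unit = x_unit)
}

# Canonical sorting for order-insensitive table comparison.
sort_tidy <- function(tab) {
  df <- as.data.frame(tab)
  df <- df[order(df$sample, df$channel, df$time_min, df$volume_mL), ]
  rownames(df) <- NULL
  df
}

expect_same_table <- function(a, b) {
  expect_equal(sort_tidy(a), sort_tidy(b))
}

simple_tidy <- function(signals = c(2, 4, 8, 6), sample = "S1",
                        channel = "ch1", x = NULL) {
  if (is.null(x)) x <- seq_along(signals) - 1
  tidy_table(data.frame(experiment = "E", sample = sample, channel = channel,
                        time_min = x, signal = signals,
                        stringsAsFactors = FALSE), x_unit = "time")
}

# One simulated analytic run parsed back through a dialect on disk.
emit_and_parse <- function(experiment, dialect, dir = withr::local_tempdir()) {
  paths <- emit_dialect_files(experiment, dialect, dir)
  runs <- list()
  for (p in paths) runs <- c(runs, parse_chromatogram(p))
  list(paths = paths, runs = runs)
}
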