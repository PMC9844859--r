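#' Parametric chromatographic peak
#'
#' Phenomenological peak shape: a Gaussian of amplitude `height` and width
#' `sigma`, optionally convolved with an exponential decay of time constant
#' `tau` (the exponentially modified Gaussian, the standard model for
#' tailing peaks). `height` is the amplitude of the underlying Gaussian;
#' with `tau > 0` the realized maximum is lower and shifted right, as
#' tailing spreads the same area.
#'
#' @param center peak position (minutes or mL, matching the trace axis).
#' @param height > 0, signal units.
#' @param sigma > 0, Gaussian standard deviation in x units.
#' @param tau >= 0, exponential tailing constant in x units; 0 gives a pure
#'   Gaussian.
#' @export
peak_spec <- function(center, height, sigma, tau = 0) {
  if (!is.finite(height) || height <= 0) stop("peak_spec: height must be > 0")
  if (!is.finite(sigma) || sigma <= 0) stop("peak_spec: sigma must be > 0")
  if (!is.finite(tau) || tau < 0) stop("peak_spec: tau must be >= 0")
  structure(list(center = as.numeric(center), height = as.numeric(height),
                 sigma = as.numeric(sigma), tau = as.numeric(tau)),
            class = "peak_spec")
}

# EMG in the erfcx-stable form; reduces to the Gaussian as tau -> 0.
# Overflow guard: tiny tau relative to sigma falls back to the pure
# Gaussian outright.
peak_signal <- function(x, peak) {
  u <- x - peak$center
  g <- exp(-u^2 / (2 * peak$sigma^2))
  if (peak$tau < peak$sigma * 1e-6) {
    return(peak$height * g)
  }
  r <- peak$sigma / peak$tau
  z <- (r - u / peak$sigma) / sqrt(2)
  peak$height * r * sqrt(pi / 2) * pracma::erfcx(z) * g
}

#' Trace simulation parameters
#'
#' Defines one synthetic chromatogram: a regular x grid of
#' `floor(duration / interval) + 1` points, a constant baseline with linear
#' drift, a sum of [peak_spec()] peaks, and i.i.d. Gaussian noise drawn from
#' a named seed so every trace is exactly reproducible.
#'
#' @param duration trace length in x units (> 0).
#' @param interval sampling interval in x units (> 0).
#' @param peaks list of [peak_spec()].
#' @param baseline constant offset, signal units.
#' @param drift linear drift, signal units per x unit.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed integer RNG seed for the noise.
#' @export
sim_spec <- function(duration, interval, peaks = list(), baseline = 0,
                     drift = 0, noise_sd = 0, seed = 1L) {
  if (!is.finite(duration) || duration <= 0) {
    stop("sim_spec: duration must be > 0")
  }
  if (!is.finite(interval) || interval <= 0) {
    stop("sim_spec: interval must be > 0")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("sim_spec: noise_sd must be >= 0")
  }
  stopifnot(all(vapply(peaks, inherits, logical(1), "peak_spec")))
  structure(list(duration = as.numeric(duration),
                 interval = as.numeric(interval), peaks = peaks,
                 baseline = as.numeric(baseline), drift = as.numeric(drift),
                 noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
            class = "sim_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

# Noise-free closed-form signal at arbitrary x: baseline + drift*x + peaks.
signal_function <- function(spec, x) {
  s <- spec$baseline + spec$drift * x
  for (p in spec$peaks) s <- s + peak_signal(x, p)
  s
}

#' Simulate one chromatogram trace
#'
#' Evaluates `baseline + drift * x + sum(peaks)` on the spec's grid and adds
#' seeded Gaussian noise; deterministic for a fixed spec.
#'
#' @param spec [sim_spec()].
#' @param sample,channel,experiment_id names stamped on the records.
#' @param x_unit `"time"` (analytic) or `"volume"` (preparative).
#' @return a [tidy_table()] with one trace group; the spec is attached as
#'   attribute `"sim_spec"` (the ground truth record).
#' @export
simulate_trace <- function(spec, sample = "sim", channel = "signal",
                           experiment_id = "", x_unit = c("time", "volume")) {
  stopifnot(inherits(spec, "sim_spec"))
  x_unit <- match.arg(x_unit)
  n <- floor(spec$duration / spec$interval) + 1L
  x <- (seq_len(n) - 1L) * spec$interval
  s <- signal_function(spec, x)
  if (spec$noise_sd > 0) {
    s <- s + with_seed(spec$seed, stats::rnorm(n, 0, spec$noise_sd))
  }
  df <- data.frame(experiment = experiment_id, sample = sample,
                   channel = channel, signal = s, stringsAsFactors = FALSE)
  df[[if (x_unit == "time") "time_min" else "volume_mL"]] <- x
  out <- tidy_table(df, x_unit = x_unit)
  attr(out, "sim_spec") <- spec
  out
}

# Deterministic sub-seed: combine a base seed with a stream index, kept
# well inside the 32-bit integer range.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + k * 7919) %% 2147483647)
}

#' Generate a seeded experiment fixture with known ground truth
#'
#' Builds a full [experiment()] from randomized-but-seeded peak layouts.
#' Analytic fixtures emulate short analytic SEC runs: 3 min at 0.3 s
#' sampling (601 points) with 1-3 Gaussian/EMG peaks per trace over a small
#' drifting baseline. Preparative fixtures emulate an FPLC run over 24 mL
#' with fraction marks covering the main peak region. The same seed always
#' yields a bit-identical experiment.
#'
#' @param name experiment id.
#' @param n_samples,n_channels number of injections and detector channels
#'   (>= 1 each).
#' @param preparative generate a preparative (volume-axis, fractionated)
#'   experiment instead of an analytic one.
#' @param seed integer master seed.
#' @param duration,interval grid of each trace, in minutes (analytic) or mL
#'   (preparative); defaults 3 min / 0.005 min and 24 mL / 0.05 mL.
#' @param noise_sd detector noise (signal units); default 1 against peak
#'   heights of 100-800.
#' @return an [experiment()] with attribute `"ground_truth"`: per-group
#'   [sim_spec()]s, channel names, the flow rate, and fraction marks.
#' @export
make_experiment_fixture <- function(name, n_samples = 2L, n_channels = 2L,
                                    preparative = FALSE, seed = 1L,
                                    duration = if (preparative) 24 else 3,
                                    interval = if (preparative) 0.05 else 0.005,
                                    noise_sd = 1) {
  stopifnot(n_samples >= 1, n_channels >= 1)
  x_unit <- if (preparative) "volume" else "time"
  channels <- if (preparative) {
    c("UV", "Cond", "280nm", "260nm")[seq_len(min(n_channels, 4L))]
  } else {
    c("GFP", "280nm", "Trp", "260nm")[seq_len(min(n_channels, 4L))]
  }
  if (length(channels) < n_channels) {
    channels <- c(channels,
                  sprintf("ch%d", seq_len(n_channels - length(channels))))
  }
  samples <- sprintf("%s_S%d", if (preparative) "prep" else "inj",
                     seq_len(n_samples))
  flow_rate <- 0.5   # mL/min, typical for analytic SEC columns
  groups <- list()
  truth <- list(flow_rate = flow_rate, seed = as.integer(seed),
                channels = channels, samples = samples, specs = list())
  k <- 0L
  for (s in samples) {
    for (ch in channels) {
      k <- k + 1L
      sk <- sub_seed(seed, k)
      spec <- with_seed(sk, {
        n_peaks <- sample(1:3, 1)
        centers <- sort(stats::runif(n_peaks, 0.25 * duration,
                                     0.75 * duration))
        peaks <- lapply(seq_len(n_peaks), function(i) {
          peak_spec(center = centers[i],
                    height = stats::runif(1, 100, 800),
                    sigma = stats::runif(1, 0.02, 0.05) * duration,
                    tau = sample(c(0, 1), 1) *
                      stats::runif(1, 0.005, 0.02) * duration)
        })
        sim_spec(duration = duration, interval = interval, peaks = peaks,
                 baseline = stats::runif(1, 0, 5),
                 drift = stats::runif(1, -0.2, 0.2),
                 noise_sd = noise_sd, seed = sub_seed(sk, 1L))
      })
      groups[[paste(s, ch)]] <- simulate_trace(
        spec, sample = s, channel = ch, experiment_id = name,
        x_unit = x_unit)
      truth$specs[[paste(s, ch, sep = HEADER_SEP)]] <-
        list(sample = s, channel = ch, spec = spec)
    }
  }
  tab <- tidy_table(do.call(rbind, lapply(groups, as.data.frame)),
                    x_unit = x_unit)
  fractions <- list()
  if (preparative) {
    # fraction marks across the main elution window of the first trace
    first_spec <- truth$specs[[1]]$spec
    main <- first_spec$peaks[[which.max(vapply(first_spec$peaks, `[[`,
                                               numeric(1), "height"))]]
    lo <- max(0, main$center - 3 * main$sigma)
    marks <- seq(lo, min(duration, lo + 4 * 1.0), by = 1.0)
    marks <- marks[marks < duration]
    ends <- c(marks[-1], duration)
    fractions <- Map(fraction_record,
                     sprintf("A%d", seq_along(marks)), marks, ends)
    names(fractions) <- NULL
    truth$fraction_marks <- marks
  }
  ex <- experiment(name,
                   analytic = if (preparative) NULL else tab,
                   preparative = if (preparative) tab else NULL,
                   fractions = fractions)
  attr(ex, "ground_truth") <- truth
  ex
}

sanitize_filename <- function(s) gsub("[^A-Za-z0-9._-]+", "_", s)

emit_lines <- function(lines, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  path
}

#' Emit an experiment in a vendor export dialect
#'
#' Writes files that conform exactly to the canonical dialect layouts the
#' parsers read, with full round-trip numeric precision, so
#' `parse(emit(experiment))` reproduces the traces bit-identically. A
#' ground-truth sidecar YAML (`<name>_groundtruth.yaml`) records the
#' simulation specs, seeds and flow rate of the fixture.
#'
#' @param experiment an [experiment()] from [make_experiment_fixture()].
#' @param dialect `"akta-csv"` for preparative experiments; one of
#'   `"waters-arw"`, `"shimadzu-ascii"`, `"agilent-csv"` for analytic ones.
#' @param out_dir output directory (created if needed).
#' @return character vector of written data-file paths (the sidecar path is
#'   attached as attribute `"sidecar"`).
#' @export
emit_dialect_files <- function(experiment, dialect, out_dir) {
  stopifnot(inherits(experiment, "chrom_experiment"))
  dialect <- match.arg(dialect, DIALECTS)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- attr(experiment, "ground_truth")
  preparative <- nrow(experiment$preparative) > 0
  if (dialect == "akta-csv" && !preparative) {
    stop("emit_dialect_files: akta-csv holds preparative (volume-axis) ",
         "runs, but the experiment has none")
  }
  if (dialect != "akta-csv" && nrow(experiment$analytic) == 0) {
    stop("emit_dialect_files: dialect '", dialect,
         "' holds analytic runs, but the experiment has none")
  }
  tab <- if (dialect == "akta-csv") experiment$preparative else
    experiment$analytic
  flow <- if (!is.null(truth)) truth$flow_rate else NA_real_
  paths <- character()
  if (dialect == "waters-arw") {
    for (g in split(seq_len(nrow(tab)), paste(tab$sample, tab$channel,
                                              sep = "\r"))) {
      s <- tab$sample[g[1]]; ch <- tab$channel[g[1]]
      path <- file.path(out_dir, sprintf("%s_%s_%s.arw",
                                         sanitize_filename(experiment$id),
                                         sanitize_filename(s),
                                         sanitize_filename(ch)))
      hdr_f <- c("SampleName", "Channel", "Instrument Method",
                 "Flow Rate(mL/min)")
      hdr_v <- c(s, ch, "analytic_sec",
                 if (is.na(flow)) "" else fmt_repr(flow))
      rows <- paste(fmt_repr(tab$time_min[g]), fmt_repr(tab$signal[g]),
                    sep = "\t")
      emit_lines(c(paste(hdr_f, collapse = "\t"),
                   paste(hdr_v, collapse = "\t"), rows), path)
      paths <- c(paths, path)
    }
  } else if (dialect == "shimadzu-ascii") {
    for (s in unique(tab$sample)) {
      path <- file.path(out_dir, sprintf("%s_%s.txt",
                                         sanitize_filename(experiment$id),
                                         sanitize_filename(s)))
      lines <- c("[Header]", paste0("Sample Name\t", s), "")
      st <- tab[tab$sample == s, , drop = FALSE]
      for (ch in unique(st$channel)) {
        g <- st[st$channel == ch, , drop = FALSE]
        dt <- diff(g$time_min)
        if (nrow(g) > 1 && diff(range(dt)) > 1e-9) {
          stop("emit_dialect_files: shimadzu-ascii needs a uniform ",
               "sampling interval in group (", s, ", ", ch, ")")
        }
        msec <- if (nrow(g) > 1) dt[1] * 60000 else 1000
        lines <- c(lines,
                   sprintf("[LC Chromatogram(%s)]", ch),
                   paste0("Interval(msec)\t", fmt_repr(msec)),
                   paste0("# of Points\t", nrow(g)),
                   fmt_repr(g$signal), "")
      }
      emit_lines(lines, path)
      paths <- c(paths, path)
    }
  } else if (dialect == "agilent-csv") {
    for (g in split(seq_len(nrow(tab)), paste(tab$sample, tab$channel,
                                              sep = "\r"))) {
      s <- tab$sample[g[1]]; ch <- tab$channel[g[1]]
      path <- file.path(out_dir, sprintf("%s_%s_%s.csv",
                                         sanitize_filename(experiment$id),
                                         sanitize_filename(s),
                                         sanitize_filename(ch)))
      emit_lines(c("Time,Signal",
                   paste(fmt_repr(tab$time_min[g]), fmt_repr(tab$signal[g]),
                         sep = ",")), path)
      paths <- c(paths, path)
    }
  } else {                                # akta-csv
    for (s in unique(tab$sample)) {
      st <- tab[tab$sample == s, , drop = FALSE]
      chans <- unique(st$channel)
      cols <- list()
      hdr1 <- character(); hdr2 <- character()
      for (ch in chans) {
        g <- st[st$channel == ch, , drop = FALSE]
        cols[[length(cols) + 1L]] <- fmt_repr(g$volume_mL)
        cols[[length(cols) + 1L]] <- fmt_repr(g$signal)
        hdr1 <- c(hdr1, ch, "")
        hdr2 <- c(hdr2, "mL", "mAU")
      }
      if (length(experiment$fractions)) {
        fr <- experiment$fractions
        cols[[length(cols) + 1L]] <-
          fmt_repr(vapply(fr, `[[`, numeric(1), "start"))
        cols[[length(cols) + 1L]] <- vapply(fr, `[[`, character(1), "label")
        hdr1 <- c(hdr1, "Fraction", "")
        hdr2 <- c(hdr2, "mL", "")
      }
      nmax <- max(vapply(cols, length, integer(1)))
      cols <- lapply(cols, function(col) c(col, rep("", nmax - length(col))))
      rows <- do.call(paste, c(cols, sep = ","))
      # file name carries the sample: the dialect has no metadata block
      path <- file.path(out_dir, paste0(sanitize_filename(s), ".csv"))
      emit_lines(c(paste(hdr1, collapse = ","),
                   paste(hdr2, collapse = ","), rows), path)
      paths <- c(paths, path)
    }
  }
  sidecar <- file.path(out_dir,
                       sprintf("%s_groundtruth.yaml",
                               sanitize_filename(experiment$id)))
  write_ground_truth(experiment, dialect, paths, sidecar)
  attr(paths, "sidecar") <- sidecar
  paths
}

write_ground_truth <- function(experiment, dialect, paths, sidecar) {
  truth <- attr(experiment, "ground_truth")
  doc <- list(experiment = experiment$id, dialect = dialect,
              files = basename(paths))
  if (!is.null(truth)) {
    doc$flow_rate <- truth$flow_rate
    doc$seed <- truth$seed
    doc$groups <- lapply(truth$specs, function(gs) {
      list(sample = gs$sample, channel = gs$channel,
           duration = gs$spec$duration, interval = gs$spec$interval,
           baseline = gs$spec$baseline, drift = gs$spec$drift,
           noise_sd = gs$spec$noise_sd, seed = gs$spec$seed,
           peaks = lapply(gs$spec$peaks, unclass))
    })
  }
  yaml::write_yaml(doc, sidecar)
  sidecar
}
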