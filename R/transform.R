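RESERVED_ID_CHARS <- c("+", "?", "&", "=")

#' Labeled fraction interval of a preparative run
#'
#' A fraction is a labeled interval of collected eluate, bounded by
#' fraction-collector marks. Intervals are half-open `[start, end)` except
#' the last one of a run, which closes at the trace end, so together they
#' partition the eluate without overlap.
#'
#' @param label collector label, e.g. `"A1"`.
#' @param start,end bounding volumes in mL, `start < end`.
#' @export
fraction_record <- function(label, start, end) {
  stopifnot(is.character(label), length(label) == 1)
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start >= end) {
    stop("fraction_record: need start < end (got [", start, ", ", end, "))")
  }
  structure(list(label = label, start = start, end = end),
            class = "fraction_record")
}

empty_tidy <- function(x_unit) {
  tidy_table(data.frame(experiment = character(), sample = character(),
                        channel = character(), time_min = numeric(),
                        volume_mL = numeric(), signal = numeric(),
                        stringsAsFactors = FALSE), x_unit = x_unit)
}

validate_experiment_id <- function(id, allow_plus = FALSE) {
  if (!is.character(id) || length(id) != 1 || !nzchar(id)) {
    stop("experiment id must be a non-empty string")
  }
  reserved <- setdiff(RESERVED_ID_CHARS, if (allow_plus) "+" else character())
  hit <- reserved[vapply(reserved, grepl, logical(1), x = id, fixed = TRUE)]
  if (length(hit)) {
    stop("experiment id '", id, "' contains reserved URL character(s): ",
         paste(hit, collapse = " "))
  }
  invisible(id)
}

#' A processed chromatography experiment
#'
#' The unit of storage and plotting: a named container holding the analytic
#' traces (time axis, volume derivable from flow rate), the preparative
#' traces (volume axis), and the preparative fraction intervals.
#'
#' @param id experiment name; must be free of the URL-reserved characters
#'   `+ ? & =` because ids travel verbatim in share links.
#' @param analytic [tidy_table()] with `x_unit = "time"` (may be empty).
#' @param preparative [tidy_table()] with `x_unit = "volume"` (may be empty).
#' @param fractions list of [fraction_record()], sorted, non-overlapping.
#' @param version schema/content version, >= 1.
#' @export
experiment <- function(id, analytic = NULL, preparative = NULL,
                       fractions = list(), version = 1L) {
  validate_experiment_id(id, allow_plus = isTRUE(attr(id, "combined")))
  if (is.null(analytic)) analytic <- empty_tidy("time")
  if (is.null(preparative)) preparative <- empty_tidy("volume")
  stopifnot(inherits(analytic, "tidy_table"),
            attr(analytic, "x_unit") == "time",
            inherits(preparative, "tidy_table"),
            attr(preparative, "x_unit") == "volume")
  if (length(fractions)) {
    stopifnot(all(vapply(fractions, inherits, logical(1), "fraction_record")))
    starts <- vapply(fractions, `[[`, numeric(1), "start")
    fractions <- fractions[order(starts)]
    ends <- vapply(fractions, `[[`, numeric(1), "end")
    starts <- sort(starts)
    if (any(starts[-1] < ends[-length(ends)] - 1e-12)) {
      stop("experiment: fractions overlap")
    }
  }
  if (nrow(analytic) && all(!nzchar(analytic$experiment))) {
    analytic$experiment <- as.character(id)
  }
  if (nrow(preparative) && all(!nzchar(preparative$experiment))) {
    preparative$experiment <- as.character(id)
  }
  structure(list(id = as.character(id), analytic = analytic,
                 preparative = preparative, fractions = fractions,
                 version = as.integer(version)),
            class = "chrom_experiment")
}

#' @export
print.chrom_experiment <- function(x, ...) {
  n_an <- length(unique(x$analytic$sample[nzchar(x$analytic$sample)]))
  n_pr <- length(unique(x$preparative$sample[nzchar(x$preparative$sample)]))
  cat(sprintf(
    "<experiment '%s'> %d analytic sample(s), %d preparative sample(s), %d fraction(s)\n",
    x$id, n_an, n_pr, length(x$fractions)))
  invisible(x)
}

#' Derive elution volume from retention time
#'
#' volume (mL) = time (min) x flow rate (mL/min), per record; the time
#' column is retained.
#'
#' @param table [tidy_table()] with `x_unit = "time"`.
#' @param flow_rate mL/min, > 0.
#' @export
add_volume <- function(table, flow_rate) {
  stopifnot(inherits(table, "tidy_table"))
  if (attr(table, "x_unit") != "time") {
    stop("add_volume: table is already on a volume axis")
  }
  if (!is.numeric(flow_rate) || length(flow_rate) != 1 ||
      !is.finite(flow_rate) || flow_rate <= 0) {
    stop("add_volume: flow_rate must be a single value > 0")
  }
  table$volume_mL <- table$time_min * flow_rate
  table
}

#' Scale raw signal by a batch factor
#'
#' Multiplies every raw signal by `factor`, e.g. to reconcile differing
#' flow-cell path lengths between instruments. Applied before any
#' normalization; [normalize_range()] output is invariant to it.
#'
#' @param table [tidy_table()].
#' @param factor unitless, > 0.
#' @export
apply_scale <- function(table, factor) {
  stopifnot(inherits(table, "tidy_table"))
  if (!is.numeric(factor) || length(factor) != 1 ||
      !is.finite(factor) || factor <= 0) {
    stop("apply_scale: factor must be a single value > 0")
  }
  table$signal <- table$signal * factor
  table
}

#' Normalization parameters
#'
#' @param range_start,range_end interval on the table's x axis (same unit as
#'   the trace: minutes or mL), `range_start < range_end`.
#' @param zero_min also anchor the in-range minimum at 0, mapping the range
#'   onto `[0, 1]` to correct simple baseline offsets.
#' @export
norm_params <- function(range_start, range_end, zero_min = FALSE) {
  range_start <- as.numeric(range_start); range_end <- as.numeric(range_end)
  if (!is.finite(range_start) || !is.finite(range_end) ||
      range_start >= range_end) {
    stop("norm_params: need range_start < range_end")
  }
  structure(list(range_start = range_start, range_end = range_end,
                 zero_min = isTRUE(zero_min)),
            class = "norm_params")
}

#' Range-based trace normalization
#'
#' For each (sample, channel) trace independently, the maximum signal over
#' the selected x interval is mapped to 1.0 and the whole trace — not just
#' the in-range part — is scaled linearly, so out-of-range values may exceed
#' 1. With `zero_min`, the in-range minimum is additionally mapped to 0
#' (affine map `(s - m) / (M - m)`). Results are stored in `signal_norm`;
#' the raw `signal` column is untouched, so normalized and raw views can be
#' presented side by side.
#'
#' @param table [tidy_table()].
#' @param params a [norm_params()]; alternatively pass `range_start`,
#'   `range_end`, `zero_min` directly.
#' @param range_start,range_end,zero_min used when `params` is missing.
#' @return the table with `signal_norm` filled.
#' @export
normalize_range <- function(table, params = NULL, range_start = NULL,
                            range_end = NULL, zero_min = FALSE) {
  stopifnot(inherits(table, "tidy_table"))
  if (is.null(params)) params <- norm_params(range_start, range_end, zero_min)
  stopifnot(inherits(params, "norm_params"))
  xs <- x_values(table)
  gid <- group_id(table)
  out <- rep(NA_real_, nrow(table))
  for (g in unique(gid)) {
    sel <- gid == g
    in_range <- sel & !is.na(xs) &
      xs >= params$range_start & xs <= params$range_end
    parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    label <- paste0("(", parts[2], ", ", parts[3], ")")
    if (!any(in_range)) {
      stop("normalize_range: group ", label, " has no points in [",
           params$range_start, ", ", params$range_end, "]")
    }
    M <- max(table$signal[in_range])
    if (params$zero_min) {
      m <- min(table$signal[in_range])
      if (M == m) {
        stop("normalize_range: degenerate trace ", label,
             " is flat over the range (max == min)")
      }
      out[sel] <- (table$signal[sel] - m) / (M - m)
    } else {
      if (M <= 0) {
        stop("normalize_range: degenerate trace ", label,
             ": range maximum is not positive")
      }
      out[sel] <- table$signal[sel] / M
    }
  }
  table$signal_norm <- out
  table
}

#' Classify a run as analytic or preparative
#'
#' A run from a preparative FPLC, or any run that collected fractions, is
#' preparative; everything else is analytic.
#'
#' @param meta [run_meta()].
#' @param fractions list of [fraction_record()] (possibly empty).
#' @return `"analytic"` or `"preparative"`.
#' @export
classify_run <- function(meta, fractions = list()) {
  stopifnot(inherits(meta, "run_meta"))
  if (identical(meta$instrument_kind, "fplc") || length(fractions) > 0) {
    "preparative"
  } else {
    "analytic"
  }
}

# Disambiguate duplicate sample names arriving from different files of the
# same kind: a file re-claiming an already-seen (sample, channel) trace is a
# distinct injection and gets a numeric suffix ("A", "A (2)", ...). Files
# contributing only new channels of a seen sample are the same injection
# acquired per-channel (one file per detector) and keep the shared name.
disambiguate_samples <- function(runs) {
  # claimants[[sample]]: list of injections, each list(paths, channels)
  claimants <- list()
  for (i in seq_along(runs)) {
    s <- runs[[i]]$meta$sample
    p <- runs[[i]]$meta$source_path
    chs <- unique(runs[[i]]$table$channel)
    if (!length(chs)) chs <- runs[[i]]$meta$channel
    cl <- claimants[[s]]
    k <- NA_integer_
    for (j in seq_along(cl)) {
      if (p %in% cl[[j]]$paths) { k <- j; break }
    }
    if (is.na(k)) {
      for (j in seq_along(cl)) {
        if (!any(chs %in% cl[[j]]$channels)) { k <- j; break }
      }
    }
    if (is.na(k)) {
      k <- length(cl) + 1L
      cl[[k]] <- list(paths = character(), channels = character())
    }
    cl[[k]]$paths <- union(cl[[k]]$paths, p)
    cl[[k]]$channels <- union(cl[[k]]$channels, chs)
    claimants[[s]] <- cl
    if (k > 1L) {
      new <- sprintf("%s (%d)", s, k)
      runs[[i]]$meta$sample <- new
      runs[[i]]$table$sample <- rep(new, nrow(runs[[i]]$table))
    }
  }
  runs
}

#' Assemble parsed runs into an experiment
#'
#' Classifies each run with [classify_run()], merges analytic runs into one
#' time-axis table and preparative runs into one volume-axis table with
#' their fractions, and stamps the experiment id on every record. Duplicate
#' sample names arriving from different files of the same kind are
#' disambiguated with a numeric suffix (`"A"`, `"A (2)"`, ...).
#'
#' @param id experiment name (no `+ ? & =`).
#' @param runs list of parsed runs, each `list(table, meta, fractions)` with
#'   resolved metadata.
#' @return a [experiment()].
#' @export
assemble_experiment <- function(id, runs) {
  validate_experiment_id(id)
  if (!length(runs)) stop("assemble_experiment: nothing to assemble")
  kind <- vapply(runs, function(r)
    classify_run(r$meta, r$fractions), character(1))
  an <- disambiguate_samples(runs[kind == "analytic"])
  pr <- disambiguate_samples(runs[kind == "preparative"])
  bind_runs <- function(rs, x_unit) {
    if (!length(rs)) return(empty_tidy(x_unit))
    tabs <- lapply(rs, function(r) {
      t <- r$table
      t$experiment <- id
      as.data.frame(t)
    })
    tidy_table(do.call(rbind, tabs), x_unit = x_unit)
  }
  fractions <- do.call(c, c(list(list()), lapply(pr, `[[`, "fractions")))
  experiment(id,
             analytic = bind_runs(an, "time"),
             preparative = bind_runs(pr, "volume"),
             fractions = fractions)
}

#' Combine experiments for side-by-side comparison
#'
#' The combined id is the constituent ids joined with `"+"` (the same form
#' share links use). Every sample is relabeled `"<experiment id>: <sample>"`
#' so injections stay attributable, and the combined fraction list is empty
#' — combined preparative views show overall profiles without fraction
#' fills.
#'
#' @param experiments list of >= 2 [experiment()]s with distinct ids.
#' @export
combine_experiments <- function(experiments) {
  if (length(experiments) < 2) {
    stop("combine_experiments: need at least 2 experiments")
  }
  stopifnot(all(vapply(experiments, inherits, logical(1),
                       "chrom_experiment")))
  ids <- vapply(experiments, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("combine_experiments: duplicate experiment ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  relabel <- function(tab, eid) {
    if (nrow(tab)) tab$sample <- paste0(eid, ": ", tab$sample)
    as.data.frame(tab)
  }
  an <- do.call(rbind, Map(function(e) relabel(e$analytic, e$id),
                           experiments))
  pr <- do.call(rbind, Map(function(e) relabel(e$preparative, e$id),
                           experiments))
  cid <- paste(ids, collapse = "+")
  attr(cid, "combined") <- TRUE
  experiment(cid,
             analytic = tidy_table(an, x_unit = "time"),
             preparative = tidy_table(pr, x_unit = "volume"),
             fractions = list())
}

#' Peak height over an x window
#'
#' The maximum signal of one (sample, channel) trace over a window —
#' normalized values when present, raw otherwise. With traces normalized to
#' a reference peak, relative peak heights act as a proxy for the relative
#' proportion of the labeled species in each state.
#'
#' @param table [tidy_table()].
#' @param sample,channel trace selector.
#' @param range length-2 numeric x window.
#' @export
peak_height <- function(table, sample, channel, range) {
  stopifnot(inherits(table, "tidy_table"), length(range) == 2)
  xs <- x_values(table)
  sel <- table$sample == sample & table$channel == channel &
    !is.na(xs) & xs >= range[1] & xs <= range[2]
  if (!any(sel)) {
    stop("peak_height: no points for (", sample, ", ", channel,
         ") in [", range[1], ", ", range[2], "]")
  }
  vals <- table$signal_norm[sel]
  if (all(is.na(vals))) vals <- table$signal[sel]
  max(vals, na.rm = TRUE)
}

#' Percentage bound from relative peak heights
#'
#' Heuristic binding readout from fluorescence-detection SEC: once traces
#' are normalized to the unbound peak, the bound and unbound peak heights of
#' the tagged species give the bound percentage as
#' `100 * h_bound / (h_bound + h_unbound)`. An unbound peak four times the
#' bound one therefore reads as approximately 20% bound.
#'
#' @param h_bound,h_unbound non-negative peak heights, not both zero.
#' @return percentage in `[0, 100]`.
#' @export
percent_bound <- function(h_bound, h_unbound) {
  stopifnot(is.numeric(h_bound), is.numeric(h_unbound))
  if (h_bound < 0 || h_unbound < 0) {
    stop("percent_bound: peak heights must be non-negative")
  }
  if (h_bound + h_unbound == 0) {
    stop("percent_bound: both peak heights are zero")
  }
  100 * h_bound / (h_bound + h_unbound)
}
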