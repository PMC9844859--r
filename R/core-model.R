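# Canonical column order of a tidy table.
TIDY_COLS <- c("experiment", "sample", "channel",
               "time_min", "volume_mL", "signal", "signal_norm")

# Separator reserved for wide-table column headers.
HEADER_SEP <- " | "

#' Construct a tidy chromatogram table
#'
#' The canonical long-form container: one row is one observation, i.e. one
#' signal reading of one detector channel for one injection at one x
#' position. Time is in minutes, volume in mL. `x_unit` states which of the
#' two is the primary axis: analytic (HPLC) runs are acquired over time and
#' may gain a derived volume via [add_volume()]; preparative (FPLC) runs are
#' recorded over elution volume.
#'
#' @param df data.frame with columns `experiment`, `sample`, `channel`,
#'   `signal`, and at least the x column implied by `x_unit` (`time_min` or
#'   `volume_mL`). Missing optional columns (`volume_mL`, `signal_norm`, or
#'   `time_min` for volume-axis tables) are added as `NA`.
#' @param x_unit `"time"` or `"volume"`.
#' @param validate validate invariants (uniqueness, monotone x) and stop on
#'   the first violation.
#' @return A `tidy_table`: a data.frame with the seven canonical columns and
#'   an `x_unit` attribute.
#' @seealso [validate_table()], [tidy_to_wide()]
#' @export
tidy_table <- function(df, x_unit = c("time", "volume"), validate = TRUE) {
  x_unit <- match.arg(x_unit)
  stopifnot(is.data.frame(df))
  needed <- c("experiment", "sample", "channel", "signal",
              if (x_unit == "time") "time_min" else "volume_mL")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("tidy_table: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(TIDY_COLS, names(df))) {
    df[[col]] <- rep(NA_real_, nrow(df))
  }
  df <- df[TIDY_COLS]
  df$experiment <- as.character(df$experiment)
  df$sample     <- as.character(df$sample)
  df$channel    <- as.character(df$channel)
  for (col in c("time_min", "volume_mL", "signal", "signal_norm")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  bad <- grepl(HEADER_SEP, df$sample, fixed = TRUE) |
    grepl(HEADER_SEP, df$channel, fixed = TRUE)
  if (any(bad)) {
    stop("tidy_table: sample/channel names must not contain the reserved ",
         "separator '", HEADER_SEP, "'")
  }
  # canonical row order: group-major, x ascending (radix = locale-stable),
  # so construction is insensitive to input row order
  xs <- if (x_unit == "volume") df$volume_mL else df$time_min
  df <- df[order(df$experiment, df$sample, df$channel, xs,
                 method = "radix"), ]
  rownames(df) <- NULL
  out <- structure(df, x_unit = x_unit,
                   class = c("tidy_table", "data.frame"))
  if (validate) {
    v <- validate_table(out)
    if (nrow(v)) stop("tidy_table: invalid table: ", v$message[1])
  }
  out
}

#' @export
print.tidy_table <- function(x, ...) {
  groups <- unique(paste(x$sample, x$channel, sep = HEADER_SEP))
  cat(sprintf("<tidy_table> %d observations, %d trace group(s), x = %s\n",
              nrow(x), length(groups), attr(x, "x_unit")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# x values of a tidy table according to its x_unit.
x_values <- function(table) {
  if (attr(table, "x_unit") == "volume") table$volume_mL else table$time_min
}

x_col_name <- function(table) {
  if (attr(table, "x_unit") == "volume") "volume_mL" else "time_min"
}

# Key used to align grids across groups: x rounded to 9 decimals to absorb
# float noise from parsing; stored values stay untouched.
x_key <- function(x) sprintf("%.9f", round(x, 9))

group_id <- function(table) {
  paste(table$experiment, table$sample, table$channel, sep = "\r")
}

#' Validate a tidy table against its invariants
#'
#' Checks, per (experiment, sample, channel) trace group: non-negative x,
#' uniqueness of (experiment, sample, channel, x), and strictly increasing x.
#' Violations are returned, never raised, so callers can report them all.
#'
#' @param table a [tidy_table()].
#' @return data.frame with columns `rule`, `key`, `message`; zero rows iff
#'   the table conforms.
#' @export
validate_table <- function(table) {
  stopifnot(inherits(table, "tidy_table"))
  out <- list()
  add <- function(rule, key, message) {
    out[[length(out) + 1L]] <<- data.frame(rule = rule, key = key,
                                           message = message,
                                           stringsAsFactors = FALSE)
  }
  xs <- x_values(table)
  if (anyNA(xs) && nrow(table)) {
    add("x-present", "", sprintf("%d row(s) missing the %s x value",
                                 sum(is.na(xs)), attr(table, "x_unit")))
  }
  neg <- which(!is.na(xs) & xs < 0)
  for (i in neg) {
    add("x-nonnegative", paste(table$sample[i], table$channel[i], xs[i]),
        sprintf("negative x value %g in group (%s, %s)",
                xs[i], table$sample[i], table$channel[i]))
  }
  vneg <- which(!is.na(table$volume_mL) & table$volume_mL < 0)
  if (attr(table, "x_unit") != "volume") {
    for (i in vneg) {
      add("volume-nonnegative",
          paste(table$sample[i], table$channel[i]),
          sprintf("negative volume in group (%s, %s)",
                  table$sample[i], table$channel[i]))
    }
  }
  gid <- group_id(table)
  for (g in unique(gid)) {
    sel <- gid == g
    gx <- xs[sel]
    parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    key <- paste(parts[2], parts[3], sep = " / ")
    if (anyDuplicated(x_key(gx))) {
      dup <- gx[duplicated(x_key(gx))][1]
      add("unique-key", key,
          sprintf("duplicate reading at x = %g in group (%s)", dup, key))
    } else if (is.unsorted(gx, strictly = TRUE)) {
      add("monotone-x", key,
          sprintf("x values not strictly increasing in group (%s)", key))
    }
  }
  if (!length(out)) {
    return(data.frame(rule = character(), key = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Pivot a tidy table to wide form
#'
#' One column per (sample, channel) trace, headers `"<sample> | <channel>"`,
#' x column first. The x axis is the sorted union of every group's sampling
#' grid (channels may be acquired at different rates), so a cell is `NA`
#' where that trace has no reading at that x. No signal value is altered.
#'
#' @param table a [tidy_table()].
#' @param value which value column to spread: `"signal"` (default) or
#'   `"signal_norm"`.
#' @return A `wide_table`: data.frame whose first column is `time_min` or
#'   `volume_mL` (per the table's `x_unit`), remaining columns one per trace.
#' @export
tidy_to_wide <- function(table, value = c("signal", "signal_norm")) {
  stopifnot(inherits(table, "tidy_table"))
  value <- match.arg(value)
  xname <- x_col_name(table)
  if (!nrow(table)) {
    out <- data.frame(x = numeric(0))
    names(out) <- xname
    return(structure(out, x_unit = attr(table, "x_unit"),
                     class = c("wide_table", "data.frame")))
  }
  v <- validate_table(table)
  if (nrow(v)) stop("tidy_to_wide: ", v$message[1])
  xs <- x_values(table)
  keys <- x_key(xs)
  ord <- order(xs)
  ukeys <- keys[ord][!duplicated(keys[ord])]
  uxs <- xs[ord][!duplicated(keys[ord])]
  header <- paste(table$sample, table$channel, sep = HEADER_SEP)
  out <- data.frame(x = uxs)
  names(out) <- xname
  for (h in unique(header)) {
    sel <- header == h
    col <- rep(NA_real_, length(ukeys))
    col[match(keys[sel], ukeys)] <- table[[value]][sel]
    out[[h]] <- col
  }
  structure(out, x_unit = attr(table, "x_unit"),
            class = c("wide_table", "data.frame"))
}

#' Rebuild a tidy table from a wide one
#'
#' Inverse of [tidy_to_wide()] up to row order: headers are split on the
#' reserved `" | "` separator back into (sample, channel), `NA` cells are
#' dropped, and values land in the `signal` column.
#'
#' @param wide a `wide_table` (or any data.frame whose first column is the x
#'   variable and remaining headers follow the `"<sample> | <channel>"`
#'   convention).
#' @param experiment_id experiment name stamped on every record.
#' @return a [tidy_table()].
#' @export
wide_to_tidy <- function(wide, experiment_id) {
  stopifnot(is.data.frame(wide), ncol(wide) >= 1)
  xname <- names(wide)[1]
  x_unit <- if (identical(xname, "volume_mL")) "volume" else "time"
  series <- names(wide)[-1]
  recs <- list()
  for (h in series) {
    parts <- strsplit(h, HEADER_SEP, fixed = TRUE)[[1]]
    if (length(parts) != 2L || !nzchar(parts[1]) || !nzchar(parts[2])) {
      stop("wide_to_tidy: header '", h, "' does not follow the ",
           "'<sample>", HEADER_SEP, "<channel>' convention")
    }
    keep <- !is.na(wide[[h]])
    if (!any(keep)) next
    recs[[h]] <- data.frame(
      experiment = experiment_id,
      sample = parts[1], channel = parts[2],
      x = wide[[1]][keep], signal = wide[[h]][keep],
      stringsAsFactors = FALSE)
  }
  df <- if (length(recs)) do.call(rbind, recs) else
    data.frame(experiment = character(), sample = character(),
               channel = character(), x = numeric(), signal = numeric())
  names(df)[names(df) == "x"] <- xname
  tidy_table(df, x_unit = x_unit)
}

# Shortest round-trip decimal representation: the fewest significant digits
# whose re-parse is bit-identical. Vectorised over the common 15-digit case.
fmt_repr <- function(x) {
  out <- character(length(x))
  na <- is.na(x)
  out[na] <- ""
  todo <- which(!na)
  for (d in c(15L, 16L, 17L)) {
    if (!length(todo)) break
    s <- formatC(x[todo], digits = d, format = "g", width = 1)
    ok <- as.numeric(s) == x[todo]
    out[todo[ok]] <- s[ok]
    todo <- todo[!ok]
  }
  if (length(todo)) out[todo] <- sprintf("%.17g", x[todo])
  out
}

#' Write / read tidy and wide CSV files
#'
#' Tidy CSV columns: `experiment,sample,channel,time_min,volume_mL,signal,
#' signal_norm`; absent volume/signal_norm cells are written empty. Wide CSV:
#' the x column then one column per trace under the header convention, empty
#' string as the missing-cell marker. Numbers are written with full
#' round-trip precision.
#'
#' @param table a [tidy_table()] (or `wide_table` for the wide writer).
#' @param path output file.
#' @return `path`, invisibly; readers return the parsed table.
#' @export
write_tidy_csv <- function(table, path) {
  stopifnot(inherits(table, "tidy_table"))
  df <- as.data.frame(table)
  num <- c("time_min", "volume_mL", "signal", "signal_norm")
  for (col in num) df[[col]] <- fmt_repr(df[[col]])
  names(df) <- c("experiment", "sample", "channel", "time_min",
                 "volume_mL", "signal", "signal_norm")
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_tidy_csv
#' @param x_unit x axis of the file being read.
#' @export
read_tidy_csv <- function(path, x_unit = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(experiment = "character",
                                       sample = "character",
                                       channel = "character"))
  if (is.null(x_unit)) {
    x_unit <- if (all(is.na(df$time_min)) && !all(is.na(df$volume_mL)))
      "volume" else "time"
  }
  tidy_table(df, x_unit = x_unit)
}

#' @rdname write_tidy_csv
#' @export
write_wide_csv <- function(table, path) {
  stopifnot(inherits(table, "wide_table"))
  df <- as.data.frame(table)
  for (i in seq_along(df)) df[[i]] <- fmt_repr(df[[i]])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
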