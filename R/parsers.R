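DIALECTS <- c("waters-arw", "shimadzu-ascii", "agilent-csv", "akta-csv")

#' Run metadata
#'
#' Metadata attached to one parsed trace group: injection (sample) name,
#' detector channel, pump flow rate in mL/min, and whether the source
#' instrument is an analytic HPLC or a preparative FPLC. Fields a dialect
#' does not carry are `NA` and must be completed with [resolve_metadata()]
#' before an experiment can be assembled.
#'
#' @param sample injection name.
#' @param channel detector channel name, or `NA`.
#' @param flow_rate mL/min (> 0), or `NA`.
#' @param instrument_kind `"hplc"` or `"fplc"`.
#' @param source_path originating file.
#' @param dialect originating dialect id (used as a defaults-database key).
#' @param method instrument method name, if the file carries one.
#' @export
run_meta <- function(sample = NA_character_, channel = NA_character_,
                     flow_rate = NA_real_,
                     instrument_kind = c("hplc", "fplc"),
                     source_path = NA_character_, dialect = NA_character_,
                     method = NA_character_) {
  instrument_kind <- match.arg(instrument_kind)
  if (!is.na(flow_rate) && flow_rate <= 0) {
    stop("run_meta: flow_rate must be > 0")
  }
  structure(list(sample = sample, channel = channel,
                 flow_rate = as.numeric(flow_rate),
                 instrument_kind = instrument_kind,
                 source_path = source_path, dialect = dialect,
                 method = method),
            class = "run_meta")
}

#' @export
print.run_meta <- function(x, ...) {
  cat(sprintf("<run_meta> sample=%s channel=%s flow=%s mL/min [%s, %s]\n",
              x$sample, x$channel,
              ifelse(is.na(x$flow_rate), "?", format(x$flow_rate)),
              x$instrument_kind,
              ifelse(is.na(x$dialect), "?", x$dialect)))
  invisible(x)
}

read_head_lines <- function(path, n = 50L) {
  con <- file(path, "rt", encoding = "UTF-8")
  on.exit(close(con))
  out <- tryCatch(readLines(con, n = n, warn = FALSE),
                  error = function(e) {
                    close(con)
                    con <<- file(path, "rt", encoding = "latin1")
                    readLines(con, n = n, warn = FALSE)
                  })
  out
}

read_all_lines <- function(path) {
  txt <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (any(validEnc(txt) == FALSE)) {
    txt <- readLines(path, warn = FALSE, encoding = "latin1")
    txt <- enc2utf8(txt)
  }
  txt
}

csv_cells <- function(line) {
  # dialect files never quote cells, so a plain split is exact; the sentinel
  # keeps trailing empty cells (strsplit would drop them)
  cells <- strsplit(paste0(line, "\x01"), ",", fixed = TRUE)[[1]]
  cells[length(cells)] <- sub("\x01$", "", cells[length(cells)])
  cells
}

is_num <- function(s) {
  s <- trimws(s)
  nzchar(s) & !is.na(suppressWarnings(as.numeric(s)))
}

# AKTA sentinel: second line's odd cells (the x column of every pair) are
# all "mL" volume-unit labels.
is_akta_header <- function(lines) {
  if (length(lines) < 2) return(FALSE)
  units <- csv_cells(lines[2])
  n <- length(units)
  if (n < 2 || n %% 2 != 0) return(FALSE)
  odd <- units[seq(1, n, by = 2)]
  all(tolower(trimws(odd)) == "ml")
}

#' Identify the vendor dialect of an export file
#'
#' Extension decides `.arw` (Waters/Empower-style); for `.csv`/`.txt` the
#' first-line sentinel wins: a `[Header]` section opener means Shimadzu
#' sectioned ASCII, a paired-column two-row header with `mL` unit cells
#' means AKTA/UNICORN, and otherwise a bare two-column numeric CSV is read
#' as the Agilent export.
#'
#' @param path file to sniff.
#' @param head_lines optionally, pre-read leading lines (used by tests).
#' @return one of `"waters-arw"`, `"shimadzu-ascii"`, `"agilent-csv"`,
#'   `"akta-csv"`.
#' @export
detect_dialect <- function(path, head_lines = NULL) {
  if (is.null(head_lines)) head_lines <- read_head_lines(path)
  head_lines <- head_lines[nzchar(trimws(head_lines))]
  if (!length(head_lines)) {
    stop("unsupported format: '", path, "' is empty")
  }
  ext <- tolower(tools::file_ext(path))
  first <- trimws(head_lines[1])
  if (identical(first, "[Header]")) return("shimadzu-ascii")
  if (is_akta_header(head_lines)) return("akta-csv")
  if (ext == "arw") return("waters-arw")
  cells <- csv_cells(head_lines[1])
  two_col <- length(cells) == 2
  if (two_col) {
    probe <- if (all(is_num(cells))) cells else
      if (length(head_lines) >= 2) csv_cells(head_lines[2]) else character()
    if (length(probe) == 2 && all(is_num(probe))) return("agilent-csv")
  }
  stop("unsupported format: cannot identify the dialect of '", path, "'")
}

#' Parse a Waters/Empower-style tab-delimited ASCII export
#'
#' Layout: two tab-delimited header rows (field names, then values;
#' `SampleName` and `Channel` required, `Flow Rate(mL/min)` and
#' `Instrument Method` optional), followed by two-column time/signal rows.
#' One file holds one (sample, channel) trace; times are minutes.
#'
#' @param path `.arw` file.
#' @return list with `table` (a [tidy_table()], one group), `meta`
#'   (a [run_meta()], `instrument_kind = "hplc"`), `fractions` (empty list).
#' @export
parse_waters_arw <- function(path) {
  lines <- read_all_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("parse error in '", path, "': missing header rows")
  fields <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  values <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  length(values) <- length(fields)
  hdr <- stats::setNames(as.list(trimws(gsub('^"|"$', "", values))),
                         trimws(gsub('^"|"$', "", fields)))
  absent <- setdiff(c("SampleName", "Channel"), names(hdr))
  absent <- c(absent, names(hdr)[names(hdr) %in% c("SampleName", "Channel") &
                                   !nzchar(unlist(hdr[names(hdr) %in%
                                                        c("SampleName", "Channel")]))])
  if (length(absent)) {
    stop("parse error in '", path, "': missing header field(s): ",
         paste(unique(absent), collapse = ", "))
  }
  flow <- if (!is.null(hdr[["Flow Rate(mL/min)"]]) &&
              nzchar(hdr[["Flow Rate(mL/min)"]]))
    as.numeric(hdr[["Flow Rate(mL/min)"]]) else NA_real_
  data_lines <- lines[-(1:2)]
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, function(p)
    length(p) != 2 || !all(is_num(p)), logical(1)))
  if (length(bad)) {
    stop("parse error in '", path, "': non-numeric data row at line ",
         bad[1] + 2L)
  }
  m <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  tab <- tidy_table(data.frame(
    experiment = "", sample = hdr$SampleName, channel = hdr$Channel,
    time_min = m[, 1], signal = m[, 2], stringsAsFactors = FALSE),
    x_unit = "time")
  meta <- run_meta(sample = hdr$SampleName, channel = hdr$Channel,
                   flow_rate = flow, instrument_kind = "hplc",
                   source_path = path, dialect = "waters-arw",
                   method = if (!is.null(hdr[["Instrument Method"]]))
                     hdr[["Instrument Method"]] else NA_character_)
  list(table = tab, meta = meta, fractions = list())
}

#' Parse a Shimadzu sectioned ASCII export
#'
#' Layout: a `[Header]` block carrying `Sample Name`, then one
#' `[LC Chromatogram(<channel>)]` block per detector channel with
#' `Interval(msec)` and `# of Points` followed by one signal value per line.
#' Times are reconstructed as index x interval, converted to minutes; the
#' record count of each block must equal its declared point count.
#'
#' @param path sectioned ASCII file.
#' @return unnamed list with one element per channel block, each a list of
#'   `table`, `meta`, `fractions` as in [parse_waters_arw()]; blocks share
#'   the sample name.
#' @export
parse_shimadzu_ascii <- function(path) {
  lines <- read_all_lines(path)
  sec_starts <- grep("^\\[.*\\]\\s*$", lines)
  if (!length(sec_starts) || trimws(lines[sec_starts[1]]) != "[Header]") {
    stop("parse error in '", path, "': no [Header] section")
  }
  sec_names <- trimws(lines[sec_starts])
  sec_end <- c(sec_starts[-1] - 1L, length(lines))
  get_field <- function(block, name) {
    hit <- grep(paste0("^", gsub("([().#])", "\\\\\\1", name), "\t"), block)
    if (!length(hit)) return(NA_character_)
    trimws(strsplit(block[hit[1]], "\t", fixed = TRUE)[[1]][2])
  }
  hdr_block <- lines[sec_starts[1]:sec_end[1]]
  sample <- get_field(hdr_block, "Sample Name")
  if (is.na(sample)) {
    stop("parse error in '", path, "': [Header] lacks Sample Name")
  }
  chrom_idx <- grep("^\\[LC Chromatogram\\(.*\\)\\]$", sec_names)
  out <- list()
  for (i in chrom_idx) {
    block <- lines[sec_starts[i]:sec_end[i]]
    channel <- sub("^\\[LC Chromatogram\\((.*)\\)\\]$", "\\1", sec_names[i])
    msec <- suppressWarnings(as.numeric(get_field(block, "Interval(msec)")))
    npts <- suppressWarnings(as.integer(get_field(block, "# of Points")))
    if (is.na(msec)) {
      stop("parse error in '", path, "': block '", sec_names[i],
           "' lacks Interval(msec)")
    }
    if (is.na(npts)) {
      stop("parse error in '", path, "': block '", sec_names[i],
           "' lacks # of Points")
    }
    body <- block[-1]
    body <- body[!grepl("\t", body, fixed = TRUE)]
    body <- trimws(body)
    body <- body[nzchar(body)]
    if (length(body) != npts) {
      stop("parse error in '", path, "': block '", sec_names[i],
           "' declares ", npts, " points but contains ", length(body))
    }
    sig <- suppressWarnings(as.numeric(body))
    if (anyNA(sig)) {
      stop("parse error in '", path, "': non-numeric signal value in '",
           sec_names[i], "'")
    }
    times <- (seq_len(npts) - 1L) * (msec / 60000)
    tab <- tidy_table(data.frame(
      experiment = character(npts), sample = rep(sample, npts),
      channel = rep(channel, npts), time_min = times, signal = sig,
      stringsAsFactors = FALSE), x_unit = "time")
    meta <- run_meta(sample = sample, channel = channel,
                     instrument_kind = "hplc", source_path = path,
                     dialect = "shimadzu-ascii")
    out[[length(out) + 1L]] <- list(table = tab, meta = meta,
                                    fractions = list())
  }
  out
}

#' Parse a bare Agilent two-column CSV export
#'
#' Layout: optional `Time,Signal` header line, then time,signal rows and
#' nothing else — no metadata block. The returned table carries placeholder
#' sample/channel names; channel and flow rate are `NA` and must be
#' completed with [resolve_metadata()].
#'
#' @param path two-column CSV.
#' @return list of `table`, `meta`, `fractions` as in [parse_waters_arw()].
#' @export
parse_agilent_csv <- function(path) {
  lines <- read_all_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && !any(is_num(csv_cells(lines[1])))) {
    lines <- lines[-1]                    # header line such as "Time,Signal"
  }
  if (!length(lines)) stop("parse error in '", path, "': no data rows")
  parts <- lapply(lines, csv_cells)
  wide <- which(vapply(parts, length, integer(1)) != 2)
  if (length(wide)) {
    stop("parse error in '", path, "': expected 2 columns, found ",
         length(parts[[wide[1]]]), " at data row ", wide[1])
  }
  bad <- which(!vapply(parts, function(p) all(is_num(p)), logical(1)))
  if (length(bad)) {
    stop("parse error in '", path, "': non-numeric cell at data row ", bad[1])
  }
  m <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  sample <- tools::file_path_sans_ext(basename(path))
  tab <- tidy_table(data.frame(
    experiment = "", sample = sample, channel = "unknown",
    time_min = m[, 1], signal = m[, 2], stringsAsFactors = FALSE),
    x_unit = "time")
  meta <- run_meta(sample = sample, channel = NA_character_,
                   instrument_kind = "hplc", source_path = path,
                   dialect = "agilent-csv")
  list(table = tab, meta = meta, fractions = list())
}

#' Parse an AKTA/UNICORN paired-column CSV export
#'
#' Layout: a two-row header — channel name over the first column of each
#' (volume mL, signal) pair, unit row `mL,<unit>` below — then the paired
#' data columns, optionally ending in a (volume, fraction-label) pair.
#' Channels may have different trace lengths (short pairs are padded with
#' empty cells). Fraction marks become labelled intervals: each label's
#' start is its marker volume, its end the next marker's volume, and the
#' last fraction closes at the trace end.
#'
#' @param path paired-column CSV.
#' @return list with `table` (multi-channel [tidy_table()], `x_unit`
#'   `"volume"`), `meta` (a [run_meta()] with `instrument_kind = "fplc"`,
#'   sample taken from the file name), and `fractions` (list of
#'   [fraction_record()]).
#' @export
parse_akta_csv <- function(path) {
  lines <- read_all_lines(path)
  if (length(lines) < 2 ||
      tolower(trimws(csv_cells(lines[2])[1])) != "ml") {
    stop("parse error in '", path, "': missing paired-column two-row header")
  }
  names_row <- csv_cells(lines[1])
  units_row <- csv_cells(lines[2])
  ncol_file <- length(units_row)
  if (ncol_file %% 2 != 0) {
    stop("parse error in '", path, "': odd column count (", ncol_file,
         "); columns must come in (volume, value) pairs")
  }
  length(names_row) <- ncol_file
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  cells <- lapply(body, function(l) {
    v <- csv_cells(l)
    length(v) <- ncol_file
    v
  })
  grid <- if (length(cells)) do.call(rbind, cells) else
    matrix(character(0), ncol = ncol_file)
  grid[is.na(grid)] <- ""
  sample <- tools::file_path_sans_ext(basename(path))
  groups <- list()
  fractions <- list()
  trace_end <- -Inf
  for (p in seq(1, ncol_file, by = 2)) {
    cname <- trimws(names_row[p])
    if (is.na(cname) || !nzchar(cname)) {
      stop("parse error in '", path, "': pair at column ", p,
           " lacks a channel name")
    }
    xs_raw <- trimws(grid[, p])
    vs_raw <- trimws(grid[, p + 1])
    keep <- nzchar(xs_raw)
    xs_raw <- xs_raw[keep]; vs_raw <- vs_raw[keep]
    if (!all(is_num(xs_raw))) {
      stop("parse error in '", path, "': non-numeric volume in pair '",
           cname, "'")
    }
    xs <- as.numeric(xs_raw)
    if (is.unsorted(xs, strictly = TRUE)) {
      stop("validation error in '", path, "': volumes non-monotone in pair '",
           cname, "'")
    }
    if (identical(cname, "Fraction")) {
      fractions <- Map(function(lab, v) list(label = lab, start = v),
                       vs_raw, xs)
      next
    }
    if (!all(is_num(vs_raw))) {
      stop("parse error in '", path, "': non-numeric signal in pair '",
           cname, "'")
    }
    trace_end <- max(trace_end, xs[length(xs)])
    groups[[cname]] <- data.frame(
      experiment = "", sample = sample, channel = cname,
      volume_mL = xs, signal = as.numeric(vs_raw), stringsAsFactors = FALSE)
  }
  if (!length(groups)) {
    stop("parse error in '", path, "': no signal column pairs found")
  }
  frecs <- list()
  if (length(fractions)) {
    starts <- vapply(fractions, function(f) f$start, numeric(1))
    labs <- vapply(fractions, function(f) f$label, character(1))
    ends <- c(starts[-1], trace_end)
    keep <- ends > starts
    frecs <- Map(fraction_record, labs[keep], starts[keep], ends[keep])
    names(frecs) <- NULL
  }
  tab <- tidy_table(do.call(rbind, groups), x_unit = "volume")
  meta <- run_meta(sample = sample, channel = NA_character_,
                   instrument_kind = "fplc", source_path = path,
                   dialect = "akta-csv")
  list(table = tab, meta = meta, fractions = frecs)
}

#' Metadata sources with a fixed precedence chain
#'
#' What the file itself carries always wins; after that, per-file overrides,
#' then batch-wide overrides, then the persisted defaults database (a YAML
#' file keyed by instrument method name or dialect id).
#'
#' @param per_file named list: file path -> list of overrides
#'   (`flow_rate`, `channel`, `sample`).
#' @param batch list of overrides applied to every file.
#' @param defaults_db path to a defaults YAML
#'   (`<key>: {flow_rate: <mL/min>, channel: <name>}`) or an equivalent
#'   named list; `NULL` for none.
#' @export
meta_sources <- function(per_file = list(), batch = list(),
                         defaults_db = NULL) {
  db <- defaults_db
  if (is.character(db)) {
    db <- if (file.exists(db)) yaml::read_yaml(db) else list()
  }
  if (is.null(db)) db <- list()
  structure(list(per_file = per_file, batch = batch, defaults_db = db),
            class = "meta_sources")
}

#' Default location of the persisted defaults database
#'
#' A per-user YAML config file; set once, used by every later run.
#' @export
default_db_path <- function() {
  file.path(tools::R_user_dir("tidychrom", "config"), "defaults.yaml")
}

#' Complete run metadata through the precedence chain
#'
#' Every absent (`NA`) field is filled from the highest-precedence source
#' that provides it: file content, then per-file override, then batch
#' override, then the defaults database (looked up by instrument method
#' name, then by dialect id). If a required field is still absent, the
#' prompt callback is invoked when `interactive`, otherwise a hard error is
#' raised — an analytic (HPLC) run cannot enter the pipeline without a flow
#' rate and a channel name.
#'
#' @param meta a [run_meta()] as returned by a parser.
#' @param sources a [meta_sources()].
#' @param interactive whether missing required fields may be prompted for.
#' @param prompt callback `function(field, meta) -> value`, injected so
#'   that nothing in the package reads a terminal directly.
#' @return the completed [run_meta()].
#' @export
resolve_metadata <- function(meta, sources = meta_sources(),
                             interactive = FALSE, prompt = NULL) {
  stopifnot(inherits(meta, "run_meta"), inherits(sources, "meta_sources"))
  lookup_db <- function(field) {
    for (key in c(meta$method, meta$dialect)) {
      if (!is.na(key) && !is.null(sources$defaults_db[[key]][[field]])) {
        return(sources$defaults_db[[key]][[field]])
      }
    }
    NULL
  }
  fill <- function(field) {
    val <- meta[[field]]
    if (!is.na(val)) return(val)
    pf <- if (!is.na(meta$source_path))
      sources$per_file[[meta$source_path]][[field]] else NULL
    for (cand in list(pf, sources$batch[[field]], lookup_db(field))) {
      if (!is.null(cand) && !is.na(cand)) return(cand)
    }
    NA
  }
  meta$flow_rate <- as.numeric(fill("flow_rate"))
  ch <- fill("channel")
  meta$channel <- if (is.null(ch)) NA_character_ else as.character(ch)
  if (meta$instrument_kind == "hplc") {
    if (is.na(meta$flow_rate)) {
      if (interactive && is.function(prompt)) {
        meta$flow_rate <- as.numeric(prompt("flow_rate", meta))
      }
      if (is.na(meta$flow_rate)) {
        stop("flow rate required for '", meta$source_path,
             "' and no source provides it")
      }
    }
    if (is.na(meta$channel)) {
      if (interactive && is.function(prompt)) {
        meta$channel <- as.character(prompt("channel", meta))
      }
      if (is.na(meta$channel)) {
        stop("channel name required for '", meta$source_path,
             "' and no source provides it")
      }
    }
  }
  if (!is.na(meta$flow_rate) && meta$flow_rate <= 0) {
    stop("resolved flow rate must be > 0 (got ", meta$flow_rate, ")")
  }
  meta
}

#' Detect and parse any supported export file
#'
#' Convenience front door used by the pipeline: sniffs the dialect with
#' [detect_dialect()] and dispatches to the matching parser.
#'
#' @param path export file.
#' @return unnamed list of parsed runs, each `list(table, meta, fractions)`
#'   (Shimadzu files yield one element per channel block).
#' @export
parse_chromatogram <- function(path) {
  dialect <- detect_dialect(path)
  switch(dialect,
    "waters-arw" = list(parse_waters_arw(path)),
    "shimadzu-ascii" = parse_shimadzu_ascii(path),
    "agilent-csv" = list(parse_agilent_csv(path)),
    "akta-csv" = list(parse_akta_csv(path)))
}
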