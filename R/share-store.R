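SCHEMA_VERSION <- 1L

#' Shareable view state
#'
#' The state a share link carries: which experiments are on screen, the
#' x-axis zoom, and the normalization interval. Encoded in the URL path and
#' query string so a link reproduces not just the experiment list but the
#' exact region under inspection.
#'
#' @param experiment_ids ordered character vector of experiment ids, each
#'   free of the reserved characters `+ ? & =`.
#' @param view_range,norm_range optional length-2 numeric `(start, end)`
#'   intervals in x units, `start < end`, non-negative.
#' @export
view_state <- function(experiment_ids, view_range = NULL, norm_range = NULL) {
  if (!length(experiment_ids)) stop("view_state: need at least one id")
  for (id in experiment_ids) validate_experiment_id(id)
  chk <- function(r, what) {
    if (is.null(r)) return(NULL)
    r <- as.numeric(r)
    if (length(r) != 2 || !all(is.finite(r)) || r[1] >= r[2] || r[1] < 0) {
      stop("view_state: ", what,
           " must be a non-negative (start, end) with start < end")
    }
    r
  }
  structure(list(experiment_ids = as.character(experiment_ids),
                 view_range = chk(view_range, "view_range"),
                 norm_range = chk(norm_range, "norm_range")),
            class = "view_state")
}

fmt_range <- function(r) paste0(fmt_repr(r[1]), "-", fmt_repr(r[2]))

#' Encode / decode the URL share-state
#'
#' The path segment is the experiment ids joined with `"+"`; the query
#' string carries `view-range=<start>-<end>` and `norm-range=<start>-<end>`
#' when set, numbers rendered with minimal round-trip decimals. So
#' `encode_state(view_state(c("HPLC_Example_1", "HPLC_Example_2"),
#' view_range = c(1.93, 2.13)))` is
#' `"HPLC_Example_1+HPLC_Example_2?view-range=1.93-2.13"`. `decode_state`
#' is the exact inverse and ignores unknown query keys.
#'
#' @param state a [view_state()].
#' @return `encode_state`: the path+query fragment; `decode_state`: the
#'   [view_state()].
#' @export
encode_state <- function(state) {
  stopifnot(inherits(state, "view_state"))
  path <- paste(state$experiment_ids, collapse = "+")
  q <- character()
  if (!is.null(state$view_range)) {
    q <- c(q, paste0("view-range=", fmt_range(state$view_range)))
  }
  if (!is.null(state$norm_range)) {
    q <- c(q, paste0("norm-range=", fmt_range(state$norm_range)))
  }
  if (length(q)) paste0(path, "?", paste(q, collapse = "&")) else path
}

parse_range_value <- function(v, key) {
  m <- regmatches(v, regexec("^([0-9]+\\.?[0-9]*)-([0-9]+\\.?[0-9]*)$", v))[[1]]
  if (length(m) != 3) {
    stop("decode_state: malformed ", key, " '", v,
         "': expected <start>-<end> with plain non-negative numbers")
  }
  r <- as.numeric(m[2:3])
  if (r[1] >= r[2]) {
    stop("decode_state: malformed ", key, " '", v, "': start >= end")
  }
  r
}

#' @rdname encode_state
#' @param url_fragment a path+query fragment as produced by [encode_state()]
#'   (a full URL's leading `scheme://host/` part is tolerated and stripped).
#' @export
decode_state <- function(url_fragment) {
  stopifnot(is.character(url_fragment), length(url_fragment) == 1)
  frag <- sub("^[a-zA-Z][a-zA-Z0-9+.-]*://[^/]*/", "", url_fragment)
  parts <- strsplit(frag, "?", fixed = TRUE)[[1]]
  ids <- strsplit(parts[1], "+", fixed = TRUE)[[1]]
  if (!length(ids) || any(!nzchar(ids))) {
    stop("decode_state: empty experiment id in '", url_fragment, "'")
  }
  view <- NULL; norm <- NULL
  if (length(parts) > 1 && nzchar(parts[2])) {
    for (kv in strsplit(parts[2], "&", fixed = TRUE)[[1]]) {
      eq <- regmatches(kv, regexpr("=", kv, fixed = TRUE))
      pieces <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(pieces) != 2) next
      if (pieces[1] == "view-range") {
        view <- parse_range_value(pieces[2], "view-range")
      } else if (pieces[1] == "norm-range") {
        norm <- parse_range_value(pieces[2], "norm-range")
      }                                   # unknown keys ignored
    }
  }
  view_state(ids, view_range = view, norm_range = norm)
}

num_or_na <- function(v) {
  vapply(v, function(x) if (is.null(x)) NA_real_ else as.numeric(x),
         numeric(1), USE.NAMES = FALSE)
}

chr_col <- function(v) {
  vapply(v, function(x) if (is.null(x)) NA_character_ else as.character(x),
         character(1), USE.NAMES = FALSE)
}

table_to_payload <- function(tab) {
  list(experiment = tab$experiment, sample = tab$sample,
       channel = tab$channel, time_min = tab$time_min,
       volume_mL = tab$volume_mL, signal = tab$signal,
       signal_norm = tab$signal_norm)
}

payload_to_table <- function(p, x_unit) {
  df <- data.frame(experiment = chr_col(p$experiment),
                   sample = chr_col(p$sample),
                   channel = chr_col(p$channel),
                   time_min = num_or_na(p$time_min),
                   volume_mL = num_or_na(p$volume_mL),
                   signal = num_or_na(p$signal),
                   signal_norm = num_or_na(p$signal_norm),
                   stringsAsFactors = FALSE)
  tidy_table(df, x_unit = x_unit)
}

#' Serialize an experiment to / from a versioned document
#'
#' The document is the storage and exchange form of an [experiment()]:
#' column-oriented arrays per field (compact, and invisible through the
#' round-trip contract), a schema version, and a provenance block. The two
#' functions are mutually inverse; signal arrays survive bit-identically.
#'
#' @param e an [experiment()].
#' @param provenance optional list recorded verbatim (source files,
#'   processing options).
#' @export
experiment_to_document <- function(e, provenance = list()) {
  stopifnot(inherits(e, "chrom_experiment"))
  list(doc_id = e$id,
       schema_version = SCHEMA_VERSION,
       version = e$version,
       analytic = table_to_payload(e$analytic),
       preparative = table_to_payload(e$preparative),
       fractions = lapply(e$fractions, unclass),
       provenance = provenance)
}

#' @rdname experiment_to_document
#' @param d a document as produced by [experiment_to_document()] (or read
#'   back from a store).
#' @export
document_to_experiment <- function(d) {
  if (is.null(d$schema_version) || d$schema_version != SCHEMA_VERSION) {
    stop("unknown document schema_version '", d$schema_version,
         "' (this build reads version ", SCHEMA_VERSION, ")")
  }
  fr <- lapply(d$fractions, function(f)
    fraction_record(f$label, f$start, f$end))
  id <- d$doc_id
  if (grepl("+", id, fixed = TRUE)) attr(id, "combined") <- TRUE
  experiment(id,
             analytic = payload_to_table(d$analytic, "time"),
             preparative = payload_to_table(d$preparative, "volume"),
             fractions = fr,
             version = if (is.null(d$version)) 1L else d$version)
}

document_json <- function(doc) {
  # I(17) significant digits: full float round-trip precision
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), null = "null",
                   na = "null", pretty = TRUE)
}

#' Filesystem-backed experiment document store
#'
#' One pretty-printed canonical JSON file per document, named
#' `<doc_id>.json`, in a store directory. `store_put` is an upsert keyed by
#' `doc_id`; `store_get` raises a not-found error for absent ids;
#' `store_list` returns the ids matching a prefix, sorted. A remote
#' document-database backend could implement the same put/get/list
#' contract.
#'
#' @param doc a document from [experiment_to_document()].
#' @param dir store directory (created on first put).
#' @export
store_put <- function(doc, dir) {
  stopifnot(is.list(doc), !is.null(doc$doc_id))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0(doc$doc_id, ".json"))
  writeLines(document_json(doc), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname store_put
#' @param id document id.
#' @export
store_get <- function(id, dir) {
  path <- file.path(dir, paste0(id, ".json"))
  if (!file.exists(path)) {
    stop("store_get: document '", id, "' not found in '", dir, "'")
  }
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}

#' @rdname store_put
#' @param prefix id prefix filter; `""` lists everything.
#' @export
store_list <- function(dir, prefix = "") {
  if (!dir.exists(dir)) return(character())
  ids <- sub("\\.json$", "", list.files(dir, pattern = "\\.json$"))
  sort(ids[startsWith(ids, prefix)])
}
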