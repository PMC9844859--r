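# Stable palette keyed by sorted labels, so the same fixture always renders
# with the same colors.
trace_palette <- function(labels) {
  labels <- sort(unique(labels))
  stats::setNames(grDevices::hcl.colors(max(length(labels), 2L), "Dark 3")
                  [seq_along(labels)], labels)
}

fill_palette <- function(n) grDevices::hcl.colors(max(n, 2L), "Set 2")[seq_len(n)]

open_device <- function(out_path, out_format, width, height) {
  switch(out_format,
         svg = grDevices::svg(out_path, width = width, height = height),
         png = grDevices::png(out_path, width = width * 96,
                              height = height * 96, res = 96),
         stop("unsupported output format '", out_format, "'"))
}

# Cairo stamps per-process counters into SVG ids; strip them so identical
# input renders byte-identical files.
sanitize_svg <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- gsub('id="surface[0-9]+"', 'id="surface0"', txt)
  txt <- gsub('#surface[0-9]+', "#surface0", txt)
  writeLines(txt, path, useBytes = TRUE)
  path
}

panel_trace_plot <- function(tab, value, channel, palette, x_unit,
                             view_range = NULL, ylab) {
  ct <- tab[tab$channel == channel, , drop = FALSE]
  xs <- if (x_unit == "volume") ct$volume_mL else ct$time_min
  xlim <- if (!is.null(view_range)) view_range else range(xs)
  keep <- xs >= xlim[1] & xs <= xlim[2]
  ylim <- range(ct[[value]][keep], na.rm = TRUE)
  graphics::plot(NA, xlim = xlim, ylim = ylim,
                 xlab = if (x_unit == "volume") "Volume (mL)" else
                   "Time (min)",
                 ylab = ylab, main = channel, bty = "l")
  for (s in sort(unique(ct$sample))) {
    g <- ct[ct$sample == s, , drop = FALSE]
    gx <- if (x_unit == "volume") g$volume_mL else g$time_min
    graphics::lines(gx, g[[value]], col = palette[[s]], lwd = 1.5)
  }
  invisible(NULL)
}

add_legend <- function(palette) {
  graphics::legend("topright", legend = names(palette),
                   col = unname(palette), lwd = 1.5, bty = "n", cex = 0.8)
}

#' Plot the analytic traces of an experiment
#'
#' One panel per detector channel, one line per injection, colored by
#' injection name with a stable palette. When `normalized`, the
#' `signal_norm` panels are drawn alongside a parallel set of raw-signal
#' panels (panel count doubles).
#'
#' @param experiment an [experiment()] with a non-empty analytic table.
#' @param out_path output file.
#' @param normalized plot `signal_norm` next to the raw panels (the table
#'   must have been through [normalize_range()]).
#' @param view_range optional x interval cropping the axis (zoom only; it
#'   never re-normalizes).
#' @param out_format `"svg"` (deterministic output) or `"png"`.
#' @param overlay_preparative also draw the experiment's preparative
#'   trace(s) of a matching channel, rescaled, over the analytic panels.
#' @return `out_path`, invisibly.
#' @export
plot_analytic <- function(experiment, out_path, normalized = FALSE,
                          view_range = NULL,
                          out_format = c("svg", "png"),
                          overlay_preparative = FALSE) {
  stopifnot(inherits(experiment, "chrom_experiment"))
  out_format <- match.arg(out_format)
  tab <- experiment$analytic
  if (!nrow(tab)) stop("plot_analytic: experiment '", experiment$id,
                       "' has no analytic traces")
  if (normalized && all(is.na(tab$signal_norm))) {
    stop("plot_analytic: normalized view requested but signal_norm is empty")
  }
  channels <- sort(unique(tab$channel))
  values <- if (normalized) c("signal", "signal_norm") else "signal"
  n_panels <- length(channels) * length(values)
  palette <- trace_palette(tab$sample)
  open_device(out_path, out_format, width = 7, height = 2.6 * n_panels)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(n_panels, 1), mar = c(4, 4, 2, 1))
  for (value in values) {
    ylab <- if (value == "signal") "Signal" else "Normalized signal"
    for (ch in channels) {
      panel_trace_plot(tab, value, ch, palette, "time", view_range, ylab)
      if (overlay_preparative && nrow(experiment$preparative) &&
          value == "signal" &&
          ch %in% experiment$preparative$channel) {
        pt <- experiment$preparative[experiment$preparative$channel == ch, ]
        sc <- max(tab$signal[tab$channel == ch], na.rm = TRUE) /
          max(pt$signal, na.rm = TRUE)
        # rescale the volume axis onto the analytic panel's x range
        xr <- graphics::par("usr")[1:2]
        vx <- xr[1] + (pt$volume_mL - min(pt$volume_mL)) /
          diff(range(pt$volume_mL)) * diff(xr)
        graphics::lines(vx, pt$signal * sc, col = "grey40", lty = 2)
      }
      add_legend(palette)
    }
  }
  grDevices::dev.off()
  on.exit()
  if (out_format == "svg") sanitize_svg(out_path)
  invisible(out_path)
}

#' Plot the preparative traces of an experiment
#'
#' The overall volume-axis trace per channel, with each collected fraction
#' highlighted as a distinctly colored fill under the curve and labeled at
#' its midpoint.
#'
#' @inheritParams plot_analytic
#' @export
plot_preparative <- function(experiment, out_path, normalized = FALSE,
                             view_range = NULL,
                             out_format = c("svg", "png")) {
  stopifnot(inherits(experiment, "chrom_experiment"))
  out_format <- match.arg(out_format)
  tab <- experiment$preparative
  if (!nrow(tab)) stop("plot_preparative: experiment '", experiment$id,
                       "' has no preparative traces")
  value <- if (normalized) "signal_norm" else "signal"
  if (normalized && all(is.na(tab$signal_norm))) {
    stop("plot_preparative: normalized view requested but signal_norm is empty")
  }
  channels <- sort(unique(tab$channel))
  palette <- trace_palette(tab$sample)
  fills <- fill_palette(length(experiment$fractions))
  open_device(out_path, out_format, width = 7,
              height = 2.8 * length(channels))
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(length(channels), 1), mar = c(4, 4, 2, 1))
  for (ch in channels) {
    panel_trace_plot(tab, value, ch, palette, "volume", view_range,
                     if (normalized) "Normalized signal" else "Signal")
    for (k in seq_along(experiment$fractions)) {
      f <- experiment$fractions[[k]]
      for (s in unique(tab$sample)) {
        g <- tab[tab$sample == s & tab$channel == ch, , drop = FALSE]
        sel <- g$volume_mL >= f$start & g$volume_mL <= f$end
        if (sum(sel) < 2) next
        graphics::polygon(c(g$volume_mL[sel], rev(range(g$volume_mL[sel]))),
                          c(g[[value]][sel], 0, 0),
                          col = grDevices::adjustcolor(fills[k], 0.5),
                          border = NA)
      }
      graphics::mtext(f$label, side = 1, at = (f$start + f$end) / 2,
                      line = -1.2, cex = 0.6)
    }
    add_legend(palette)
  }
  grDevices::dev.off()
  on.exit()
  if (out_format == "svg") sanitize_svg(out_path)
  invisible(out_path)
}

#' Plot several experiments together
#'
#' Combines the experiments with [combine_experiments()] — so lines are
#' labeled `"<experiment>: <sample>"` and fraction fills are omitted — then
#' renders the analytic and/or preparative view as available.
#'
#' @param experiments list of >= 2 [experiment()]s.
#' @param out_path output file; with both analytic and preparative content,
#'   `_analytic` / `_preparative` suffixes are inserted before the
#'   extension.
#' @inheritParams plot_analytic
#' @return character vector of written paths, invisibly.
#' @export
plot_combined <- function(experiments, out_path, normalized = FALSE,
                          view_range = NULL, out_format = c("svg", "png")) {
  out_format <- match.arg(out_format)
  combined <- combine_experiments(experiments)
  has_an <- nrow(combined$analytic) > 0
  has_pr <- nrow(combined$preparative) > 0
  out <- character()
  suffixed <- function(sfx) {
    if (has_an && has_pr) {
      sub("(\\.[a-zA-Z]+)$", paste0("_", sfx, "\\1"), out_path)
    } else out_path
  }
  if (has_an) {
    out <- c(out, plot_analytic(combined, suffixed("analytic"),
                                normalized = normalized,
                                view_range = view_range,
                                out_format = out_format))
  }
  if (has_pr) {
    out <- c(out, plot_preparative(combined, suffixed("preparative"),
                                   normalized = normalized,
                                   view_range = view_range,
                                   out_format = out_format))
  }
  invisible(out)
}
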