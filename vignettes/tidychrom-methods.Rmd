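---
title: "tidychrom: data model, transforms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tidychrom: data model, transforms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidychrom)
```

## The tidy data model

A chromatogram is an ordered series of (x, signal) readings per *trace* —
one (injection, detector channel) pair. `tidychrom` stores everything in a
single long-form table (`tidy_table`) where one row is one observation:

| column        | meaning                                   | unit     |
|---------------|-------------------------------------------|----------|
| `experiment`  | experiment name                           | —        |
| `sample`      | injection name                            | —        |
| `channel`     | detector channel (e.g. `280nm`, `GFP`)    | —        |
| `time_min`    | retention time                            | minutes  |
| `volume_mL`   | elution volume                            | mL       |
| `signal`      | raw detector reading                      | mAU / AU |
| `signal_norm` | range-normalized signal, when computed    | unitless |

Minutes and millilitres are the internal units throughout, the conventional
choice for analytical HPLC and lab-scale FPLC. An `x_unit` attribute says
which axis is primary: analytic (HPLC) runs are acquired over time and gain
volume via `add_volume()` (`v = t · F`); preparative (FPLC) runs are
recorded over volume directly. Rows are kept in a canonical order
(group-major, x ascending, radix/C-locale collation), which makes
construction insensitive to input row order and keeps all downstream output
deterministic.

The wide form (`tidy_to_wide()`) carries the x column first and one column
per trace. Since a wide header must hold both the injection and the channel,
the convention `"<sample> | <channel>"` is used with `" | "` reserved:
names containing the separator are rejected at ingest, which is what makes
`wide_to_tidy()` an exact inverse. Grids from different channels are
united by x value (channels may be sampled at different rates); cells where
a trace has no reading are `NA` in memory and the empty string in CSV. Grid
x values are matched after rounding to 9 decimals — enough to absorb float
noise from text parsing while never merging real sampling points — and the
stored values are left untouched. The wide table carries one value column
per trace (`signal` by default, `signal_norm` on request), so the
tidy→wide→tidy round trip is exact for tables whose value content is the
raw signal; derived columns are a property of the tidy form.

## Vendor dialects

No vendor publishes a normative spec for its text exports, so the package
defines one canonical layout per vendor family, modeled on the shapes users
actually see, and requires *emitter↔parser agreement*: the fixture
generator writes each dialect and the parsers must reproduce the simulated
experiment, signal values bit-identical and metadata exact. The layouts:

- **waters-arw** (`.arw`): two tab-delimited header rows (field names, then
  values; `SampleName` and `Channel` required, `Flow Rate(mL/min)` and
  `Instrument Method` optional), then two-column time/signal rows. One
  trace per file.
- **shimadzu-ascii**: a `[Header]` block with `Sample Name`, then one
  `[LC Chromatogram(<channel>)]` block per channel with `Interval(msec)`
  and `# of Points` followed by bare signal values. Times are reconstructed
  as `index × interval`; a declared/actual point-count mismatch is a parse
  error. Multi-detector blocks are treated as channels of one sample, not
  separate samples — the natural reading for simultaneous acquisition.
  Because times are reconstructed from an msec field, the round-trip
  contract for this dialect compares times at 1e−9 while signals remain
  bit-identical.
- **agilent-csv**: a bare two-column CSV (optional `Time,Signal` header
  line). It carries no metadata, so the parser returns placeholder
  sample/channel and the caller must complete them via `resolve_metadata()`.
- **akta-csv**: paired (volume, value) columns under a two-row header
  (channel name over each pair, `mL,<unit>` beneath), optionally ending in
  a (volume, fraction-label) pair. Channels may have different lengths;
  short pairs are padded with empty cells.

Dialect detection is extension-first (`.arw`), then first-line sentinels
(`[Header]` → Shimadzu; a units row whose volume cells are all `mL` → AKTA;
otherwise two numeric columns → Agilent), with sentinels beating the
extension for `.csv`/`.txt` — so an AKTA export renamed `.csv` still
resolves correctly.

Fraction marks become labeled intervals: each label starts at its marker
volume and ends at the next marker, half-open `[start, end)`, with the last
fraction closed at the trace end. This partitions the eluate without
overlap or gaps.

Numbers in emitted files use a shortest-round-trip decimal formatter (the
fewest significant digits, 15–17, whose re-parse is bit-identical), so
fixtures are both readable and exact.

## Metadata resolution

The minimum information an analytic run needs is the flow rate and the
channel name. Some dialects carry them; for the rest, `resolve_metadata()`
fills absent fields through a fixed precedence chain: file content →
per-file override → batch override → persisted defaults database (a YAML
file keyed by instrument method name, then dialect id, living in the
per-user config directory). Interactive prompting is injected as a callback
rather than read from a terminal, so scripts and tests can supply answers;
non-interactively, an unresolvable flow rate is a hard error rather than a
silently volume-less table.

## Transforms

**Scaling** multiplies raw signal by a batch factor (> 0) at processing
time, before any normalization; normalized output is invariant to it, so
the order is observable only in the raw column.

**Range normalization** works per trace, independently: with *M* the
maximum signal at x inside the selected interval, every point of the whole
trace — not just the in-range part — maps to `s / M`, so out-of-range
values may exceed 1. With `zero_min`, the in-range minimum *m* is also
pinned: `s ↦ (s − m)/(M − m)`, a simple baseline correction. The in-range
minimum (not the whole-trace minimum) is used for symmetry with the
maximum rule. Results go to `signal_norm`; the raw column is never
modified, so raw and normalized views can be shown side by side. Degenerate
traces — no points in range, flat in range with `zero_min`, or a
non-positive range maximum in max-only mode — raise named errors rather
than emitting NaN/Inf, which would silently poison every downstream plot
and document.

**Classification** is a two-clause rule: FPLC origin or a non-empty
fraction list means preparative; everything else is analytic. Assembly
merges runs into one experiment, disambiguating duplicate injection names
that arrive from *different* files with numeric suffixes (`A`, `A (2)`);
files that contribute only new channels of an already-seen sample are
recognized as per-channel exports of the same injection and keep the
shared name. Combination joins experiment ids with `+` (the share-URL
form), relabels every injection `"<experiment>: <sample>"`, and drops
fraction fills, since a combined preparative view is an overview, not a
collection record.

**Peak height** is the window maximum (normalized values preferred when
present); with traces normalized to an unbound reference peak,
`percent_bound(h_b, h_u) = 100 · h_b / (h_b + h_u)` turns two peak heights
into a heuristic bound fraction — an unbound peak four times the bound one
reads as 20 %.

## The synthetic generator

`sim_spec()` describes a trace as `baseline + drift·x + Σ peaks + noise`.
Peaks are phenomenological: a Gaussian `h·exp(−(x−c)²/2σ²)`, or, for
tailing peaks, the exponentially modified Gaussian evaluated in the
numerically stable scaled-complementary-error-function form
`h·(σ/τ)·√(π/2)·erfcx(z)·exp(−(x−c)²/2σ²)`, `z = (σ/τ − (x−c)/σ)/√2`,
which avoids the overflow of the naive `exp(·)·erfc(·)` product; `h` is
the Gaussian-limit amplitude, and `τ < σ·10⁻⁶` falls back to the pure
Gaussian outright. Noise is i.i.d. Gaussian from a named seed; seeds are
derived per trace from the master seed and recorded in the ground-truth
sidecar, so every fixture is exactly reproducible and stays inside 32-bit
integer range.

Default fixture conditions emulate a short analytic SEC run: 3 min at
0.3 s sampling (601 points), 1–3 peaks per trace with heights 100–800
signal units over a 0–5 unit baseline, noise σ = 1, flow rate 0.5 mL/min —
typical of analytical SEC columns; preparative fixtures run over 24 mL with
1 mL fraction marks covering the main peak. Tests use the same generator at
smaller grids (tens of points) to keep the suite fast; grid size changes
nothing but resolution. What the generator does *not* emulate: real column
physics (no plate theory, no van Deemter broadening), detector saturation,
baseline artifacts beyond linear drift, or vendor file corruption — so
passing round trips certify the data plumbing exactly, but say nothing
about how gracefully truly malformed vendor files fail.

## Plots, documents, share links

Static plots use base graphics: one row per channel, one line per
injection, a stable palette keyed by sorted labels so re-renders are
reproducible; normalized views double the panel set (raw alongside
normalized); preparative fractions are drawn as translucent fills under the
trace with midpoint labels. SVG output has the renderer's per-process
surface counters stripped, making byte-identical golden-file comparison
possible. Zooming (`view_range`) only crops the axis; it never
re-normalizes — normalization is an explicit, separate input.

Documents are column-oriented JSON (arrays per field) with a schema
version checked on read; the filesystem store keeps one pretty-printed
file per id with 17-significant-digit numbers, so a get→put cycle is
byte-identical. Share state encodes as
`<id1>+<id2>?view-range=<a>-<b>&norm-range=<a>-<b>`; experiment ids
therefore may not contain `+ ? & =`, ranges are non-negative plain
decimals (the `<a>-<b>` form would be ambiguous for negatives), and the
codec is exactly invertible. `norm-range` is this package's parallel to
`view-range`; unknown query keys are ignored for forward compatibility.

## Command-line pipeline

`run_process()` chains detect → parse → resolve → volume/scale → classify →
assemble → normalize → CSV → plots → store, and the `exec/tidychrom`
script exposes it as `process`, plus `fixture`, `plot` and `db` verbs.
When an experiment mixes analytic and preparative content, a `--normalize`
range (given in minutes, the analytic axis) is applied to the analytic
table; a purely preparative experiment is normalized over volume. Option
validation (e.g. `--scale > 0`) happens before any file is opened. A YAML
config can pre-populate any option; flags win.

## Known limitations

- Text exports only; proprietary binary formats (Empower projects, `.ch`,
  UNICORN result archives) are out of scope.
- Single signal per channel per x — no 2D photodiode-array spectra.
- No peak detection, integration, deconvolution or baseline fitting beyond
  the min→0 option; peak queries are window maxima.
- The dialect layouts are canonical reconstructions, not byte-level clones
  of any particular instrument software version; real exports that deviate
  from them will need a thin pre-cleaning step.
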