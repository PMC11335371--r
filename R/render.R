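# Renderer: one self-contained HTML file (embedded JSON payload + a small
# hand-written SVG viewer), plus a static SVG exporter for figures. The
# renderer never alters numbers: pA values reach the payload at full
# precision, and re-rendering the same layout with the same build stamp is
# byte-identical.

glyph_payload <- function(g) {
  list(read_id = g$read_id, strand = g$strand,
       x = g$points$x, y = g$points$y,
       base_pos = g$points$base_pos,
       gaps = if (nrow(g$gap_spans) > 0L)
         list(x0 = g$gap_spans$x0, x1 = g$gap_spans$x1,
              label = g$gap_spans$label, skip = g$gap_spans$skip)
       else NULL,
       insertions = lapply(g$insertion_markers, function(m)
         list(x = m$x, values = m$values)))
}

layout_payload <- function(layout, stamp) {
  tracks <- lapply(layout$tracks, function(tr) {
    out <- list(kind = tr$kind, strand = tr$strand)
    if (!is.null(tr$glyphs))
      out$reads <- unname(lapply(tr$glyphs, glyph_payload))
    if (!is.null(tr$intervals))
      out$intervals <- list(start = tr$intervals$start,
                            end = tr$intervals$end,
                            label = tr$intervals$label,
                            color = tr$intervals$color)
    out
  })
  list(stamp = stamp,
       region = list(ref_name = layout$region$ref_name,
                     start = layout$region$start, end = layout$region$end),
       base_width = layout$base_width, width = layout$width,
       columns = list(pos = layout$columns$pos, x0 = layout$columns$x0,
                      x1 = layout$columns$x1, base = layout$columns$base),
       selected = layout$selected,
       tracks = tracks)
}

#' Render a pileup layout as an interactive HTML browser view
#'
#' Produces a single self-contained file: the layout is embedded as one
#' JSON payload and drawn by an inline SVG viewer offering pan/zoom along
#' the reference axis, per-read select/deselect checkboxes driving overlay
#' membership, and a "show signal points" toggle revealing insertion
#' markers. Base columns are colour-coded (colour-blind-safe palette
#' available via `palette = "cb"`).
#'
#' @param layout a `pileup_layout`.
#' @param out_path output HTML file.
#' @param stamp build stamp written into the file; fixing it makes
#'   re-rendering byte-identical.
#' @param palette "default" or "cb" (colour-blind safe).
#' @return `out_path`, invisibly.
#' @export
render_html <- function(layout, out_path, stamp = paste("sigpile", SIGPILE_VERSION),
                        palette = c("default", "cb")) {
  stopifnot(inherits(layout, "pileup_layout"))
  palette <- match.arg(palette)
  pal <- if (palette == "cb") BASE_COLORS_CB else BASE_COLORS
  payload <- jsonlite::toJSON(layout_payload(layout, stamp),
                              auto_unbox = TRUE, digits = NA, null = "null")
  colors <- jsonlite::toJSON(as.list(pal), auto_unbox = TRUE)
  n_reads <- sum(vapply(layout$tracks, function(tr)
    if (!is.null(tr$glyphs)) length(tr$glyphs) else 0L, 0L))
  empty_msg <- if (n_reads == 0L)
    "<p class=\"empty\">No reads overlap this region.</p>" else ""
  html <- paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\">\n",
    "<!-- generated by ", stamp, " -->\n",
    "<title>signal pileup ", layout$region$ref_name, ":",
    layout$region$start + 1L, "-", layout$region$end, "</title>\n",
    "<style>\n", SIGPILE_CSS, "</style>\n</head>\n<body>\n",
    "<h2>", layout$region$ref_name, ":", layout$region$start + 1L, "-",
    layout$region$end, "</h2>\n", empty_msg,
    "<div id=\"toolbar\">",
    "<button id=\"zoom-in\">+</button><button id=\"zoom-out\">&minus;</button>",
    "<button id=\"pan-left\">&larr;</button><button id=\"pan-right\">&rarr;</button>",
    "<label><input type=\"checkbox\" id=\"show-points\"> show signal points</label>",
    "</div>\n",
    "<div id=\"view\"></div>\n<div id=\"controls\"></div>\n",
    "<script type=\"application/json\" id=\"payload\">", payload, "</script>\n",
    "<script>var BASE_COLORS = ", colors, ";\n", SIGPILE_JS, "</script>\n",
    "</body>\n</html>\n")
  con <- withCallingHandlers(
    tryCatch(file(out_path, "wb"),
             error = function(e) stop("cannot write HTML to ", out_path,
                                      ": ", conditionMessage(e))),
    warning = function(w) invokeRestart("muffleWarning"))
  on.exit(close(con))
  writeLines(html, con, sep = "")
  invisible(out_path)
}

#' Export a pileup layout as a static SVG figure
#'
#' @param layout a `pileup_layout`.
#' @param out_path output SVG file.
#' @param track_height vertical space per track.
#' @return `out_path`, invisibly.
#' @export
export_svg <- function(layout, out_path, track_height = 120) {
  stopifnot(inherits(layout, "pileup_layout"))
  drawable <- Filter(function(tr) !is.null(tr$glyphs), layout$tracks)
  h <- max(1L, length(drawable)) * track_height + 40
  out <- c(sprintf(
    "<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%g\" height=\"%g\">",
    layout$width + 20, h))
  y_off <- 20
  for (tr in drawable) {
    ys <- unlist(lapply(tr$glyphs, function(g) g$points$y))
    if (length(ys) == 0L) { y_off <- y_off + track_height; next }
    lo <- min(ys); hi <- max(ys); span <- max(hi - lo, 1e-9)
    sy <- function(v) y_off + (track_height - 20) * (1 - (v - lo) / span)
    for (i in seq_len(nrow(layout$columns))) {
      cc <- layout$columns[i, ]
      out <- c(out, sprintf(
        "<rect x=\"%g\" y=\"%g\" width=\"%g\" height=\"%g\" fill=\"%s\" fill-opacity=\"0.15\"/>",
        cc$x0 + 10, y_off, cc$x1 - cc$x0, track_height - 20,
        BASE_COLORS[[cc$base]]))
    }
    for (g in tr$glyphs) {
      if (nrow(g$points) == 0L) next
      pts <- paste(sprintf("%g,%g", g$points$x + 10, sy(g$points$y)),
                   collapse = " ")
      out <- c(out, sprintf(
        "<polyline points=\"%s\" fill=\"none\" stroke=\"#333\" stroke-width=\"0.8\" stroke-opacity=\"0.7\"/>",
        pts))
    }
    out <- c(out, sprintf(
      "<text x=\"10\" y=\"%g\" font-size=\"10\">%s (%s)</text>",
      y_off + 10, tr$kind, tr$strand))
    y_off <- y_off + track_height
  }
  out <- c(out, "</svg>")
  writeLines(out, out_path)
  invisible(out_path)
}

SIGPILE_CSS <- "
body { font-family: sans-serif; margin: 12px; }
#toolbar { margin-bottom: 6px; }
#toolbar button { width: 2em; margin-right: 2px; }
#view svg { border: 1px solid #ccc; background: #fff; }
#controls { margin-top: 8px; font-size: 12px; }
#controls label { margin-right: 10px; }
.empty { color: #a00; }
.track-label { font-size: 11px; fill: #333; }
.gap-label { font-size: 10px; fill: #a00; }
"

SIGPILE_JS <- "
var payload = JSON.parse(document.getElementById('payload').textContent);
var viewStart = 0, viewWidth = payload.width || 1;
var showPoints = false;
var selected = {};
payload.tracks.forEach(function (tr) {
  (tr.reads || []).forEach(function (r) { selected[r.read_id] = true; });
});
var TRACK_H = 120, PAD = 50, W = 900;

function sx(x) { return PAD + (x - viewStart) * (W - PAD - 10) / viewWidth; }

function yScale(tr) {
  var lo = Infinity, hi = -Infinity;
  (tr.reads || []).forEach(function (r) {
    if (tr.kind === 'pileup_overlay' && !selected[r.read_id]) return;
    r.y.forEach(function (v) { if (v < lo) lo = v; if (v > hi) hi = v; });
  });
  if (lo > hi) { lo = 0; hi = 1; }
  var span = Math.max(hi - lo, 1e-9);
  return function (v) { return (TRACK_H - 30) * (1 - (v - lo) / span) + 15; };
}

function svgEl(tag, attrs, text) {
  var el = document.createElementNS('http://www.w3.org/2000/svg', tag);
  for (var k in attrs) el.setAttribute(k, attrs[k]);
  if (text) el.textContent = text;
  return el;
}

function render() {
  var view = document.getElementById('view');
  view.innerHTML = '';
  var tracks = payload.tracks;
  var H = Math.max(1, tracks.length) * TRACK_H + 30;
  var svg = svgEl('svg', { width: W, height: H });
  var y0 = 10;
  tracks.forEach(function (tr) {
    var g = svgEl('g', { transform: 'translate(0,' + y0 + ')' });
    payload.columns.pos.forEach(function (p, i) {
      var x0 = sx(payload.columns.x0[i]), x1 = sx(payload.columns.x1[i]);
      if (x1 < PAD || x0 > W) return;
      g.appendChild(svgEl('rect', {
        x: Math.max(x0, PAD), y: 15,
        width: Math.max(0, Math.min(x1, W) - Math.max(x0, PAD)),
        height: TRACK_H - 30,
        fill: BASE_COLORS[payload.columns.base[i]] || '#ccc',
        'fill-opacity': 0.15 }));
    });
    if (tr.intervals) {
      (tr.intervals.start || []).forEach(function (s, i) {
        var x0 = sx((tr.intervals.start[i] - payload.region.start) * payload.base_width);
        var x1 = sx((tr.intervals.end[i] - payload.region.start) * payload.base_width);
        g.appendChild(svgEl('rect', { x: x0, y: TRACK_H / 2 - 6,
          width: Math.max(1, x1 - x0), height: 12,
          fill: tr.intervals.color && tr.intervals.color[i] ? tr.intervals.color[i] : '#6a51a3' }));
        g.appendChild(svgEl('text', { x: x0, y: TRACK_H / 2 - 10,
          'class': 'track-label' }, tr.intervals.label[i]));
      });
    }
    var ys = yScale(tr);
    (tr.reads || []).forEach(function (r) {
      if (tr.kind === 'pileup_overlay' && !selected[r.read_id]) return;
      var d = '';
      for (var i = 0; i < r.x.length; i++) {
        var x = sx(r.x[i]);
        if (x < PAD - 50 || x > W + 50) continue;
        d += (d === '' ? 'M' : 'L') + x + ' ' + ys(r.y[i]);
      }
      if (d !== '') g.appendChild(svgEl('path', { d: d, fill: 'none',
        stroke: r.strand === '-' ? '#8856a7' : '#2b8cbe',
        'stroke-width': 0.9, 'stroke-opacity': 0.7 }));
      if (showPoints) {
        for (var j = 0; j < r.x.length; j++) {
          var px = sx(r.x[j]);
          if (px < PAD || px > W) continue;
          g.appendChild(svgEl('circle', { cx: px, cy: ys(r.y[j]), r: 1.2,
            fill: '#000' }));
        }
        (r.insertions || []).forEach(function (m) {
          var mx = sx(m.x);
          if (mx < PAD || mx > W) return;
          m.values.forEach(function (v) {
            g.appendChild(svgEl('circle', { cx: mx, cy: ys(v), r: 1.6,
              fill: '#d95f02' }));
          });
        });
      }
      if (r.gaps) {
        (r.gaps.x0 || []).forEach(function (gx0, i) {
          var x0 = sx(r.gaps.x0[i]), x1 = sx(r.gaps.x1[i]);
          if (x1 < PAD || x0 > W) return;
          g.appendChild(svgEl('text', { x: (x0 + x1) / 2, y: TRACK_H / 2,
            'class': 'gap-label', 'text-anchor': 'middle' }, r.gaps.label[i]));
        });
      }
    });
    g.appendChild(svgEl('text', { x: 4, y: 12, 'class': 'track-label' },
      tr.kind + ' (' + tr.strand + ')'));
    svg.appendChild(g);
    y0 += TRACK_H;
  });
  view.appendChild(svg);
}

function renderControls() {
  var box = document.getElementById('controls');
  box.innerHTML = '<b>reads:</b> ';
  var seen = {};
  payload.tracks.forEach(function (tr) {
    (tr.reads || []).forEach(function (r) {
      if (tr.kind !== 'stacked_reads' && tr.kind !== 'pileup_overlay') return;
      if (seen[r.read_id]) return;
      seen[r.read_id] = true;
      var lab = document.createElement('label');
      var cb = document.createElement('input');
      cb.type = 'checkbox';
      cb.checked = !!selected[r.read_id];
      cb.addEventListener('change', function () {
        selected[r.read_id] = cb.checked;
        render();
      });
      lab.appendChild(cb);
      lab.appendChild(document.createTextNode(' ' + r.read_id + ' (' + r.strand + ')'));
      box.appendChild(lab);
    });
  });
}

document.getElementById('zoom-in').addEventListener('click', function () {
  var c = viewStart + viewWidth / 2; viewWidth /= 1.5;
  viewStart = c - viewWidth / 2; render();
});
document.getElementById('zoom-out').addEventListener('click', function () {
  var c = viewStart + viewWidth / 2; viewWidth *= 1.5;
  viewStart = c - viewWidth / 2; render();
});
document.getElementById('pan-left').addEventListener('click', function () {
  viewStart -= viewWidth / 4; render();
});
document.getElementById('pan-right').addEventListener('click', function () {
  viewStart += viewWidth / 4; render();
});
document.getElementById('show-points').addEventListener('change', function (e) {
  showPoints = e.target.checked; render();
});
document.getElementById('view').addEventListener('wheel', function (e) {
  e.preventDefault();
  var f = e.deltaY > 0 ? 1.2 : 1 / 1.2;
  var c = viewStart + viewWidth / 2;
  viewWidth *= f; viewStart = c - viewWidth / 2; render();
});

renderControls();
render();
"
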