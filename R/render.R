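# Thin renderers over the plot data layers.  All geometry comes from the
# data builders in viz.R; renderers only map columns to aesthetics.

.contig_palette <- function(contigs) {
  u <- unique(contigs)
  stats::setNames(grDevices::hcl(h = (seq_along(u) * 137.508) %% 360,
                                 c = 70, l = 55), u)
}

.gg_bubble <- function(df, meta) {
  p <- ggplot2::ggplot(as.data.frame(df))
  if (nrow(df)) {
    df$colour <- integrity_colour(df$integrity)
    p <- ggplot2::ggplot(df,
           ggplot2::aes(x = .data$x_index, y = .data$y_index,
                        size = .data$tot_length, fill = .data$colour)) +
      ggplot2::geom_point(shape = 21, colour = "grey30") +
      ggplot2::scale_fill_identity() +
      ggplot2::scale_size_area(max_size = 12, guide = "none")
  }
  p + ggplot2::labs(x = "contig (assignment order)",
                    y = "chromosome", title = "Mapped blocks") +
    ggplot2::theme_minimal()
}

.gg_tracks <- function(df, meta) {
  kind <- meta$kind %||% "blocks"
  df <- as.data.frame(df)
  p <- ggplot2::ggplot(df)
  if (nrow(df)) {
    df$y0 <- df$y_lane - 0.35
    df$y1 <- df$y_lane + 0.35
    if (kind == "gaps") {
      p <- ggplot2::ggplot(df) +
        ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                        ymin = .data$y0, ymax = .data$y1),
                           fill = "black")
    } else {
      pal <- .contig_palette(df$contig)
      p <- ggplot2::ggplot(df) +
        ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                           y = .data$y_lane, yend = .data$y_lane),
                              colour = "grey60",
                              data = df[df$connector, , drop = FALSE]) +
        ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                        ymin = .data$y0, ymax = .data$y1,
                                        fill = .data$contig)) +
        ggplot2::scale_fill_manual(values = pal, guide = "none")
    }
  }
  p + ggplot2::labs(x = "reference position (bases)", y = "chromosome",
                    title = paste0("Genome ", kind)) +
    ggplot2::theme_minimal()
}

.gg_lanes <- function(df, meta) {
  df <- as.data.frame(df)
  p <- ggplot2::ggplot(df)
  if (nrow(df)) {
    pal <- .contig_palette(df$contig)
    conn <- df[df$connector, , drop = FALSE]
    if (nrow(conn)) {
      # previous end within each contig (rows are already in lane order)
      df$prev_end <- stats::ave(df$end, df$contig,
                                FUN = function(x) c(NA_real_, x[-length(x)]))
      conn <- df[df$connector & !is.na(df$prev_end), , drop = FALSE]
    }
    p <- ggplot2::ggplot(df) +
      ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                      ymin = .data$y_lane - 0.35,
                                      ymax = .data$y_lane + 0.35,
                                      fill = .data$contig)) +
      ggplot2::scale_fill_manual(values = pal, guide = "none")
    if (nrow(conn)) {
      p <- p + ggplot2::geom_segment(
        ggplot2::aes(x = .data$prev_end, xend = .data$start,
                     y = .data$y_lane, yend = .data$y_lane),
        data = conn, colour = "grey50", linewidth = 0.3)
    }
  }
  p + ggplot2::labs(x = "reference position (bases)", y = "contig lane",
                    title = paste0("Contigs on ", meta$chromosome %||% "")) +
    ggplot2::theme_minimal()
}

.gg_dotplot <- function(df, meta) {
  df <- as.data.frame(df)
  p <- ggplot2::ggplot(df)
  if (nrow(df)) {
    pal <- .contig_palette(df$contig)
    conn_idx <- which(df$connector)
    p <- ggplot2::ggplot(df) +
      ggplot2::geom_segment(ggplot2::aes(x = .data$x1, xend = .data$x2,
                                         y = .data$y1, yend = .data$y2,
                                         colour = .data$contig)) +
      ggplot2::geom_point(ggplot2::aes(x = .data$x1, y = .data$y1,
                                       colour = .data$contig), shape = 16, size = 1.6) +
      ggplot2::geom_point(ggplot2::aes(x = .data$x2, y = .data$y2,
                                       colour = .data$contig), shape = 17, size = 1.6) +
      ggplot2::scale_colour_manual(values = pal, guide = "none")
    if (length(conn_idx)) {
      seg <- data.frame(x = df$x2[conn_idx - 1], xend = df$x1[conn_idx],
                        y = df$y2[conn_idx - 1], yend = df$y1[conn_idx])
      p <- p + ggplot2::geom_segment(
        ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                     yend = .data$yend),
        data = seg, linetype = "dotted", colour = "grey40")
    }
  }
  p + ggplot2::labs(x = "reference position (bases)",
                    y = "contig position (bases)",
                    title = paste0("Dotplot ", meta$chromosome %||% "")) +
    ggplot2::theme_minimal()
}

.gg_bars <- function(df, meta, value_col, ylab) {
  df <- as.data.frame(df)
  df$category <- factor(df$category, levels = df$category)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category,
                                   y = .data[[value_col]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "block length category", y = ylab) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

.gg_chromolen <- function(df, meta) {
  df <- as.data.frame(df)
  df$chromosome <- factor(df$chromosome, levels = df$chromosome)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chromosome, y = .data$length)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "chromosome", y = "length (bases)",
                  title = "Chromosome lengths") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

.build_ggplot <- function(data, value = NULL) {
  type <- attr(data, "plot_type")
  meta <- attr(data, "plot_meta") %||% list()
  switch(type,
    bubble = .gg_bubble(data, meta),
    tracks = .gg_tracks(data, meta),
    lanes = .gg_lanes(data, meta),
    dotplot = .gg_dotplot(data, meta),
    threshold_bars = .gg_bars(data, meta, value %||% "tot_length",
                              value %||% "tot_length"),
    chromolen = .gg_chromolen(data, meta),
    stop("no renderer for plot type '", type, "'"))
}

.html_template <- function(svg, title) {
  paste0(
"<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"><title>", title, "</title>\n",
"<style>body{font-family:sans-serif;margin:0}#wrap{width:100vw;height:94vh;overflow:hidden;border:1px solid #ccc}svg{width:100%;height:100%}</style>\n",
"</head><body>\n<h3 style=\"margin:4px\">", title, "</h3>\n<div id=\"wrap\">\n",
svg,
"\n</div>\n<script>\n",
"(function(){var svg=document.querySelector('#wrap svg');if(!svg)return;\n",
"var vb=svg.viewBox.baseVal;if(!vb||vb.width===0){var bb=svg.getBBox();svg.setAttribute('viewBox',bb.x+' '+bb.y+' '+bb.width+' '+bb.height);vb=svg.viewBox.baseVal;}\n",
"var drag=null;\n",
"svg.addEventListener('wheel',function(e){e.preventDefault();var k=e.deltaY<0?0.8:1.25;\n",
"var pt=svg.createSVGPoint();pt.x=e.clientX;pt.y=e.clientY;var p=pt.matrixTransform(svg.getScreenCTM().inverse());\n",
"vb.x=p.x-(p.x-vb.x)*k;vb.y=p.y-(p.y-vb.y)*k;vb.width*=k;vb.height*=k;});\n",
"svg.addEventListener('mousedown',function(e){drag={x:e.clientX,y:e.clientY};});\n",
"window.addEventListener('mouseup',function(){drag=null;});\n",
"window.addEventListener('mousemove',function(e){if(!drag)return;\n",
"var sc=vb.width/svg.clientWidth;vb.x-=(e.clientX-drag.x)*sc;vb.y-=(e.clientY-drag.y)*sc;drag={x:e.clientX,y:e.clientY};});\n",
"})();\n</script>\n</body></html>\n")
}

#' Render a plot data layer to a file
#'
#' Renders any plot data object to a self-contained pan/zoomable HTML page
#' (an embedded SVG with a small zoom script), a static SVG or a PNG.
#' Rendering never alters the data layer, which remains serializable via
#' [plot_data_json()].
#'
#' @param data a plot data object from the `*_data`/`genome_tracks`/
#'   `chromosome_view`/`threshold_bars` builders.
#' @param out output file path.
#' @param format `"html"`, `"svg"` or `"png"`.
#' @param width,height device size in inches.
#' @param title plot title for the HTML page.
#' @param value for threshold bars: which series to draw (`"tot_length"`
#'   or `"n_blocks"`).
#' @return the output path, invisibly.
#' @export
render_plot <- function(data, out, format = c("html", "svg", "png"),
                        width = 9, height = 6, title = NULL, value = NULL) {
  format <- match.arg(format)
  p <- .build_ggplot(data, value = value)
  title <- title %||% attr(data, "plot_type")
  if (format == "png") {
    grDevices::png(out, width = width, height = height, units = "in",
                   res = 110, type = "cairo")
    print(p)
    grDevices::dev.off()
    return(invisible(out))
  }
  svg_file <- if (format == "svg") out else tempfile(fileext = ".svg")
  grDevices::svg(svg_file, width = width, height = height)
  print(p)
  grDevices::dev.off()
  if (format == "svg") return(invisible(out))
  svg_txt <- paste(readLines(svg_file, warn = FALSE), collapse = "\n")
  # drop the xml prolog; keep the <svg> element only
  svg_txt <- sub("^.*?<svg", "<svg", svg_txt)
  writeLines(.html_template(svg_txt, title), out)
  unlink(svg_file)
  invisible(out)
}
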