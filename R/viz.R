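# Plot data builders.  Every plot has a pure data layer (a classed
# data.frame built here and serializable as JSON) and a thin renderer in
# render.R; rendering never alters the data.

.plotdata <- function(df, type, ...) {
  structure(df, plot_type = type, plot_meta = list(...),
            class = c("blockmap_plotdata", class(df)))
}

#' Serialize a plot data layer
#'
#' Deterministic JSON serialization of the data behind a plot, used to
#' test that rendering leaves the data untouched.
#'
#' @param data a plot data object.
#' @return a JSON string.
#' @export
plot_data_json <- function(data) {
  jsonlite::toJSON(list(type = attr(data, "plot_type"),
                        data = as.data.frame(data)),
                   dataframe = "columns", digits = NA, auto_unbox = TRUE)
}

#' Bubble map data
#'
#' Aggregates filtered blocks per (contig, chromosome) intersection: the
#' bubble size driver is the total aligned length at the intersection, the
#' colour driver is the integrity level (largest block at the intersection
#' divided by contig length).  X order follows the contig assignment, y
#' order the chromosome display order, so a collinear assembly lies on the
#' main diagonal.
#'
#' @param blocks filtered annotated block table.
#' @param assignment output of [assign_and_order_contigs()].
#' @param chromolist a `chromosome_list`.
#' @param contig_table contig sequence table (for contig lengths).
#' @return plot data with one row per intersection: `contig`, `x_index`,
#'   `chromosome`, `y_index`, `tot_length`, `integrity`, `n_blocks`.
#' @export
bubble_data <- function(blocks, assignment, chromolist, contig_table) {
  b <- blocks[blocks$ref_name %in% chromolist$name, , drop = FALSE]
  if (!nrow(b)) {
    return(.plotdata(data.frame(contig = character(), x_index = integer(),
                                chromosome = character(), y_index = integer(),
                                tot_length = numeric(), integrity = numeric(),
                                n_blocks = integer()), "bubble"))
  }
  key <- interaction(b$contig_name, b$ref_name, drop = TRUE)
  tot <- tapply(b$length, key, sum)
  mx <- tapply(b$length, key, max)
  nb <- tapply(b$length, key, length)
  # contig names may contain "."; recover them via the levels, not by
  # splitting the interaction label
  lev <- levels(key)
  first <- match(lev, as.character(key))
  ctg <- b$contig_name[first]
  chr <- b$ref_name[first]
  clen <- contig_table$length[match(ctg, contig_table$name)]
  integ <- as.numeric(mx) / clen
  if (any(integ > 1, na.rm = TRUE)) {
    warning("integrity > 1 clipped (estimated contig length shorter than a block)")
    integ <- pmin(integ, 1)
  }
  df <- data.frame(contig = ctg,
                   x_index = assignment$order_index[match(ctg, assignment$contig)],
                   chromosome = chr,
                   y_index = chromolist$index[match(chr, chromolist$name)],
                   tot_length = as.numeric(tot),
                   integrity = integ,
                   n_blocks = as.integer(nb))
  df <- df[order(df$x_index, df$y_index), , drop = FALSE]
  rownames(df) <- NULL
  .plotdata(df, "bubble")
}

#' Integrity gradient colour
#'
#' Piecewise-linear colour gradient encoding the integrity level: white at
#' 1 (a single block contributes the whole contig), through yellow (0.5),
#' red (0.3) and blue (0.15), down to black at 0.05 and below (many small
#' blocks).  Anchors are configurable.
#'
#' @param integrity numeric vector in (0, 1]; out-of-range values are
#'   clamped.
#' @param anchors named numeric-to-colour map (defaults above).
#' @return character vector of hex colours.
#' @export
integrity_colour <- function(integrity,
                             anchors = c("0.05" = "#000000",
                                         "0.15" = "#0000FF",
                                         "0.3" = "#FF0000",
                                         "0.5" = "#FFFF00",
                                         "1" = "#FFFFFF")) {
  x <- as.numeric(names(anchors))
  o <- order(x)
  x <- x[o]
  cols <- grDevices::col2rgb(anchors[o])
  v <- pmin(pmax(integrity, x[1]), x[length(x)])
  ch <- vapply(1:3, function(i) {
    stats::approx(x, cols[i, ], xout = v, rule = 2)$y
  }, numeric(length(v)))
  if (length(v) == 1) ch <- matrix(ch, nrow = 1)
  grDevices::rgb(ch[, 1], ch[, 2], ch[, 3], maxColorValue = 255)
}

#' Whole-genome track data
#'
#' One y-lane per chromosome.  `kind = "blocks"` yields one segment per
#' block (coloured by contig, with a connector flag between consecutive
#' blocks of the same contig); `"contigs"` merges each contig's blocks on
#' a chromosome to its overall extent; `"gaps"` yields the uncovered
#' intervals per chromosome.
#'
#' @param blocks filtered annotated block table.
#' @param chromolist a `chromosome_list`.
#' @param kind `"blocks"`, `"contigs"` or `"gaps"`.
#' @return plot data: `chromosome`, `y_lane`, `start`, `end`, `contig`
#'   (NA for gaps), `connector` flag.
#' @export
genome_tracks <- function(blocks, chromolist, kind = c("blocks", "contigs", "gaps")) {
  kind <- match.arg(kind)
  if (kind == "gaps") {
    g <- chromosome_gaps(blocks, chromolist)
    df <- data.frame(chromosome = g$chromosome,
                     y_lane = chromolist$index[match(g$chromosome, chromolist$name)],
                     start = g$start, end = g$end,
                     contig = NA_character_, connector = FALSE)
    return(.plotdata(df, "tracks", kind = kind))
  }
  b <- blocks[blocks$ref_name %in% chromolist$name, , drop = FALSE]
  if (kind == "contigs" && nrow(b)) {
    agg_s <- stats::aggregate(s1 ~ contig_name + ref_name, data = b, FUN = min)
    agg_e <- stats::aggregate(e1 ~ contig_name + ref_name, data = b, FUN = max)
    b <- data.frame(ref_name = agg_s$ref_name, contig_name = agg_s$contig_name,
                    s1 = agg_s$s1, e1 = agg_e$e1)
  }
  if (!nrow(b)) {
    return(.plotdata(data.frame(chromosome = character(), y_lane = integer(),
                                start = numeric(), end = numeric(),
                                contig = character(), connector = logical()),
                     "tracks", kind = kind))
  }
  # connector: this block has a previous block of the same contig on the
  # same chromosome lane (drawn as a horizontal line between the two)
  ord <- order(match(b$ref_name, chromolist$name), b$contig_name, b$s1)
  b <- b[ord, , drop = FALSE]
  conn <- rep(FALSE, nrow(b))
  if (kind == "blocks" && nrow(b) >= 2) {
    conn <- c(FALSE, b$contig_name[-1] == b$contig_name[-nrow(b)] &
                       b$ref_name[-1] == b$ref_name[-nrow(b)])
  }
  lane_ord <- order(match(b$ref_name, chromolist$name), b$s1)
  b <- b[lane_ord, , drop = FALSE]
  conn <- conn[lane_ord]
  df <- data.frame(chromosome = b$ref_name,
                   y_lane = chromolist$index[match(b$ref_name, chromolist$name)],
                   start = b$s1, end = b$e1,
                   contig = b$contig_name, connector = conn)
  rownames(df) <- NULL
  .plotdata(df, "tracks", kind = kind)
}

#' Single-chromosome view data
#'
#' Builds the two per-chromosome representations: contig lanes (one y-lane
#' per contig, blocks as rectangles at their reference position, thin
#' connectors between non-contiguous blocks of a contig) and the polarized
#' dotplot (each block as a segment from (s1, start-on-contig) to
#' (e1, end-on-contig); forward blocks have positive slope, reversed
#' blocks negative slope; dotted connectors join consecutive blocks of a
#' contig wherever they are discontinuous on either axis, so insertions
#' show as a jump between parallel diagonals).
#'
#' @param blocks filtered annotated block table.
#' @param chromosome chromosome name.
#' @param chromolist a `chromosome_list` (for name validation).
#' @param assignment optional contig assignment controlling lane order.
#' @return list with plot data `lanes` and `dots`.
#' @export
chromosome_view <- function(blocks, chromosome, chromolist, assignment = NULL) {
  if (!chromosome %in% chromolist$name) {
    stop("unknown chromosome '", chromosome, "'; valid names: ",
         paste(chromolist$name, collapse = ", "))
  }
  b <- blocks[blocks$ref_name == chromosome, , drop = FALSE]
  ctgs <- unique(b$contig_name)
  if (!is.null(assignment)) {
    ctgs <- ctgs[order(match(ctgs, assignment$contig))]
  }
  b <- b[order(match(b$contig_name, ctgs), b$s1), , drop = FALSE]
  lane <- match(b$contig_name, ctgs)
  if (nrow(b) >= 2) {
    same_prev <- c(FALSE, b$contig_name[-1] == b$contig_name[-nrow(b)])
    adj_ref <- c(FALSE, b$s1[-1] == b$e1[-nrow(b)] + 1)
    adj_ctg <- c(FALSE, b$s3[-1] == b$e3[-nrow(b)] + 1)
    # lanes connect blocks of a contig that are not contiguous on the
    # chromosome; the dotplot also marks jumps on the contig axis
    # (insertions), which appear as parallel-diagonal offsets
    connector <- same_prev & !adj_ref
    dot_connector <- same_prev & !(adj_ref & adj_ctg)
  } else {
    connector <- dot_connector <- rep(FALSE, nrow(b))
  }
  lanes <- data.frame(chromosome = chromosome, y_lane = lane,
                      contig = b$contig_name, start = b$s1, end = b$e1,
                      connector = connector)
  y1 <- ifelse(b$rev, b$e3, b$s3)
  y2 <- ifelse(b$rev, b$s3, b$e3)
  dots <- data.frame(chromosome = chromosome, contig = b$contig_name,
                     x1 = b$s1, x2 = b$e1, y1 = y1, y2 = y2,
                     orientation = ifelse(b$rev, "reverse", "forward"),
                     connector = dot_connector)
  rownames(lanes) <- rownames(dots) <- NULL
  list(lanes = .plotdata(lanes, "lanes", chromosome = chromosome),
       dots = .plotdata(dots, "dotplot", chromosome = chromosome))
}

#' Threshold bar series
#'
#' Total length and block count per block-length category, the data behind
#' the category bar plots.  Reuses the [block_stats()] categories.
#'
#' @inheritParams block_stats
#' @return plot data: `category`, `threshold`, `tot_length`, `n_blocks`.
#' @export
threshold_bars <- function(blocks, thresholds = default_thresholds(),
                           mode = c("above", "between")) {
  st <- block_stats(blocks, thresholds, mode = mode)
  .plotdata(st[, c("category", "threshold", "tot_length", "n_blocks")],
            "threshold_bars", mode = match.arg(mode))
}

#' Chromosome length bars
#'
#' @param chromolist a `chromosome_list`.
#' @return plot data: `chromosome`, `index`, `length`.
#' @export
chromosome_length_data <- function(chromolist) {
  .plotdata(data.frame(chromosome = chromolist$name,
                       index = chromolist$index,
                       length = chromolist$length),
            "chromolen")
}
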