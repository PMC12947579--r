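# Table calculation dispatch and the multi-level HTML report.

#' Compute a calc table
#'
#' The single dispatch point behind both the `calc` command and the
#' report builder, so that report tables are byte-identical to standalone
#' calc output.
#'
#' @param dataset a `blockmap_dataset`.
#' @param what one of `"blocks"`, `"blockstats"`, `"cntgstats"`,
#'   `"chromostats"`, `"cntg"`, `"chromo"`, `"exchromo"`.
#' @param min_length,require_no_larger filter settings (see
#'   [filter_blocks()]).
#' @param thresholds,mode category settings for `"blockstats"`.
#' @param n_chromosomes optional chromosome count for resolution.
#' @param filtered for `"blocks"`: apply the default filter to the
#'   annotated block table (default FALSE: all imported blocks).
#' @return a data.frame.
#' @export
calc_table <- function(dataset, what = c("blocks", "blockstats", "cntgstats",
                                         "chromostats", "cntg", "chromo",
                                         "exchromo"),
                       min_length = 10000, require_no_larger = TRUE,
                       thresholds = default_thresholds(), mode = "above",
                       n_chromosomes = NULL, filtered = FALSE) {
  what <- match.arg(what)
  ann <- annotate_blocks(dataset$blocks)
  if (what == "blocks") {
    if (filtered) {
      return(filter_blocks(ann, min_length = min_length,
                           require_no_larger = require_no_larger))
    }
    return(ann)
  }
  if (what == "blockstats") {
    return(block_stats(ann, thresholds = thresholds, mode = mode))
  }
  chromolist <- resolve_chromosomes(dataset, n_chromosomes = n_chromosomes)
  if (what == "chromo") {
    return(as.data.frame(chromolist))
  }
  if (what == "exchromo") {
    return(excluded_sequences(chromolist))
  }
  if (what == "cntgstats") {
    return(contig_stats(ann, dataset$contig_sequences, chromolist))
  }
  flt <- filter_blocks(ann, min_length = min_length,
                       require_no_larger = require_no_larger)
  if (what == "chromostats") {
    return(chromosome_stats(flt, chromolist))
  }
  # cntg: contig assignment view
  assign_and_order_contigs(flt, chromolist)
}

#' Write a calc table as TSV
#'
#' @param table a data.frame from [calc_table()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_calc_table <- function(table, path) {
  data.table::fwrite(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     na = "NA")
  invisible(path)
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.html_table <- function(df, max_rows = 50) {
  df <- as.data.frame(df)
  truncated <- nrow(df) > max_rows
  show <- utils::head(df, max_rows)
  cells <- apply(show, 1, function(r) {
    paste0("<tr>", paste0("<td>", .html_escape(as.character(r)), "</td>",
                          collapse = ""), "</tr>")
  })
  paste0("<table border=\"1\" cellspacing=\"0\" cellpadding=\"3\">\n<tr>",
         paste0("<th>", .html_escape(names(df)), "</th>", collapse = ""),
         "</tr>\n", paste(cells, collapse = "\n"),
         if (truncated) paste0("\n<tr><td colspan=\"", ncol(df),
                               "\"><i>(first ", max_rows, " of ", nrow(df),
                               " rows; full table in the linked TSV)</i></td></tr>"),
         "\n</table>\n")
}

#' Build a multi-level HTML report
#'
#' Assembles a self-contained HTML bundle (index page plus linked TSV
#' tables and HTML plots, all relative links) at one of four complexity
#' levels:
#' \describe{
#'   \item{1}{summary: run metadata, the echoed QUAST report and the block
#'     statistics table.}
#'   \item{2}{adds the chromosomes table, the bubble map and the
#'     whole-genome block/contig/gap tracks.}
#'   \item{3}{adds the two per-chromosome views for every chromosome.}
#'   \item{4}{adds the full annotated block table and the contig tables.}
#' }
#'
#' @param dataset a `blockmap_dataset`.
#' @param level report complexity level, 1-4.
#' @param out_dir output directory (created).
#' @param min_length,require_no_larger filter settings.
#' @param thresholds block statistics thresholds.
#' @param n_chromosomes optional chromosome count.
#' @return path to the index HTML, invisibly.
#' @export
build_report <- function(dataset, level = 1, out_dir,
                         min_length = 10000, require_no_larger = TRUE,
                         thresholds = default_thresholds(),
                         n_chromosomes = NULL) {
  if (!level %in% 1:4) stop("report level must be 1, 2, 3 or 4")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ann <- annotate_blocks(dataset$blocks)
  bs <- block_stats(ann, thresholds = thresholds)
  sections <- character(0)
  link <- function(label, rel) paste0("<a href=\"", rel, "\">", label, "</a>")

  meta <- data.frame(
    key = c("experiment", "date", "reference", "assembly", "source",
            "blocks imported", "rejected rows"),
    value = c(dataset$experiment_name, dataset$experiment_date,
              dataset$reference_name, dataset$assembly_name,
              dataset$alignment_source, nrow(dataset$blocks),
              dataset$rejected_rows))
  sections <- c(sections, "<h2>Run</h2>", .html_table(meta))
  if (length(dataset$report)) {
    qr <- data.frame(key = names(dataset$report),
                     value = unname(dataset$report))
    sections <- c(sections, "<h2>Evaluator report</h2>", .html_table(qr))
  }
  write_calc_table(bs, file.path(out_dir, "blockstats.tsv"))
  sections <- c(sections, "<h2>Block statistics</h2>",
                .html_table(bs, max_rows = nrow(bs)),
                paste0("<p>", link("blockstats.tsv", "blockstats.tsv"), "</p>"))

  if (level >= 2) {
    chromolist <- resolve_chromosomes(dataset, n_chromosomes = n_chromosomes)
    flt <- filter_blocks(ann, min_length = min_length,
                         require_no_larger = require_no_larger)
    assignment <- assign_and_order_contigs(flt, chromolist)
    cs <- chromosome_stats(flt, chromolist)
    write_calc_table(cs, file.path(out_dir, "chromostats.tsv"))
    sections <- c(sections, "<h2>Chromosomes</h2>",
                  .html_table(cs, max_rows = nrow(cs)),
                  paste0("<p>", link("chromostats.tsv", "chromostats.tsv"), "</p>"))
    bub <- bubble_data(flt, assignment, chromolist, dataset$contig_sequences)
    render_plot(bub, file.path(out_dir, "mappedblocks.html"), "html",
                title = "Mapped blocks")
    plots <- c("mappedblocks.html")
    for (kind in c("blocks", "contigs", "gaps")) {
      tr <- genome_tracks(flt, chromolist, kind = kind)
      f <- paste0(kind, "onchrs.html")
      render_plot(tr, file.path(out_dir, f), "html",
                  title = paste("Genome", kind))
      plots <- c(plots, f)
    }
    sections <- c(sections, "<h2>Genome plots</h2><ul>",
                  paste0("<li>", vapply(plots, function(f) link(f, f),
                                        character(1)), "</li>"),
                  "</ul>")

    if (level >= 3) {
      chrom_links <- character(0)
      for (chr in chromolist$name) {
        view <- chromosome_view(flt, chr, chromolist, assignment)
        safe <- gsub("[^A-Za-z0-9._-]", "_", chr)
        f1 <- paste0("contigsonchr_", safe, ".html")
        f2 <- paste0("chromomap_", safe, ".html")
        render_plot(view$lanes, file.path(out_dir, f1), "html",
                    title = paste("Contigs on", chr))
        render_plot(view$dots, file.path(out_dir, f2), "html",
                    title = paste("Dotplot", chr))
        page <- file.path(out_dir, paste0("chromosome_", safe, ".html"))
        writeLines(paste0(
          "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"><title>", chr,
          "</title></head><body><h1>", .html_escape(chr), "</h1><ul>",
          "<li>", link("contig lanes", f1), "</li>",
          "<li>", link("dotplot", f2), "</li>",
          "</ul></body></html>"), page)
        chrom_links <- c(chrom_links,
                         paste0("<li class=\"chrompage\">",
                                link(chr, paste0("chromosome_", safe, ".html")),
                                "</li>"))
      }
      sections <- c(sections, "<h2>Chromosome pages</h2><ul>", chrom_links,
                    "</ul>")
    }
    if (level >= 4) {
      write_calc_table(flt, file.path(out_dir, "blocks.tsv"))
      cg <- contig_stats(ann, dataset$contig_sequences, chromolist)
      write_calc_table(cg, file.path(out_dir, "cntgstats.tsv"))
      write_calc_table(assignment, file.path(out_dir, "cntg.tsv"))
      sections <- c(
        sections, "<h2>Detailed tables</h2><ul>",
        paste0("<li>", link("annotated blocks (filtered)", "blocks.tsv"),
               "</li>"),
        paste0("<li>", link("contig statistics", "cntgstats.tsv"), "</li>"),
        paste0("<li>", link("contig assignment", "cntg.tsv"), "</li>"),
        "</ul>")
    }
  }

  idx <- file.path(out_dir, "index.html")
  writeLines(c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    paste0("<title>", .html_escape(dataset$experiment_name),
           " - assembly comparison report</title>"),
    "<style>body{font-family:sans-serif;max-width:1100px;margin:auto}",
    "table{border-collapse:collapse;font-size:13px}</style></head><body>",
    paste0("<h1>", .html_escape(dataset$experiment_name),
           " (level ", level, " report)</h1>"),
    sections,
    "</body></html>"), idx)
  invisible(idx)
}
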