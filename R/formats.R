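# Reading and writing the alignment-block file dialects and dataset
# persistence.
#
# Coordinate convention: all coordinates are 1-based inclusive on both the
# reference and the contig axis (the nucmer convention).  Conversion to
# 0-based half-open happens only at BED export.

#' Construct a sequence table
#'
#' A sequence table lists sequences (reference chromosomes/scaffolds or
#' assembly contigs) with their length and whether the length was declared
#' in an input file or estimated as the maximum observed end coordinate.
#'
#' @param name character vector of unique sequence names.
#' @param length integer vector of lengths in bases (>= 1).
#' @param origin "declared" or "estimated", recycled.
#' @return a `data.frame` with columns `name`, `length`, `origin`.
#' @export
sequence_table <- function(name = character(), length = integer(),
                           origin = character()) {
  if (anyDuplicated(name)) stop("sequence names must be unique")
  if (length(name) && any(length < 1)) stop("sequence lengths must be >= 1")
  data.frame(name = as.character(name), length = as.numeric(length),
             origin = rep_len(if (length(name)) origin else character(),
                              length(name)),
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Alignment file parsing

.sniff_dialect <- function(lines) {
  for (ln in utils::head(lines, 50)) {
    if (grepl("\\[S1\\]", ln, fixed = FALSE)) return("nucmer")
    toks <- strsplit(trimws(ln), "[\t ]+")[[1]]
    if (all(c("S1", "E1") %in% toks)) return("quast")
    if (grepl("^=+$", trimws(ln))) return("nucmer")
  }
  # fall back on the column count of the first row that looks like data
  for (ln in lines) {
    toks <- strsplit(trimws(ln), "[\t ]+")[[1]]
    if (length(toks) >= 7 && all(.is_intlike(toks[1:4]))) {
      return(if (length(toks) >= 9) "nucmer" else "quast")
    }
  }
  "quast"
}

#' Parse an alignment-block file
#'
#' Reads a QUAST `all_alignments_*.tsv` table or a nucmer `show-coords`
#' style tab file into a block table.  Every line of the file is classified
#' exactly once as an alignment row, a contig declaration, a junction
#' comment or a header/ignored line.  Junction comment lines (e.g. QUAST
#' misassembly descriptions such as "translocation" or
#' "indel: gap ...") are attached to both flanking alignment rows: as
#' `right_comment` of the previous block and `left_comment` of the next; at
#' file start or end they attach to the single neighbour.
#'
#' Rows whose reference end precedes the reference start are rejected (and
#' counted) rather than aborting the parse; real evaluator output contains
#' occasional status lines and malformed rows.
#'
#' @param path path to the alignment file (or a character vector of lines
#'   via `text`).
#' @param dialect `"auto"` (default, sniffed from headers and column
#'   counts), `"quast"` (columns S1 E1 S2 E2 Reference Contig IDY ...) or
#'   `"nucmer"` (columns S1 E1 S2 E2 LEN1 LEN2 IDY ... Ref Contig; the LEN
#'   columns are ignored and recomputed from coordinates).
#' @param text optional character vector of lines, used instead of `path`.
#' @return a list with elements
#'   \describe{
#'     \item{blocks}{data.frame of raw blocks: `s1,e1,s2,e2,ref_name,
#'       contig_name,idy,left_comment,right_comment`. `s2 > e2` encodes a
#'       reversed alignment and is preserved as read.}
#'     \item{contigs}{sequence table for the assembly contigs; contigs
#'       declared with a `CONTIG` line get `origin = "declared"`, all
#'       others are estimated as the maximum observed contig coordinate.}
#'     \item{line_classes}{named counts of the four line classes; they sum
#'       to the number of lines in the file.}
#'     \item{rejected}{number of rejected alignment rows.}
#'     \item{dialect}{the dialect actually used.}
#'   }
#' @export
parse_alignment_file <- function(path = NULL,
                                 dialect = c("auto", "quast", "nucmer"),
                                 text = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(text)) {
    if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
      stop("cannot read alignment file: ", path)
    }
    lines <- readLines(path, warn = FALSE)
  } else {
    lines <- text
  }
  if (dialect == "auto") dialect <- .sniff_dialect(lines)

  n <- length(lines)
  trimmed <- trimws(lines)
  tok_list <- strsplit(trimmed, "[\t ]+")
  ntok <- lengths(tok_list)

  # vectorized line classification (exactly one class per line)
  is_hdr <- !nzchar(trimmed) |
    grepl("^=+$", trimmed) | grepl("^NUCMER\\s*$", trimmed) |
    grepl("^/", trimmed) | grepl("\\[S1\\]", trimmed) |
    (grepl("(^|[\t ])S1([\t ]|$)", trimmed) &
       grepl("(^|[\t ])E1([\t ]|$)", trimmed))

  tok1 <- vapply(tok_list, function(t) if (length(t)) t[1] else "", character(1))
  tok_at <- function(k) vapply(tok_list, function(t)
    if (length(t) >= k) t[k] else NA_character_, character(1))
  t2 <- tok_at(2); t3 <- tok_at(3); t4 <- tok_at(4)
  t5 <- tok_at(5); t6 <- tok_at(6); t7 <- tok_at(7)

  is_decl <- !is_hdr & ntok >= 3 & tok1 == "CONTIG" & .is_intlike(t3)
  is_algn <- !is_hdr & !is_decl & ntok >= 7 &
    .is_intlike(tok1) & .is_intlike(t2) & .is_intlike(t3) & .is_intlike(t4) &
    .is_numlike(t7)
  is_cmt <- !is_hdr & !is_decl & !is_algn

  cls <- rep("comment", n)
  cls[is_hdr] <- "header"
  cls[is_decl] <- "declaration"
  cls[is_algn] <- "alignment"

  decl_name <- t2[is_decl]
  decl_len <- as.numeric(t3[is_decl])

  ai <- which(is_algn)
  s1 <- as.numeric(tok1[ai]); e1 <- as.numeric(t2[ai])
  s2 <- as.numeric(t3[ai]); e2 <- as.numeric(t4[ai])
  idy <- as.numeric(t7[ai])
  if (dialect == "nucmer") {
    refn <- vapply(tok_list[ai], function(t)
      if (length(t) >= 9) t[length(t) - 1] else t[5], character(1))
    ctgn <- vapply(tok_list[ai], function(t)
      if (length(t) >= 9) t[length(t)] else t[6], character(1))
  } else {
    refn <- t5[ai]; ctgn <- t6[ai]
  }
  ok <- e1 >= s1
  rejected <- sum(!ok)
  row_line <- ai[ok]

  if (!length(row_line)) stop("empty alignment: no alignment rows in input")

  blocks <- data.frame(
    s1 = s1[ok], e1 = e1[ok], s2 = s2[ok], e2 = e2[ok],
    ref_name = refn[ok], contig_name = ctgn[ok], idy = idy[ok],
    left_comment = "", right_comment = "",
    stringsAsFactors = FALSE)

  # Attach junction comments to both flanking alignment rows.
  cm_idx <- which(cls == "comment")
  if (length(cm_idx)) {
    prev_block <- findInterval(cm_idx, row_line)   # 0 if before first row
    for (k in seq_along(cm_idx)) {
      txt <- gsub("\t", " ", trimws(lines[cm_idx[k]]))
      p <- prev_block[k]
      if (p >= 1) {
        blocks$right_comment[p] <-
          if (nzchar(blocks$right_comment[p]))
            paste(blocks$right_comment[p], txt, sep = "; ") else txt
      }
      if (p < nrow(blocks)) {
        blocks$left_comment[p + 1] <-
          if (nzchar(blocks$left_comment[p + 1]))
            paste(blocks$left_comment[p + 1], txt, sep = "; ") else txt
      }
    }
  }

  # Contig table: declared lengths win; the rest are estimated from the
  # largest observed contig coordinate.
  seen <- unique(blocks$contig_name)
  est <- setdiff(seen, decl_name)
  est_len <- if (length(est)) {
    mx <- tapply(pmax(blocks$s2, blocks$e2), blocks$contig_name, max)
    as.numeric(mx[est])
  } else numeric(0)
  contigs <- rbind(
    sequence_table(decl_name, decl_len, "declared"),
    sequence_table(est, est_len, "estimated"))

  counts <- c(alignment = sum(cls == "alignment"),
              declaration = sum(cls == "declaration"),
              comment = sum(cls == "comment"),
              header = sum(cls == "header"))

  list(blocks = blocks, contigs = contigs, line_classes = counts,
       rejected = rejected, dialect = dialect)
}

#' Parse a chromosome conversion file
#'
#' A conversion file is a TSV declaring which reference sequences are
#' chromosomes, in display order, with their lengths.  Extra columns are
#' ignored.
#'
#' @param path path to the TSV (or lines via `text`).
#' @param text optional character vector of lines.
#' @return a sequence table (origin `"declared"`), in file order.
#' @export
parse_conversion_file <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(sequence_table())
  toks <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(toks, `[`, character(1), 1)
  lenstr <- vapply(toks, function(t) if (length(t) >= 2) t[2] else NA_character_, character(1))
  bad <- is.na(lenstr) | !.is_intlike(lenstr)
  if (any(bad)) {
    stop("conversion file: non-integer length on line ", which(bad)[1],
         ": ", lines[which(bad)[1]])
  }
  sequence_table(trimws(nm), as.numeric(lenstr), "declared")
}

#' Parse a QUAST summary report
#'
#' Reads the two-column key/value `report.tsv`/`report.txt` summary emitted
#' by QUAST.  Values are kept as strings; they are echoed in reports, never
#' recomputed.
#'
#' @param path path to the report file (missing file gives a warning and an
#'   empty map).
#' @param text optional character vector of lines.
#' @return named character vector (key -> value).
#' @export
parse_quast_report <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path)) {
      if (!is.null(path)) warning("QUAST report not found: ", path)
      return(stats::setNames(character(0), character(0)))
    }
    lines <- readLines(path, warn = FALSE)
  } else {
    lines <- text
  }
  lines <- lines[nzchar(trimws(lines))]
  out <- character(0)
  for (ln in lines) {
    toks <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(toks) < 2) next
    key <- trimws(toks[1]); val <- trimws(paste(toks[-1], collapse = "\t"))
    if (key %in% names(out)) warning("duplicate report key '", key, "': last value wins")
    out[key] <- val
  }
  out
}

# ---------------------------------------------------------------------------
# Dataset construction and persistence

#' Import an alignment run into a dataset
#'
#' Builds the in-memory dataset behind all downstream calculations: run
#' metadata, the raw block table (stably ordered by reference then start),
#' and the reference and contig sequence tables.  Reference lengths come
#' from the conversion file where declared and are otherwise estimated as
#' the largest observed end coordinate on that sequence.
#'
#' @param alignment_file path to a QUAST/nucmer alignment file.
#' @param conversion_file optional path to the chromosome conversion TSV.
#' @param report_file optional path to a QUAST summary report.
#' @param name experiment name.
#' @param reference_name,assembly_name display names for the two genomes.
#' @param dialect passed to [parse_alignment_file()].
#' @return an object of class `blockmap_dataset`.
#' @export
import_alignment <- function(alignment_file, conversion_file = NULL,
                             report_file = NULL, name = "run",
                             reference_name = "reference",
                             assembly_name = "assembly",
                             dialect = "auto") {
  parsed <- parse_alignment_file(alignment_file, dialect = dialect)
  conversion <- if (!is.null(conversion_file)) {
    parse_conversion_file(conversion_file)
  } else sequence_table()
  report <- if (!is.null(report_file)) parse_quast_report(report_file) else
    stats::setNames(character(0), character(0))

  blocks <- parsed$blocks
  # reference table: declared (conversion order) first, then estimated
  # sequences by descending length.
  seen_ref <- unique(blocks$ref_name)
  est <- setdiff(seen_ref, conversion$name)
  est_len <- if (length(est)) {
    mx <- tapply(pmax(blocks$s1, blocks$e1), blocks$ref_name, max)
    as.numeric(mx[est])
  } else numeric(0)
  est_tab <- sequence_table(est, est_len, "estimated")
  est_tab <- est_tab[order(-est_tab$length, est_tab$name), , drop = FALSE]
  ref_sequences <- rbind(conversion, est_tab)
  rownames(ref_sequences) <- NULL

  # stable order: reference (sequence-table order) then s1
  ref_rank <- match(blocks$ref_name, ref_sequences$name)
  blocks <- blocks[order(ref_rank, blocks$s1), , drop = FALSE]
  rownames(blocks) <- NULL

  structure(list(
    experiment_date = as.character(Sys.Date()),
    experiment_name = name,
    reference_name = reference_name,
    assembly_name = assembly_name,
    alignment_source = as.character(alignment_file),
    report_path = if (is.null(report_file)) NA_character_ else as.character(report_file),
    conversion_path = if (is.null(conversion_file)) NA_character_ else as.character(conversion_file),
    report = report,
    conversion = conversion,
    blocks = blocks,
    ref_sequences = ref_sequences,
    contig_sequences = parsed$contigs,
    line_classes = parsed$line_classes,
    rejected_rows = parsed$rejected,
    dialect = parsed$dialect
  ), class = "blockmap_dataset")
}

#' @export
print.blockmap_dataset <- function(x, ...) {
  cat("<blockmap_dataset> ", x$experiment_name, " (", x$experiment_date, ")\n",
      "  reference: ", x$reference_name, " (", nrow(x$ref_sequences),
      " sequences)\n",
      "  assembly:  ", x$assembly_name, " (", nrow(x$contig_sequences),
      " contigs)\n",
      "  blocks:    ", nrow(x$blocks), "\n", sep = "")
  invisible(x)
}

.BLOCK_TSV_COLS <- c(S1 = "s1", E1 = "e1", S2 = "s2", E2 = "e2",
                     Ref = "ref_name", Contig = "contig_name", IDY = "idy",
                     LeftComment = "left_comment", RightComment = "right_comment")

#' Persist a dataset to a directory
#'
#' Writes a normalized block TSV, the two sequence tables and a JSON
#' metadata/manifest pair.  [load_dataset()] restores the dataset
#' field-for-field.
#'
#' @param dataset a `blockmap_dataset`.
#' @param directory target directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
save_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "blockmap_dataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)

  blk <- dataset$blocks
  out <- stats::setNames(blk[, .BLOCK_TSV_COLS], names(.BLOCK_TSV_COLS))
  data.table::fwrite(out, file.path(directory, "blocks.tsv"), sep = "\t",
                     quote = FALSE)
  data.table::fwrite(dataset$ref_sequences,
                     file.path(directory, "ref_sequences.tsv"), sep = "\t",
                     quote = FALSE)
  data.table::fwrite(dataset$contig_sequences,
                     file.path(directory, "contig_sequences.tsv"), sep = "\t",
                     quote = FALSE)
  if (nrow(dataset$conversion)) {
    data.table::fwrite(dataset$conversion,
                       file.path(directory, "conversion.tsv"), sep = "\t",
                       quote = FALSE)
  }
  meta <- dataset[c("experiment_date", "experiment_name", "reference_name",
                    "assembly_name", "alignment_source", "report_path",
                    "conversion_path", "rejected_rows", "dialect")]
  meta$report <- as.list(dataset$report)
  meta$line_classes <- as.list(dataset$line_classes)
  jsonlite::write_json(meta, file.path(directory, "metadata.json"),
                       auto_unbox = TRUE, null = "null", na = "null")
  manifest <- list(
    format = "blockmapr-dataset",
    version = 1L,
    n_blocks = nrow(blk),
    files = list(blocks = "blocks.tsv",
                 ref_sequences = "ref_sequences.tsv",
                 contig_sequences = "contig_sequences.tsv",
                 metadata = "metadata.json",
                 conversion = if (nrow(dataset$conversion)) "conversion.tsv" else NULL))
  path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE)
  invisible(path)
}

.read_seq_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        na.strings = NULL,
                                        colClasses = list(character = "name")))
  if (!nrow(df)) return(sequence_table())
  sequence_table(df$name, df$length, df$origin)
}

#' Load a persisted dataset
#'
#' @param directory directory written by [save_dataset()].
#' @return a `blockmap_dataset`.
#' @export
load_dataset <- function(directory) {
  man_path <- file.path(directory, "manifest.json")
  if (!file.exists(man_path)) stop("load error: missing manifest.json in ", directory)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  need <- c("blocks", "ref_sequences", "contig_sequences", "metadata")
  for (piece in need) {
    f <- man$files[[piece]]
    if (is.null(f) || !file.exists(file.path(directory, f))) {
      stop("load error: missing dataset piece '", piece, "'")
    }
  }
  blk <- as.data.frame(data.table::fread(
    file.path(directory, man$files$blocks), sep = "\t", header = TRUE,
    na.strings = NULL,
    colClasses = list(character = c("Ref", "Contig", "LeftComment",
                                    "RightComment"))))
  blocks <- data.frame(
    s1 = as.numeric(blk$S1), e1 = as.numeric(blk$E1),
    s2 = as.numeric(blk$S2), e2 = as.numeric(blk$E2),
    ref_name = blk$Ref, contig_name = blk$Contig, idy = as.numeric(blk$IDY),
    left_comment = blk$LeftComment, right_comment = blk$RightComment,
    stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(directory, man$files$metadata),
                              simplifyVector = TRUE)
  conversion <- if (!is.null(man$files$conversion) &&
                    file.exists(file.path(directory, man$files$conversion))) {
    .read_seq_table(file.path(directory, man$files$conversion))
  } else sequence_table()
  report <- unlist(meta$report) %||% character(0)
  if (is.null(report)) report <- stats::setNames(character(0), character(0))
  structure(list(
    experiment_date = meta$experiment_date,
    experiment_name = meta$experiment_name,
    reference_name = meta$reference_name,
    assembly_name = meta$assembly_name,
    alignment_source = meta$alignment_source,
    report_path = meta$report_path %||% NA_character_,
    conversion_path = meta$conversion_path %||% NA_character_,
    report = report,
    conversion = conversion,
    blocks = blocks,
    ref_sequences = .read_seq_table(file.path(directory, man$files$ref_sequences)),
    contig_sequences = .read_seq_table(file.path(directory, man$files$contig_sequences)),
    line_classes = unlist(meta$line_classes),
    rejected_rows = meta$rejected_rows,
    dialect = meta$dialect
  ), class = "blockmap_dataset")
}

#' Export blocks as BED
#'
#' Writes one BED line per block, converting the 1-based inclusive
#' reference coordinates to BED's 0-based half-open convention.  The name
#' field is the contig, the score is the percent identity scaled to 0-1000
#' and the strand reflects the alignment orientation.
#'
#' @param blocks a raw or annotated block table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
export_bed <- function(blocks, path) {
  strand <- ifelse(blocks$s2 > blocks$e2, "-", "+")
  bed <- data.frame(chrom = blocks$ref_name,
                    start = blocks$s1 - 1,
                    end = blocks$e1,
                    name = blocks$contig_name,
                    score = pmin(1000, round(blocks$idy * 10)),
                    strand = strand)
  data.table::fwrite(bed, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}
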