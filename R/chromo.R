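# Resolving which reference sequences are chromosomes and ordering contigs
# against them.

.chromosome_list <- function(entries, excluded) {
  entries$index <- seq_len(nrow(entries))
  structure(entries[, c("name", "length", "index")],
            excluded = excluded[, c("name", "length"), drop = FALSE],
            class = c("chromosome_list", "data.frame"))
}

#' Excluded reference sequences
#'
#' @param chromolist a chromosome list.
#' @return data.frame of reference sequences not designated chromosomes.
#' @export
excluded_sequences <- function(chromolist) attr(chromolist, "excluded")

#' Guess the chromosome set from sequence lengths
#'
#' Sorts the reference sequences by descending length and accepts them as
#' chromosomes while each is strictly larger than 50% of the previously
#' accepted one; the scan stops at the first failure and all later
#' sequences are excluded.  The largest sequence is always a chromosome.
#' The boundary is strict: a sequence exactly half the previous length
#' stops the scan.
#'
#' @param ref_lengths data.frame with `name` and `length` columns (a
#'   sequence table works).
#' @return a `chromosome_list`: data.frame `name`, `length`, `index` with
#'   the excluded sequences available via [excluded_sequences()].
#' @export
guess_chromosomes <- function(ref_lengths) {
  if (is.null(ref_lengths) || !nrow(ref_lengths)) {
    stop("guess_chromosomes: no reference sequences")
  }
  o <- order(-ref_lengths$length, ref_lengths$name)
  srt <- ref_lengths[o, , drop = FALSE]
  k <- 1L
  while (k < nrow(srt) && srt$length[k + 1] > 0.5 * srt$length[k]) k <- k + 1L
  .chromosome_list(srt[seq_len(k), , drop = FALSE],
                   srt[-seq_len(k), , drop = FALSE])
}

#' Resolve the chromosome list for a dataset
#'
#' Precedence: an explicit conversion table (declared order and lengths
#' win, overriding estimated lengths) > a stated chromosome count (top-n
#' reference sequences by length) > the size-based guess of
#' [guess_chromosomes()].
#'
#' @param dataset a `blockmap_dataset`.
#' @param conversion optional sequence table of chromosomes; defaults to
#'   the conversion table imported with the dataset, when present.
#' @param n_chromosomes optional number of chromosomes.
#' @return a `chromosome_list`.
#' @export
resolve_chromosomes <- function(dataset, conversion = NULL, n_chromosomes = NULL) {
  refs <- dataset$ref_sequences
  if (is.null(conversion) && nrow(dataset$conversion)) {
    conversion <- dataset$conversion
  }
  if (!is.null(conversion) && nrow(conversion)) {
    unknown <- setdiff(conversion$name, refs$name)
    # names declared in the conversion file but absent from the alignment
    # are only an error when the alignment defined the universe; declared
    # sequences extend the reference table at import time, so any leftover
    # here is a genuine mismatch.
    if (length(unknown)) {
      stop("conversion names absent from reference table: ",
           paste(unknown, collapse = ", "))
    }
    entries <- data.frame(name = conversion$name, length = conversion$length)
    excl <- refs[!refs$name %in% conversion$name, c("name", "length"), drop = FALSE]
    return(.chromosome_list(entries, excl))
  }
  if (!is.null(n_chromosomes)) {
    if (n_chromosomes > nrow(refs)) {
      stop("n_chromosomes (", n_chromosomes, ") exceeds available reference sequences (",
           nrow(refs), ")")
    }
    o <- order(-refs$length, refs$name)
    srt <- refs[o, c("name", "length"), drop = FALSE]
    return(.chromosome_list(srt[seq_len(n_chromosomes), , drop = FALSE],
                            srt[-seq_len(n_chromosomes), , drop = FALSE]))
  }
  guess_chromosomes(refs)
}

#' Assign contigs to chromosomes and order them
#'
#' Each contig is assigned to the chromosome on which it aligns the most
#' bases (sum of block contig-footprint lengths); ties break toward the
#' chromosome with the smaller display index.  Contigs are then ordered by
#' assigned chromosome (chromosome display order) and, within a
#' chromosome, by the leftmost reference start of their blocks there, so
#' that a collinear assembly produces a diagonal bubble map.  Contigs
#' aligning only to excluded reference sequences are unplaced and ordered
#' last, alphabetically.
#'
#' @param blocks filtered annotated block table.
#' @param chromolist a `chromosome_list`.
#' @return data.frame with one row per contig: `contig`,
#'   `assigned_chromosome` (NA when unplaced), `aligned_bases` (on the
#'   assigned chromosome), `order_index`.
#' @export
assign_and_order_contigs <- function(blocks, chromolist) {
  contigs <- unique(blocks$contig_name)
  if (!length(contigs)) {
    return(data.frame(contig = character(), assigned_chromosome = character(),
                      aligned_bases = numeric(), order_index = integer()))
  }
  onchr <- blocks[blocks$ref_name %in% chromolist$name, , drop = FALSE]
  if (nrow(onchr)) {
    dt <- data.table::data.table(contig = onchr$contig_name,
                                 ref = onchr$ref_name,
                                 len = onchr$length, s1 = onchr$s1)
    agg <- dt[, list(aligned_bases = sum(len), leftmost_s1 = min(s1)),
              by = c("contig", "ref")]
    agg$chr_index <- match(agg$ref, chromolist$name)
    data.table::setorder(agg, contig, -aligned_bases, chr_index)
    best <- as.data.frame(agg[!duplicated(agg$contig), ])
  } else {
    best <- data.frame(contig = character(), ref = character(),
                       aligned_bases = numeric(), leftmost_s1 = numeric(),
                       chr_index = integer())
  }
  m <- match(contigs, best$contig)
  out <- data.frame(contig = contigs,
                    assigned_chromosome = best$ref[m],
                    aligned_bases = ifelse(is.na(m), 0, best$aligned_bases[m]),
                    chr_index = best$chr_index[m],
                    leftmost_s1 = best$leftmost_s1[m])
  placed <- !is.na(out$chr_index)
  o <- c(which(placed)[order(out$chr_index[placed], out$leftmost_s1[placed],
                             out$contig[placed])],
         which(!placed)[order(out$contig[!placed])])
  out <- out[o, c("contig", "assigned_chromosome", "aligned_bases"), drop = FALSE]
  out$order_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
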