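# Block, contig and chromosome statistics: N/L contiguity values, coverage
# unions and gaps, and the length-category block statistics table.

#' N and L contiguity statistic
#'
#' Sorts the lengths in descending order and finds the smallest k such that
#' the first k lengths cover at least p% of the total; `N_p` is the k-th
#' length, `L_p` is k.
#'
#' @param lengths vector of positive lengths (bases).
#' @param p percentage in (0, 100].
#' @return named numeric vector `c(n = N_p, l = L_p)`; an empty input
#'   returns `c(0, 0)` with a warning.
#' @export
nl_statistic <- function(lengths, p) {
  lengths <- lengths[!is.na(lengths)]
  if (!length(lengths)) {
    warning("nl_statistic: empty length list")
    return(c(n = 0, l = 0))
  }
  if (p <= 0 || p > 100) stop("p must be in (0, 100]")
  srt <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(srt)
  k <- which(cs >= p / 100 * cs[length(cs)] - 1e-9)[1]
  c(n = srt[k], l = k)
}

#' Coverage union and gaps on one chromosome
#'
#' Computes the number of bases covered by the union of the given reference
#' intervals and the maximal uncovered (gap) intervals of
#' `[1, chr_length]`.  Intervals extending past the chromosome end are
#' clipped with a warning.  `covered + sum(gap widths) == chr_length`
#' always holds.
#'
#' @param intervals data.frame (or matrix) with columns `start`/`end` (or
#'   `s1`/`e1`), 1-based inclusive.
#' @param chr_length chromosome length in bases.
#' @return list with `covered` (bases) and `gaps` (data.frame
#'   `start`,`end`).
#' @export
coverage_and_gaps <- function(intervals, chr_length) {
  iv <- as.data.frame(intervals)
  if (!nrow(iv)) {
    return(list(covered = 0,
                gaps = data.frame(start = 1, end = chr_length)))
  }
  s <- iv[[if ("start" %in% names(iv)) "start" else "s1"]]
  e <- iv[[if ("end" %in% names(iv)) "end" else "e1"]]
  if (any(e > chr_length | s < 1)) {
    warning("intervals exceed [1, chr_length]; clipping")
    s <- pmax(s, 1)
    e <- pmin(e, chr_length)
    keep <- s <= e
    s <- s[keep]; e <- e[keep]
  }
  if (!length(s)) {
    return(list(covered = 0,
                gaps = data.frame(start = 1, end = chr_length)))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = s, end = e))
  gp <- IRanges::gaps(ir, start = 1, end = chr_length)
  list(covered = sum(IRanges::width(ir)),
       gaps = data.frame(start = IRanges::start(gp), end = IRanges::end(gp)))
}

#' Default block-length thresholds
#'
#' The descending length categories used for the block statistics table.
#' @return numeric vector of thresholds in bases.
#' @export
default_thresholds <- function() {
  c(500000, 200000, 100000, 50000, 20000, 10000, 5000, 2000, 1000, 500, 200, 100, 0)
}

.empty_stats_row <- function(label) {
  data.frame(category = label, threshold = NA_real_, tot_length = 0,
             genome_fraction = 0, n_blocks = 0L, n_unique = 0L,
             n_repeated = 0L, avg_length = NA_real_, n50_kb = NA_real_,
             l50 = 0L, n90_kb = NA_real_, l90 = 0L, n_contigs = 0L,
             n_ref = 0L, blocks_per_contig = NA_real_,
             blocks_per_ref = NA_real_, avg_identity = NA_real_)
}

.stats_row <- function(members, label, threshold, tot_all, idy_weighted,
                       repeated_rule) {
  if (!nrow(members)) {
    row <- .empty_stats_row(label)
    row$threshold <- threshold
    return(row)
  }
  tot <- sum(members$length)
  nb <- nrow(members)
  overlap_counts <- members$n_same + members$n_alternatives +
    members$n_larger + members$n_ov_left + members$n_ov_right
  if (repeated_rule == "containment") {
    overlap_counts <- members$n_same + members$n_alternatives + members$n_larger
  }
  n_rep <- sum(overlap_counts > 0)
  n50 <- nl_statistic(members$length, 50)
  n90 <- nl_statistic(members$length, 90)
  nc <- length(unique(members$contig_name))
  nr <- length(unique(members$ref_name))
  idy <- if (idy_weighted) {
    sum(members$idy * members$length) / sum(members$length)
  } else mean(members$idy)
  data.frame(
    category = label, threshold = threshold, tot_length = tot,
    genome_fraction = round_half_up(tot / tot_all, 2),
    n_blocks = nb, n_unique = nb - n_rep, n_repeated = n_rep,
    avg_length = round_half_up(tot / nb),
    n50_kb = round_half_up(n50[["n"]] / 1000, 1), l50 = n50[["l"]],
    n90_kb = round_half_up(n90[["n"]] / 1000, 1), l90 = n90[["l"]],
    n_contigs = nc, n_ref = nr,
    blocks_per_contig = round_half_up(nb / nc),
    blocks_per_ref = round_half_up(nb / nr),
    avg_identity = round_half_up(idy, 1))
}

#' Block statistics by length category
#'
#' Computes one statistics row per block-length category.  In `"above"`
#' mode a category holds the blocks strictly longer than its threshold; in
#' `"between"` mode the sorted thresholds define bands `(low, high]` plus a
#' final open-ended band, which partition the blocks when the lowest
#' threshold is 0.
#'
#' Genome fraction is the category's share of the total aligned length of
#' all blocks passed in (so the threshold-0 category prints 1.00), not of
#' the reference length.  A block counts as repeated when any of its five
#' overlap counters (`n_same`, `n_alternatives`, `n_larger`, `n_ov_left`,
#' `n_ov_right`) is positive; `n_unrelated` does not make a block
#' repeated.
#'
#' @param blocks annotated block table with counters.
#' @param thresholds category thresholds in bases (any order).
#' @param mode `"above"` or `"between"`.
#' @param idy_weighted length-weight the average identity (default FALSE:
#'   unweighted mean across blocks).
#' @param repeated_rule `"overlap"` (default, any of the five overlap
#'   counters) or `"containment"` (`n_same`/`n_alternatives`/`n_larger`
#'   only).
#' @return data.frame with one row per category: `category`, `threshold`,
#'   `tot_length`, `genome_fraction` (2 decimals), `n_blocks`, `n_unique`,
#'   `n_repeated`, `avg_length` (nearest integer), `n50_kb`/`n90_kb` (kb,
#'   1 decimal), `l50`, `l90`, `n_contigs`, `n_ref`, `blocks_per_contig`,
#'   `blocks_per_ref` (nearest integer), `avg_identity` (1 decimal).
#' @export
block_stats <- function(blocks, thresholds = default_thresholds(),
                        mode = c("above", "between"),
                        idy_weighted = FALSE,
                        repeated_rule = c("overlap", "containment")) {
  mode <- match.arg(mode)
  repeated_rule <- match.arg(repeated_rule)
  tot_all <- sum(blocks$length)
  if (mode == "above") {
    thr <- sort(unique(thresholds), decreasing = TRUE)
    rows <- lapply(thr, function(t) {
      .stats_row(blocks[blocks$length > t, , drop = FALSE],
                 paste0(">", format(t, scientific = FALSE, trim = TRUE)),
                 t, tot_all, idy_weighted, repeated_rule)
    })
  } else {
    thr <- sort(unique(thresholds))
    lo <- thr
    hi <- c(thr[-1], Inf)
    rows <- mapply(function(l, h) {
      fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
      lab <- if (is.infinite(h)) paste0(">", fmt(l)) else paste0(fmt(l), "-", fmt(h))
      .stats_row(blocks[blocks$length > l & blocks$length <= h, , drop = FALSE],
                 lab, l, tot_all, idy_weighted, repeated_rule)
    }, lo, hi, SIMPLIFY = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chromosome-by-chromosome summary
#'
#' One row per chromosome of the resolved list: extent of the aligned
#' region (leftmost block start, rightmost block end), fraction of the
#' chromosome covered by the union of block intervals, number of mapping
#' contigs with their L50/L90 (over per-contig total aligned bases on that
#' chromosome), average identity, block count, total aligned length and
#' chromosome length.  Operates on the filtered block set by default
#' (pass unfiltered blocks to override).
#'
#' @param blocks filtered annotated block table.
#' @param chromolist a `chromosome_list`.
#' @return data.frame with one row per chromosome.
#' @export
chromosome_stats <- function(blocks, chromolist) {
  rows <- lapply(seq_len(nrow(chromolist)), function(i) {
    chr <- chromolist$name[i]
    len <- chromolist$length[i]
    b <- blocks[blocks$ref_name == chr, , drop = FALSE]
    if (!nrow(b)) {
      return(data.frame(chromosome = chr, s1_min = 0, e1_max = 0,
                        covered_fraction = 0, n_contigs = 0L,
                        l90_contigs = 0L, l50_contigs = 0L,
                        avg_identity = NA_real_, n_blocks = 0L,
                        tot_aligned = 0, chr_length = len))
    }
    cov <- coverage_and_gaps(data.frame(start = b$s1, end = b$e1), len)
    per_ctg <- tapply(b$length, b$contig_name, sum)
    data.frame(
      chromosome = chr, s1_min = min(b$s1), e1_max = max(b$e1),
      covered_fraction = cov$covered / len,
      n_contigs = length(per_ctg),
      l90_contigs = unname(nl_statistic(as.numeric(per_ctg), 90)[["l"]]),
      l50_contigs = unname(nl_statistic(as.numeric(per_ctg), 50)[["l"]]),
      avg_identity = round_half_up(mean(b$idy), 1),
      n_blocks = nrow(b), tot_aligned = sum(b$length), chr_length = len)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gap intervals per chromosome
#'
#' Maximal uncovered reference intervals for every chromosome of the list.
#'
#' @param blocks filtered annotated block table.
#' @param chromolist a `chromosome_list`.
#' @return data.frame `chromosome`, `start`, `end`.
#' @export
chromosome_gaps <- function(blocks, chromolist) {
  rows <- lapply(seq_len(nrow(chromolist)), function(i) {
    chr <- chromolist$name[i]
    b <- blocks[blocks$ref_name == chr, , drop = FALSE]
    g <- coverage_and_gaps(data.frame(start = b$s1, end = b$e1),
                           chromolist$length[i])$gaps
    if (!nrow(g)) return(NULL)
    cbind(chromosome = chr, g)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(chromosome = character(),
                                      start = numeric(), end = numeric())
  rownames(out) <- NULL
  out
}

#' Per-contig statistics
#'
#' One row per contig: block count, total aligned bases, largest block,
#' contig length, integrity level (largest block / contig length — a
#' continuity measure in (0,1]), number of distinct reference sequences
#' hit, assigned chromosome (argmax of aligned bases over the chromosome
#' list when given) and mean identity.  Integrity is flagged approximate
#' when the contig length was estimated from block coordinates rather than
#' declared.
#'
#' @param blocks annotated block table.
#' @param contig_table contig sequence table (name, length, origin).
#' @param chromolist optional `chromosome_list` used for the assignment.
#' @return data.frame with one row per contig.
#' @export
contig_stats <- function(blocks, contig_table, chromolist = NULL) {
  dt <- data.table::data.table(contig = blocks$contig_name,
                               ref = blocks$ref_name,
                               len = blocks$length, idy = blocks$idy)
  per <- dt[, list(n_blocks = .N, tot_aligned = sum(len),
                   largest_block = max(len),
                   n_ref = length(unique(ref)),
                   avg_identity = round_half_up(mean(idy), 1)),
            by = "contig"]
  per <- as.data.frame(per[order(per$contig), ])
  m <- match(per$contig, contig_table$name)
  per$contig_length <- ifelse(is.na(m), NA_real_, contig_table$length[m])
  per$length_estimated <- is.na(m) | contig_table$origin[m] == "estimated"
  # contigs absent from the table fall back to the largest observed footprint
  if (anyNA(per$contig_length)) {
    mx <- tapply(blocks$e3, blocks$contig_name, max)
    nas <- is.na(per$contig_length)
    per$contig_length[nas] <- as.numeric(mx[per$contig[nas]])
  }
  per$integrity <- per$largest_block / per$contig_length
  assigned <- if (!is.null(chromolist)) {
    asg <- assign_and_order_contigs(blocks, chromolist)
    asg$assigned_chromosome[match(per$contig, asg$contig)]
  } else {
    dt2 <- dt[, list(tot = sum(len)), by = c("contig", "ref")]
    data.table::setorder(dt2, contig, -tot, ref)
    best <- dt2[!duplicated(dt2$contig), ]
    best$ref[match(per$contig, best$contig)]
  }
  per$assigned_chromosome <- assigned
  out <- per[, c("contig", "n_blocks", "tot_aligned", "largest_block",
                 "contig_length", "integrity", "length_estimated", "n_ref",
                 "assigned_chromosome", "avg_identity")]
  rownames(out) <- NULL
  out
}
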