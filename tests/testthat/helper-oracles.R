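# Brute-force oracles and fixture builders, independent of the package's
# implementation paths.

# Evaluate the six relation predicates independently; exactly one must hold.
oracle_relation_predicates <- function(ts, te, os, oe) {
  same <- os == ts && oe == te
  c(same = same,
    larger = os <= ts && oe >= te && !same,
    alternative = ts <= os && te >= oe && !same,
    ov_left = os < ts && ts <= oe && oe < te,
    ov_right = ts < os && os <= te && oe > te,
    unrelated = oe < ts || os > te)
}

oracle_relation <- function(ts, te, os, oe) {
  p <- oracle_relation_predicates(ts, te, os, oe)
  stopifnot(sum(p) == 1)
  names(p)[p]
}

# Exhaustive-scan N/L oracle: try every k over the descending sort.
oracle_nl <- function(lengths, p) {
  srt <- sort(lengths, decreasing = TRUE)
  total <- sum(srt)
  for (k in seq_along(srt)) {
    if (sum(srt[seq_len(k)]) >= p / 100 * total) return(c(n = srt[k], l = k))
  }
  stop("unreachable")
}

# Per-base coverage oracle.
oracle_coverage <- function(starts, ends, chr_length) {
  covered <- logical(chr_length)
  for (i in seq_along(starts)) {
    s <- max(1, starts[i]); e <- min(chr_length, ends[i])
    if (s <= e) covered[s:e] <- TRUE
  }
  r <- rle(covered)
  stop_at <- cumsum(r$lengths)
  start_at <- stop_at - r$lengths + 1
  gi <- which(!r$values)
  list(covered = sum(covered),
       gaps = data.frame(start = start_at[gi], end = stop_at[gi]))
}

# Stop-at-first-failure 50% chromosome guessing oracle.
oracle_guess <- function(lengths) {
  srt <- sort(lengths, decreasing = TRUE)
  keep <- 1L
  for (i in seq_along(srt)[-1]) {
    if (srt[i] > 0.5 * srt[i - 1]) keep <- i else break
  }
  srt[seq_len(keep)]
}

# Quick raw-block table builder.
raw_blocks <- function(s1, e1, s2 = s1, e2 = e1, ref = "chr1", contig = "ctgA",
                       idy = 99, left = "", right = "") {
  n <- length(s1)
  data.frame(s1 = s1, e1 = e1, s2 = rep_len(s2, n), e2 = rep_len(e2, n),
             ref_name = rep_len(ref, n), contig_name = rep_len(contig, n),
             idy = rep_len(idy, n), left_comment = rep_len(left, n),
             right_comment = rep_len(right, n), stringsAsFactors = FALSE)
}

# Random non-degenerate interval set on one reference sequence.
random_intervals <- function(n, max_pos = 1000) {
  s <- sample.int(max_pos, n, replace = TRUE)
  w <- sample.int(max_pos %/% 4, n, replace = TRUE)
  data.frame(s = s, e = pmin(s + w, max_pos + max_pos %/% 4))
}

# Annotated-block table with counters preset (for stats-layer tests where
# relations are irrelevant or supplied by hand).
annotated_stub <- function(lengths, contig, ref, idy = 99,
                           n_same = 0, n_alternatives = 0, n_larger = 0,
                           n_ov_left = 0, n_ov_right = 0, n_unrelated = 0) {
  n <- length(lengths)
  pos <- cumsum(c(1, utils::head(lengths, -1) + 10))
  data.frame(s1 = pos, e1 = pos + lengths - 1, s2 = 1, e2 = lengths,
             ref_name = rep_len(ref, n), contig_name = rep_len(contig, n),
             idy = rep_len(idy, n), left_comment = "", right_comment = "",
             rev = FALSE, s3 = 1, e3 = lengths, length = lengths,
             len_on_chr = lengths, len_diff = 0, len_excess = 1,
             ctg_st = FALSE, ctg_end = FALSE,
             left_transloc = FALSE, left_indel = FALSE, left_loc_mis = FALSE,
             right_transloc = FALSE, right_indel = FALSE, right_loc_mis = FALSE,
             n_unrelated = rep_len(n_unrelated, n),
             n_same = rep_len(n_same, n),
             n_alternatives = rep_len(n_alternatives, n),
             n_larger = rep_len(n_larger, n),
             n_ov_left = rep_len(n_ov_left, n),
             n_ov_right = rep_len(n_ov_right, n),
             stringsAsFactors = FALSE)
}

# A small chromosome list without going through resolve_chromosomes.
chromolist_of <- function(names, lengths) {
  df <- data.frame(name = names, length = lengths, index = seq_along(names))
  attr(df, "excluded") <- data.frame(name = character(), length = numeric())
  class(df) <- c("chromosome_list", "data.frame")
  df
}
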