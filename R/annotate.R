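# Per-block derived parameters: features, junction end annotations, the six
# related-block counters and the default block filter.

#' Derive block features
#'
#' Adds the orientation flag and the derived coordinate/length columns to a
#' raw block table:
#' \describe{
#'   \item{rev}{TRUE when the contig coordinates are reversed (`s2 > e2`),
#'     i.e. the block aligns in the opposite orientation to the reference.}
#'   \item{s3, e3}{the sorted contig footprint, `s3 = min(s2,e2)`,
#'     `e3 = max(s2,e2)`; `rev` alone records direction so interval math
#'     stays uniform.}
#'   \item{length}{bases on the contig, `e3 - s3 + 1`.}
#'   \item{len_on_chr}{bases on the reference, `e1 - s1 + 1`.}
#'   \item{len_diff, len_excess}{difference and ratio of the two lengths.}
#'   \item{ctg_st, ctg_end}{TRUE on the first (minimal `s3`) and last
#'     (maximal `e3`) block of each contig; ties go to the block with the
#'     smaller `e3` (resp. larger `s3`), deterministically.}
#' }
#'
#' @param blocks raw block table from [parse_alignment_file()].
#' @return the table with feature columns added.
#' @export
derive_block_features <- function(blocks) {
  b <- blocks
  b$rev <- b$s2 > b$e2
  b$s3 <- pmin(b$s2, b$e2)
  b$e3 <- pmax(b$s2, b$e2)
  b$length <- b$e3 - b$s3 + 1
  b$len_on_chr <- b$e1 - b$s1 + 1
  b$len_diff <- b$length - b$len_on_chr
  b$len_excess <- b$length / b$len_on_chr
  b$ctg_st <- FALSE
  b$ctg_end <- FALSE
  o_st <- order(b$contig_name, b$s3, b$e3)
  b$ctg_st[o_st[!duplicated(b$contig_name[o_st])]] <- TRUE
  o_en <- order(b$contig_name, -b$e3, -b$s3)
  b$ctg_end[o_en[!duplicated(b$contig_name[o_en])]] <- TRUE
  b
}

#' Default junction keyword map
#'
#' Maps case-insensitive substrings of junction comments to the three end
#' flags.  Comments such as QUAST's "relocation, inconsistency = ..." or
#' "inversion" are retained verbatim but set no flag under the defaults.
#'
#' @return named list of character vectors of keywords.
#' @export
default_keyword_map <- function() {
  list(transloc = "translocation",
       indel = "indel",
       loc_mis = "local misassembly")
}

.match_keywords <- function(comments, keywords) {
  hit <- rep(FALSE, length(comments))
  lc <- tolower(comments)
  for (kw in keywords) hit <- hit | grepl(tolower(kw), lc, fixed = TRUE)
  hit & nzchar(comments)
}

#' Attach block-end annotations
#'
#' Scans the left and right junction comments of every block and sets the
#' translocation / indel / local-misassembly flags for each end.  Matching
#' is case-insensitive substring matching against a configurable keyword
#' map; unmatched comments are preserved verbatim and set no flag.
#'
#' @param blocks block table with `left_comment`/`right_comment`.
#' @param keyword_map see [default_keyword_map()].
#' @return the table with logical columns `left_transloc`, `left_indel`,
#'   `left_loc_mis`, `right_transloc`, `right_indel`, `right_loc_mis`.
#' @export
attach_end_annotations <- function(blocks, keyword_map = default_keyword_map()) {
  b <- blocks
  for (side in c("left", "right")) {
    cm <- b[[paste0(side, "_comment")]]
    b[[paste0(side, "_transloc")]] <- .match_keywords(cm, keyword_map$transloc)
    b[[paste0(side, "_indel")]] <- .match_keywords(cm, keyword_map$indel)
    b[[paste0(side, "_loc_mis")]] <- .match_keywords(cm, keyword_map$loc_mis)
  }
  b
}

#' Classify the relation between two reference intervals
#'
#' Exactly one of six mutually exclusive labels describes how another
#' block's reference interval relates to the interval under test:
#' \describe{
#'   \item{same}{identical endpoints.}
#'   \item{larger}{the other contains the test interval (not identical).}
#'   \item{alternative}{the other is completely contained in the test
#'     interval (not identical).}
#'   \item{ov_left}{the other overhangs the test interval on the left.}
#'   \item{ov_right}{the other overhangs it on the right.}
#'   \item{unrelated}{disjoint intervals on the same reference sequence.}
#' }
#'
#' @param test,other numeric length-2 vectors `c(start, end)`, 1-based
#'   inclusive, start <= end.
#' @param test_ref,other_ref optional reference names; supplying different
#'   names is a contract violation (relations are only defined within one
#'   reference sequence).
#' @return one of `"same"`, `"larger"`, `"alternative"`, `"ov_left"`,
#'   `"ov_right"`, `"unrelated"`.
#' @export
classify_relation <- function(test, other, test_ref = NULL, other_ref = NULL) {
  if (!is.null(test_ref) && !is.null(other_ref) && test_ref != other_ref) {
    stop("classify_relation: intervals on different reference sequences")
  }
  ts <- test[1]; te <- test[2]; os <- other[1]; oe <- other[2]
  if (ts > te || os > oe) stop("classify_relation: invalid interval (start > end)")
  if (os == ts && oe == te) return("same")
  if (os <= ts && oe >= te) return("larger")
  if (ts <= os && te >= oe) return("alternative")
  if (oe < ts || os > te) return("unrelated")
  if (os < ts) return("ov_left")
  "ov_right"
}

.count_relations_group <- function(s, e) {
  n <- length(s)
  ir <- IRanges::IRanges(start = s, end = e)
  key <- paste(s, e, sep = ":")
  eqn <- as.vector(table(key)[key])          # multiplicity incl. self
  n_same <- eqn - 1L

  contain <- IRanges::countOverlaps(ir, ir, type = "within")  # o containing b
  n_larger <- contain - eqn
  hits <- IRanges::findOverlaps(ir, ir, type = "within")
  within_cnt <- tabulate(S4Vectors::subjectHits(hits), n)     # o within b
  n_alternatives <- within_cnt - eqn

  n_unrelated <- n - IRanges::countOverlaps(ir, ir, type = "any")

  # ov_left(b) = #{o : o.e in [s_b, e_b - 1]} - #{o within [s_b, e_b - 1]}
  se <- sort(e)
  cnt_e_le <- function(x) findInterval(x, se)
  A <- cnt_e_le(e - 1) - cnt_e_le(s - 1)
  w1 <- e - 1 >= s
  B <- integer(n)
  if (any(w1)) {
    sub <- IRanges::IRanges(start = s[w1], end = e[w1] - 1)
    h2 <- IRanges::findOverlaps(ir, sub, type = "within")
    B[w1] <- tabulate(S4Vectors::subjectHits(h2), sum(w1))
  }
  n_ov_left <- ifelse(w1, A - B, 0L)
  n_ov_right <- (n - 1L) - n_same - n_larger - n_alternatives -
    n_unrelated - n_ov_left

  data.frame(n_unrelated = n_unrelated, n_same = n_same,
             n_alternatives = n_alternatives, n_larger = n_larger,
             n_ov_left = n_ov_left, n_ov_right = n_ov_right)
}

#' Count related blocks
#'
#' For every block, counts the other blocks on the same reference sequence
#' in each of the six relation classes of [classify_relation()].  The six
#' counters of a block always sum to the number of other blocks on its
#' reference sequence.  Counters are computed once over all imported
#' blocks, before any filtering.
#'
#' @param blocks feature-annotated block table.
#' @param scope `"reference"` (default: population = all other blocks on
#'   the same reference sequence) or `"contig"` (restrict the population to
#'   blocks of the same assembly contig, for sensitivity analysis).
#' @return the table with the six counter columns added.
#' @export
count_relations <- function(blocks, scope = c("reference", "contig")) {
  scope <- match.arg(scope)
  n <- nrow(blocks)
  counters <- data.frame(n_unrelated = integer(n), n_same = integer(n),
                         n_alternatives = integer(n), n_larger = integer(n),
                         n_ov_left = integer(n), n_ov_right = integer(n))
  grp <- if (scope == "reference") blocks$ref_name else
    paste(blocks$ref_name, blocks$contig_name, sep = "\r")
  for (idx in split(seq_len(n), grp)) {
    counters[idx, ] <- .count_relations_group(blocks$s1[idx], blocks$e1[idx])
  }
  cbind(blocks, counters)
}

#' Filter blocks by length and containment
#'
#' The default downstream filter: keep blocks strictly longer than
#' `min_length` bases (contig footprint length) and, unless disabled, only
#' blocks not contained in any larger block (`n_larger == 0`).  Counters
#' are not recomputed on the subset.
#'
#' @param blocks annotated block table with counters.
#' @param min_length minimum block length in bases (default 10000).
#' @param require_no_larger drop blocks with `n_larger > 0` (default TRUE).
#' @return the kept subset, order preserved.
#' @export
filter_blocks <- function(blocks, min_length = 10000, require_no_larger = TRUE) {
  if (!is.numeric(min_length) || length(min_length) != 1 || min_length < 0) {
    stop("min_length must be a single non-negative number")
  }
  keep <- blocks$length > min_length
  if (require_no_larger) keep <- keep & blocks$n_larger == 0
  out <- blocks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate blocks end to end
#'
#' Convenience wrapper running [derive_block_features()],
#' [attach_end_annotations()] and [count_relations()] in order.
#'
#' @inheritParams count_relations
#' @inheritParams attach_end_annotations
#' @return fully annotated block table.
#' @export
annotate_blocks <- function(blocks, keyword_map = default_keyword_map(),
                            scope = "reference") {
  count_relations(
    attach_end_annotations(derive_block_features(blocks), keyword_map),
    scope = scope)
}
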