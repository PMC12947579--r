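# Seeded scenario simulator: builds assembly-vs-reference comparisons with
# known ground truth and emits them in the supported alignment dialects.
# Simulation happens at the alignment-block level (never at the sequence
# level): the tool under test consumes alignments, so block-level
# simulation keeps expectations exact and generation fast.

#' Scenario configuration
#'
#' Describes a synthetic assembly-vs-reference comparison.  Contigs tile
#' the covered (non-gap) portion of each chromosome; structural events
#' inject the corresponding block structure:
#' \describe{
#'   \item{inversion}{a block with reversed contig coordinates.}
#'   \item{indel}{a contig split into two reference-adjacent blocks offset
#'     on the contig by an inserted stretch, junction comment "indel".}
#'   \item{translocation}{one contig whose consecutive blocks sit on two
#'     chromosomes, junction comment "translocation".}
#'   \item{duplication}{an extra contig whose single block is strictly
#'     contained in another block's reference interval.}
#'   \item{gap_fraction}{fraction of each chromosome left uncovered.}
#' }
#' Percent identities are drawn from a normal noise model and clipped to
#' [80, 100].  The seed fixes all randomness; the same configuration and
#' seed produce byte-identical files.
#'
#' @param chromosome_lengths lengths in bases of the reference
#'   chromosomes, in display order.
#' @param contig_length target mean contig length in bases.
#' @param p_inversion per-block probability of reversed orientation.
#' @param p_indel per-contig probability of an indel split.
#' @param indel_size inserted-stretch size range (bases).
#' @param p_translocation per chromosome-junction probability of a
#'   contig spanning two chromosomes.
#' @param p_duplication per-contig probability of emitting a contained
#'   duplicate block.
#' @param gap_fraction fraction of each chromosome left uncovered, in
#'   [0, 1).
#' @param idy_mean,idy_sd identity noise model (percent).
#' @param seed integer seed.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(chromosome_lengths = round(5e5 * 0.85^(0:4)),
                            contig_length = 20000,
                            p_inversion = 0.05,
                            p_indel = 0.10,
                            indel_size = c(200, 2000),
                            p_translocation = 0.25,
                            p_duplication = 0.03,
                            gap_fraction = 0.05,
                            idy_mean = 99, idy_sd = 0.5,
                            seed = 1L) {
  stopifnot(all(chromosome_lengths >= 1), contig_length >= 100,
            p_inversion >= 0, p_inversion <= 1,
            p_indel >= 0, p_indel <= 1,
            p_translocation >= 0, p_translocation <= 1,
            p_duplication >= 0, p_duplication <= 1)
  if (gap_fraction < 0 || gap_fraction >= 1) {
    stop("gap_fraction must be in [0, 1)")
  }
  structure(list(chromosome_lengths = chromosome_lengths,
                 contig_length = contig_length,
                 p_inversion = p_inversion, p_indel = p_indel,
                 indel_size = indel_size,
                 p_translocation = p_translocation,
                 p_duplication = p_duplication,
                 gap_fraction = gap_fraction,
                 idy_mean = idy_mean, idy_sd = idy_sd,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# split `total` into n parts of at least `min_part`, randomly
.random_composition <- function(total, n, min_part = 1) {
  if (n == 1) return(total)
  free <- total - n * min_part
  if (free < 0) stop("cannot split ", total, " into ", n, " parts >= ", min_part)
  cuts <- sort(sample.int(free + 1, n - 1, replace = TRUE) - 1L)
  parts <- diff(c(0, cuts, free))
  parts + min_part
}

#' Simulate a ground-truth scenario
#'
#' Generates the block structure described by the configuration and writes
#' it in both supported dialects plus the conversion file and a truth
#' JSON.  The returned ground truth carries, per block, the true
#' orientation and junction events, and per chromosome the true gap list
#' and covered fraction; [expected_tables()] turns it into expected
#' downstream values through an independent brute-force code path.
#'
#' @param config a [scenario_config()].
#' @param out_dir optional output directory; when given, writes
#'   `alignments_quast.tsv`, `alignments_nucmer.coords`, `conversion.tsv`
#'   and `truth.json`.
#' @return list with `truth` (list: `config`, `chromosomes`, `blocks`,
#'   `contigs`, `gaps`) and `files` (named paths, when `out_dir` given).
#' @export
simulate_scenario <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n_chr <- length(config$chromosome_lengths)
  chr_names <- sprintf("chr%02d", seq_len(n_chr))

  gaps <- list()
  contig_rows <- list()   # per contig: list of block rows
  ctg_counter <- 0L

  for (ci in seq_len(n_chr)) {
    L <- config$chromosome_lengths[ci]
    G <- round(config$gap_fraction * L)
    # alternate covered/gap segments; gaps never at position 1 so the
    # first covered segment is non-empty
    n_gaps <- if (G > 0) sample(1:3, 1) else 0L
    if (n_gaps > 0 && G < n_gaps) n_gaps <- 1L
    gap_lens <- if (n_gaps > 0) .random_composition(G, n_gaps) else integer(0)
    cov_lens <- .random_composition(L - G, n_gaps + 1,
                                    min_part = max(1, min(200, floor((L - G) / (n_gaps + 1)))))
    pos <- 1
    seg_id <- 0
    for (k in seq_len(n_gaps + 1)) {
      seg_len <- cov_lens[k]
      seg_start <- pos
      seg_end <- pos + seg_len - 1
      pos <- seg_end + 1
      if (k <= n_gaps) {
        gaps[[length(gaps) + 1]] <- data.frame(
          chromosome = chr_names[ci], start = pos, end = pos + gap_lens[k] - 1)
        pos <- pos + gap_lens[k]
      }
      # tile the covered segment with contigs
      n_ctg <- max(1L, round(seg_len / config$contig_length))
      ctg_lens <- .random_composition(seg_len, n_ctg,
                                      min_part = max(1, min(200, floor(seg_len / n_ctg))))
      cpos <- seg_start
      for (cl in ctg_lens) {
        ctg_counter <- ctg_counter + 1L
        contig_rows[[ctg_counter]] <- list(
          ref = chr_names[ci], s1 = cpos, e1 = cpos + cl - 1)
        cpos <- cpos + cl
      }
      seg_id <- seg_id + 1
    }
  }

  # translocations: merge the last contig of chromosome i with the first
  # contig of chromosome i+1 into one contig
  ctg_ref <- vapply(contig_rows, function(d) d$ref[[1]], character(1))
  merge_with_next <- rep(FALSE, length(contig_rows))
  for (ci in seq_len(n_chr - 1)) {
    if (stats::runif(1) < config$p_translocation) {
      i_last <- max(which(ctg_ref == chr_names[ci]))
      merge_with_next[i_last] <- TRUE
    }
  }

  # assemble contigs: apply indels (split into two ref-adjacent blocks with
  # a contig-side insertion) and inversions; assign contig coordinates
  blocks <- list()
  contigs <- list()
  ctg_id <- 0L
  i <- 1L
  while (i <= length(contig_rows)) {
    pieces <- as.data.frame(data.table::rbindlist(contig_rows[i]))
    while (merge_with_next[i] && i < length(contig_rows)) {
      i <- i + 1L
      pieces <- rbind(pieces, as.data.frame(contig_rows[[i]]))
    }
    ctg_id <- ctg_id + 1L
    ctg_name <- sprintf("ctg_%04d", ctg_id)

    # each piece (one reference interval) may be split by an indel; a
    # segment records its reference interval, the contig-side insertion
    # preceding it and the junction event at its left end
    segs <- list()
    for (p in seq_len(nrow(pieces))) {
      s1 <- pieces$s1[p]; e1 <- pieces$e1[p]
      ev <- if (p == 1) NA_character_ else "translocation"
      plen <- e1 - s1 + 1
      if (stats::runif(1) < config$p_indel && plen >= 1000) {
        cut <- s1 + sample(seq(200, plen - 200), 1) - 1
        ins <- sample(seq(config$indel_size[1], config$indel_size[2]), 1)
        segs[[length(segs) + 1]] <- list(ref = pieces$ref[p], s1 = s1,
                                         e1 = cut, ins = 0, ev = ev)
        segs[[length(segs) + 1]] <- list(ref = pieces$ref[p], s1 = cut + 1,
                                         e1 = e1, ins = ins, ev = "indel")
      } else {
        segs[[length(segs) + 1]] <- list(ref = pieces$ref[p], s1 = s1,
                                         e1 = e1, ins = 0, ev = ev)
      }
    }

    cpos <- 1
    for (sg in segs) {
      cpos <- cpos + sg$ins
      blen <- sg$e1 - sg$s1 + 1
      rev <- stats::runif(1) < config$p_inversion
      s2 <- if (rev) cpos + blen - 1 else cpos
      e2 <- if (rev) cpos else cpos + blen - 1
      blocks[[length(blocks) + 1]] <- list(
        ref = sg$ref, s1 = sg$s1, e1 = sg$e1,
        contig = ctg_name, s2 = s2, e2 = e2, rev = rev,
        left_event = sg$ev, right_event = NA_character_,
        is_duplicate = FALSE)
      cpos <- cpos + blen
    }
    contigs[[ctg_id]] <- list(name = ctg_name, length = cpos - 1)
    i <- i + 1L
  }

  blocks <- as.data.frame(data.table::rbindlist(blocks))
  # right events mirror the following block's left event within a contig
  n <- nrow(blocks)
  if (n >= 2) {
    same_ctg <- blocks$contig[-1] == blocks$contig[-n]
    blocks$right_event[c(same_ctg, FALSE)] <- blocks$left_event[c(FALSE, same_ctg)]
  }

  contigs <- as.data.frame(data.table::rbindlist(contigs))

  # duplications: an extra one-block contig strictly contained in a host
  # block; at most one duplicate per host keeps containment counts exact
  host_ok <- which(!blocks$rev & (blocks$e1 - blocks$s1 + 1) >= 1000 &
                     is.na(blocks$left_event) & is.na(blocks$right_event))
  n_dup <- stats::rbinom(1, length(host_ok), config$p_duplication)
  if (n_dup > 0) {
    hosts <- sample(host_ok, n_dup)
    dup_rows <- vector("list", n_dup)
    dup_ctgs <- vector("list", n_dup)
    for (k in seq_len(n_dup)) {
      h <- hosts[k]
      hs <- blocks$s1[h]; he <- blocks$e1[h]
      dlen <- max(100, floor((he - hs + 1) * stats::runif(1, 0.2, 0.6)))
      ds <- hs + sample(seq_len(he - hs + 1 - dlen - 1), 1)
      de <- ds + dlen - 1
      ctg_id <- ctg_id + 1L
      nm <- sprintf("dup_%04d", ctg_id)
      dup_rows[[k]] <- list(ref = blocks$ref[h], s1 = ds, e1 = de,
                            contig = nm, s2 = 1, e2 = dlen, rev = FALSE,
                            left_event = NA_character_,
                            right_event = NA_character_, is_duplicate = TRUE)
      dup_ctgs[[k]] <- list(name = nm, length = dlen)
    }
    blocks <- rbind(blocks, as.data.frame(data.table::rbindlist(dup_rows)))
    contigs <- rbind(contigs, as.data.frame(data.table::rbindlist(dup_ctgs)))
  }

  blocks$idy <- round(pmin(100, pmax(80, stats::rnorm(nrow(blocks),
                                                      config$idy_mean,
                                                      config$idy_sd))), 2)

  gaps <- if (length(gaps)) as.data.frame(data.table::rbindlist(gaps)) else
    data.frame(chromosome = character(), start = numeric(), end = numeric())
  chromosomes <- data.frame(name = chr_names,
                            length = config$chromosome_lengths)

  truth <- list(config = config, chromosomes = chromosomes, blocks = blocks,
                contigs = contigs, gaps = gaps)

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      quast = file.path(out_dir, "alignments_quast.tsv"),
      nucmer = file.path(out_dir, "alignments_nucmer.coords"),
      conversion = file.path(out_dir, "conversion.tsv"),
      truth = file.path(out_dir, "truth.json"))
    .emit_quast(truth, files$quast)
    .emit_nucmer(truth, files$nucmer)
    writeLines(sprintf("%s\t%d", chromosomes$name, chromosomes$length),
               files$conversion)
    jsonlite::write_json(list(chromosomes = chromosomes,
                              blocks = blocks, contigs = contigs,
                              gaps = gaps, seed = config$seed),
                         files$truth, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  list(truth = truth, files = files)
}

.emit_quast <- function(truth, path) {
  b <- truth$blocks
  row_txt <- sprintf("%d\t%d\t%d\t%d\t%s\t%s\t%s",
                     as.integer(b$s1), as.integer(b$e1),
                     as.integer(b$s2), as.integer(b$e2),
                     b$ref, b$contig, sprintf("%.2f", b$idy))
  ctgs <- unique(b$contig)
  clen <- truth$contigs$length[match(ctgs, truth$contigs$name)]
  decl_txt <- sprintf("CONTIG\t%s\t%d", ctgs, as.integer(clen))
  idx <- split(seq_len(nrow(b)), factor(b$contig, levels = ctgs))
  chunks <- vector("list", length(ctgs))
  for (k in seq_along(ctgs)) {
    sel <- idx[[k]]
    body <- row_txt[sel]
    cm <- !is.na(b$left_event[sel]) & seq_along(sel) > 1
    if (any(cm)) {
      pieces <- rbind(ifelse(cm, b$left_event[sel], NA_character_), body)
      body <- pieces[!is.na(pieces)]
    }
    chunks[[k]] <- c(decl_txt[k], body)
  }
  writeLines(c("S1\tE1\tS2\tE2\tReference\tContig\tIDY", unlist(chunks)),
             path)
}

.emit_nucmer <- function(truth, path) {
  b <- truth$blocks
  hdr <- c("reference.fa assembly.fa", "NUCMER", "",
           "[S1]\t[E1]\t[S2]\t[E2]\t[LEN 1]\t[LEN 2]\t[% IDY]\t[TAGS]",
           "===============================================================")
  rows <- sprintf("%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s\t%s",
                  as.integer(b$s1), as.integer(b$e1),
                  as.integer(b$s2), as.integer(b$e2),
                  as.integer(b$e1 - b$s1 + 1),
                  as.integer(abs(b$e2 - b$s2) + 1),
                  sprintf("%.2f", b$idy), b$ref, b$contig)
  writeLines(c(hdr, rows), path)
}

#' Expected tables from ground truth
#'
#' Computes, by brute force directly from the truth intervals and through
#' a code path independent of the annotate/stats modules, the values the
#' pipeline is expected to produce: per-chromosome covered bases, covered
#' fraction and gap list; per-block orientation and end flags; the six
#' relation counters; the all-category genome fraction; and the number of
#' blocks that the default filter removes because of containment
#' (`n_larger > 0`).
#'
#' @param truth truth component of [simulate_scenario()].
#' @param min_length default-filter length threshold.
#' @return list of expected values.
#' @export
expected_tables <- function(truth, min_length = 10000) {
  b <- truth$blocks
  chr <- truth$chromosomes

  # per-chromosome coverage by per-base marking
  coverage <- lapply(seq_len(nrow(chr)), function(i) {
    L <- chr$length[i]
    covered <- logical(L)
    sel <- which(b$ref == chr$name[i])
    for (j in sel) covered[b$s1[j]:b$e1[j]] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    gap_idx <- which(!r$values)
    list(chromosome = chr$name[i],
         covered = sum(covered),
         covered_fraction = sum(covered) / L,
         gaps = data.frame(start = starts[gap_idx], end = ends[gap_idx]))
  })
  names(coverage) <- chr$name

  # six counters by explicit pairwise predicates, per reference sequence
  n <- nrow(b)
  counters <- data.frame(n_unrelated = integer(n), n_same = integer(n),
                         n_alternatives = integer(n), n_larger = integer(n),
                         n_ov_left = integer(n), n_ov_right = integer(n))
  for (i in seq_len(n)) {
    o <- which(b$ref == b$ref[i])
    o <- o[o != i]
    ts <- b$s1[i]; te <- b$e1[i]
    os <- b$s1[o]; oe <- b$e1[o]
    same <- os == ts & oe == te
    larger <- os <= ts & oe >= te & !same
    alt <- ts <= os & te >= oe & !same
    unrel <- oe < ts | os > te
    ovl <- !same & !larger & !alt & !unrel & os < ts
    ovr <- !same & !larger & !alt & !unrel & os > ts
    counters[i, ] <- c(sum(unrel), sum(same), sum(alt), sum(larger),
                       sum(ovl), sum(ovr))
  }

  lengths2 <- abs(b$e2 - b$s2) + 1
  removed_by_larger <- sum(lengths2 > min_length & counters$n_larger > 0)

  list(
    coverage = coverage,
    covered_fraction = vapply(coverage, `[[`, numeric(1), "covered_fraction"),
    gaps = lapply(coverage, `[[`, "gaps"),
    counters = counters,
    rev = b$rev,
    left_indel = !is.na(b$left_event) & b$left_event == "indel",
    left_transloc = !is.na(b$left_event) & b$left_event == "translocation",
    right_indel = !is.na(b$right_event) & b$right_event == "indel",
    right_transloc = !is.na(b$right_event) & b$right_event == "translocation",
    genome_fraction_all = 1.00,
    tot_length = sum(lengths2),
    n_blocks = n,
    n_duplicates = sum(b$is_duplicate),
    removed_by_larger_filter = removed_by_larger)
}
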