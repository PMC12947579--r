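test_that("block features follow the orientation and length conventions", {
  b <- derive_block_features(raw_blocks(
    s1 = c(1000, 1000, 1), e1 = c(1100, 1100, 100),
    s2 = c(10, 110, 1), e2 = c(110, 10, 120),
    contig = c("a", "b", "c")))
  # forward identity-length block
  expect_false(b$rev[1])
  expect_equal(unlist(b[1, c("s3", "e3", "length", "len_on_chr", "len_diff")],
                      use.names = FALSE), c(10, 110, 101, 101, 0))
  expect_equal(b$len_excess[1], 1.0)
  # reversed block: sorted footprint, rev flag
  expect_true(b$rev[2])
  expect_equal(unlist(b[2, c("s3", "e3", "length")], use.names = FALSE),
               c(10, 110, 101))
  # contig longer than its reference footprint
  expect_equal(unlist(b[3, c("length", "len_on_chr", "len_diff")],
                      use.names = FALSE), c(120, 100, 20))
  expect_equal(b$len_excess[3], 1.2)
})

test_that("contig start/end flags mark the coordinate extremes", {
  b <- derive_block_features(raw_blocks(
    s1 = c(1, 200, 400), e1 = c(100, 300, 500),
    s2 = c(201, 1, 101), e2 = c(300, 100, 200)))
  expect_equal(b$ctg_st, c(FALSE, TRUE, FALSE))
  expect_equal(b$ctg_end, c(TRUE, FALSE, FALSE))
  # single-block contig carries both flags
  one <- derive_block_features(raw_blocks(1, 50))
  expect_true(one$ctg_st && one$ctg_end)
  # tie on minimal s3: the smaller e3 wins ctg_st
  tie <- derive_block_features(raw_blocks(
    s1 = c(1, 200), e1 = c(100, 300), s2 = c(1, 1), e2 = c(80, 120)))
  expect_equal(tie$ctg_st, c(TRUE, FALSE))
  expect_equal(tie$ctg_end, c(FALSE, TRUE))
})

test_that("feature derivation is permutation-invariant", {
  set.seed(42)
  b0 <- raw_blocks(s1 = c(1, 150, 300, 500), e1 = c(100, 280, 450, 620),
                   s2 = c(1, 101, 240, 1), e2 = c(100, 230, 390, 121),
                   contig = c("a", "a", "a", "b"))
  f0 <- derive_block_features(b0)
  perm <- sample(nrow(b0))
  f1 <- derive_block_features(b0[perm, ])
  key0 <- paste(f0$contig_name, f0$s1)
  key1 <- paste(f1$contig_name, f1$s1)
  m <- match(key0, key1)
  for (col in c("rev", "s3", "e3", "length", "ctg_st", "ctg_end")) {
    expect_equal(f1[[col]][m], f0[[col]], info = col)
  }
})

test_that("end annotations follow the keyword map", {
  b <- derive_block_features(raw_blocks(
    s1 = c(1, 200, 400), e1 = c(100, 300, 500),
    right = c("translocation", "", ""),
    left = c("", "indel: gap at junction", "relocation, inconsistency = 12000")))
  a <- attach_end_annotations(b)
  expect_true(a$right_transloc[1])
  expect_false(any(a$right_indel[1], a$right_loc_mis[1]))
  expect_true(a$left_indel[2])
  # unmatched comments set no flag but are retained verbatim
  expect_false(any(a$left_transloc[3], a$left_indel[3], a$left_loc_mis[3]))
  expect_equal(a$left_comment[3], "relocation, inconsistency = 12000")
  # matching is case-insensitive and configurable
  a2 <- attach_end_annotations(b, keyword_map = list(
    transloc = "translocation", indel = "indel",
    loc_mis = c("local misassembly", "relocation")))
  expect_true(a2$left_loc_mis[3])
})

test_that("relation classification matches the stated contracts", {
  expect_equal(classify_relation(c(100, 200), c(100, 200)), "same")
  expect_equal(classify_relation(c(100, 200), c(50, 300)), "larger")
  expect_equal(classify_relation(c(50, 300), c(100, 200)), "alternative")
  expect_equal(classify_relation(c(100, 200), c(250, 300)), "unrelated")
  expect_equal(classify_relation(c(100, 200), c(50, 150)), "ov_left")
  expect_equal(classify_relation(c(100, 200), c(150, 250)), "ov_right")
  expect_error(classify_relation(c(1, 2), c(1, 2), "chr1", "chr2"),
               "different reference")
})

test_that("classification agrees with the six-predicate oracle and is dual", {
  set.seed(1)
  for (i in 1:2000) {
    a <- sort(sample.int(50, 2, replace = TRUE))
    b <- sort(sample.int(50, 2, replace = TRUE))
    lab <- classify_relation(a, b)
    expect_identical(lab, oracle_relation(a[1], a[2], b[1], b[2]))
    rev_lab <- classify_relation(b, a)
    dual <- c(same = "same", larger = "alternative", alternative = "larger",
              ov_left = "ov_right", ov_right = "ov_left",
              unrelated = "unrelated")
    expect_identical(rev_lab, unname(dual[lab]))
  }
})

test_that("relation counters match hand-enumerated cases", {
  # single block on a chromosome
  one <- count_relations(derive_block_features(raw_blocks(100, 200)))
  expect_equal(sum(one[, c("n_unrelated", "n_same", "n_alternatives",
                           "n_larger", "n_ov_left", "n_ov_right")]), 0)
  # A=[1,100], B=[50,150], C=[200,300]
  abc <- count_relations(derive_block_features(raw_blocks(
    s1 = c(1, 50, 200), e1 = c(100, 150, 300),
    contig = c("a", "b", "c"))))
  expect_equal(abc$n_ov_right, c(1, 0, 0))
  expect_equal(abc$n_ov_left, c(0, 1, 0))
  expect_equal(abc$n_unrelated, c(1, 1, 2))
  expect_equal(abc$n_same + abc$n_alternatives + abc$n_larger, c(0, 0, 0))
  # identical pair
  same <- count_relations(derive_block_features(raw_blocks(
    s1 = c(1, 1), e1 = c(100, 100), contig = c("a", "b"))))
  expect_equal(same$n_same, c(1, 1))
})

test_that("counters agree with per-pair classification and sum to n-1", {
  set.seed(7)
  for (trial in 1:25) {
    n <- sample(2:40, 1)
    iv <- random_intervals(n, max_pos = 60)  # small space forces collisions
    refs <- sample(c("c1", "c2"), n, replace = TRUE)
    blocks <- derive_block_features(raw_blocks(
      s1 = iv$s, e1 = iv$e, ref = refs,
      contig = paste0("t", seq_len(n))))
    got <- count_relations(blocks)
    for (i in seq_len(n)) {
      pop <- setdiff(which(refs == refs[i]), i)
      labs <- vapply(pop, function(j) {
        classify_relation(c(iv$s[i], iv$e[i]), c(iv$s[j], iv$e[j]))
      }, character(1))
      cnt <- table(factor(labs, levels = c("unrelated", "same", "alternative",
                                           "larger", "ov_left", "ov_right")))
      expect_equal(unlist(got[i, c("n_unrelated", "n_same", "n_alternatives",
                                   "n_larger", "n_ov_left", "n_ov_right")],
                          use.names = FALSE),
                   as.vector(cnt))
      expect_equal(sum(cnt), length(pop))
    }
  }
})

test_that("contig-scoped counting restricts the population", {
  blocks <- derive_block_features(raw_blocks(
    s1 = c(1, 1, 200), e1 = c(100, 100, 300),
    contig = c("a", "b", "a")))
  ref_scope <- count_relations(blocks, scope = "reference")
  ctg_scope <- count_relations(blocks, scope = "contig")
  expect_equal(ref_scope$n_same[1], 1)   # the twin on contig b counts
  expect_equal(ctg_scope$n_same[1], 0)   # only contig-a blocks in population
  expect_equal(ctg_scope$n_unrelated[1], 1)
})

test_that("the default filter keeps long, uncontained blocks", {
  b <- annotated_stub(lengths = c(15000, 15000, 5000), contig = "a",
                      ref = "chr1")
  b$n_larger <- c(0, 1, 0)
  kept <- filter_blocks(b)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$length, 15000)
  expect_equal(nrow(filter_blocks(b, min_length = 0, require_no_larger = FALSE)), 3)
  expect_equal(nrow(filter_blocks(b, min_length = 1e6)), 0)
  expect_error(filter_blocks(b, min_length = -1), "non-negative")
  # monotonicity: raising the threshold never keeps more blocks
  set.seed(3)
  lens <- sample.int(50000, 200, replace = TRUE)
  bb <- annotated_stub(lengths = lens, contig = "a", ref = "chr1")
  counts <- vapply(c(0, 1000, 5000, 10000, 20000, 60000),
                   function(m) nrow(filter_blocks(bb, min_length = m)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})
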