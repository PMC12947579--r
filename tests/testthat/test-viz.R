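viz_fixture <- function() {
  cl <- chromolist_of(c("chr1", "chr2"), c(2000, 1500))
  ctab <- sequence_table(c("a", "b"), c(1000, 400), "declared")
  blocks <- count_relations(derive_block_features(raw_blocks(
    s1 = c(1, 500, 1), e1 = c(400, 699, 100),
    s2 = c(1, 401, 1), e2 = c(400, 600, 100),
    ref = c("chr1", "chr1", "chr2"), contig = c("a", "a", "b"))))
  asg <- assign_and_order_contigs(blocks, cl)
  list(cl = cl, ctab = ctab, blocks = blocks, asg = asg)
}

test_that("bubble cells aggregate per contig/chromosome intersection", {
  f <- viz_fixture()
  bub <- bubble_data(f$blocks, f$asg, f$cl, f$ctab)
  a <- bub[bub$contig == "a", ]
  expect_equal(nrow(a), 1)
  expect_equal(a$tot_length, 600)
  expect_equal(a$integrity, 0.4)
  expect_equal(a$n_blocks, 2)
  # a contig split across chromosomes yields two cells on one x column
  split_blocks <- count_relations(derive_block_features(raw_blocks(
    s1 = c(1, 1), e1 = c(300, 100), s2 = c(1, 301), e2 = c(300, 400),
    ref = c("chr1", "chr2"), contig = "s")))
  asg2 <- assign_and_order_contigs(split_blocks, f$cl)
  bub2 <- bubble_data(split_blocks, asg2, f$cl,
                      sequence_table("s", 400, "declared"))
  expect_equal(nrow(bub2), 2)
  expect_equal(length(unique(bub2$x_index)), 1)
  expect_equal(sort(bub2$y_index), c(1, 2))
})

test_that("bubble totals conserve the filtered block lengths", {
  sim <- simulate_scenario(scenario_config(seed = 13))
  b <- sim$truth$blocks
  blocks <- count_relations(derive_block_features(raw_blocks(
    s1 = b$s1, e1 = b$e1, s2 = b$s2, e2 = b$e2, ref = b$ref, contig = b$contig)))
  cl <- chromolist_of(sim$truth$chromosomes$name, sim$truth$chromosomes$length)
  flt <- filter_blocks(blocks, min_length = 0)
  asg <- assign_and_order_contigs(flt, cl)
  ctab <- sequence_table(sim$truth$contigs$name, sim$truth$contigs$length,
                         "declared")
  bub <- bubble_data(flt, asg, cl, ctab)
  expect_equal(sum(bub$tot_length),
               sum(flt$length[flt$ref_name %in% cl$name]))
  expect_true(all(bub$integrity > 0 & bub$integrity <= 1))
})

test_that("the integrity gradient hits its anchors and clamps", {
  expect_equal(integrity_colour(1), "#FFFFFF")
  expect_equal(integrity_colour(0.5), "#FFFF00")
  expect_equal(integrity_colour(0.3), "#FF0000")
  expect_equal(integrity_colour(0.15), "#0000FF")
  expect_equal(integrity_colour(0.03), "#000000")
  expect_equal(integrity_colour(2), "#FFFFFF")   # clamped
  # monotone red channel between black and blue anchors
  reds <- grDevices::col2rgb(integrity_colour(seq(0.05, 1, by = 0.05)))["red", ]
  expect_true(all(diff(reds) >= 0))
})

test_that("genome tracks carry connectors and gap complements", {
  cl <- chromolist_of("chr1", 200)
  blocks <- count_relations(derive_block_features(raw_blocks(
    s1 = c(1, 180), e1 = c(100, 200), s2 = c(1, 101), e2 = c(100, 121))))
  tr <- genome_tracks(blocks, cl, kind = "blocks")
  expect_equal(nrow(tr), 2)
  expect_equal(tr$connector, c(FALSE, TRUE))
  gp <- genome_tracks(blocks, cl, kind = "gaps")
  expect_equal(gp$start, 101)
  expect_equal(gp$end, 179)
  # an empty chromosome is one full-length gap
  empty <- genome_tracks(blocks[0, ], cl, kind = "gaps")
  expect_equal(empty$start, 1)
  expect_equal(empty$end, 200)
  # block-track union and gaps partition the chromosome
  both <- sum(tr$end - tr$start + 1) + sum(gp$end - gp$start + 1)
  expect_equal(both, 200)
})

test_that("dotplot segments are polarized by orientation", {
  cl <- chromolist_of("chr1", 1000)
  blocks <- count_relations(derive_block_features(raw_blocks(
    s1 = c(1, 101), e1 = c(100, 200), s2 = c(1, 200), e2 = c(100, 101),
    contig = c("f", "r"))))
  v <- chromosome_view(blocks, "chr1", cl)
  f <- v$dots[v$dots$contig == "f", ]
  expect_equal(c(f$x1, f$y1, f$x2, f$y2), c(1, 1, 100, 100))     # positive slope
  r <- v$dots[v$dots$contig == "r", ]
  expect_equal(c(r$x1, r$y1, r$x2, r$y2), c(101, 200, 200, 101)) # negative slope
  expect_equal(r$orientation, "reverse")
  expect_error(chromosome_view(blocks, "chrX", cl), "valid names")
})

test_that("a contig insertion draws a dotted connector between diagonals", {
  cl <- chromolist_of("chr1", 1000)
  # adjacent on the reference, gapped on the contig (insertion of 50)
  blocks <- count_relations(derive_block_features(raw_blocks(
    s1 = c(1, 101), e1 = c(100, 200), s2 = c(1, 151), e2 = c(100, 250))))
  v <- chromosome_view(blocks, "chr1", cl)
  expect_equal(v$dots$connector, c(FALSE, TRUE))
  # the lanes view connects only reference-side discontinuities
  expect_equal(v$lanes$connector, c(FALSE, FALSE))
  gapped <- count_relations(derive_block_features(raw_blocks(
    s1 = c(1, 151), e1 = c(100, 250), s2 = c(1, 101), e2 = c(100, 200))))
  v2 <- chromosome_view(gapped, "chr1", cl)
  expect_equal(v2$lanes$connector, c(FALSE, TRUE))
})

test_that("threshold bars mirror the category statistics", {
  set.seed(41)
  b <- annotated_stub(lengths = sample.int(30000, 100, replace = TRUE),
                      contig = "a", ref = "chr1")
  single <- threshold_bars(b, thresholds = 0)
  expect_equal(single$tot_length, sum(b$length))
  expect_equal(single$n_blocks, 100)
  above <- threshold_bars(b, thresholds = c(0, 1000, 10000))
  expect_true(all(diff(above$tot_length) >= 0))
  between <- threshold_bars(b, thresholds = c(0, 1000, 10000), mode = "between")
  expect_equal(sum(between$n_blocks), 100)
  expect_equal(sum(between$tot_length), sum(b$length))
})

test_that("rendering writes files without touching the data layer", {
  f <- viz_fixture()
  bub <- bubble_data(f$blocks, f$asg, f$cl, f$ctab)
  json_before <- plot_data_json(bub)
  dir <- withr::local_tempdir()
  html <- file.path(dir, "bubble.html")
  render_plot(bub, html, format = "html")
  expect_true(file.exists(html))
  txt <- paste(readLines(html, warn = FALSE), collapse = "\n")
  expect_match(txt, "<svg", fixed = TRUE)
  expect_match(txt, "viewBox", fixed = TRUE)
  expect_identical(plot_data_json(bub), json_before)
  # svg and png formats
  render_plot(bub, file.path(dir, "b.svg"), format = "svg")
  expect_true(file.size(file.path(dir, "b.svg")) > 0)
  render_plot(bub, file.path(dir, "b.png"), format = "png")
  expect_true(file.size(file.path(dir, "b.png")) > 0)
  # empty data renders a valid page, and serialization is deterministic
  empty <- bubble_data(f$blocks[0, ], f$asg, f$cl, f$ctab)
  render_plot(empty, file.path(dir, "e.html"), format = "html")
  expect_true(file.exists(file.path(dir, "e.html")))
  expect_identical(plot_data_json(empty), plot_data_json(empty))
})
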