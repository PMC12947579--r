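test_that("alignment rows map directly onto raw blocks", {
  res <- parse_alignment_file(text = c(
    "S1\tE1\tS2\tE2\tReference\tContig\tIDY",
    "1\t100\t1\t100\tchr1\tctgA\t99.5"))
  b <- res$blocks
  expect_equal(nrow(b), 1)
  expect_equal(unlist(b[1, c("s1", "e1", "s2", "e2")], use.names = FALSE),
               c(1, 100, 1, 100))
  expect_equal(b$ref_name, "chr1")
  expect_equal(b$contig_name, "ctgA")
  expect_equal(b$idy, 99.5)
})

test_that("reversed rows are accepted and preserved raw", {
  res <- parse_alignment_file(text = c(
    "S1\tE1\tS2\tE2\tReference\tContig\tIDY",
    "1\t100\t110\t10\tchr1\tctgA\t98"))
  expect_equal(res$blocks$s2, 110)
  expect_equal(res$blocks$e2, 10)
})

test_that("junction comments attach to both flanking blocks", {
  res <- parse_alignment_file(text = c(
    "S1\tE1\tS2\tE2\tReference\tContig\tIDY",
    "1\t100\t1\t100\tchr1\tctgA\t99",
    "translocation",
    "200\t300\t101\t201\tchr1\tctgA\t99"))
  expect_equal(res$blocks$right_comment[1], "translocation")
  expect_equal(res$blocks$left_comment[2], "translocation")
  expect_equal(res$blocks$left_comment[1], "")
  expect_equal(res$blocks$right_comment[2], "")
})

test_that("every line is classified exactly once", {
  txt <- c("S1\tE1\tS2\tE2\tReference\tContig\tIDY",
           "CONTIG\tctgA\t500",
           "1\t100\t1\t100\tchr1\tctgA\t99",
           "indel: gap 12",
           "150\t250\t101\t201\tchr1\tctgA\t99",
           "",
           "300\t200\t1\t50\tchr1\tctgB\t99")   # rejected (e1 < s1)
  res <- parse_alignment_file(text = txt)
  expect_equal(sum(res$line_classes), length(txt))
  expect_equal(unname(res$line_classes["alignment"]), 3)
  expect_equal(unname(res$line_classes["declaration"]), 1)
  expect_equal(unname(res$line_classes["comment"]), 1)
  expect_equal(unname(res$line_classes["header"]), 2)
  expect_equal(res$rejected, 1)
  expect_equal(nrow(res$blocks), 2)
})

test_that("declared contigs keep their length, others are estimated", {
  res <- parse_alignment_file(text = c(
    "S1\tE1\tS2\tE2\tReference\tContig\tIDY",
    "CONTIG\tctgA\t500",
    "1\t100\t1\t100\tchr1\tctgA\t99",
    "200\t260\t30\t90\tchr1\tctgB\t99"))
  tab <- res$contigs
  expect_equal(tab$length[tab$name == "ctgA"], 500)
  expect_equal(tab$origin[tab$name == "ctgA"], "declared")
  expect_equal(tab$length[tab$name == "ctgB"], 90)
  expect_equal(tab$origin[tab$name == "ctgB"], "estimated")
})

test_that("the two dialects parse to identical block lists", {
  cfg <- scenario_config(chromosome_lengths = c(40000, 25000), seed = 11)
  dir <- withr::local_tempdir()
  sim <- simulate_scenario(cfg, out_dir = dir)
  q <- parse_alignment_file(sim$files$quast)
  n <- parse_alignment_file(sim$files$nucmer)
  expect_equal(q$dialect, "quast")
  expect_equal(n$dialect, "nucmer")
  cols <- c("s1", "e1", "s2", "e2", "ref_name", "contig_name", "idy")
  expect_equal(q$blocks[, cols], n$blocks[, cols])
})

test_that("an input without alignment rows is an error", {
  expect_error(parse_alignment_file(text = c("S1\tE1\tS2\tE2\tReference\tContig\tIDY")),
               "empty alignment")
  expect_error(parse_alignment_file("/nonexistent/file.tsv"), "cannot read")
})

test_that("conversion files parse in order and tolerate extra columns", {
  expect_equal(parse_conversion_file(text = c("chr1\t1000", "chr2\t600"))$name,
               c("chr1", "chr2"))
  expect_equal(parse_conversion_file(text = character(0)),
               sequence_table())
  t3 <- parse_conversion_file(text = "chr1\t1000\tMyChr")
  expect_equal(t3$length, 1000)
  expect_error(parse_conversion_file(text = "chr1\tabc"), "line 1")
})

test_that("QUAST report parsing keeps values as strings", {
  m <- parse_quast_report(text = c("Genome fraction (%)\t94.5", "",
                                   "N50\t123456"))
  expect_equal(unname(m["Genome fraction (%)"]), "94.5")
  expect_equal(unname(m["N50"]), "123456")
  expect_warning(m2 <- parse_quast_report(text = c("k\t1", "k\t2")),
                 "duplicate")
  expect_equal(unname(m2["k"]), "2")
  expect_warning(m3 <- parse_quast_report("/nonexistent/report.tsv"),
                 "not found")
  expect_length(m3, 0)
})

test_that("save and load round-trip a dataset field for field", {
  dir <- withr::local_tempdir()
  cfg <- scenario_config(seed = 3)
  sim <- simulate_scenario(cfg, out_dir = file.path(dir, "scen"))
  conv <- sim$files$conversion
  ds <- import_alignment(sim$files$quast, conversion_file = conv, name = "rt")
  out <- file.path(dir, "ds")
  save_dataset(ds, out)
  ds2 <- load_dataset(out)
  expect_equal(ds2$blocks, ds$blocks)
  expect_equal(ds2$ref_sequences, ds$ref_sequences)
  expect_equal(ds2$contig_sequences, ds$contig_sequences)
  expect_equal(ds2$experiment_name, ds$experiment_name)
  expect_equal(ds2$conversion, ds$conversion)
  # second save overwrites with an identical manifest
  save_dataset(ds, out)
  m1 <- readLines(file.path(out, "manifest.json"))
  save_dataset(ds2, out)
  expect_identical(readLines(file.path(out, "manifest.json")), m1)
})

test_that("missing manifest pieces fail loading with a named error", {
  dir <- withr::local_tempdir()
  expect_error(load_dataset(dir), "manifest")
  cfg <- scenario_config(seed = 5, chromosome_lengths = 30000)
  sim <- simulate_scenario(cfg, out_dir = file.path(dir, "s"))
  ds <- import_alignment(sim$files$quast)
  save_dataset(ds, file.path(dir, "d"))
  unlink(file.path(dir, "d", "blocks.tsv"))
  expect_error(load_dataset(file.path(dir, "d")), "blocks")
})

test_that("BED export converts to 0-based half-open coordinates", {
  b <- raw_blocks(s1 = c(1, 51), e1 = c(100, 120), s2 = c(1, 120),
                  e2 = c(100, 51))
  f <- withr::local_tempfile(fileext = ".bed")
  export_bed(b, f)
  lines <- strsplit(readLines(f), "\t")
  expect_equal(as.numeric(lines[[1]][2:3]), c(0, 100))
  expect_equal(lines[[1]][6], "+")
  expect_equal(as.numeric(lines[[2]][2:3]), c(50, 120))
  expect_equal(lines[[2]][6], "-")
})
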