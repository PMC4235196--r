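test_that("GFF3 annotation reading maps fields, sorts and validates", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tgene\t400\t500\t.\t-\t.\tID=g3",
               "chr\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
               "chr\tsrc\tgene\t151\t300\t.\t+\t.\tID=g2"), gff)
  genes <- read_annotation(gff)
  expect_equal(genes$gene_id, c("g1", "g2", "g3"))
  expect_equal(genes$start, c(1L, 151L, 400L))
  expect_equal(genes$strand, c("+", "+", "-"))

  empty <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_equal(nrow(read_annotation(empty)), 0L)

  dup <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tgene\t1\t100\t.\t+\t.\tID=gX",
               "chr\tsrc\tgene\t200\t300\t.\t+\t.\tID=gX"), dup)
  expect_error(read_annotation(dup), "gX")
})

test_that("annotation writing round-trips", {
  genes <- data.frame(gene_id = c("a", "b"), start = c(10L, 200L),
                      end = c(100L, 380L), strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(genes, path)
  expect_equal(read_annotation(path), genes)
})

test_that("operon table reading enforces the invariants", {
  genes <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                      start = c(1L, 201L, 401L, 601L),
                      end = c(100L, 300L, 500L, 700L),
                      strand = c("+", "+", "+", "-"),
                      stringsAsFactors = FALSE)
  tab <- withr::local_tempfile()
  writeLines("op1\tgA,gB,gC", tab)
  ops <- read_operon_table(tab, genes)
  expect_equal(ops$gene_id, c("gA", "gB", "gC"))
  expect_equal(ops$position, 1:3)

  writeLines("op1\tgA,gZ", tab)
  expect_error(read_operon_table(tab, genes), "gZ")

  writeLines(c("op1\tgA,gB", "op2\tgC"), tab)
  expect_warning(ops <- read_operon_table(tab, genes), "op2")
  expect_equal(unique(ops$operon_id), "op1")

  writeLines("op1\tgC,gD", tab)    # mixed strands
  expect_error(read_operon_table(tab, genes), "strand")

  # round trip
  writeLines(c("op1\tgA,gB", "op2\tgC,gD"), tab)
  genes$strand <- "+"
  ops <- read_operon_table(tab, genes)
  out <- withr::local_tempfile()
  write_operon_table(ops, out)
  expect_equal(read_operon_table(out, genes), ops)
})

test_that("coverage reading produces dense tracks from sparse files", {
  f <- withr::local_tempfile()
  writeLines(sprintf("chr\t%d\tA\t7", 10:20), f)
  tr <- read_coverage(f, genome_length = 100L)
  expect_equal(tr$depth[10:20], rep(7, 11))
  expect_equal(sum(tr$depth), 77)
  expect_equal(tr$genome_length, 100L)

  writeLines(character(), f)
  expect_equal(sum(read_coverage(f, 50L)$depth), 0)

  writeLines(c("5\t3", "6\t4"), f)       # 2-column dialect
  expect_equal(read_coverage(f, 10L)$depth[5:6], c(3, 4))

  writeLines("200\t3", f)
  expect_error(read_coverage(f, 100L), "out of range")
  writeLines("5\t-1", f)
  expect_error(read_coverage(f, 100L), "negative")
})

test_that("stranded coverage splits into per-strand arrays that sum to the total", {
  f <- withr::local_tempfile()
  writeLines(c("5\t3\t+", "5\t2\t-", "9\t4\t-"), f)
  tr <- read_coverage(f, 20L)
  expect_false(is.null(tr$strand_depth))
  expect_equal(tr$strand_depth[["+"]][5], 3)
  expect_equal(tr$strand_depth[["-"]][c(5, 9)], c(2, 4))
  expect_equal(tr$depth, tr$strand_depth[["+"]] + tr$strand_depth[["-"]])
  # unstranded parse of the equivalent collapsed file agrees
  f2 <- withr::local_tempfile()
  writeLines(c("5\t5", "9\t4"), f2)
  expect_equal(read_coverage(f2, 20L)$depth, tr$depth)
})

test_that("coverage write/read round-trips, stranded and not", {
  d <- c(rep(0, 10), rep(6, 5), rep(0, 5))
  tr <- coverage_track(d)
  p <- withr::local_tempfile()
  write_coverage(tr, p)
  expect_equal(read_coverage(p, 20L)$depth, d)
  tr2 <- coverage_track(d, strand_depth = list(`+` = d / 2, `-` = d / 2))
  write_coverage(tr2, p)
  rt <- read_coverage(p, 20L)
  expect_equal(rt$strand_depth[["+"]], d / 2)
})

test_that("BED signals convert to 1-based inclusive and round-trip", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr\t99\t150\ttt:terminator\t0\t+",
               "chr\t0\t10\tpp:promoter\t0\t."), bed)
  sg <- read_signals(bed)
  expect_equal(sg$start, c(100L, 1L))
  expect_equal(sg$end, c(150L, 10L))
  expect_equal(sg$kind, c("terminator", "promoter"))
  expect_equal(sg$source, c("tt", "pp"))
  expect_equal(sg$strand, c("+", "*"))
  out <- withr::local_tempfile(fileext = ".bed")
  write_signals(sg, out)
  expect_equal(read_signals(out)[, names(sg)], sg)   # BED -> internal -> BED identity

  writeLines(character(), bed)
  expect_equal(nrow(read_signals(bed)), 0L)
})

test_that("CDS FASTA round-trips keyed by gene id", {
  cds <- c(gA = "ATGAAATAA", gB = "ATGCCCTAA")
  p <- withr::local_tempfile(fileext = ".fa")
  write_cds(cds, p)
  expect_equal(read_cds(p), cds)
})
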