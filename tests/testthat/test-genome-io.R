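test_that("read_tss applies strand conventions and validates gene ids", {
  f <- write_lines_tmp(c("chr1\t1000\t1500\tgeneA\t0\t+",
                         "chr1\t2000\t2500\tgeneB\t0\t-"), ".bed")
  tss <- read_tss(f)
  expect_equal(tss$tss[tss$gene_id == "geneA"], 1000L)  # + strand: start
  expect_equal(tss$tss[tss$gene_id == "geneB"], 2499L)  # - strand: end - 1
  expect_equal(tss$strand, c("+", "-"))

  # 4-column direct-TSS layout
  f4 <- write_lines_tmp(c("chr1\t1234\tgeneX\t-"))
  expect_equal(read_tss(f4)$tss, 1234L)

  dup <- write_lines_tmp(c("chr1\t1000\t1500\tgeneA\t0\t+",
                           "chr2\t100\t200\tgeneA\t0\t+"), ".bed")
  expect_error(read_tss(dup), "duplicate gene_id")

  bad <- write_lines_tmp(c("chr1\t1000\t1500\tgeneA\t0\t+",
                           "chr1\tnotanumber\t99\tgeneB\t0\t+"), ".bed")
  expect_error(read_tss(bad), "line 2")

  badstrand <- write_lines_tmp(c("chr1\t1000\t1500\tgeneA\t0\t*"), ".bed")
  expect_error(read_tss(badstrand), "strand")
})

test_that("read_tags reduces reads to 5' positions and validates bounds", {
  cs <- c(chr1 = 1000L)
  f <- write_lines_tmp(c("chr1\t100\t136\t.\t0\t+",
                         "chr1\t100\t136\t.\t0\t-",
                         "chr1\t500\t530\t.\t0\t+"), ".bed")
  lib <- read_tags(f, "s1", "H3", "cond", cs)
  expect_equal(lib$total_tags, 3L)
  expect_equal(sort(lib$pos), c(100L, 135L, 500L))   # minus strand: end - 1

  # optional fixed shift is strand-aware
  lib_s <- read_tags(f, "s1", "H3", "cond", cs, shift = 10L)
  expect_equal(sort(lib_s$pos), c(110L, 125L, 510L))

  # tag beyond chromosome end / unknown chromosome
  off <- write_lines_tmp(c("chr1\t980\t1036\t.\t0\t-"), ".bed")
  expect_error(read_tags(off, "s1", "H3", "c", c(chr1 = 1000L)),
               "beyond chromosome end")
  unk <- write_lines_tmp(c("chrZ\t10\t46\t.\t0\t+"), ".bed")
  expect_error(read_tags(unk, "s1", "H3", "c", cs), "absent from chrom_sizes")

  # empty file: zero-tag library plus a warning
  empty <- write_lines_tmp(character(0), ".bed")
  expect_warning(lib0 <- read_tags(empty, "s1", "H3", "c", cs), "empty")
  expect_equal(lib0$total_tags, 0L)
})

test_that("tag libraries round-trip exactly through BED", {
  lib <- uniform_lib(500, 10000, seed = 11, mark = "H3K4me3")
  f <- tempfile(fileext = ".bed")
  write_tags(lib, f)
  back <- read_tags(f, lib$sample_id, lib$mark, lib$condition,
                    c(chr1 = 10000L))
  expect_identical(back$pos, lib$pos)
  expect_identical(back$total_tags, lib$total_tags)
})

test_that("SAM input yields the same 5' tags as equivalent BED", {
  skip_if_not_installed("Rsamtools")
  sam <- write_lines_tmp(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:1000",
    "r1\t0\tchr1\t101\t60\t36M\t*\t0\t0\t*\t*",     # fwd: 0-based 100
    "r2\t16\tchr1\t101\t60\t36M\t*\t0\t0\t*\t*",    # rev: 100 + 36 - 1 = 135
    "r3\t16\tchr1\t201\t60\t10M5D10M\t*\t0\t0\t*\t*"), ".sam")
  lib <- read_tags(sam, "s", "H3", "c", c(chr1 = 1000L), format = "sam")
  expect_equal(sort(lib$pos), c(100L, 135L, 200L + 25L - 1L))
})

test_that("bedGraph writing validates intervals and round-trips", {
  f <- tempfile(fileext = ".bedGraph")
  bg <- data.frame(chrom = "chr1", start = 0L, end = 100L, score = 1.5)
  write_bedgraph(bg, f)
  expect_equal(readLines(f), "chr1\t0\t100\t1.5")
  expect_equal(read_bedgraph(f), bg)

  # empty input -> empty file
  write_bedgraph(bg[0, ], f)
  expect_length(readLines(f), 0L)
  expect_equal(nrow(read_bedgraph(f)), 0L)

  unsorted <- data.frame(chrom = "chr1", start = c(100L, 0L),
                         end = c(200L, 50L), score = 1)
  expect_error(write_bedgraph(unsorted, f), "not sorted")
  overlapping <- data.frame(chrom = "chr1", start = c(0L, 50L),
                            end = c(100L, 150L), score = 1)
  expect_error(write_bedgraph(overlapping, f), "overlapping")
})

test_that("gene sets, expression tables and qPCR plates are validated", {
  gs <- write_lines_tmp(c("set,gene_id", "testis_specific,geneA",
                          "testis_specific,geneB", "ovary_specific,geneC"),
                        ".csv")
  sets <- read_gene_sets(gs, tiny_tss())
  expect_equal(sets$testis_specific, c("geneA", "geneB"))
  bad <- write_lines_tmp(c("set,gene_id", "testis_specific,nosuchgene"), ".csv")
  expect_error(read_gene_sets(bad, tiny_tss()), "not in the annotation")

  ex <- write_lines_tmp(c("gene_id,condition,value", "geneA,t1,5.5",
                          "geneB,t1,NaN"), ".csv")
  expect_error(read_expression(ex), "non-finite")

  qp <- write_lines_tmp(c("target,antibody,replicate,ct_bound,ct_unbound",
                          "Hoxd10,H3K27me3,1,50,20"), ".csv")
  expect_error(read_qpcr(qp), "CT values")
})
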