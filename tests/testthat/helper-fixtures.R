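# Shared fixture builders.  All fixtures are generated in code; file-based
# fixtures are written to tempdir().

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# a tiny deterministic annotation on two chromosomes
tiny_tss <- function() {
  data.frame(gene_id = c("geneA", "geneB", "geneC"),
             chrom = c("chr1", "chr1", "chr2"),
             tss = c(10000L, 30000L, 5000L),
             strand = c("+", "-", "+"),
             stringsAsFactors = FALSE)
}

tiny_chrom_sizes <- function() c(chr1 = 100000L, chr2 = 50000L)

# uniform tag library with fixed seed
uniform_lib <- function(n, len, seed, mark = "H3", chrom = "chr1") {
  set.seed(seed)
  tag_library(rep(chrom, n), sample.int(len, n, replace = TRUE) - 1L,
              sample_id = paste0("u", seed), mark = mark,
              condition = "test", chrom_sizes = setNames(len, chrom))
}

# brute-force window count: per-tag membership scan
brute_count <- function(lib, windows) {
  vapply(seq_len(nrow(windows)), function(i) {
    sum(lib$chrom == windows$chrom[i] &
        lib$pos >= windows$start[i] & lib$pos < windows$end[i])
  }, numeric(1))
}
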