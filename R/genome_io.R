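## I/O for annotations, tag libraries, gene sets, expression tables and
## qPCR plates.  Coordinates are 0-based half-open everywhere; BED files are
## read and written in their native 0-based convention without shifting.

VALID_MARKS <- c("H3", "H3K4me3", "H3K27me3")

#' Read a chromosome sizes table
#'
#' @param path Two-column whitespace-separated file: chromosome name, length
#'   in bp (the standard `chrom.sizes` layout).
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  stopifnot(file.exists(path))
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chrom", "length"))
  if (!is.numeric(df$length) || any(df$length <= 0)) {
    stop("chromosome lengths must be positive numbers")
  }
  if (anyDuplicated(df$chrom)) stop("duplicate chromosome names in ", path)
  setNames(as.integer(df$length), df$chrom)
}

#' Read a TSS annotation
#'
#' Accepts either BED6 (`chrom start end name score strand`), in which case
#' the TSS is `start` for `+` genes and `end - 1` for `-` genes (half-open
#' end), or a 4-column table `chrom pos name strand` giving the TSS
#' directly.
#'
#' @param path Annotation file.
#' @return A data.frame with columns `gene_id`, `chrom`, `tss` (0-based),
#'   `strand`, one row per gene.
#' @export
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t1000\t1500\tgeneA\t0\t+",
#'              "chr1\t5000\t5500\tgeneB\t0\t-"), f)
#' read_tss(f)
read_tss <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty annotation file: ", path)
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  recs <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) >= 6L) {                      # BED6
      start <- suppressWarnings(as.numeric(f[2]))
      end <- suppressWarnings(as.numeric(f[3]))
      strand <- f[6]
      gene <- f[4]
      if (is.na(start) || is.na(end) || end <= start) {
        stop("malformed annotation row at line ", i, ": ", lines[i])
      }
      tss <- if (strand == "+") start else end - 1
    } else if (length(f) == 4L) {               # chrom pos name strand
      tss <- suppressWarnings(as.numeric(f[2]))
      gene <- f[3]
      strand <- f[4]
      if (is.na(tss)) stop("malformed annotation row at line ", i, ": ", lines[i])
    } else {
      stop("malformed annotation row at line ", i,
           " (expected 4 or >= 6 fields, got ", length(f), ")")
    }
    if (!strand %in% c("+", "-")) {
      stop("invalid strand at line ", i, ": ", strand)
    }
    if (tss < 0) stop("negative TSS at line ", i)
    data.frame(gene_id = gene, chrom = f[1], tss = as.integer(tss),
               strand = strand, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  dup <- out$gene_id[duplicated(out$gene_id)]
  if (length(dup) > 0L) {
    stop("duplicate gene_id in annotation: ", paste(unique(dup), collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Construct a tag library
#'
#' A tag library holds one ChIP sample's aligned tag positions, each reduced
#' to a single 0-based 5' base, plus the library size.
#'
#' @param chrom Character vector of chromosome names, one per tag.
#' @param pos Integer vector of 0-based tag positions.
#' @param sample_id,mark,condition Sample metadata; `mark` must be one of
#'   `"H3"`, `"H3K4me3"`, `"H3K27me3"`.
#' @param chrom_sizes Optional named vector from [read_chrom_sizes()]; when
#'   given, every tag is validated against its chromosome length.
#' @return An object of class `tag_library`: a list with elements `chrom`,
#'   `pos`, `sample_id`, `mark`, `condition`, `total_tags`.
#' @export
tag_library <- function(chrom, pos, sample_id, mark, condition,
                        chrom_sizes = NULL) {
  if (!mark %in% VALID_MARKS) {
    stop("mark must be one of ", paste(VALID_MARKS, collapse = ", "))
  }
  stopifnot(length(chrom) == length(pos))
  pos <- as.integer(pos)
  if (length(pos) > 0L && any(pos < 0)) stop("negative tag position")
  if (!is.null(chrom_sizes) && length(pos) > 0L) {
    unknown <- setdiff(unique(chrom), names(chrom_sizes))
    if (length(unknown) > 0L) {
      stop("tags on chromosome(s) absent from chrom_sizes: ",
           paste(unknown, collapse = ", "))
    }
    beyond <- pos >= chrom_sizes[chrom]
    if (any(beyond)) {
      stop(sum(beyond), " tag(s) beyond chromosome end")
    }
  }
  structure(list(chrom = as.character(chrom), pos = pos,
                 sample_id = sample_id, mark = mark, condition = condition,
                 total_tags = length(pos)),
            class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat("tag_library:", x$sample_id, sprintf("(%s, %s)", x$mark, x$condition),
      "-", format(x$total_tags, big.mark = ","), "tags on",
      length(unique(x$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Read aligned ChIP tags from BED or SAM
#'
#' Each aligned read is reduced to its 5' base: `start` for `+` alignments,
#' `end - 1` (half-open end) for `-` alignments, plus an optional fixed
#' shift toward 3'.  Duplicate tags are retained.
#'
#' @param path BED6 file of aligned tags, or a SAM file when
#'   `format = "sam"` (requires the Rsamtools package).
#' @param sample_id,mark,condition Metadata stored on the library.
#' @param chrom_sizes Named vector from [read_chrom_sizes()]; tags beyond a
#'   chromosome end or on unknown chromosomes are a validation error.
#' @param format `"bed"` (default) or `"sam"`.
#' @param shift Fixed bp shift applied toward 3' (strand-aware); default 0.
#' @return A [tag_library()].  An empty file yields a library with
#'   `total_tags = 0` and a warning.
#' @export
read_tags <- function(path, sample_id, mark, condition, chrom_sizes = NULL,
                      format = c("bed", "sam"), shift = 0L) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "sam") {
    return(read_tags_sam(path, sample_id, mark, condition, chrom_sizes, shift))
  }
  df <- tryCatch(
    read.table(path, header = FALSE, stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0L) {
    warning("empty tag file: ", path)
    return(tag_library(character(), integer(), sample_id, mark, condition))
  }
  if (ncol(df) < 3L) stop("BED tag file needs at least 3 columns: ", path)
  strand <- if (ncol(df) >= 6L) df[[6]] else rep("+", nrow(df))
  pos <- ifelse(strand == "-", df[[3]] - 1L, df[[2]])
  if (shift != 0L) pos <- pos + ifelse(strand == "-", -shift, shift)
  tag_library(df[[1]], pos, sample_id, mark, condition, chrom_sizes)
}

# SAM input: converted to BAM with Rsamtools, 5' ends computed from POS,
# FLAG and the reference span of the CIGAR.
read_tags_sam <- function(path, sample_id, mark, condition, chrom_sizes,
                          shift = 0L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("SAM input requires the Rsamtools package")
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1]]
  if (length(res$pos) == 0L) {
    warning("no aligned reads in ", path)
    return(tag_library(character(), integer(), sample_id, mark, condition))
  }
  refwidth <- cigar_ref_width(res$cigar)
  start0 <- res$pos - 1L                       # SAM POS is 1-based
  minus <- res$strand == "-"
  pos <- ifelse(minus, start0 + refwidth - 1L, start0)
  if (shift != 0L) pos <- pos + ifelse(minus, -shift, shift)
  tag_library(as.character(res$rname), pos, sample_id, mark, condition,
              chrom_sizes)
}

# reference-consuming CIGAR ops: M, D, N, =, X
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Write a tag library as BED
#'
#' Each tag becomes one width-1 plus-strand BED record, so that
#' [read_tags()] on the output reproduces positions and `total_tags`
#' exactly.
#'
#' @param lib A [tag_library()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_tags <- function(lib, path) {
  stopifnot(inherits(lib, "tag_library"))
  df <- data.frame(lib$chrom, lib$pos, lib$pos + 1L, ".", 0L, "+")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a bedGraph track
#'
#' @param values data.frame with columns `chrom`, `start`, `end`, `score`;
#'   intervals must be 0-based half-open, sorted, and non-overlapping
#'   within each chromosome.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(values, path) {
  stopifnot(is.data.frame(values),
            all(c("chrom", "start", "end", "score") %in% names(values)))
  if (nrow(values) > 0L) {
    if (any(values$start < 0) || any(values$end <= values$start)) {
      stop("bedGraph intervals must be non-negative half-open with end > start")
    }
    for (ch in unique(values$chrom)) {
      v <- values[values$chrom == ch, ]
      if (is.unsorted(v$start, strictly = TRUE)) {
        stop("bedGraph intervals not sorted on ", ch)
      }
      if (nrow(v) > 1L && any(v$start[-1] < v$end[-nrow(v)])) {
        stop("overlapping bedGraph intervals on ", ch)
      }
    }
  }
  lines <- sprintf("%s\t%d\t%d\t%s", values$chrom, as.integer(values$start),
                   as.integer(values$end),
                   format(values$score, trim = TRUE, scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path bedGraph file written by [write_bedgraph()] (or any 4-column
#'   bedGraph without track lines).
#' @return data.frame with columns `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  stopifnot(file.exists(path))
  if (length(readLines(path, n = 1L)) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), score = numeric()))
  }
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "score"))
  df
}

#' Read gene-set membership lists
#'
#' @param path CSV with header columns `set` and `gene_id`.
#' @param annotation Optional data.frame from [read_tss()]; when given,
#'   members absent from the annotation are a validation error.
#' @return Named list of character vectors, one per set.
#' @export
read_gene_sets <- function(path, annotation = NULL) {
  stopifnot(file.exists(path))
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  if (!all(c("set", "gene_id") %in% names(df))) {
    stop("gene-set file needs columns 'set' and 'gene_id'")
  }
  sets <- split(df$gene_id, df$set)
  if (!is.null(annotation)) {
    for (nm in names(sets)) {
      missing <- setdiff(sets[[nm]], annotation$gene_id)
      if (length(missing) > 0L) {
        stop("gene set '", nm, "' has members not in the annotation: ",
             paste(head(missing, 5L), collapse = ", "))
      }
    }
  }
  sets
}

#' Read a per-gene expression table
#'
#' @param path CSV with header columns `gene_id`, `condition`, `value`
#'   (log-intensity).
#' @return data.frame with those columns; non-finite values are an error.
#' @export
read_expression <- function(path) {
  stopifnot(file.exists(path))
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "condition", "value") %in% names(df))) {
    stop("expression file needs columns gene_id, condition, value")
  }
  if (!all(is.finite(df$value))) stop("non-finite expression values")
  df
}

#' Read a qPCR plate table
#'
#' @param path CSV with header; expected columns depend on the protocol
#'   (see [analyze_qpcr()]): `target`, `antibody`, `replicate`, and either
#'   `ct_bound`/`ct_unbound` (native) or `ct_ip`/`ct_input` plus
#'   `input_fraction` (cross-linked / re-ChIP).
#' @return data.frame of the plate.
#' @export
read_qpcr <- function(path) {
  stopifnot(file.exists(path))
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  ct_cols <- intersect(names(df), c("ct_bound", "ct_unbound", "ct_ip", "ct_input"))
  if (length(ct_cols) == 0L) stop("qPCR file has no CT columns")
  for (cc in ct_cols) {
    bad <- !is.na(df[[cc]]) & (df[[cc]] <= 0 | df[[cc]] >= 45)
    if (any(bad)) stop("CT values must lie in (0, 45): column ", cc)
  }
  df
}
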