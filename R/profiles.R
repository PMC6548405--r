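## Average H3-normalized signal around TSSs (metaprofiles).

#' Metaprofile configuration
#'
#' @param span Total profile width centered on the TSS in bp (default
#'   10000, i.e. +/- 5 kb; 20000 is a common wider preset).  Must be
#'   divisible by `bin`.
#' @param bin Bin width in bp (default 1000).
#' @param orient_by_strand Mirror offsets for minus-strand genes so that
#'   upstream is always on the left (default `TRUE`).
#' @param mode `"ratio_then_average"` (default): the per-gene per-bin
#'   IP/H3 ratio is averaged across genes; `"average_then_ratio"`: bin
#'   counts are averaged across genes first and a single ratio is formed.
#' @param norm A [norm_config()] supplying pseudocount and depth scaling.
#' @return Object of class `profile_config`.
#' @export
profile_config <- function(span = 10000L, bin = 1000L,
                           orient_by_strand = TRUE,
                           mode = c("ratio_then_average", "average_then_ratio"),
                           norm = norm_config()) {
  mode <- match.arg(mode)
  stopifnot(bin > 0, span %% bin == 0)
  structure(list(span = as.integer(span), bin = as.integer(bin),
                 orient_by_strand = orient_by_strand, mode = mode,
                 norm = norm),
            class = "profile_config")
}

# per-gene x per-bin tag count matrix around TSSs
bin_counts_around_tss <- function(lib, tss, config) {
  nbins <- config$span %/% config$bin
  half <- config$span %/% 2L
  counts <- matrix(0L, nrow(tss), nbins)
  for (ch in unique(tss$chrom)) {
    gi <- which(tss$chrom == ch)
    p <- lib$pos[lib$chrom == ch]
    if (length(p) == 0L) next
    spans <- IRanges(pmax(tss$tss[gi] - half, 0L) + 1L, tss$tss[gi] + half)
    tags <- IRanges(p + 1L, p + 1L)
    hits <- findOverlaps(spans, tags)
    if (length(hits) == 0L) next
    g <- gi[queryHits(hits)]
    tagpos <- p[subjectHits(hits)]
    # bin index under the plus-strand convention, then mirrored for minus
    k <- (tagpos - tss$tss[g] + half) %/% config$bin + 1L
    keep <- k >= 1L & k <= nbins
    g <- g[keep]; k <- k[keep]
    if (config$orient_by_strand) {
      minus <- tss$strand[g] == "-"
      k[minus] <- nbins + 1L - k[minus]
    }
    idx <- (k - 1L) * nrow(tss) + g        # column-major linear index
    tab <- tabulate(idx, nbins = nrow(tss) * nbins)
    counts <- counts + matrix(tab, nrow(tss), nbins)
  }
  counts
}

#' Average H3-normalized signal around TSSs
#'
#' For every gene and bin, the depth-scaled IP count is divided by the
#' depth-scaled H3 count (both with pseudocount, see [norm_config()]), and
#' the per-bin ratios are averaged across genes (default mode).  For
#' minus-strand genes, offsets are mirrored so upstream is on the left.
#'
#' @param ip,h3 [tag_library()] objects (both non-empty).
#' @param tss data.frame from [read_tss()].
#' @param genes Optional character vector restricting to a gene set.
#' @param config A [profile_config()].
#' @return Object of class `meta_profile`: data.frame with columns
#'   `offset` (bin center relative to the TSS, bp) and `signal`, with
#'   attribute `n_genes`.
#' @export
metaprofile <- function(ip, h3, tss, genes = NULL,
                        config = profile_config()) {
  stopifnot(inherits(ip, "tag_library"), inherits(h3, "tag_library"))
  if (ip$total_tags == 0L || h3$total_tags == 0L) stop("empty tag library")
  if (!is.null(genes)) {
    missing <- setdiff(genes, tss$gene_id)
    if (length(missing) > 0L) {
      stop("genes absent from annotation: ",
           paste(head(missing, 5L), collapse = ", "))
    }
    tss <- tss[tss$gene_id %in% genes, , drop = FALSE]
  }
  if (nrow(tss) == 0L) stop("empty gene selection")
  nbins <- config$span %/% config$bin
  cm_ip <- bin_counts_around_tss(ip, tss, config)
  cm_h3 <- bin_counts_around_tss(h3, tss, config)
  nc <- config$norm
  k_ip <- if (nc$depth_scale) nc$reference_depth / ip$total_tags else 1
  k_h3 <- if (nc$depth_scale) nc$reference_depth / h3$total_tags else 1
  if (config$mode == "ratio_then_average") {
    ratios <- (cm_ip * k_ip + nc$pseudocount) /
              (cm_h3 * k_h3 + nc$pseudocount)
    signal <- colMeans(ratios)
  } else {
    signal <- (colMeans(cm_ip) * k_ip + nc$pseudocount) /
              (colMeans(cm_h3) * k_h3 + nc$pseudocount)
  }
  half <- config$span %/% 2L
  out <- data.frame(
    offset = -half + (seq_len(nbins) - 0.5) * config$bin,
    signal = signal)
  class(out) <- c("meta_profile", "data.frame")
  attr(out, "n_genes") <- nrow(tss)
  attr(out, "mark") <- ip$mark
  out
}

#' @export
print.meta_profile <- function(x, ...) {
  cat("meta_profile:", attr(x, "mark"), "over", attr(x, "n_genes"),
      "genes,", nrow(x), "bins\n")
  print.data.frame(x)
  invisible(x)
}

#' Plot a TSS metaprofile
#'
#' @param x A `meta_profile`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.meta_profile <- function(x, ...) {
  plot(x$offset, x$signal, type = "l", lwd = 2,
       xlab = "distance from TSS (bp)",
       ylab = "mean IP/H3 signal", ...)
  abline(v = 0, lty = 3)
  invisible(x)
}
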