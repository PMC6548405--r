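## Promoter quantification: 4 kb TSS windows, tag counting, H3-normalized
## log2 enrichment.

#' Normalization configuration for H3-normalized enrichment
#'
#' Enrichment is computed as
#' `E = log2((c_ip * K / N_ip + p) / (c_h3 * K / N_h3 + p))`
#' where `c` are window tag counts, `N` library totals, `K` the reference
#' depth and `p` the pseudocount.  Scaling to a fixed reference depth
#' before adding the pseudocount makes `E` exactly invariant to duplicating
#' every tag in both libraries.  With `depth_scale = FALSE` raw counts are
#' used (`E = log2((c_ip + p) / (c_h3 + p))`), retained for sensitivity
#' analysis.
#'
#' @param pseudocount Positive pseudocount `p` added to both scaled counts
#'   (default 1), keeping `E` finite and symmetric for empty windows.
#' @param depth_scale Scale counts by library totals before the H3 ratio
#'   (default `TRUE`).
#' @param reference_depth Reference library size `K` for depth scaling
#'   (default `1e6`, i.e. counts per million).
#' @return Object of class `norm_config`.
#' @export
norm_config <- function(pseudocount = 1, depth_scale = TRUE,
                        reference_depth = 1e6) {
  stopifnot(pseudocount > 0, reference_depth > 0)
  structure(list(pseudocount = pseudocount, depth_scale = depth_scale,
                 reference_depth = reference_depth),
            class = "norm_config")
}

#' Build promoter windows around TSSs
#'
#' Each TSS is expanded to the half-open window
#' `[tss - flank, tss + flank)`, clipped at chromosome edges.  The window is
#' symmetric and therefore strand-independent.
#'
#' @param tss data.frame from [read_tss()] (columns `gene_id`, `chrom`,
#'   `tss`, `strand`).
#' @param flank bp on each side of the TSS (default 2000, i.e. 4 kb
#'   windows).
#' @param chrom_sizes Named vector from [read_chrom_sizes()].
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `clipped` (logical; `TRUE` where the window
#'   was truncated at a chromosome edge).
#' @export
promoter_windows <- function(tss, flank = 2000L, chrom_sizes) {
  stopifnot(flank > 0)
  unknown <- setdiff(unique(tss$chrom), names(chrom_sizes))
  if (length(unknown) > 0L) {
    stop("TSS on chromosome(s) absent from chrom_sizes: ",
         paste(unknown, collapse = ", "))
  }
  start <- pmax(tss$tss - flank, 0L)
  end <- pmin(tss$tss + flank, chrom_sizes[tss$chrom])
  data.frame(gene_id = tss$gene_id, chrom = tss$chrom,
             start = as.integer(start), end = as.integer(end),
             clipped = (end - start) < 2L * flank,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Count tags falling in promoter windows
#'
#' A tag at position `p` is counted in window `[start, end)` iff
#' `start <= p < end`.  Overlapping windows each count shared tags.
#'
#' @param lib A [tag_library()].
#' @param windows data.frame from [promoter_windows()].
#' @return Named integer vector of counts, one per `gene_id`, in window
#'   order.
#' @export
count_window_tags <- function(lib, windows) {
  stopifnot(inherits(lib, "tag_library"))
  counts <- integer(nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    p <- lib$pos[lib$chrom == ch]
    if (length(p) == 0L) next
    # 0-based half-open [start, end) -> 1-based closed [start+1, end]
    win <- IRanges(windows$start[wi] + 1L, windows$end[wi])
    tags <- IRanges(p + 1L, p + 1L)
    counts[wi] <- countOverlaps(win, tags)
  }
  setNames(counts, windows$gene_id)
}

#' H3-normalized log2 enrichment score
#'
#' @param c_ip,c_h3 Window tag counts for the IP mark and H3 (vectors).
#' @param n_ip,n_h3 Library totals; must be positive when
#'   `config$depth_scale` is `TRUE`.
#' @param config A [norm_config()].
#' @return Numeric vector of log2 enrichments, finite whenever the
#'   pseudocount is positive.
#' @export
#' @examples
#' # equal counts at equal depth are unenriched
#' enrichment_score(10, 10, 1e6, 1e6)
#' # 8-fold more IP than H3 signal
#' enrichment_score(80, 10, 1e6, 1e6)   # log2(81 / 11)
enrichment_score <- function(c_ip, c_h3, n_ip, n_h3,
                             config = norm_config()) {
  stopifnot(inherits(config, "norm_config"),
            all(c_ip >= 0), all(c_h3 >= 0))
  if (config$depth_scale) {
    if (n_ip <= 0 || n_h3 <= 0) stop("empty library: totals must be > 0")
    k <- config$reference_depth
    num <- c_ip * (k / n_ip) + config$pseudocount
    den <- c_h3 * (k / n_h3) + config$pseudocount
  } else {
    num <- c_ip + config$pseudocount
    den <- c_h3 + config$pseudocount
  }
  log2(num / den)
}

#' Quantify promoters: counts and H3-normalized enrichment for both marks
#'
#' Counts tags from the H3K4me3, H3K27me3 and H3 libraries in each 4 kb
#' promoter window and computes the H3-normalized log2 enrichment of each
#' IP mark.
#'
#' @param k4,k27,h3 [tag_library()] objects for H3K4me3, H3K27me3 and H3,
#'   measured over the same genome.
#' @param windows data.frame from [promoter_windows()].
#' @param config A [norm_config()].
#' @return Object of class `promoter_quant`: a data.frame with columns
#'   `gene_id`, `c_k4`, `c_k27`, `c_h3`, `E_k4`, `E_k27`.
#' @export
quantify_promoters <- function(k4, k27, h3, windows, config = norm_config()) {
  stopifnot(k4$mark == "H3K4me3", k27$mark == "H3K27me3", h3$mark == "H3")
  c_k4 <- count_window_tags(k4, windows)
  c_k27 <- count_window_tags(k27, windows)
  c_h3 <- count_window_tags(h3, windows)
  out <- data.frame(
    gene_id = windows$gene_id,
    c_k4 = as.integer(c_k4), c_k27 = as.integer(c_k27),
    c_h3 = as.integer(c_h3),
    E_k4 = enrichment_score(c_k4, c_h3, k4$total_tags, h3$total_tags, config),
    E_k27 = enrichment_score(c_k27, c_h3, k27$total_tags, h3$total_tags, config),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("promoter_quant", "data.frame")
  attr(out, "config") <- config
  out
}

#' @export
print.promoter_quant <- function(x, ...) {
  cat("promoter_quant:", nrow(x), "promoters\n")
  cat(sprintf("  E_k4  range: [%.2f, %.2f]\n", min(x$E_k4), max(x$E_k4)))
  cat(sprintf("  E_k27 range: [%.2f, %.2f]\n", min(x$E_k27), max(x$E_k27)))
  invisible(x)
}

#' Scatterplot of promoter enrichments
#'
#' H3K27me3 enrichment on x, H3K4me3 on y, with the high-enrichment
#' threshold drawn on both axes; genes in `highlight` are overplotted.
#'
#' @param x A `promoter_quant`.
#' @param high_cut Threshold line position (default 2.5).
#' @param highlight Optional character vector of gene ids to emphasise.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.promoter_quant <- function(x, high_cut = 2.5, highlight = NULL, ...) {
  plot(x$E_k27, x$E_k4, pch = 16, cex = 0.4, col = "grey50",
       xlab = "H3K27me3 log2 enrichment / H3",
       ylab = "H3K4me3 log2 enrichment / H3", ...)
  abline(h = high_cut, v = high_cut, lty = 2, col = "red")
  if (!is.null(highlight)) {
    sel <- x$gene_id %in% highlight
    graphics::points(x$E_k27[sel], x$E_k4[sel], pch = 16, cex = 0.7,
                     col = "blue")
  }
  invisible(x)
}
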