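## Promoter chromatin-state assignment and censuses.  A promoter is
## K4_ONLY, K27_ONLY, BIVALENT or NEITHER, either by thresholding its
## H3-normalized log2 enrichments ("high" is strictly greater than the
## cut) or by >= 1 bp overlap between called domains and its 4 kb window.

#' Classify promoters by enrichment threshold
#'
#' A mark is "high" at a promoter iff its H3-normalized log2 enrichment is
#' strictly greater than `high_cut` (a value exactly equal to the cut is
#' not high).  BIVALENT = both marks high; K4_ONLY / K27_ONLY = exactly
#' one; NEITHER otherwise.
#'
#' @param e_k4,e_k27 Numeric vectors of log2 enrichments (finite).
#' @param high_cut High-enrichment threshold (default 2.5).
#' @return Factor of states with levels [chromatin_states()].
#' @export
#' @examples
#' classify_threshold(c(3, 2.5, 0), c(3, 3, 0))
classify_threshold <- function(e_k4, e_k27, high_cut = 2.5) {
  stopifnot(length(e_k4) == length(e_k27),
            all(is.finite(e_k4)), all(is.finite(e_k27)))
  k4 <- e_k4 > high_cut
  k27 <- e_k27 > high_cut
  st <- ifelse(k4 & k27, "BIVALENT",
        ifelse(k4, "K4_ONLY",
        ifelse(k27, "K27_ONLY", "NEITHER")))
  as_state_factor(st)
}

#' Build a state table from promoter quantification
#'
#' @param quant A `promoter_quant` from [quantify_promoters()].
#' @param condition Condition label (e.g. `"XY_E10.5"`).
#' @param high_cut Threshold passed to [classify_threshold()].
#' @return Object of class `state_table`: a data.frame with columns
#'   `gene_id`, `state`; attributes `condition` and `mode = "threshold"`.
#' @export
state_table <- function(quant, condition, high_cut = 2.5) {
  stopifnot(inherits(quant, "promoter_quant"))
  new_state_table(quant$gene_id,
                  classify_threshold(quant$E_k4, quant$E_k27, high_cut),
                  condition, "threshold")
}

#' Construct a state table from explicit assignments
#'
#' Low-level constructor, useful for working with published or externally
#' derived state calls.
#'
#' @param gene_id Character vector of gene ids (unique).
#' @param state Vector of states from [chromatin_states()].
#' @param condition Condition label.
#' @param mode Label recording how the states were derived.
#' @return A `state_table`.
#' @export
as_state_table <- function(gene_id, state, condition, mode = "external") {
  if (anyDuplicated(gene_id)) stop("duplicate gene_id in state table")
  new_state_table(gene_id, state, condition, mode)
}

new_state_table <- function(gene_id, state, condition, mode) {
  out <- data.frame(gene_id = gene_id, state = as_state_factor(state),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("state_table", "data.frame")
  attr(out, "condition") <- condition
  attr(out, "mode") <- mode
  out
}

#' Classify promoters by peak-promoter overlap
#'
#' A mark is "present" at a gene iff at least 1 bp of any of its called
#' domains overlaps the gene's promoter window (half-open intervals: a
#' domain ending exactly at the window start does not overlap).
#'
#' @param domains_k4,domains_k27 `peak_domains` from [call_domains()] for
#'   H3K4me3 and H3K27me3.
#' @param windows data.frame from [promoter_windows()].
#' @param condition Condition label.
#' @return A `state_table` with `mode = "peak_overlap"`.
#' @export
classify_peak_overlap <- function(domains_k4, domains_k27, windows,
                                  condition) {
  present <- function(domains) {
    hit <- logical(nrow(windows))
    if (nrow(domains) == 0L) return(hit)
    for (ch in unique(windows$chrom)) {
      wi <- which(windows$chrom == ch)
      d <- domains[domains$chrom == ch, , drop = FALSE]
      if (nrow(d) == 0L) next
      wr <- IRanges(windows$start[wi] + 1L, windows$end[wi])
      dr <- IRanges(d$start + 1L, d$end)
      hit[wi] <- countOverlaps(wr, dr) > 0L
    }
    hit
  }
  k4 <- present(domains_k4)
  k27 <- present(domains_k27)
  st <- ifelse(k4 & k27, "BIVALENT",
        ifelse(k4, "K4_ONLY",
        ifelse(k27, "K27_ONLY", "NEITHER")))
  new_state_table(windows$gene_id, st, condition, "peak_overlap")
}

#' Combine replicate state tables
#'
#' Replicate calls are combined at the level of per-mark presence (a mark
#' is present at a gene in a state iff the state contains that mark):
#' `"union"` marks a gene iff either replicate marks it, `"intersection"`
#' iff both do.  The state is then re-derived from the combined presences.
#'
#' @param a,b `state_table` objects over the same gene universe.
#' @param method `"union"` or `"intersection"`.
#' @return A `state_table` (condition taken from `a`, mode records the
#'   combination).
#' @export
combine_state_tables <- function(a, b, method = c("union", "intersection")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "state_table"), inherits(b, "state_table"))
  if (!setequal(a$gene_id, b$gene_id)) {
    stop("replicate state tables cover different gene universes")
  }
  b <- b[match(a$gene_id, b$gene_id), ]
  has_k4 <- function(s) s %in% c("K4_ONLY", "BIVALENT")
  has_k27 <- function(s) s %in% c("K27_ONLY", "BIVALENT")
  op <- if (method == "union") `|` else `&`
  k4 <- op(has_k4(a$state), has_k4(b$state))
  k27 <- op(has_k27(a$state), has_k27(b$state))
  st <- ifelse(k4 & k27, "BIVALENT",
        ifelse(k4, "K4_ONLY",
        ifelse(k27, "K27_ONLY", "NEITHER")))
  new_state_table(a$gene_id, st, attr(a, "condition"),
                  paste0(attr(a, "mode"), "_", method))
}

#' State census: fraction of promoters in each state
#'
#' @param st A `state_table`.
#' @param universe Optional character vector restricting the census to a
#'   gene set (all genes must be in the table).
#' @return Named numeric vector of four fractions summing to 1, in
#'   [chromatin_states()] order.
#' @export
state_census <- function(st, universe = NULL) {
  stopifnot(inherits(st, "state_table"))
  if (!is.null(universe)) {
    missing <- setdiff(universe, st$gene_id)
    if (length(missing) > 0L) {
      stop("universe genes absent from state table: ",
           paste(head(missing, 5L), collapse = ", "))
    }
    st <- st[st$gene_id %in% universe, ]
  }
  if (nrow(st) == 0L) stop("empty gene universe")
  tab <- table(st$state)
  as.numeric(tab) / nrow(st) -> frac
  setNames(frac, names(tab))
}

#' @export
print.state_table <- function(x, ...) {
  cat("state_table:", attr(x, "condition"),
      sprintf("(mode = %s), %d genes\n", attr(x, "mode"), nrow(x)))
  cen <- state_census(x)
  for (s in names(cen)) {
    cat(sprintf("  %-8s %5d (%5.1f%%)\n", s, sum(x$state == s), 100 * cen[[s]]))
  }
  invisible(x)
}

#' @export
summary.state_table <- function(object, ...) {
  list(condition = attr(object, "condition"), mode = attr(object, "mode"),
       n_genes = nrow(object), census = state_census(object))
}
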