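## ChIP-qPCR quantification.  Native MNase ChIP is analyzed as the
## bound/unbound ratio 2^(CT_unbound - CT_bound) with IgG subtraction;
## cross-linked ChIP and ChIP-re-ChIP as percent of (dilution-adjusted)
## input.  Primer efficiency is assumed to be 2 (the plain delta-CT form).

#' Bound/unbound enrichment ratio from CT values
#'
#' `ratio = 1 / 2^(CT_bound - CT_unbound) = 2^(CT_unbound - CT_bound)`;
#' strictly decreasing in `ct_bound`.
#'
#' @param ct_bound,ct_unbound qPCR cycle thresholds for the bound (IP) and
#'   unbound fractions; must be finite and in (0, 45).
#' @return Numeric ratio (vectorized).
#' @export
#' @examples
#' bound_unbound_ratio(21, 20)   # one cycle later than unbound: 0.5
bound_unbound_ratio <- function(ct_bound, ct_unbound) {
  check_ct(ct_bound); check_ct(ct_unbound)
  2^(ct_unbound - ct_bound)
}

check_ct <- function(ct) {
  if (any(!is.finite(ct))) stop("missing or non-finite CT value")
  if (any(ct <= 0 | ct >= 45)) stop("CT values must lie in (0, 45)")
  invisible(ct)
}

#' Subtract the IgG (or no-antibody) control ratio
#'
#' Negative results are clamped to 0 with a warning: background above the
#' specific signal means no detectable enrichment.
#'
#' @param specific,igg Enrichment ratios from the same target/plate.
#' @return Non-negative ratio (vectorized).
#' @export
subtract_igg <- function(specific, igg) {
  out <- specific - igg
  if (any(out < 0)) {
    warning(sum(out < 0), " enrichment value(s) below the IgG control; ",
            "clamped to 0")
    out <- pmax(out, 0)
  }
  out
}

#' Percent input from cross-linked ChIP CT values
#'
#' The input CT is first adjusted for the input dilution
#' (`ct_input - log2(1 / input_fraction)`, e.g. `- log2(10)` when 10% of
#' chromatin was kept as input), then
#' `% input = 100 * 2^(adjusted_input_ct - ct_ip)`.  Adding a constant to
#' both CTs leaves the result unchanged.
#'
#' @param ct_ip,ct_input Cycle thresholds for IP and input.
#' @param input_fraction Fraction of chromatin kept as input, in (0, 1]
#'   (default 0.10).
#' @return Percentage (vectorized).
#' @export
#' @examples
#' percent_input(20, 20, input_fraction = 1.0)              # 100
#' percent_input(20, 20 + log2(10), input_fraction = 0.10)  # 100
percent_input <- function(ct_ip, ct_input, input_fraction = 0.10) {
  if (any(input_fraction <= 0 | input_fraction > 1)) {
    stop("input_fraction must lie in (0, 1]")
  }
  check_ct(ct_ip); check_ct(ct_input)
  adj <- ct_input - log2(1 / input_fraction)
  100 * 2^(adj - ct_ip)
}

#' Aggregate replicate enrichment values
#'
#' @param values Numeric vector of per-replicate enrichments (>= 1).
#' @return Object of class `qpcr_result`: list with `mean`,
#'   `sem` (`sd/sqrt(n)`; 0 when `n = 1`, flagged by
#'   `single_replicate = TRUE`) and `n`.
#' @export
#' @examples
#' aggregate_replicates(c(0.4, 0.6))   # mean 0.5, SEM 0.1
aggregate_replicates <- function(values) {
  if (length(values) == 0L) stop("no replicates to aggregate")
  n <- length(values)
  structure(list(mean = mean(values),
                 sem = if (n > 1L) sd(values) / sqrt(n) else 0,
                 n = n, single_replicate = n == 1L),
            class = "qpcr_result")
}

#' @export
print.qpcr_result <- function(x, ...) {
  cat(sprintf("qpcr_result: %.4g +/- %.4g (SEM, n = %d%s)\n", x$mean, x$sem,
              x$n, if (x$single_replicate) ", single replicate" else ""))
  invisible(x)
}

#' Analyze a ChIP-qPCR plate
#'
#' Computes per-replicate enrichment (bound/unbound ratio for the native
#' protocol, percent input for cross-linked and re-ChIP), subtracts the
#' control antibody (IgG, or the no-antibody control in re-ChIP)
#' per replicate, then aggregates replicates per target and antibody.
#'
#' @param plate data.frame from [read_qpcr()].  Native protocol columns:
#'   `target`, `antibody`, `replicate`, `ct_bound`, `ct_unbound`.
#'   Cross-linked / re-ChIP: `target`, `antibody`, `replicate`, `ct_ip`,
#'   `ct_input`, `input_fraction`.
#' @param protocol `"native"`, `"crosslinked"` or `"rechip"`.
#' @param control_antibody Name of the control antibody row to subtract
#'   (default `"IgG"`); set `NULL` to skip subtraction.
#' @return data.frame with one row per (target, antibody): `enrichment`
#'   (mean), `sem`, `n_replicates`, `igg_subtracted`.
#' @export
analyze_qpcr <- function(plate, protocol = c("native", "crosslinked", "rechip"),
                         control_antibody = "IgG") {
  protocol <- match.arg(protocol)
  if (protocol == "native") {
    stopifnot(all(c("target", "antibody", "replicate", "ct_bound",
                    "ct_unbound") %in% names(plate)))
    plate$enrichment <- bound_unbound_ratio(plate$ct_bound, plate$ct_unbound)
  } else {
    stopifnot(all(c("target", "antibody", "replicate", "ct_ip",
                    "ct_input", "input_fraction") %in% names(plate)))
    plate$enrichment <- percent_input(plate$ct_ip, plate$ct_input,
                                      plate$input_fraction)
  }
  subtracted <- FALSE
  if (!is.null(control_antibody) && control_antibody %in% plate$antibody) {
    ctrl <- plate[plate$antibody == control_antibody, ]
    spec <- plate[plate$antibody != control_antibody, ]
    key <- paste(ctrl$target, ctrl$replicate)
    ctrl_val <- setNames(ctrl$enrichment, key)
    skey <- paste(spec$target, spec$replicate)
    if (!all(skey %in% key)) {
      stop("missing ", control_antibody, " control for some target/replicate")
    }
    spec$enrichment <- subtract_igg(spec$enrichment, ctrl_val[skey])
    plate <- spec
    subtracted <- TRUE
  }
  out <- do.call(rbind, lapply(
    split(plate, list(plate$target, plate$antibody), drop = TRUE),
    function(g) {
      agg <- aggregate_replicates(g$enrichment)
      data.frame(target = g$target[1], antibody = g$antibody[1],
                 enrichment = agg$mean, sem = agg$sem,
                 n_replicates = agg$n, igg_subtracted = subtracted,
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out[order(out$target, out$antibody), , drop = FALSE]
}
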