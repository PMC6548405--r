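## Cross-condition dynamics: state transition matrices, bivalency
## resolution fractions, shared-state overlaps, and the association of
## expression with chromatin state.

#' Build a state transition table between two conditions
#'
#' @param states_t0,states_t1 `state_table` objects over the same gene
#'   universe (a mismatch is an error listing offending genes).
#' @param gene_set Optional character vector restricting the comparison.
#' @return Object of class `transition_summary`: a 4x4 integer matrix of
#'   counts (rows = state at t0, columns = state at t1) with attributes
#'   `condition_pair` and `restricted_to`.
#' @export
transition_table <- function(states_t0, states_t1, gene_set = NULL) {
  stopifnot(inherits(states_t0, "state_table"),
            inherits(states_t1, "state_table"))
  only0 <- setdiff(states_t0$gene_id, states_t1$gene_id)
  only1 <- setdiff(states_t1$gene_id, states_t0$gene_id)
  if (length(only0) > 0L || length(only1) > 0L) {
    stop("gene universes differ between conditions; offending genes: ",
         paste(head(c(only0, only1), 10L), collapse = ", "))
  }
  g <- states_t0$gene_id
  if (!is.null(gene_set)) {
    missing <- setdiff(gene_set, g)
    if (length(missing) > 0L) {
      stop("gene_set members absent from the universe: ",
           paste(head(missing, 5L), collapse = ", "))
    }
    g <- intersect(g, gene_set)
  }
  s0 <- states_t0$state[match(g, states_t0$gene_id)]
  s1 <- states_t1$state[match(g, states_t1$gene_id)]
  counts <- table(t0 = s0, t1 = s1)
  m <- matrix(as.integer(counts), nrow = 4L, dimnames = dimnames(counts))
  structure(m, class = c("transition_summary", class(m)),
            condition_pair = c(attr(states_t0, "condition"),
                               attr(states_t1, "condition")),
            restricted_to = if (is.null(gene_set)) NA_character_ else "gene_set")
}

#' Construct a transition summary from a count matrix
#'
#' Useful for working with published transition counts directly.
#'
#' @param counts 4x4 matrix (rows t0, columns t1) with dimnames drawn from
#'   [chromatin_states()]; missing states are filled with zero.
#' @param condition_pair Length-2 character vector of condition labels.
#' @return A `transition_summary`.
#' @export
transition_summary <- function(counts, condition_pair = c("t0", "t1")) {
  states <- chromatin_states()
  m <- matrix(0L, 4L, 4L, dimnames = list(t0 = states, t1 = states))
  for (r in rownames(counts)) for (cc in colnames(counts)) {
    m[r, cc] <- as.integer(counts[r, cc])
  }
  structure(m, class = c("transition_summary", class(m)),
            condition_pair = condition_pair, restricted_to = NA_character_)
}

#' @export
print.transition_summary <- function(x, ...) {
  cp <- attr(x, "condition_pair")
  cat("transition_summary:", cp[1], "->", cp[2],
      sprintf("(%d genes)\n", sum(x)))
  print(unclass(x)[seq_len(4), seq_len(4)])
  invisible(x)
}

#' Resolution fraction between two states
#'
#' The percentage of genes in `from_state` at the first condition that are
#' in `to_state` at the second, reported with nearest-integer rounding
#' alongside the raw counts; `round(100 * 260/382)` is 68, for example.
#'
#' @param summary A `transition_summary`.
#' @param from_state,to_state State labels from [chromatin_states()].
#'   The default measures resolution of bivalency toward the active
#'   H3K4me3-only state.
#' @return List with `count` (numerator), `total` (the `from_state` row
#'   sum), `percent` (nearest integer) and `percent_raw`.
#' @export
#' @examples
#' m <- matrix(0, 4, 4, dimnames = list(chromatin_states(), chromatin_states()))
#' m["BIVALENT", "K4_ONLY"] <- 260; m["BIVALENT", "BIVALENT"] <- 122
#' resolution_fraction(transition_summary(m))   # 68%
resolution_fraction <- function(summary, from_state = "BIVALENT",
                                to_state = "K4_ONLY") {
  stopifnot(inherits(summary, "transition_summary"),
            from_state %in% chromatin_states(),
            to_state %in% chromatin_states())
  total <- sum(summary[from_state, ])
  if (total == 0L) stop("no genes in from_state '", from_state, "'")
  count <- summary[from_state, to_state]
  raw <- 100 * count / total
  list(count = as.integer(count), total = as.integer(total),
       percent = round(raw), percent_raw = raw)
}

#' Fraction of genes leaving a state ("resolved")
#'
#' Resolution of bivalency is leaving `from_state` for any other state.
#'
#' @inheritParams resolution_fraction
#' @return List as in [resolution_fraction()], with `count` the number of
#'   genes not remaining in `from_state`.
#' @export
resolved_fraction <- function(summary, from_state = "BIVALENT") {
  stay <- resolution_fraction(summary, from_state, from_state)
  raw <- 100 * (stay$total - stay$count) / stay$total
  list(count = stay$total - stay$count, total = stay$total,
       percent = round(raw), percent_raw = raw)
}

#' Shared-state overlap between two conditions
#'
#' Sizes of the gene sets in a given state in each of two state tables and
#' of their intersection (e.g. bivalent promoters shared between XY and XX
#' cells).
#'
#' @param states_a,states_b `state_table` objects over a shared universe.
#' @param state State label from [chromatin_states()].
#' @return List with `n_a`, `n_b`, `n_shared`, and the member gene ids
#'   (`shared`).
#' @export
shared_state_overlap <- function(states_a, states_b, state = "BIVALENT") {
  stopifnot(state %in% chromatin_states())
  a <- states_a$gene_id[states_a$state == state]
  b <- states_b$gene_id[states_b$state == state]
  shared <- intersect(a, b)
  list(n_a = length(a), n_b = length(b), n_shared = length(shared),
       shared = shared)
}

#' Expression by chromatin state
#'
#' Per-state mean, SEM and n of expression log-intensities, plus pairwise
#' two-sample t-tests between states.  Welch's unequal-variance test is
#' the default; the pooled-variance form is available via
#' `var_equal = TRUE`.  Pairs where either state has fewer than 2
#' expressed genes are skipped with a warning.
#'
#' @param states A `state_table`.
#' @param expression data.frame from [read_expression()] (columns
#'   `gene_id`, `condition`, `value`).
#' @param condition Optional expression condition to select; default uses
#'   all rows matching the state table's genes.
#' @param var_equal Use the pooled-variance (classical Student) test.
#' @return List with `groups` (data.frame state, n, mean, sem) and
#'   `tests` (data.frame state_a, state_b, t, df, p_value).
#' @export
expression_by_state <- function(states, expression, condition = NULL,
                                var_equal = FALSE) {
  stopifnot(inherits(states, "state_table"))
  expr <- expression
  if (!is.null(condition)) expr <- expr[expr$condition == condition, ]
  expr <- expr[expr$gene_id %in% states$gene_id, ]
  expr$state <- states$state[match(expr$gene_id, states$gene_id)]
  groups <- do.call(rbind, lapply(chromatin_states(), function(s) {
    v <- expr$value[expr$state == s]
    data.frame(state = s, n = length(v),
               mean = if (length(v) > 0L) mean(v) else NA_real_,
               sem = if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(chromatin_states(), 2L)
  tests <- list()
  for (j in seq_len(ncol(pairs))) {
    sa <- pairs[1, j]; sb <- pairs[2, j]
    va <- expr$value[expr$state == sa]
    vb <- expr$value[expr$state == sb]
    if (length(va) < 2L || length(vb) < 2L) {
      warning("skipping ", sa, " vs ", sb,
              ": fewer than 2 expressed genes in a group")
      next
    }
    tt <- t.test(va, vb, var.equal = var_equal)
    tests[[length(tests) + 1L]] <- data.frame(
      state_a = sa, state_b = sb, t = unname(tt$statistic),
      df = unname(tt$parameter), p_value = tt$p.value,
      stringsAsFactors = FALSE)
  }
  tests <- if (length(tests) > 0L) do.call(rbind, tests) else
    data.frame(state_a = character(), state_b = character(), t = numeric(),
               df = numeric(), p_value = numeric())
  list(groups = groups, tests = tests)
}
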