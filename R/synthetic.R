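## Synthetic ChIP experiment generator.  Produces an annotation, tag
## libraries for H3 / H3K4me3 / H3K27me3 at one or two timepoints,
## state-dependent expression values and qPCR plates, all with known
## chromatin-state truth, so every pipeline stage can be tested against
## the generating parameters.

#' Synthetic experiment configuration
#'
#' Defaults describe a desk-scale experiment: 400 genes on a 40 Mb
#' chromosome (one gene per 100 kb, the mammalian gene density, so
#' promoter windows hold a realistically small share of each library and
#' depth normalization behaves as it does on real data), an H3 baseline
#' of 30 tags per 4 kb promoter window, IP rates of 12x the H3 baseline
#' at promoters carrying the mark and 0.5x otherwise (true depth-scaled
#' log2 IP/H3 ratios near +3.5 and -1, straddling the 2.5 classification
#' cut), uniform genomic background, state proportions with a realistic
#' bivalent fraction (16%), and a transition matrix in which 68% of
#' bivalent promoters resolve to the active H3K4me3-only state.
#'
#' @param n_genes Number of genes (default 400).
#' @param chrom_len Chromosome length in bp (default 4e7); genes are
#'   packed with >= 8 kb spacing so promoter windows never overlap.
#' @param flank Promoter half-width in bp (default 2000).
#' @param state_proportions Named probabilities over [chromatin_states()]
#'   for the state at the first timepoint.
#' @param lambda_h3 Mean H3 tags per promoter window (default 30).
#' @param ip_high_mult,ip_low_mult IP window rate as a multiple of
#'   `lambda_h3` when the promoter carries / lacks the mark (defaults 12
#'   and 0.5).
#' @param background_rate Uniform H3 background outside promoter windows,
#'   tags per bp (default `lambda_h3 / (4 * flank)`: nucleosome density,
#'   hence H3 signal, is uniform genome-wide).
#' @param ip_background_mult IP background as a multiple of
#'   `background_rate` (default 0.5).
#' @param transition_matrix 4x4 row-stochastic matrix (rows/cols in
#'   [chromatin_states()] order) giving the state at the second timepoint.
#' @param expression_means,expression_sd Named per-state means and common
#'   sd of the simulated expression log-intensities (defaults 8, 4.8, 5,
#'   4.5 for K4_ONLY, K27_ONLY, BIVALENT, NEITHER; sd 1).
#' @param overdispersion Negative-binomial size parameter; `Inf` (default)
#'   gives pure Poisson window counts.
#' @param seed Integer master seed; every generator derives its stream
#'   from it, so a fixed seed reproduces the full experiment exactly.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 400L,
                             chrom_len = 4e7,
                             flank = 2000L,
                             state_proportions = c(K4_ONLY = 0.45,
                                                   K27_ONLY = 0.05,
                                                   BIVALENT = 0.16,
                                                   NEITHER = 0.34),
                             lambda_h3 = 30,
                             ip_high_mult = 12,
                             ip_low_mult = 0.5,
                             background_rate = lambda_h3 / (4 * flank),
                             ip_background_mult = 0.5,
                             transition_matrix = default_transition_matrix(),
                             expression_means = c(K4_ONLY = 8,
                                                  K27_ONLY = 4.8,
                                                  BIVALENT = 5,
                                                  NEITHER = 4.5),
                             expression_sd = 1,
                             overdispersion = Inf,
                             seed = 1L) {
  states <- chromatin_states()
  stopifnot(setequal(names(state_proportions), states),
            abs(sum(state_proportions) - 1) < 1e-8,
            all(state_proportions >= 0),
            setequal(names(expression_means), states),
            lambda_h3 > 0, ip_high_mult > 0, ip_low_mult >= 0,
            background_rate >= 0, ip_background_mult >= 0,
            all(dim(transition_matrix) == c(4L, 4L)),
            all(abs(rowSums(transition_matrix) - 1) < 1e-8))
  structure(list(n_genes = as.integer(n_genes), chrom_len = chrom_len,
                 flank = as.integer(flank),
                 state_proportions = state_proportions[states],
                 lambda_h3 = lambda_h3, ip_high_mult = ip_high_mult,
                 ip_low_mult = ip_low_mult,
                 background_rate = background_rate,
                 ip_background_mult = ip_background_mult,
                 transition_matrix = transition_matrix,
                 expression_means = expression_means[states],
                 expression_sd = expression_sd,
                 overdispersion = overdispersion,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default chromatin-state transition matrix
#'
#' Rows/columns in [chromatin_states()] order.  Bivalent promoters resolve
#' to the active H3K4me3-only state with probability 0.68 (the dominant
#' resolution mode during supporting-cell differentiation), remain
#' bivalent with 0.22, and otherwise drift to the repressed or unmarked
#' states; single-mark and unmarked promoters are largely stable.
#'
#' @return 4x4 row-stochastic matrix.
#' @export
default_transition_matrix <- function() {
  states <- chromatin_states()
  matrix(c(
    # K4_ONLY K27_ONLY BIVALENT NEITHER
    0.94, 0.01, 0.03, 0.02,   # from K4_ONLY
    0.02, 0.90, 0.04, 0.04,   # from K27_ONLY
    0.68, 0.05, 0.22, 0.05,   # from BIVALENT
    0.03, 0.03, 0.02, 0.92),  # from NEITHER
    nrow = 4L, byrow = TRUE, dimnames = list(t0 = states, t1 = states))
}

#' Generate a synthetic annotation
#'
#' Places `n_genes` TSSs on one chromosome with pairwise spacing >= 8 kb
#' (so 4 kb promoter windows never overlap), random strands, and samples
#' two disjoint gene sets (`testis_specific`, `ovary_specific`, 10% of
#' genes each).
#'
#' @param config A [synthetic_config()].
#' @return List with elements `tss` (data.frame as from [read_tss()]),
#'   `chrom_sizes` and `gene_sets`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_genes
  spacing <- 8000
  lo <- config$flank
  hi <- config$chrom_len - config$flank
  slack <- (hi - lo) - (n - 1) * spacing
  if (slack < 0) {
    stop("infeasible packing: ", n, " genes at >= ", spacing,
         " bp spacing do not fit in ", config$chrom_len, " bp")
  }
  u <- sort(runif(n, 0, slack))
  tss_pos <- as.integer(lo + (seq_len(n) - 1) * spacing + floor(u))
  tss <- data.frame(gene_id = sprintf("gene%04d", seq_len(n)),
                    chrom = "chrSim", tss = tss_pos,
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    stringsAsFactors = FALSE)
  set_size <- min(max(10L, round(0.1 * n)), n %/% 2L)
  shuffled <- sample(tss$gene_id)
  gene_sets <- list(testis_specific = sort(shuffled[seq_len(set_size)]),
                    ovary_specific = sort(shuffled[set_size + seq_len(set_size)]))
  list(tss = tss,
       chrom_sizes = c(chrSim = config$chrom_len),
       gene_sets = gene_sets)
}

#' Draw the true chromatin state of each gene
#'
#' States at the first timepoint follow `state_proportions`; states at the
#' second follow the row of `transition_matrix` for the first state.
#'
#' @param config A [synthetic_config()].
#' @return data.frame with columns `gene_id`, `state_t0`, `state_t1`
#'   (factors over [chromatin_states()]).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  states <- chromatin_states()
  n <- config$n_genes
  s0 <- sample(states, n, replace = TRUE, prob = config$state_proportions)
  s1 <- vapply(s0, function(s) {
    sample(states, 1L, prob = config$transition_matrix[s, ])
  }, character(1))
  data.frame(gene_id = sprintf("gene%04d", seq_len(n)),
             state_t0 = as_state_factor(s0), state_t1 = as_state_factor(s1),
             stringsAsFactors = FALSE)
}

state_has_mark <- function(state, mark) {
  if (mark == "H3K4me3") state %in% c("K4_ONLY", "BIVALENT")
  else if (mark == "H3K27me3") state %in% c("K27_ONLY", "BIVALENT")
  else rep(TRUE, length(state))
}

# window count draw: Poisson, or NB when overdispersion is finite
draw_counts <- function(n, mu, size) {
  if (is.finite(size)) stats::rnbinom(n, mu = mu, size = size) else rpois(n, mu)
}

# map offsets within the concatenated non-window space back to genomic
# coordinates (windows assumed sorted and non-overlapping)
nonwindow_positions <- function(u, windows, chrom_len) {
  gap_start <- c(0, windows$end)
  gap_end <- c(windows$start, chrom_len)
  gap_len <- gap_end - gap_start
  cum <- cumsum(gap_len)
  idx <- findInterval(u, c(0, cum[-length(cum)]))
  as.integer(gap_start[idx] + (u - c(0, cum)[idx]))
}

#' Simulate tag libraries for one timepoint
#'
#' Per promoter window the tag count is Poisson with the state-dependent
#' rate (H3: `lambda_h3`; IP marks: `ip_high_mult * lambda_h3` when the
#' true state carries the mark, `ip_low_mult * lambda_h3` otherwise) and
#' positions are uniform within the window; outside windows tags fall as
#' uniform background.
#'
#' @param truth data.frame from [simulate_truth()].
#' @param annotation List from [generate_annotation()].
#' @param config A [synthetic_config()].
#' @param timepoint 1 (uses `state_t0`) or 2 (`state_t1`).
#' @return Named list of three [tag_library()] objects: `h3`, `k4`, `k27`.
#' @export
simulate_tags <- function(truth, annotation, config, timepoint = 1L) {
  stopifnot(inherits(config, "synthetic_config"), timepoint %in% c(1L, 2L))
  state <- as.character(
    if (timepoint == 1L) truth$state_t0 else truth$state_t1)
  windows <- promoter_windows(annotation$tss, config$flank,
                              annotation$chrom_sizes)
  windows <- windows[order(windows$start), ]
  state <- state[match(windows$gene_id, truth$gene_id)]
  width <- windows$end - windows$start
  chrom_len <- config$chrom_len
  nonwin_len <- chrom_len - sum(width)
  cond <- paste0("t", timepoint)

  one_library <- function(mark, idx) {
    set.seed(config$seed + 1000L * timepoint + idx)
    if (mark == "H3") {
      mu <- rep(config$lambda_h3, nrow(windows))
      bg_rate <- config$background_rate
    } else {
      mult <- ifelse(state_has_mark(state, mark),
                     config$ip_high_mult, config$ip_low_mult)
      mu <- mult * config$lambda_h3
      bg_rate <- config$background_rate * config$ip_background_mult
    }
    counts <- draw_counts(nrow(windows), mu, config$overdispersion)
    pos <- rep(windows$start, counts) +
      floor(runif(sum(counts), 0, rep(width, counts)))
    n_bg <- rpois(1L, bg_rate * nonwin_len)
    if (n_bg > 0L) {
      bg <- nonwindow_positions(sort(runif(n_bg, 0, nonwin_len)),
                                windows, chrom_len)
      pos <- c(pos, bg)
    }
    tag_library(rep("chrSim", length(pos)), as.integer(pos),
                sample_id = paste("sim", mark, cond, sep = "_"),
                mark = mark, condition = cond,
                chrom_sizes = annotation$chrom_sizes)
  }
  list(h3 = one_library("H3", 1L),
       k4 = one_library("H3K4me3", 2L),
       k27 = one_library("H3K27me3", 3L))
}

#' Simulate state-dependent expression values
#'
#' Per gene, `value ~ Normal(expression_means[state], expression_sd)`.
#'
#' @inheritParams simulate_tags
#' @return data.frame with columns `gene_id`, `condition`, `value`.
#' @export
simulate_expression <- function(truth, config, timepoint = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 100L + timepoint)
  state <- as.character(
    if (timepoint == 1L) truth$state_t0 else truth$state_t1)
  data.frame(gene_id = truth$gene_id, condition = paste0("t", timepoint),
             value = rnorm(nrow(truth),
                           mean = config$expression_means[state],
                           sd = config$expression_sd),
             stringsAsFactors = FALSE)
}

#' Simulate a native ChIP-qPCR plate
#'
#' CT pairs are generated so that the noiseless bound/unbound ratio equals
#' the specified truth (`ct_bound = ct_unbound - log2(ratio)`), then
#' independent Gaussian noise is added to each CT.
#'
#' @param true_ratios Named numeric vector of true bound/unbound ratios
#'   per target (> 0).
#' @param antibody Antibody label for the specific rows.
#' @param igg_ratio Optional true ratio of the IgG control; when given,
#'   matching IgG rows are added for every target/replicate.
#' @param noise_sd_ct SD of the Gaussian CT noise (cycles, default 0.2).
#' @param n_replicates Replicates per target (default 3).
#' @param base_ct Unbound-fraction CT level (default 20 cycles).
#' @param seed Integer seed.
#' @return data.frame plate in the native-protocol layout accepted by
#'   [analyze_qpcr()].
#' @export
simulate_qpcr <- function(true_ratios, antibody = "H3K27me3",
                          igg_ratio = NULL, noise_sd_ct = 0.2,
                          n_replicates = 3L, base_ct = 20, seed = 1L) {
  stopifnot(all(true_ratios > 0), !is.null(names(true_ratios)))
  set.seed(seed)
  make_rows <- function(ab, ratios) {
    do.call(rbind, lapply(names(ratios), function(tg) {
      ct_unbound <- base_ct + rnorm(n_replicates, 0, noise_sd_ct)
      ct_bound <- base_ct - log2(ratios[[tg]]) +
        rnorm(n_replicates, 0, noise_sd_ct)
      data.frame(target = tg, antibody = ab,
                 replicate = seq_len(n_replicates),
                 ct_bound = ct_bound, ct_unbound = ct_unbound,
                 stringsAsFactors = FALSE)
    }))
  }
  plate <- make_rows(antibody, true_ratios)
  if (!is.null(igg_ratio)) {
    plate <- rbind(plate,
                   make_rows("IgG", setNames(rep(igg_ratio,
                                                 length(true_ratios)),
                                             names(true_ratios))))
  }
  rownames(plate) <- NULL
  plate
}

#' Simulate a uniform (background-only) tag library
#'
#' @param n_tags Number of tags.
#' @param chrom_len Chromosome length in bp.
#' @param mark,condition,sample_id Library metadata.
#' @param seed Optional seed; when `NULL` the current RNG state is used.
#' @return A [tag_library()] on chromosome `chrSim`.
#' @export
simulate_uniform_library <- function(n_tags, chrom_len, mark = "H3K27me3",
                                     condition = "uniform",
                                     sample_id = "sim_uniform",
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- sample.int(chrom_len, n_tags, replace = TRUE) - 1L
  tag_library(rep("chrSim", n_tags), pos, sample_id, mark, condition,
              chrom_sizes = c(chrSim = chrom_len))
}

#' Implant an enriched region into a tag library
#'
#' Adds Poisson-distributed extra tags over `[start, end)` so that the
#' local rate becomes `fold` times the library's genome-average rate.
#'
#' @param lib A [tag_library()] on a single chromosome.
#' @param start,end Implant interval (0-based half-open).
#' @param fold Target fold enrichment over the genome-average rate (> 1).
#' @param chrom_len Chromosome length used for the rate (bp).
#' @param seed Optional seed.
#' @return A new [tag_library()] including the implant.
#' @export
implant_tags <- function(lib, start, end, fold, chrom_len, seed = NULL) {
  stopifnot(inherits(lib, "tag_library"), fold > 1, end > start)
  if (!is.null(seed)) set.seed(seed)
  rate <- lib$total_tags / chrom_len
  n_extra <- rpois(1L, (fold - 1) * rate * (end - start))
  extra <- as.integer(floor(runif(n_extra, start, end)))
  tag_library(c(lib$chrom, rep(lib$chrom[1], n_extra)),
              c(lib$pos, extra), lib$sample_id, lib$mark, lib$condition)
}

#' Simulate a complete two-timepoint ChIP experiment
#'
#' Orchestrates [generate_annotation()], [simulate_truth()],
#' [simulate_tags()] and [simulate_expression()] for both timepoints.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `config`, `annotation`, `windows`, `truth`,
#'   `tags` (list `t1`, `t2`, each `h3`/`k4`/`k27`) and `expression`
#'   (list `t1`, `t2`).
#' @export
simulate_experiment <- function(config = synthetic_config()) {
  annotation <- generate_annotation(config)
  truth <- simulate_truth(config)
  list(config = config,
       annotation = annotation,
       windows = promoter_windows(annotation$tss, config$flank,
                                  annotation$chrom_sizes),
       truth = truth,
       tags = list(t1 = simulate_tags(truth, annotation, config, 1L),
                   t2 = simulate_tags(truth, annotation, config, 2L)),
       expression = list(t1 = simulate_expression(truth, config, 1L),
                         t2 = simulate_expression(truth, config, 2L)))
}
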