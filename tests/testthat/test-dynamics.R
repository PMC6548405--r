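test_that("transition tables count state flows over a shared universe", {
  g <- paste0("g", 1:4)
  t0 <- as_state_table(g, rep("BIVALENT", 4), "t0")
  t1 <- as_state_table(g, c("K4_ONLY", "K4_ONLY", "K4_ONLY", "BIVALENT"),
                       "t1")
  tt <- transition_table(t0, t1)
  expect_equal(unname(tt["BIVALENT", "K4_ONLY"]), 3L)
  expect_equal(unname(tt["BIVALENT", "BIVALENT"]), 1L)
  expect_equal(sum(tt), 4L)

  # identical tables give a diagonal matrix
  td <- transition_table(t1, t1)
  expect_equal(sum(td), sum(diag(td)))

  # universe mismatch names the offending genes
  t1b <- as_state_table(c(g[1:3], "gX"), rep("K4_ONLY", 4), "t1")
  expect_error(transition_table(t0, t1b), "gX")

  # restriction to a gene set controls the row sums
  tt_sub <- transition_table(t0, t1, gene_set = g[1:2])
  expect_equal(sum(tt_sub), 2L)
  expect_error(transition_table(t0, t1, gene_set = "gZ"), "absent")
})

test_that("the generating transition matrix is recovered from the pipeline", {
  cfg <- synthetic_config(seed = 2)
  ex <- simulate_experiment(cfg)
  sts <- lapply(1:2, function(tp) {
    tg <- ex$tags[[tp]]
    state_table(quantify_promoters(tg$k4, tg$k27, tg$h3, ex$windows),
                paste0("t", tp))
  })
  tt <- transition_table(sts[[1]], sts[[2]])
  for (from in chromatin_states()) {
    n_r <- sum(tt[from, ])
    for (to in chromatin_states()) {
      p <- cfg$transition_matrix[from, to]
      expect_lte(abs(tt[from, to] - n_r * p),
                 3 * sqrt(max(n_r * p * (1 - p), 1)))
    }
  }
})

test_that("resolution fractions reproduce printed worked examples", {
  mk <- function(stay, leave, to = "K4_ONLY") {
    m <- matrix(0L, 4, 4,
                dimnames = list(chromatin_states(), chromatin_states()))
    m["BIVALENT", "BIVALENT"] <- stay
    m["BIVALENT", to] <- leave
    transition_summary(m)
  }
  # 260 of 382 bivalent testis-determining genes shift to K4-only: 68%
  expect_equal(resolution_fraction(mk(382L - 260L, 260L))$percent, 68)
  # 173 of 385 bivalent ovary-determining genes shift to K4-only: 45%
  expect_equal(resolution_fraction(mk(385L - 173L, 173L))$percent, 45)
  # 242 of 342 bivalent ovary-determining genes remain bivalent: 71%
  r <- resolution_fraction(mk(242L, 100L), "BIVALENT", "BIVALENT")
  expect_equal(r$percent, 71)
  # 301 of 431 bivalent testis-determining genes remain bivalent: 70%
  r <- resolution_fraction(mk(301L, 130L), "BIVALENT", "BIVALENT")
  expect_equal(r$percent, 70)
  # 219 of 431 bivalent ovary-determining genes resolve (leave): 51%
  expect_equal(resolved_fraction(mk(431L - 219L, 219L))$percent, 51)

  expect_error(resolution_fraction(mk(0L, 0L)), "no genes")
})

test_that("resolution fractions over all destinations sum to 100%", {
  m <- matrix(c(7L, 11L, 23L, 9L), 1, 4,
              dimnames = list("BIVALENT", chromatin_states()))
  ts <- transition_summary(m)
  raw <- vapply(chromatin_states(),
                function(s) resolution_fraction(ts, "BIVALENT", s)$percent_raw,
                numeric(1))
  expect_equal(sum(raw), 100)
  rounded <- vapply(chromatin_states(),
                    function(s) resolution_fraction(ts, "BIVALENT", s)$percent,
                    numeric(1))
  expect_lte(abs(sum(rounded) - 100), 2)
  # all genes staying put gives 100% to the home state, 0 elsewhere
  stay <- matrix(c(0L, 0L, 12L, 0L), 1, 4,
                 dimnames = list("BIVALENT", chromatin_states()))
  expect_equal(resolution_fraction(transition_summary(stay),
                                   "BIVALENT", "BIVALENT")$percent, 100)
})

test_that("shared-state overlaps equal naive set intersections", {
  set.seed(31)
  g <- paste0("g", 1:200)
  sa <- sample(chromatin_states(), 200, replace = TRUE)
  sb <- sample(chromatin_states(), 200, replace = TRUE)
  a <- as_state_table(g, sa, "A")
  b <- as_state_table(g, sb, "B")
  ov <- shared_state_overlap(a, b, "BIVALENT")
  expect_equal(ov$n_a, sum(sa == "BIVALENT"))
  expect_equal(ov$n_b, sum(sb == "BIVALENT"))
  expect_equal(sort(ov$shared),
               sort(intersect(g[sa == "BIVALENT"], g[sb == "BIVALENT"])))
  expect_lte(ov$n_shared, min(ov$n_a, ov$n_b))

  # identical tables: intersection equals both sets
  ov2 <- shared_state_overlap(a, a, "K4_ONLY")
  expect_equal(ov2$n_shared, ov2$n_a)
  # disjoint state sets intersect in nothing
  c_tab <- as_state_table(g, rep("NEITHER", 200), "C")
  expect_equal(shared_state_overlap(a, c_tab, "BIVALENT")$n_shared, 0L)
})

test_that("expression-by-state computes group summaries and Welch tests", {
  g <- paste0("g", 1:8)
  st <- as_state_table(g, rep(c("K4_ONLY", "BIVALENT"), each = 4), "c")
  v <- c(1, 2, 3, 4, 1, 2, 3, 4)   # identical multisets
  expr <- data.frame(gene_id = g, condition = "c", value = v,
                     stringsAsFactors = FALSE)
  suppressWarnings(res <- expression_by_state(st, expr))
  tst <- res$tests[res$tests$state_a == "K4_ONLY" &
                   res$tests$state_b == "BIVALENT", ]
  expect_equal(tst$t, 0)
  expect_equal(tst$p_value, 1)
  expect_equal(res$groups$n[res$groups$state == "K4_ONLY"], 4L)
  expect_equal(res$groups$mean[res$groups$state == "K4_ONLY"], 2.5)

  # states with < 2 expressed genes are skipped with a warning
  st2 <- as_state_table(g, c(rep("K4_ONLY", 7), "K27_ONLY"), "c")
  w <- testthat::capture_warnings(expression_by_state(st2, expr))
  expect_true(any(grepl("fewer than 2", w)))
})
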