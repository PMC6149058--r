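# Hypergeometric, chi-square and Fisher representation statistics and BH.

test_that("hypergeom_representation matches full enumeration", {
  # proportional case: f is analytically 1, nothing significant
  r1 <- hypergeom_representation(10, 100, 100, 1000)
  expect_equal(r1$fold, 1)
  expect_gt(r1$p_over, 0.05)
  expect_equal(r1$p_over, hyper_tail_oracle(10, 100, 100, 1000),
               tolerance = 1e-12)

  # small worked case: p_over = C(4,4) C(6,1) / C(10,5) = 6/252
  r2 <- hypergeom_representation(4, 5, 4, 10)
  expect_equal(r2$fold, 2)
  expect_equal(r2$p_over, 6 / 252, tolerance = 1e-12)

  # enumeration oracle across all feasible configurations with N <= 30
  set.seed(5)
  for (i in 1:200) {
    N <- draw_between(2, 30)
    K <- draw_between(1, N - 1)
    n <- draw_between(1, N)
    k <- draw_between(max(0, n - (N - K)), min(n, K))
    r <- hypergeom_representation(k, n, K, N)
    expect_equal(r$p_over, hyper_tail_oracle(k, n, K, N, upper = TRUE),
                 tolerance = 1e-12)
    expect_equal(r$p_under, hyper_tail_oracle(k, n, K, N, upper = FALSE),
                 tolerance = 1e-12)
    # tail identity: p_over + p_under - P(X = k) = 1
    pmf <- choose(K, k) * choose(N - K, n - k) / choose(N, n)
    expect_equal(r$p_over + r$p_under - pmf, 1, tolerance = 1e-9)
  }

  expect_error(hypergeom_representation(6, 5, 10, 20), "k <= min")
  expect_error(hypergeom_representation(2, 25, 10, 20), "n <= N")
})

test_that("chisq_class_representation reproduces hand-computed values", {
  # exact expectation: chi-square 0, p 1, f 1
  r0 <- chisq_class_representation(30, 100, 0.3)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$fold, 1)

  # hand computation at the published intergenic baseline
  r1 <- chisq_class_representation(380, 1158, 0.3093)
  e_in <- 1158 * 0.3093
  e_out <- 1158 * (1 - 0.3093)
  stat <- (380 - e_in)^2 / e_in + (778 - e_out)^2 / e_out
  expect_equal(r1$expected_count, e_in)          # 358.17
  expect_equal(r1$statistic, stat, tolerance = 1e-12)
  expect_equal(r1$statistic, 1.927, tolerance = 1e-3)
  expect_equal(r1$p_value, pchisq(stat, 1, lower.tail = FALSE))
  expect_equal(r1$p_value, 0.165, tolerance = 1e-2)
  expect_equal(r1$fold, (380 / 1158) / 0.3093, tolerance = 1e-12)
  expect_equal(r1$fold, 1.061, tolerance = 1e-3)

  # extreme depletion
  r2 <- chisq_class_representation(0, 100, 0.5)
  expect_equal(r2$statistic, 100)
  expect_lt(r2$p_value, 1e-20)
  expect_equal(r2$fold, 0)

  # agreement with the standard goodness-of-fit routine
  cref <- suppressWarnings(chisq.test(c(380, 778), p = c(0.3093, 0.6907)))
  expect_equal(r1$statistic, unname(cref$statistic))
  expect_equal(r1$p_value, cref$p.value)

  expect_error(chisq_class_representation(5, 0, 0.3), "> 0")
  expect_error(chisq_class_representation(5, 10, 1.2), "between 0 and 1")
})

test_that("fold is invariant to joint scaling of observed and totals", {
  base <- chisq_class_representation(40, 200, 0.25)
  scaled <- chisq_class_representation(400, 2000, 0.25)
  expect_equal(base$fold, scaled$fold)
})

test_that("fisher_two_by_two matches table enumeration", {
  r0 <- fisher_two_by_two(5, 5, 5, 5)
  expect_equal(r0$odds_ratio, 1)
  expect_equal(r0$p_value, 1)

  r1 <- fisher_two_by_two(1, 9, 9, 1)
  expect_equal(r1$p_value, fisher_oracle(1, 9, 9, 1), tolerance = 1e-12)
  expect_equal(r1$p_value, 202 / choose(20, 10), tolerance = 1e-12)

  r2 <- fisher_two_by_two(0, 10, 10, 0)
  expect_equal(r2$p_value, fisher_oracle(0, 10, 10, 0), tolerance = 1e-12)
  expect_false(r2$degenerate)

  # zero margin: degenerate, p = 1, OR undefined
  r3 <- fisher_two_by_two(0, 0, 5, 5)
  expect_true(r3$degenerate)
  expect_equal(r3$p_value, 1)
  expect_true(is.na(r3$odds_ratio))

  # random tables with all margins <= 20
  set.seed(9)
  for (i in 1:100) {
    cells <- as.integer(sample(0:10, 4, replace = TRUE))
    if ((cells[1] + cells[2]) == 0 || (cells[3] + cells[4]) == 0 ||
        (cells[1] + cells[3]) == 0 || (cells[2] + cells[4]) == 0) next
    got <- fisher_two_by_two(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got$p_value,
                 fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("benjamini_hochberg is the step-up adjustment", {
  expect_equal(benjamini_hochberg(numeric()), numeric())
  expect_equal(benjamini_hochberg(0.03), 0.03)   # m = 1 identity
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))                      # hand step-up
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))

  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))        # never smaller than raw
    expect_true(all(adj <= 1))
    # identical rejection sets at any alpha vs the step-up definition
    for (alpha in c(0.01, 0.05, 0.2)) {
      m <- length(p); o <- order(p)
      kmax <- suppressWarnings(max(which(p[o] <= alpha * seq_len(m) / m)))
      stepup <- rep(FALSE, m)
      if (is.finite(kmax)) stepup[o[seq_len(kmax)]] <- TRUE
      expect_equal(adj <= alpha, stepup)
    }
  }
})

test_that("repeat and class representation wrappers assemble families", {
  g <- sim_genome(seed = 21, n_chroms = 1, chrom_length = 200000)
  sp <- sim_peaks(g$partition, 400, seed = 22)
  ann <- annotate_peaks(sp$peaks, g$partition, g$catalog)
  t <- tally_classes(ann)

  rr <- repeat_representation(t, g$catalog)
  expect_setequal(rr$category, g$catalog$category_counts$category)
  expect_equal(unique(rr$n), glance(t)$n_with_repeat)
  expect_equal(sum(rr$k), glance(t)$n_with_repeat)
  expect_true(all(rr$q_over >= rr$p_over - 1e-15))

  cr <- class_representation(t, g$partition)
  expect_equal(sum(cr$observed), glance(t)$total)
  expect_true(all(cr$fold >= 0))
  # f > 1 exactly when observed proportion exceeds the genome fraction
  expect_equal(cr$fold > 1, cr$observed / cr$total > cr$expected_prop)
})

test_that("transcript_class_enrichment recovers planted shifts", {
  # identical columns: folds 1, p 1
  eq <- transcript_class_enrichment(
    tibble::tibble(class = c("LINE", "SINE", "rest"),
                   count_a = c(100L, 200L, 700L),
                   count_b = c(100L, 200L, 700L)))
  expect_equal(eq$fold, rep(1, 3))
  expect_equal(eq$p_value, rep(1, 3))

  # one class's proportion doubled in condition A at large totals
  sim <- sim_class_counts(shift = c(LINE = 2), total_a = 1e5,
                          total_b = 1e5, seed = 31)
  enr <- transcript_class_enrichment(sim$counts)
  line <- enr[enr$class == "LINE", ]
  expected <- unname(sim$truth$expected_fold[sim$truth$class == "LINE"])
  expect_equal(line$fold, expected, tolerance = 0.1)
  expect_lt(line$q, 0.05)

  expect_error(transcript_class_enrichment(
    tibble::tibble(class = "A", count_a = 1L, count_b = 1L)),
    "at least two")
})

test_that("p-value floor renders as the near-zero convention", {
  expect_equal(format_pvalue(1e-310), "<1e-300")
  expect_equal(format_pvalue(0.0321), "0.0321")
  r <- hypergeom_representation(0, 500, 90000, 1e5)
  expect_gte(r$p_under, 1e-300)
})
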