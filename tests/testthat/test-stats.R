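mk_profile <- function(seconds) {
  structure(list(fish_id = "f", thresholds_cm_s = c(2, 12),
                 seconds = c(rest = seconds[1], moderate = seconds[2],
                             fast = seconds[3]),
                 fractions = 100 * seconds / sum(seconds),
                 effective_time_s = sum(seconds)),
            class = "fq_sap_profile")
}

test_that("Mann-Whitney: symmetry, identical samples, and empty-group error", {
  set.seed(5)
  a <- rnorm(15); b <- rnorm(12)
  expect_equal(mann_whitney(a, b)$p, mann_whitney(b, a)$p)
  same <- mann_whitney(a, a)
  expect_gt(same$p, 0.9)
  expect_error(mann_whitney(numeric(0), b), "non-empty")
})

test_that("Mann-Whitney agrees with exhaustive permutation for small samples", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  set.seed(6)
  for (i in 1:25) {
    na <- sample(2:5, 1)
    nb <- sample(2:5, 1)
    a <- round(rnorm(na), 3)
    b <- round(rnorm(nb, 0.5), 3)
    mw <- mann_whitney(a, b)
    expect_equal(mw$method, "exact")
    expect_equal(mw$p, oracle_mw_permutation_p(a, b), tolerance = 1e-10)
  }
})

test_that("Mann-Whitney falls back to the corrected normal approximation with ties", {
  a <- c(1, 1, 2, 3, 3, 3)
  b <- c(2, 2, 3, 4, 4, 5)
  mw <- mann_whitney(a, b)
  expect_equal(mw$method, "normal")
  expect_true(mw$p >= 0 && mw$p <= 1)
})

test_that("chi-square on SAP: homogeneity null and textbook statistic", {
  pa <- list(mk_profile(c(100, 100, 100)))
  pb <- list(mk_profile(c(100, 100, 100)))
  cs <- chi_square_sap(pa, pb)
  expect_equal(cs$statistic, 0)
  expect_equal(cs$p, 1)
  expect_equal(cs$df, 2)

  set.seed(7)
  for (i in 1:30) {
    sa <- matrix(sample(50:400, 6), 2)
    pa <- lapply(1:2, function(r) mk_profile(sa[r, ]))
    sb <- matrix(sample(50:400, 6), 2)
    pb <- lapply(1:2, function(r) mk_profile(sb[r, ]))
    cs <- chi_square_sap(pa, pb)
    tab <- rbind(colSums(sa), colSums(sb))
    expect_equal(cs$statistic, oracle_chisq_stat(tab), tolerance = 1e-12)
  }
})

test_that("chi-square flags low expected counts but still reports the test", {
  cs <- chi_square_sap(list(mk_profile(c(2, 1, 1))),
                       list(mk_profile(c(1, 2, 1))))
  expect_true(cs$low_expected_flag)
  expect_true(is.finite(cs$statistic))
})

test_that("Fisher r x c enumeration matches the classical 2x2 tail sum", {
  tab <- matrix(c(1, 9, 11, 3), 2, 2, byrow = TRUE)
  f <- fisher_exact_rxc(tab)
  expect_equal(f$p, oracle_fisher_2x2(tab), tolerance = 1e-12)
  expect_equal(f$p, fisher.test(tab)$p.value, tolerance = 1e-9)

  set.seed(9)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 6), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_rxc(tab)$p, oracle_fisher_2x2(tab),
                 tolerance = 1e-9)
  }
})

test_that("Fisher enumeration probabilities sum to 1 and respect symmetries", {
  set.seed(10)
  for (i in 1:10) {
    tab <- matrix(rpois(6, 4), 2, 3)
    f <- fisher_exact_rxc(tab)
    expect_lt(abs(f$prob_total - 1), 1e-9)
    expect_equal(fisher_exact_rxc(tab[2:1, ])$p, f$p, tolerance = 1e-12)
    expect_equal(fisher_exact_rxc(tab[, c(2, 1, 3)])$p, f$p,
                 tolerance = 1e-12)
    expect_equal(fisher_exact_rxc(t(tab))$p, f$p, tolerance = 1e-12)
  }
})

test_that("Fisher r x c agrees with the reference implementation on 3-row tables", {
  set.seed(12)
  for (i in 1:10) {
    tab <- matrix(rpois(6, 5) + 1, 3, 2)
    expect_equal(fisher_exact_rxc(tab)$p, fisher.test(tab)$p.value,
                 tolerance = 1e-7)
  }
})

test_that("Fisher degenerate and guard behavior", {
  tab <- matrix(c(0, 0, 5, 7), 2, 2, byrow = TRUE)  # zero row forces the table
  expect_equal(fisher_exact_rxc(tab)$p, 1)
  big <- matrix(c(300, 300, 300, 300), 2, 2)
  expect_error(fisher_exact_rxc(big), "guard")
})

test_that("type-I error study hits its trivial bounds", {
  r0 <- type_i_error_study("mann_whitney", n_per_group = 5, n_reps = 100,
                           alpha = 0, seed = 1)
  expect_equal(as.numeric(r0), 0)
  r1 <- type_i_error_study("mann_whitney", n_per_group = 5, n_reps = 100,
                           alpha = 1, seed = 1)
  expect_equal(as.numeric(r1), 1)
})

test_that("pairwise stats report covers every group pair and metric", {
  df <- data.frame(genotype = rep(c("WT", "HT", "HM"), each = 5),
                   dist = rnorm(15), speed = rnorm(15))
  tab <- pairwise_stats(df)
  expect_equal(nrow(tab), 3 * 2)
  expect_setequal(unique(tab$metric), c("dist", "speed"))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
})
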