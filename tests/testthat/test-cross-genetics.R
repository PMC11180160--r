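test_that("goodness-of-fit reproduces published and hand-computed statistics", {
  cases <- list(
    # observed, ratio, statistic, p (published table rows and hand oracle);
    # printed values carry 2-3 decimals, so agreement is asserted to the
    # printed precision (absolute)
    list(c(48, 10), c(3, 1), 1.86, 0.172),
    list(c(8, 6), c(1, 1), 0.286, 0.593),
    list(c(99, 43), c(3, 1), 2.113, 0.146),
    list(c(190, 71), c(3, 1), 0.676, 0.411),
    list(c(69, 33), c(3, 1), 2.941, 0.086),
    list(c(48, 61), c(1, 1), 1.550, 0.213),
    list(c(57, 59), c(1, 1), 0.034, 0.852),
    list(c(26, 30), c(1, 1), 0.286, 0.593),
    list(c(34, 70, 41), c(1, 2, 1), 0.848, 0.654),
    list(c(30, 26), c(1, 1), 0.286, 0.593),
    list(c(30, 31), c(1, 1), 0.016, 0.898),
    list(c(48, 10), c(9, 7), 16.562, NA) # hand oracle
  )
  for (cs in cases) {
    fam <- cross_family("fam", "F2", cs[[1]])
    r <- chi_square_gof(fam, ratio_hypothesis(cs[[2]]))
    dp <- nchar(sub("^[0-9]+\\.", "", format(cs[[3]])))
    expect_lt(abs(r$statistic - cs[[3]]), 0.75 * 10^-dp)
    if (!is.na(cs[[4]])) expect_lt(abs(r$p_value - cs[[4]]), 1.5e-3)
    expect_equal(r$df, length(cs[[1]]) - 1L)
    # cross-check against the plain-formula oracle
    h <- hand_gof(cs[[1]], cs[[2]])
    expect_equal(r$statistic, h$statistic, tolerance = 1e-12)
    expect_equal(r$p_value, h$p_value, tolerance = 1e-12)
  }
})

test_that("exact fits give statistic 0 and p 1, at any positive scaling", {
  for (mult in c(1, 2, 7, 100)) {
    r <- chi_square_gof(cross_family("f", "F2", mult * c(30, 10)),
                        ratio_hypothesis(c(3, 1)))
    expect_identical(r$statistic, 0)
    expect_identical(r$p_value, 1)
    expect_false(r$significant)
  }
})

test_that("goodness-of-fit validates its inputs", {
  fam <- cross_family("f", "F2", c(10, 20, 5))
  expect_error(chi_square_gof(fam, ratio_hypothesis(c(3, 1))), "classes")
  expect_error(chi_square_gof(cross_family("f", "F2", c(0, 0)),
                              ratio_hypothesis(c(3, 1))), "zero")
  expect_error(ratio_hypothesis(c(1, 0)), "positive")
  expect_error(cross_family("f", "F2", c(-1, 5)), "non-negative")
  # zero observed cells are allowed (they occur in real tables)
  expect_silent(r <- chi_square_gof(cross_family("f", "F2", c(12, 0)),
                                    ratio_hypothesis(c(1, 1))))
  expect_gt(r$statistic, 0)
})

test_that("p-value equal to alpha counts as non-significant", {
  r <- chi_square_gof(cross_family("f", "F2", c(48, 10)),
                      ratio_hypothesis(c(3, 1)), alpha = 0.05)
  r_at <- chi_square_gof(cross_family("f", "F2", c(48, 10)),
                         ratio_hypothesis(c(3, 1)), alpha = r$p_value)
  expect_false(r_at$significant)
})

test_that("hypothesis panel flags exactly the compatible ratios", {
  fam <- cross_family("F2", "F2", c(48, 10))
  tab <- test_hypothesis_panel(fam, mendelian_panel(), alpha = 0.05)
  expect_equal(tab$hypothesis,
               c("3:1", "9:7", "13:3", "15:1", "37:27", "63:1"))
  # hand oracle: 13:3 is also compatible with 48:10 at this sample size
  expect_equal(tab$rejected,
               c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(tab$statistic[2], 16.562, tolerance = 1e-3)
  expect_equal(tab$statistic[4], 11.959, tolerance = 1e-3)
  trivial <- test_hypothesis_panel(cross_family("t", "F2", c(3, 1)),
                                   list(ratio_hypothesis(c(3, 1))))
  expect_identical(trivial$statistic, 0)
  expect_false(trivial$rejected)
  d <- test_hypothesis_panel(cross_family("d", "F2", c(190, 71)),
                             list(ratio_hypothesis(c(3, 1))))
  expect_equal(d$statistic, 0.676, tolerance = 1e-3)
  expect_false(d$rejected)
  expect_error(test_hypothesis_panel(fam, list()), "empty")
})

test_that("heterogeneity partition matches published family sets", {
  f2 <- list(cross_family("M1", "F2", c(99, 43)),
             cross_family("M2", "F2", c(190, 71)),
             cross_family("M3", "F2", c(69, 33)))
  res <- heterogeneity_partition(f2, ratio_hypothesis(c(3, 1)))
  expect_lt(abs(res$heterogeneity$statistic - 1.182), 1e-3)
  expect_equal(res$heterogeneity$df, 2L)
  expect_lt(abs(res$heterogeneity$p_value - 0.553), 1.5e-3)
  expect_lt(abs(res$pooled$statistic - 4.547), 1e-3)
  expect_equal(res$pooled$observed, c(358, 147))

  bc <- list(cross_family("M1", "BC_Bs", c(48, 61)),
             cross_family("M2", "BC_Bs", c(57, 59)),
             cross_family("M3", "BC_Bs", c(26, 30)))
  res_bc <- heterogeneity_partition(bc, ratio_hypothesis(c(1, 1)))
  expect_lt(abs(res_bc$heterogeneity$statistic - 0.586), 1e-3)
  expect_lt(abs(res_bc$heterogeneity$p_value - 0.746), 1.5e-3)

  expect_error(heterogeneity_partition(f2[1], ratio_hypothesis(c(3, 1))),
               "two families")
})

test_that("exactly fitting families have zero heterogeneity", {
  fams <- list(cross_family("a", "F2", c(30, 10)),
               cross_family("b", "F2", c(60, 20)),
               cross_family("c", "F2", c(90, 30)))
  res <- heterogeneity_partition(fams, ratio_hypothesis(c(3, 1)))
  expect_equal(res$heterogeneity$statistic, 0, tolerance = 1e-12)
  expect_equal(res$total_statistic, 0, tolerance = 1e-12)
})

test_that("partition identity total = pooled + heterogeneity holds on random tables", {
  set.seed(42)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    classes <- sample(2:3, 1)
    ratio <- sample(1:4, classes, replace = TRUE)
    fams <- lapply(seq_len(k), function(j) {
      cross_family(paste0("f", j), "F2",
                   rmultinom(1, sample(20:200, 1),
                             prob = ratio / sum(ratio))[, 1])
    })
    res <- heterogeneity_partition(fams, ratio_hypothesis(ratio))
    expect_equal(res$total_statistic,
                 res$pooled$statistic + res$heterogeneity$statistic,
                 tolerance = 1e-9)
    expect_gte(res$heterogeneity$statistic, -1e-9)
    expect_equal(res$heterogeneity$df,
                 (k - 1L) * (classes - 1L))
  }
})

test_that("chi-square approximation brackets the exact multinomial tail at small n", {
  # exact binomial oracle for ratio 3:1; the approximation error is reported
  # (documented bound), not asserted to vanish
  worst <- 0
  for (n in 4:12) {
    for (k in 0:n) {
      o <- c(n - k, k)
      r <- chi_square_gof(cross_family("f", "F2", o),
                          ratio_hypothesis(c(3, 1)))
      ks <- 0:n
      stats <- vapply(ks, function(kk) hand_gof(c(n - kk, kk),
                                                c(3, 1))$statistic,
                      numeric(1))
      p_exact <- sum(dbinom(ks[stats >= r$statistic - 1e-12], n, 0.25))
      expect_gte(p_exact, 0); expect_lte(p_exact, 1 + 1e-9)
      worst <- max(worst, abs(p_exact - r$p_value))
    }
  }
  # measured worst-case approximation error for totals <= 12
  expect_lt(worst, 0.59)
})
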