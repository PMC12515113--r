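test_that("normality check behaves under null, alternative and degenerate input", {
  set.seed(1)
  # normal draws: mostly non-significant
  p_null <- replicate(60, normality_check(rnorm(500))$p)
  expect_gte(mean(p_null > 0.05), 0.9)
  # strongly bimodal mixture: essentially always significant
  p_alt <- replicate(30, {
    x <- c(rnorm(250, -4), rnorm(250, 4))
    normality_check(x)$p
  })
  expect_gte(mean(p_alt < 0.05), 0.95)
  expect_error(normality_check(c(1, 2)), "at least 3")
  expect_error(normality_check(rep(1, 10)), "constant")
})

test_that("paired Wilcoxon flags degeneracy and detects shifts", {
  x <- rnorm(10)
  expect_error(paired_test(x, x), "degenerate")
  expect_error(paired_test(1:4, 1:5), "equal-length")
  set.seed(2)
  p_shift <- replicate(60, {
    x <- rnorm(30, sd = 0.1)
    paired_test(x + 1.0, x)
  })
  expect_gte(mean(p_shift < 0.01), 0.95)
})

test_that("Wilcoxon type-I error stays near the nominal level", {
  set.seed(3)
  rej <- replicate(1000, paired_test(rnorm(30), rnorm(30)) < 0.05)
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("rank tests are invariant under the transforms that preserve their ranks", {
  set.seed(4)
  x <- rnorm(20); y <- rnorm(20, 0.5)
  # Mann-Whitney uses only the joint ranks: any strictly increasing map
  expect_equal(unpaired_test(x, y), unpaired_test(exp(x), exp(y)))
  # the signed-rank test ranks |x - y|: invariant under positive affine maps
  expect_equal(paired_test(x, y), paired_test(3 * x + 7, 3 * y + 7))
})

test_that("Holm step-down: hand example, edge cases, monotonicity", {
  r <- holm_adjust(c(0.01, 0.03, 0.04), alpha = 0.05)
  expect_equal(r$reject, c(TRUE, FALSE, FALSE))  # 0.01 < 0.05/3; 0.03 > 0.05/2
  expect_equal(r$adjusted[1], 0.03)
  single <- holm_adjust(0.04)
  expect_equal(single$adjusted, 0.04)
  expect_true(all(holm_adjust(rep(0, 5))$reject))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # rejections: unadjusted >= Holm >= Bonferroni on random p-vectors
  set.seed(5)
  for (i in 1:20) {
    p <- runif(8)^2
    n_raw <- sum(p <= 0.05)
    n_holm <- sum(holm_adjust(p)$reject)
    n_bonf <- sum(p.adjust(p, "bonferroni") <= 0.05)
    expect_gte(n_raw, n_holm)
    expect_gte(n_holm, n_bonf)
  }
})

test_that("summaries mirror the variant-by-status table layout", {
  res <- data.frame(
    variant = rep(c("single_O", "single_cl5"), each = 4),
    dental_status = rep(c("full", "full", "partial", "edentulous"), 2),
    dsc = c(0.9, 1.0, 0.95, 0.96, 0.85, 0.95, 0.9, 0.93))
  s <- summarize_results(res, "dsc")
  expect_equal(sort(rownames(s$table)), sort(c("single_O", "single_cl5")))
  expect_true("overall" %in% colnames(s$table))
  row <- s$stats[s$stats$variant == "single_O" &
                   s$stats$dental_status == "full", ]
  expect_equal(row$mean, 0.95)
  expect_equal(row$sd, sd(c(0.9, 1.0)))  # sample (n-1) denominator
  # brute-force group-by oracle across all groups
  for (i in seq_len(nrow(s$stats))) {
    st <- s$stats[i, ]
    vals <- if (st$dental_status == "overall") {
      res$dsc[res$variant == st$variant]
    } else {
      res$dsc[res$variant == st$variant &
                res$dental_status == st$dental_status]
    }
    expect_equal(st$mean, mean(vals))
    expect_equal(st$n, length(vals))
  }
  # missing group -> warning and blank cell, not an error
  res2 <- res[res$dental_status != "edentulous" | res$variant != "single_O", ]
  expect_warning(s2 <- summarize_results(res2, "dsc"), "empty group")
  expect_equal(s2$table["single_O", "edentulous"], "")
  expect_error(summarize_results(res[0, ], "dsc"), "empty result")
})
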