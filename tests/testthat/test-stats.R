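test_that("gating selects the t-test for normal, homoscedastic samples", {
  set.seed(1)
  r <- choose_and_run_test(rnorm(50), rnorm(50))
  expect_equal(r$test_used, "t_test")
  expect_true(all(r$shapiro_p > 0.05) && r$levene_p > 0.05)
})

test_that("gating falls back to Mann-Whitney for skewed samples", {
  set.seed(1)
  r <- choose_and_run_test(rexp(50), rnorm(50, 1))
  expect_equal(r$test_used, "mann_whitney")
})

test_that("identical samples give p = 1 and the gating is reported", {
  set.seed(2)
  x <- rnorm(30)
  r <- choose_and_run_test(x, x)
  expect_equal(r$p_value, 1, tolerance = 1e-12)
  expect_equal(r$n1, r$n2)
})

test_that("a zero-variance sample falls back to Mann-Whitney with a warning", {
  expect_warning(r <- choose_and_run_test(rep(5, 10), rnorm(10)),
                 "Mann-Whitney")
  expect_equal(r$test_used, "mann_whitney")
})

test_that("tiny samples are rejected", {
  expect_error(choose_and_run_test(1:2, rnorm(10)), "n >= 3")
})

test_that("the reported test always matches the recomputed gating decision", {
  set.seed(9)
  for (i in 1:20) {
    x <- if (i %% 2) rnorm(20) else rexp(20)
    y <- rnorm(20, sd = sample(c(1, 4), 1))
    r <- choose_and_run_test(x, y)
    gate <- all(c(shapiro.test(x)$p.value, shapiro.test(y)$p.value,
                  r$levene_p) > 0.05)
    expect_equal(r$test_used, if (gate) "t_test" else "mann_whitney")
  }
})

aligned_df <- function(mat_by_genotype, positions) {
  rows <- list()
  for (g in names(mat_by_genotype)) {
    m <- mat_by_genotype[[g]]
    for (i in seq_len(nrow(m)))
      rows[[length(rows) + 1]] <- data.frame(
        synapse = paste0(g, i), genotype = g, position_nm = positions,
        intensity = m[i, ])
  }
  do.call(rbind, rows)
}

test_that("identical profiles in both genotypes give genotype F = 0, p = 1", {
  pos <- seq(-100, 100, 20)
  shape <- dnorm(pos, 0, 50)
  m <- matrix(shape, 4, length(pos), byrow = TRUE)
  d <- aligned_df(list(control = m, cTKO = m), pos)
  fit <- suppressWarnings(profile_anova(d))
  g <- fit$table[fit$table$term == "genotype", ]
  expect_equal(g$F, 0)
  expect_equal(g$p, 1)
})

test_that("a 200 nm window on a 20 nm grid holds exactly 11 positions", {
  pos <- seq(-500, 500, 20)
  set.seed(4)
  m <- matrix(rnorm(8 * length(pos), 10), 8)
  d <- aligned_df(list(a = m[1:4, ], b = m[5:8, ]), pos)
  fit <- profile_anova(d, window_nm = 200)
  expect_equal(fit$n_positions, 11)
})

test_that("F statistics match the direct sum-of-squares oracle", {
  set.seed(5)
  pos <- seq(-100, 100, 20)
  m1 <- matrix(rnorm(6 * 11, 10), 6)
  m2 <- matrix(rnorm(6 * 11, 12), 6)
  d <- aligned_df(list(a = m1, b = m2), pos)
  fit <- profile_anova(d)
  oracle <- anova_ss_oracle(d$intensity, d$genotype, factor(d$position_nm))
  expect_equal(fit$table$F[1:3], oracle$F, tolerance = 1e-10)
})

test_that("a constant genotype shift is detected as a genotype main effect", {
  set.seed(6)
  pos <- seq(-100, 100, 20)
  shape <- 50 * dnorm(pos, 0, 60) / dnorm(0, 0, 60)
  mk <- function(n, delta) t(replicate(n, shape + delta + rnorm(11, 0, 2)))
  d <- aligned_df(list(control = mk(30, 0), cTKO = mk(30, 5)), pos)
  fit <- profile_anova(d)
  expect_lt(fit$genotype_p, 0.001)
})

test_that("genotype p-values are calibrated under label permutation", {
  set.seed(8)
  pos <- seq(-100, 100, 20)
  base <- matrix(rnorm(20 * 11, 10), 20)
  pvals <- replicate(200, {
    lab <- sample(rep(c("a", "b"), 10))
    d <- aligned_df(split.data.frame(base, lab), pos)
    profile_anova(d)$genotype_p
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("summaries report mean, SEM and n with the standard conventions", {
  s <- summarize_mean_sem(c(2, 4, 6))
  expect_equal(s$mean, 4)
  expect_equal(s$sem, 2 / sqrt(3))
  expect_true(is.na(summarize_mean_sem(5)$sem))
  expect_equal(summarize_mean_sem(rep(3, 8))$sem, 0)
  expect_equal(signif_stars(c(0.2, 0.03, 0.004, 0.0002)),
               c("ns", "*", "**", "***"))
})
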