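test_that("adjusted score averages casts on collected trials only", {
  play <- play_from_casts(c(3, 5, 4), c("collected", "forced_fail", "collected"))
  expect_equal(adjusted_score(play), 3.5)
  const <- play_from_casts(rep(6, 10), rep("collected", 10))
  expect_equal(adjusted_score(const), 6)
  all_ff <- play_from_casts(c(2, 3), rep("forced_fail", 2))
  expect_true(is.na(adjusted_score(all_ff)))
  # invariant to trial order and to the points column
  shuffled <- play
  shuffled$trials <- shuffled$trials[c(3, 1, 2), ]
  expect_equal(adjusted_score(shuffled), adjusted_score(play))
  repointed <- play
  repointed$trials$points_banked <- 0L
  expect_equal(adjusted_score(repointed), adjusted_score(play))
  # cohort wrapper keeps ids, groups, and NA propagation
  tab <- adjusted_scores(list(play, all_ff))
  expect_equal(tab$adjusted_score, c(3.5, NA))
})

test_that("JZS t-test Bayes factor matches the noncentral-t oracle", {
  for (case in list(c(t = 2.5, n1 = 11, n2 = 24), c(t = 0.3, n1 = 15, n2 = 15),
                    c(t = -1.8, n1 = 8, n2 = 30), c(t = 4.2, n1 = 20, n2 = 20))) {
    bf <- bf_ttest_from_t(case[["t"]], case[["n1"]], case[["n2"]])
    oracle <- bf_jzs_oracle(case[["t"]], case[["n1"]], case[["n2"]])
    expect_lt(abs(bf - oracle) / oracle, 1e-4)
  }
  # BF10 increases monotonically with the effect at fixed n
  bfs <- vapply(seq(0, 4, by = 0.5), function(t) bf_ttest_from_t(t, 12, 12), 1)
  expect_true(all(diff(bfs) > 0))
})

test_that("bf_ttest favours the null for same-distribution samples", {
  set.seed(211)
  x <- rnorm(60)
  y <- rnorm(60)
  bf <- bf_ttest(x, y)
  expect_lt(bf, 1)
  expect_equal(bf, bf_ttest(y, x), tolerance = 1e-9) # two-sided symmetry
  expect_error(bf_ttest(rep(1, 5), rep(1, 5)), "pooled variance")
  expect_equal(bf_band(c(0.3, 2, 5, 30)),
               c("favours null", "anecdotal", "moderate", "strong"))
})

test_that("one-way BF ANOVA matches a Monte-Carlo oracle and is label-symmetric", {
  set.seed(221)
  samples <- list(rnorm(10, 0), rnorm(10, 0.8), rnorm(10, -0.2))
  bf <- bf_anova_oneway(samples, prior_scale = 0.5)
  # Monte-Carlo integration of the same marginal over the g prior
  y <- unlist(samples)
  grp <- rep(1:3, each = 10)
  f <- artbayes:::anova_g_integrand(y, grp)
  set.seed(222)
  g_draws <- 1 / rgamma(2e5, shape = 0.5, rate = 0.5^2 / 2)
  mc <- mean(f(g_draws))
  expect_lt(abs(bf - mc) / mc, 1e-2)
  # permuting group labels leaves the BF unchanged
  perm <- list(samples[[3]], samples[[1]], samples[[2]])
  expect_equal(bf_anova_oneway(perm), bf, tolerance = 1e-9)
  # three groups from one distribution typically favour the null
  set.seed(223)
  null_bf <- bf_anova_oneway(list(rnorm(30), rnorm(30), rnorm(30)))
  expect_lt(null_bf, 1)
  # two-group case is directionally consistent with the t-test BF
  set.seed(224)
  a <- rnorm(15); b <- rnorm(15, 1.2)
  expect_gt(bf_anova_oneway(list(a, b)), 1)
  expect_gt(bf_ttest(a, b), 1)
  expect_error(bf_anova_oneway(list(rep(1, 5), rep(1, 5))), "degenerate")
})

test_that("permutation test: null behaviour, exactness, reproducibility", {
  x <- c(1, 2, 3, 4, 5)
  p_same <- permutation_test(x, x, n_perm = 500, seed = 231)$p_value
  expect_gt(p_same, 0.9)
  # disjoint supports: exact enumeration gives 2 / choose(10, 5)
  lo <- 1:5
  hi <- 101:105
  ex <- permutation_test(lo, hi, exact = TRUE)
  expect_equal(ex$p_value, 2 / choose(10, 5))
  expect_equal(ex$n_perm, choose(10L, 5L))
  # sampled version is reproducible under a seed, small here, never 0
  r1 <- permutation_test(lo, hi, n_perm = 300, seed = 232)
  r2 <- permutation_test(lo, hi, n_perm = 300, seed = 232)
  expect_identical(r1, r2)
  expect_gt(r1$p_value, 0)
  expect_lt(r1$p_value, 0.05)
})

test_that("associate computes Pearson r with the declared transform", {
  tab <- data.frame(x = 1:20, y = 2 * (1:20), z = exp(seq(-1, 1, length.out = 20)),
                    w = rep(1, 20))
  perfect <- associate(tab, "x", "y")
  expect_equal(perfect$r, 1, tolerance = 1e-12)
  expect_lt(perfect$p, 1e-10)
  expect_equal(perfect$n, 20)
  # log transform: r computed on log(y); here log(z) is linear in x
  lg <- associate(tab, "x", "z", transform_y = "log")
  expect_equal(lg$r, 1, tolerance = 1e-12)
  expect_equal(lg$transform, "log")
  # symmetric in the untransformed case
  expect_equal(associate(tab, "y", "x")$r, perfect$r)
  # Bonferroni only when a family is declared
  expect_true(is.na(perfect$p_bonferroni))
  fam <- associate(tab, "x", "y", family_size = 6)
  expect_equal(fam$p_bonferroni, min(1, fam$p * 6))
  expect_error(associate(tab, "x", "w"), "constant")
  tab$neg <- tab$x - 10
  expect_error(associate(tab, "x", "neg", transform_y = "log"), "positive")
  expect_error(associate(tab[1:2, ], "x", "y"), "3 complete pairs")
})

test_that("associations recover the synthetic covariate correlation", {
  d <- flat_design(1, 0.5, max_casts = 1)
  co <- simulate_cohort(group_spec(5000, 2, 0.3, 0.4, 0.4, "g"), d, seed = 241)
  cv <- simulate_covariates(
    co$truth, covariate_spec("vol", "gamma_plus", -0.4, 4000, 300), seed = 242)
  tab <- merge(co$truth, cv, by = "subject_id")
  res <- associate(tab, "vol", "gamma_true")
  expect_equal(res$r, -0.4, tolerance = 0.05)
})

test_that("TIV correction is a guarded ratio", {
  expect_equal(tiv_correct(4000, 1.6e6), 0.0025)
  expect_equal(tiv_correct(0, 1.6e6), 0)
  expect_equal(tiv_correct(2 * 4000, 2 * 1.6e6), tiv_correct(4000, 1.6e6))
  expect_error(tiv_correct(4000, 0), "> 0")
  expect_error(tiv_correct(-1, 100), ">= 0")
})
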