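test_that("near-deterministic agents cast to floor(omega) then collect", {
  # beta = 100: logistic saturates; omega = 3.2 => cast at l = 1..3, collect at 4
  p <- 0.2
  gamma <- 3.2 * -log(1 - p)
  d <- flat_design(20, p, max_casts = 10)
  play <- simulate_subject(model_params(gamma, 100), d, seed = 81)
  expect_true(all(play$trials$n_casts == 3L))
  expect_true(all(play$trials$ended_by == "collected"))
  expect_true(all(play$trials$points_banked == 15L))
  # censoring binds first when max_casts = 2
  d2 <- flat_design(20, p, max_casts = 2)
  play2 <- simulate_subject(model_params(gamma, 100), d2, seed = 82)
  expect_true(all(play2$trials$n_casts == 2L))
  expect_true(all(play2$trials$ended_by == "forced_fail"))
  expect_true(all(play2$trials$points_banked == 0L))
})

test_that("beta = 0 stopping matches the truncated fair-coin expectation", {
  # casts on a max_casts = 3 trial: P(0)=.5, P(1)=.25, P(2)=.125, P(3)=.125
  d <- flat_design(4000, 0.3, max_casts = 3)
  play <- simulate_subject(model_params(1, 0), d, seed = 91)
  exact_mean <- 0 * 0.5 + 1 * 0.25 + 2 * 0.125 + 3 * 0.125
  exact_var <- 0.25 + 4 * 0.125 + 9 * 0.125 - exact_mean^2
  se <- sqrt(exact_var / 4000)
  expect_lt(abs(mean(play$trials$n_casts) - exact_mean), 4 * se)
  # uncensored trials only: conditional stopping distribution
  unc <- play$trials$n_casts[play$trials$ended_by == "collected"]
  expect_equal(as.vector(table(factor(unc, 0:2))) / length(unc),
               c(0.5, 0.25, 0.125) / 0.875, tolerance = 0.05)
})

test_that("simulated plays always satisfy the play invariants", {
  d <- canonical_design(95)
  set.seed(96)
  for (i in 1:8) {
    play <- simulate_subject(model_params(runif(1, 0.1, 5), runif(1, 0, 2)),
                             d, seed = 900 + i)
    tr <- play$trials
    expect_true(all(tr$n_casts <= tr$max_casts))
    ff <- tr$ended_by == "forced_fail"
    expect_true(all(tr$n_casts[ff] == tr$max_casts[ff]))
    expect_true(all(tr$points_banked[ff] == 0))
    expect_true(all(tr$points_banked[!ff] == 5 * tr$n_casts[!ff]))
  }
  # determinism
  p1 <- simulate_subject(model_params(1.4, 0.3), d, seed = 99)
  p2 <- simulate_subject(model_params(1.4, 0.3), d, seed = 99)
  expect_identical(p1$trials, p2$trials)
})

test_that("cohort parameter draws honour the population-mean identity", {
  # 1-trial design keeps the play simulation cheap; the check is about
  # the lognormal parameter draws
  d <- flat_design(1, 0.5, max_casts = 1)
  co <- simulate_cohort(group_spec(5000, 2, 0.5, 0.5, 0.4, "g"), d, seed = 105)
  # lognormal(location = log(2) - 0.125, sd = 0.5) has mean 2
  se_g <- 2 * sqrt(exp(0.25) - 1) / sqrt(5000)
  expect_lt(abs(mean(co$truth$gamma_true) - 2), 4 * se_g)
  se_b <- 0.5 * sqrt(exp(0.16) - 1) / sqrt(5000)
  expect_lt(abs(mean(co$truth$beta_true) - 0.5), 4 * se_b)
})

test_that("degenerate log-SD gives identical subjects; labels are kept", {
  d <- flat_design(2, 0.3, max_casts = 2)
  co <- simulate_cohort(
    list(group_spec(3, 1.2, 0.4, 0, 0, "a"), group_spec(4, 2.5, 0.1, 0, 0, "b")),
    d, seed = 111
  )
  expect_equal(co$truth$gamma_true, rep(c(1.2, 2.5), c(3, 4)))
  expect_equal(co$truth$beta_true, rep(c(0.4, 0.1), c(3, 4)))
  expect_equal(co$truth$group, rep(c("a", "b"), c(3, 4)))
  expect_equal(vapply(co$plays, function(p) p$group, ""),
               rep(c("a", "b"), c(3, 4)))
  expect_false(anyDuplicated(co$truth$subject_id) > 0)
})

test_that("covariates hit their target correlations", {
  d <- flat_design(1, 0.5, max_casts = 1)
  co <- simulate_cohort(group_spec(5000, 2, 0.3, 0.4, 0.4, "g"), d, seed = 121)
  specs <- list(
    covariate_spec("vol", "gamma_plus", -0.4, mean = 4000, sd = 300),
    covariate_spec("noise", "none", 0, mean = 0, sd = 1),
    covariate_spec("read", "beta", 0.38, mean = 30, sd = 12)
  )
  cv <- simulate_covariates(co$truth, specs, seed = 122)
  expect_equal(cor(cv$vol, co$truth$gamma_true), -0.4, tolerance = 0.05)
  expect_lt(abs(cor(cv$noise, co$truth$gamma_true)), 0.05)
  # beta covariates correlate on the log scale
  expect_lt(abs(cor(cv$read, log(co$truth$beta_true)) - 0.38), 0.05)
  # degenerate sd gives a constant column, flagged downstream by associate()
  const <- simulate_covariates(co$truth,
                               covariate_spec("c0", "none", 0, 1, 0), seed = 123)
  expect_true(all(const$c0 == 1))
})
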