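test_that("split R-hat matches a hand-computed oracle on a fixed array", {
  draws <- matrix(c(1.1, 0.9, 1.3, 0.7, 1.0, 1.2, 0.8, 1.0,
                    2.0, 2.2, 1.8, 2.1, 2.4, 1.9, 2.0, 2.2), ncol = 2)
  # independent arithmetic: split each chain in half -> 4 chains of 4
  sp <- cbind(draws[1:4, 1], draws[5:8, 1], draws[1:4, 2], draws[5:8, 2])
  W <- mean(apply(sp, 2, var))
  B <- 4 * var(colMeans(sp))
  expected <- sqrt((3 / 4 * W + B / 4) / W)
  expect_equal(split_rhat(draws), expected, tolerance = 1e-12)
})

test_that("R-hat separates mixed from unmixed chains", {
  set.seed(131)
  iid <- matrix(rnorm(4000), ncol = 4)
  expect_lt(split_rhat(iid), 1.01)
  apart <- cbind(rnorm(1000, 0), rnorm(1000, 5))
  expect_gt(split_rhat(apart), 1.5)
  expect_error(split_rhat(matrix(rnorm(10), ncol = 1)), "2 chains")
  # ESS: iid draws have ESS near the draw count; sticky chains far less
  expect_gt(ess_basic(iid), 2000)
  sticky <- matrix(0, 500, 2)
  for (j in 1:2) {
    z <- rnorm(500)
    for (i in 2:500) z[i] <- 0.95 * z[i - 1] + sqrt(1 - 0.95^2) * z[i]
    sticky[, j] <- z
  }
  expect_lt(ess_basic(sticky), 300)
})

test_that("convergence_report works on raw draw lists and art_fit objects", {
  set.seed(141)
  dr <- list(a = matrix(rnorm(2000), ncol = 2),
             b = cbind(rnorm(1000, 0), rnorm(1000, 3)))
  rep <- convergence_report(dr, threshold = 1.05)
  expect_equal(rep$parameter, c("a", "b"))
  expect_true(rep$pass[1])
  expect_false(rep$pass[2])
  expect_error(convergence_report(list(a = matrix(1:10, ncol = 1))),
               "2 chains")
})

test_that("sampler likelihood equals the cognitive-model likelihood", {
  d <- canonical_design(151)
  plays <- lapply(1:3, function(i) {
    simulate_subject(model_params(0.5 + i, 0.1 * i), d, seed = 1500 + i,
                     subject_id = paste0("s", i))
  })
  dd <- artbayes:::stack_decisions(plays)
  set.seed(152)
  for (rep in 1:5) {
    gam <- runif(3, 0.2, 4)
    bet <- runif(3, 0.02, 1)
    by_sampler <- artbayes:::loglik_by_subject(dd, gam, bet)
    by_model <- vapply(1:3, function(i) {
      subject_loglik(model_params(gam[i], bet[i]), plays[[i]])
    }, 1)
    expect_equal(by_sampler, by_model, tolerance = 1e-10)
  }
})

test_that("a single well-sampled subject is recovered near the grid MLE", {
  sched <- build_schedule(500, 0.2, 0, 500)
  d <- generate_max_casts(sched, seed = 161)
  play <- simulate_subject(model_params(2, 0.3), d, seed = 162,
                           subject_id = "solo", group = "one")
  fit <- fit_hierarchical(list(play), spec = small_hier_spec(163))
  ind <- subset(fit$summary, level == "individual")
  g_hat <- ind$mean[ind$parameter == "gamma"]
  b_hat <- ind$mean[ind$parameter == "beta"]
  expect_lt(abs(g_hat - 2) / 2, 0.15)
  expect_lt(abs(b_hat - 0.3) / 0.3, 0.15)
  mle <- grid_mle(play)
  expect_lt(abs(g_hat - mle$gamma_plus) / mle$gamma_plus, 0.15)
  expect_lt(abs(b_hat - mle$beta) / mle$beta, 0.15)
})

test_that("point estimates are posterior means inside the subject CIs, and rank correctly", {
  d <- canonical_design(171)
  co <- simulate_cohort(group_spec(24, 1.8, 0.3, 0.4, 0.3, "dD"), d, seed = 172)
  fit <- fit_hierarchical(co$plays, spec = small_hier_spec(173))
  pe <- point_estimates(fit)
  expect_equal(pe$subject_id, co$truth$subject_id)
  ind <- subset(fit$summary, level == "individual" & parameter == "gamma")
  expect_true(all(pe$gamma_hat >= ind$q2.5 & pe$gamma_hat <= ind$q97.5))
  # estimated ranking tracks the generating ranking
  expect_gt(cor(pe$gamma_hat, co$truth$gamma_true, method = "spearman"), 0.5)
  expect_gt(cor(pe$beta_hat, co$truth$beta_true, method = "spearman"), 0.5)
})

test_that("with no data the posterior reproduces the prior", {
  empty_trials <- data.frame(p_yellow = numeric(), max_casts = integer(),
                             n_casts = integer(), ended_by = character(),
                             points_banked = integer())
  plays <- lapply(1:4, function(i) {
    subject_play(paste0("s", i), "g", "A", empty_trials)
  })
  fit <- fit_hierarchical(plays, spec = small_hier_spec(181, n_samples = 500))
  mu <- as.vector(fit$draws$g$mu_gamma)
  # thin to approximate independence before the KS comparison
  mu <- mu[seq(1, length(mu), by = 5)]
  ks <- suppressWarnings(stats::ks.test(mu, "pnorm", 0, 1.5))
  expect_gt(ks$p.value, 0.01)
  sg <- as.vector(fit$draws$g$sigma_gamma)
  expect_equal(mean(sg), sqrt(2 / pi), tolerance = 0.1) # half-Normal(1) mean
})

test_that("group-level posterior means are monotone in the generating mean", {
  d <- canonical_design(191)
  means <- c(0.8, 1.8, 3.2)
  est <- vapply(seq_along(means), function(i) {
    co <- simulate_cohort(group_spec(10, means[i], 0.3, 0.2, 0.2, "g"), d,
                          seed = 1900 + i)
    fit <- fit_hierarchical(co$plays,
                            spec = small_hier_spec(1950 + i, n_warmup = 300,
                                                   n_samples = 300, thin = 3))
    s <- fit$summary
    s$mean[s$parameter == "group_mean_gamma"]
  }, 1)
  expect_true(all(diff(est) > 0))
})

test_that("identical groups give overlapping group-level posteriors", {
  d <- canonical_design(201)
  co <- simulate_cohort(
    list(group_spec(8, 1.5, 0.25, 0.2, 0.2, "g1"),
         group_spec(8, 1.5, 0.25, 0.2, 0.2, "g2")),
    d, seed = 202
  )
  fit <- fit_hierarchical(co$plays,
                          spec = small_hier_spec(203, n_warmup = 300,
                                                 n_samples = 400, thin = 3))
  diff_draws <- fit$draws$g1$group_mean_gamma - fit$draws$g2$group_mean_gamma
  ci <- quantile(as.vector(diff_draws), c(0.025, 0.975))
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("corrupt data abort with a validation message", {
  tr <- data.frame(p_yellow = 0.1, max_casts = 5L, n_casts = 3L,
                   ended_by = "collected", points_banked = 15L)
  play <- subject_play("s1", "g", "A", tr)
  play$trials$p_yellow <- NaN # corrupt after construction
  expect_error(fit_hierarchical(list(play)), "non-finite likelihood")
})
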