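# Shared fixtures, all generated in code.

canonical_design <- function(seed = 101L) {
  generate_max_casts(canonical_schedule(), seed = seed)
}

# A flat 1-block design: constant p, handy for analytic checks.
flat_design <- function(n_trials, p, max_casts = NULL, seed = 102L) {
  sched <- build_schedule(n_trials, p, 0, n_trials)
  if (is.null(max_casts)) return(generate_max_casts(sched, seed = seed))
  new_design <- artbayes::df_to_designs(
    data.frame(version = "A", trial = seq_len(n_trials), p_yellow = sched$p_yellow,
               max_casts = rep_len(max_casts, n_trials)),
    block_size = n_trials
  )
  new_design[["A"]]
}

# Build a play directly from cast counts and outcomes.
play_from_casts <- function(n_casts, ended_by, p_yellow = 0.1,
                            max_casts = NULL, subject_id = "s1",
                            group = "test") {
  if (is.null(max_casts))
    max_casts <- ifelse(ended_by == "forced_fail", n_casts, n_casts + 5L)
  trials <- do.call(rbind, Map(function(c, e, m, p) {
    trial_outcome(p, m, c, e)
  }, n_casts, ended_by, max_casts, rep_len(p_yellow, length(n_casts))))
  subject_play(subject_id, group, "A", trials)
}

# Term-by-term likelihood oracle: loops over trials and opportunities,
# adding Bernoulli log-terms explicitly (independent of decision_table and
# of plogis). log(1/(1+e^z)) is written as -log1p(e^z) with an overflow
# guard so the oracle itself is accurate to ~1e-15.
brute_loglik <- function(gamma_plus, beta, play) {
  log_logistic <- function(z) { # log(1 / (1 + exp(z)))
    if (z > 35) -z - log1p(exp(-z)) else -log1p(exp(z))
  }
  ll <- 0
  for (k in seq_len(nrow(play$trials))) {
    tr <- play$trials[k, ]
    omega <- -gamma_plus / log(1 - tr$p_yellow)
    if (tr$n_casts > 0) {
      for (l in seq_len(tr$n_casts)) {
        ll <- ll + log_logistic(beta * (l - omega))
      }
    }
    if (tr$ended_by == "collected") {
      l <- tr$n_casts + 1
      ll <- ll + log_logistic(-beta * (l - omega)) # log(1 - p_cast)
    }
  }
  ll
}

# Independent JZS oracle: integrate the noncentral-t predictive over a
# Cauchy effect-size prior (different route than the g-integral used by
# bf_ttest_from_t).
bf_jzs_oracle <- function(t_stat, n1, n2, r = sqrt(2) / 2) {
  nu <- n1 + n2 - 2
  N <- n1 * n2 / (n1 + n2)
  # dt(ncp=) routinely warns about "full precision"; the achieved
  # accuracy (~1e-12) is far inside the 1e-4 comparison used here
  num <- suppressWarnings(integrate(function(delta) {
    dt(t_stat, nu, ncp = delta * sqrt(N)) * dcauchy(delta, 0, r)
  }, -Inf, Inf, rel.tol = 1e-10)$value)
  num / dt(t_stat, nu)
}

small_hier_spec <- function(seed, n_chains = 2L, n_warmup = 400L,
                            n_samples = 400L, thin = 4L) {
  hier_spec(n_chains = n_chains, n_warmup = n_warmup,
            n_samples = n_samples, thin = thin, seed = seed)
}
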