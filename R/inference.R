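#' Hierarchical model specification
#'
#' Individual parameters are modelled on the log scale:
#' `gamma_plus_i = exp(theta_i)` with `theta_i ~ Normal(mu_gamma,
#' sigma_gamma)`, and likewise `beta_i = exp(phi_i)`. Each group gets its
#' own `(mu, sigma)` per parameter. Priors are weakly informative:
#' `mu ~ Normal(prior_mu_mean, prior_mu_sd)` and
#' `sigma ~ half-Normal(prior_sigma_scale)`, wide enough to cover the
#' plausible range of both parameters (gamma-plus up to ~6, beta down to
#' ~0.03) without dominating a 30-trial likelihood.
#'
#' @param prior_mu_mean,prior_mu_sd Normal prior on the latent location.
#' @param prior_sigma_scale Scale of the half-Normal prior on the latent SD.
#' @param n_chains Number of MCMC chains (>= 2).
#' @param n_warmup Adaptation/burn-in iterations per chain (discarded).
#' @param n_samples Kept iterations per chain.
#' @param thin Sweeps of the random-walk updates per kept draw; the chain
#'   runs `n_warmup + n_samples * thin` iterations. Random-walk updates
#'   decorrelate more slowly than gradient-based samplers, so a modest
#'   thinning factor buys the effective sample size back cheaply.
#' @param seed Optional master seed; chains use derived substreams.
#' @param rhat_threshold Split R-hat convergence threshold.
#' @return An object of class `art_hier_spec`.
#' @export
hier_spec <- function(prior_mu_mean = 0, prior_mu_sd = 1.5,
                      prior_sigma_scale = 1, n_chains = 4L,
                      n_warmup = 1500L, n_samples = 1000L, thin = 16L,
                      seed = NULL, rhat_threshold = 1.05) {
  stopifnot(n_chains >= 2, n_samples >= 1, n_warmup >= 0, thin >= 1,
            prior_mu_sd > 0, prior_sigma_scale > 0, rhat_threshold > 1)
  structure(
    list(prior_mu_mean = prior_mu_mean, prior_mu_sd = prior_mu_sd,
         prior_sigma_scale = prior_sigma_scale,
         n_chains = as.integer(n_chains), n_warmup = as.integer(n_warmup),
         n_samples = as.integer(n_samples), thin = as.integer(thin),
         seed = seed, rhat_threshold = rhat_threshold),
    class = "art_hier_spec"
  )
}

# Flatten a list of plays into the vectors the sampler touches each
# iteration: one row per binary decision, with the owning subject's index.
stack_decisions <- function(plays) {
  tabs <- lapply(plays, decision_table)
  n_rows <- vapply(tabs, nrow, 1L)
  d <- do.call(rbind, tabs)
  list(
    subj = rep(seq_along(plays), n_rows),
    l = d$l, log_surv = d$log_surv,
    sign = ifelse(d$cast, 1, -1),
    n_subj = length(plays)
  )
}

# Per-subject log-likelihood at natural-scale parameter vectors.
loglik_by_subject <- function(dd, gamma, beta) {
  ll <- numeric(dd$n_subj)
  if (length(dd$l) == 0L) return(ll)
  omega <- -gamma[dd$subj] / dd$log_surv
  v <- rowsum(plogis(dd$sign * beta[dd$subj] * (omega - dd$l), log.p = TRUE),
              dd$subj)
  ll[as.integer(rownames(v))] <- v[, 1L]
  ll
}

# Coarse per-subject grid MLE on the log scale, used only to initialise
# chains near the posterior mass.
init_point <- function(dd) {
  n <- dd$n_subj
  if (length(dd$l) == 0L)
    return(list(theta = rep(0, n), phi = rep(-1, n)))
  lg <- seq(-2.5, 2.5, length.out = 15)
  lb <- seq(-4, 1.5, length.out = 15)
  best_ll <- rep(-Inf, n)
  best_th <- rep(0, n)
  best_ph <- rep(-1, n)
  for (g in lg) {
    for (b in lb) {
      ll <- loglik_by_subject(dd, rep(exp(g), n), rep(exp(b), n))
      win <- ll > best_ll
      best_ll[win] <- ll[win]
      best_th[win] <- g
      best_ph[win] <- b
    }
  }
  list(theta = best_th, phi = best_ph)
}

# One MCMC chain for one group: adaptive random-walk Metropolis on the
# per-subject latents and on log(sigma), conjugate Gibbs on mu.
mwg_chain <- function(dd, spec, init, chain_seed) {
  n <- dd$n_subj
  pm <- spec$prior_mu_mean
  ps <- spec$prior_mu_sd
  hs <- spec$prior_sigma_scale
  n_iter <- spec$n_warmup + spec$n_samples * spec$thin
  batch <- 50L

  with_seed(chain_seed, {
    th <- init$theta + rnorm(n, 0, 0.4)
    ph <- init$phi + rnorm(n, 0, 0.4)
    mu_g <- mean(th) + rnorm(1, 0, 0.3)
    mu_b <- mean(ph) + rnorm(1, 0, 0.3)
    sg <- exp(rnorm(1, log(0.4), 0.3))
    sb <- exp(rnorm(1, log(0.4), 0.3))
    step_th <- rep(0.4, n); step_ph <- rep(0.6, n)
    step_sg <- 0.5; step_sb <- 0.5
    step_tg <- 0.2; step_tb <- 0.2
    step_wg <- 0.3; step_wb <- 0.3
    acc_th <- numeric(n); acc_ph <- numeric(n)
    acc_sg <- 0; acc_sb <- 0; acc_tg <- 0; acc_tb <- 0
    acc_wg <- 0; acc_wb <- 0

    ll <- loglik_by_subject(dd, exp(th), exp(ph))
    keep <- spec$n_samples
    out <- list(
      theta = matrix(NA_real_, keep, n), phi = matrix(NA_real_, keep, n),
      mu_gamma = numeric(keep), sigma_gamma = numeric(keep),
      mu_beta = numeric(keep), sigma_beta = numeric(keep)
    )

    for (it in seq_len(n_iter)) {
      # individual latents (vectorised independent MH across subjects)
      th2 <- th + rnorm(n) * step_th
      ll2 <- loglik_by_subject(dd, exp(th2), exp(ph))
      logr <- ll2 - ll + dnorm(th2, mu_g, sg, log = TRUE) -
        dnorm(th, mu_g, sg, log = TRUE)
      acc <- log(runif(n)) < logr
      th[acc] <- th2[acc]; ll[acc] <- ll2[acc]; acc_th <- acc_th + acc

      ph2 <- ph + rnorm(n) * step_ph
      ll2 <- loglik_by_subject(dd, exp(th), exp(ph2))
      logr <- ll2 - ll + dnorm(ph2, mu_b, sb, log = TRUE) -
        dnorm(ph, mu_b, sb, log = TRUE)
      acc <- log(runif(n)) < logr
      ph[acc] <- ph2[acc]; ll[acc] <- ll2[acc]; acc_ph <- acc_ph + acc

      # conjugate Gibbs for the locations
      prec <- n / sg^2 + 1 / ps^2
      mu_g <- rnorm(1, (sum(th) / sg^2 + pm / ps^2) / prec, sqrt(1 / prec))
      prec <- n / sb^2 + 1 / ps^2
      mu_b <- rnorm(1, (sum(ph) / sb^2 + pm / ps^2) / prec, sqrt(1 / prec))

      # joint translation: shift mu and all latents together; the
      # within-group prior is invariant, so only the likelihood and the
      # prior on mu change. This decouples mu from the latent block.
      del <- rnorm(1, 0, step_tg)
      ll2 <- loglik_by_subject(dd, exp(th + del), exp(ph))
      logr <- sum(ll2 - ll) + dnorm(mu_g + del, pm, ps, log = TRUE) -
        dnorm(mu_g, pm, ps, log = TRUE)
      if (log(runif(1)) < logr) {
        th <- th + del; mu_g <- mu_g + del; ll <- ll2
        acc_tg <- acc_tg + 1
      }
      del <- rnorm(1, 0, step_tb)
      ll2 <- loglik_by_subject(dd, exp(th), exp(ph + del))
      logr <- sum(ll2 - ll) + dnorm(mu_b + del, pm, ps, log = TRUE) -
        dnorm(mu_b, pm, ps, log = TRUE)
      if (log(runif(1)) < logr) {
        ph <- ph + del; mu_b <- mu_b + del; ll <- ll2
        acc_tb <- acc_tb + 1
      }

      # interweaved scale move (non-centered coordinates): rescale sigma
      # and the latent deviations together with the standardized
      # residuals z = (theta - mu) / sigma held fixed. In z-coordinates
      # the hierarchy prior is invariant, so only the likelihood, the
      # half-Normal prior and the log-scale Jacobian enter. This walks
      # through the funnel that appears when sigma is near zero.
      eps <- rnorm(1, 0, step_wg)
      sg2 <- sg * exp(eps)
      th2 <- mu_g + (th - mu_g) * exp(eps)
      ll2 <- loglik_by_subject(dd, exp(th2), exp(ph))
      logr <- sum(ll2 - ll) + dnorm(sg2, 0, hs, log = TRUE) -
        dnorm(sg, 0, hs, log = TRUE) + log(sg2) - log(sg)
      if (log(runif(1)) < logr) {
        th <- th2; sg <- sg2; ll <- ll2; acc_wg <- acc_wg + 1
      }
      eps <- rnorm(1, 0, step_wb)
      sb2 <- sb * exp(eps)
      ph2 <- mu_b + (ph - mu_b) * exp(eps)
      ll2 <- loglik_by_subject(dd, exp(th), exp(ph2))
      logr <- sum(ll2 - ll) + dnorm(sb2, 0, hs, log = TRUE) -
        dnorm(sb, 0, hs, log = TRUE) + log(sb2) - log(sb)
      if (log(runif(1)) < logr) {
        ph <- ph2; sb <- sb2; ll <- ll2; acc_wb <- acc_wb + 1
      }

      # MH on log(sigma) with half-Normal prior (+ Jacobian)
      sg2 <- sg * exp(rnorm(1) * step_sg)
      logr <- sum(dnorm(th, mu_g, sg2, log = TRUE)) -
        sum(dnorm(th, mu_g, sg, log = TRUE)) +
        dnorm(sg2, 0, hs, log = TRUE) - dnorm(sg, 0, hs, log = TRUE) +
        log(sg2) - log(sg)
      if (log(runif(1)) < logr) { sg <- sg2; acc_sg <- acc_sg + 1 }
      sb2 <- sb * exp(rnorm(1) * step_sb)
      logr <- sum(dnorm(ph, mu_b, sb2, log = TRUE)) -
        sum(dnorm(ph, mu_b, sb, log = TRUE)) +
        dnorm(sb2, 0, hs, log = TRUE) - dnorm(sb, 0, hs, log = TRUE) +
        log(sb2) - log(sb)
      if (log(runif(1)) < logr) { sb <- sb2; acc_sb <- acc_sb + 1 }

      # step-size adaptation toward ~0.44 acceptance (warmup only)
      if (it <= spec$n_warmup && it %% batch == 0L) {
        clip <- function(x) pmin(pmax(x, 1e-3), 10)
        step_th <- clip(step_th * exp(acc_th / batch - 0.44))
        step_ph <- clip(step_ph * exp(acc_ph / batch - 0.44))
        step_sg <- clip(step_sg * exp(acc_sg / batch - 0.44))
        step_sb <- clip(step_sb * exp(acc_sb / batch - 0.44))
        step_tg <- clip(step_tg * exp(acc_tg / batch - 0.44))
        step_tb <- clip(step_tb * exp(acc_tb / batch - 0.44))
        step_wg <- clip(step_wg * exp(acc_wg / batch - 0.44))
        step_wb <- clip(step_wb * exp(acc_wb / batch - 0.44))
        acc_th[] <- 0; acc_ph[] <- 0; acc_sg <- 0; acc_sb <- 0
        acc_tg <- 0; acc_tb <- 0; acc_wg <- 0; acc_wb <- 0
      }

      if (it > spec$n_warmup && (it - spec$n_warmup) %% spec$thin == 0L) {
        j <- (it - spec$n_warmup) %/% spec$thin
        out$theta[j, ] <- th; out$phi[j, ] <- ph
        out$mu_gamma[j] <- mu_g; out$sigma_gamma[j] <- sg
        out$mu_beta[j] <- mu_b; out$sigma_beta[j] <- sb
      }
    }
    out
  })
}

#' Fit the hierarchical Bayesian model
#'
#' Estimates individual-level `(gamma_plus_i, beta_i)` and group-level
#' hyperparameters for every group by MCMC (adaptive Metropolis-within-
#' Gibbs), with each group fitted under its own `(mu, sigma)` pair per
#' parameter. The group-level natural-scale mean is computed per draw as
#' the lognormal population mean `exp(mu + sigma^2 / 2)`; the per-draw
#' average of the sampled individual parameters is also emitted
#' (`group_avg_*`) since either construction can be read as "the group
#' mean".
#'
#' @param plays List of [subject_play()] objects.
#' @param groups Optional character vector of group labels, one per play;
#'   defaults to each play's own `group` field.
#' @param spec An [hier_spec()].
#' @return An object of class `art_fit` with elements `summary` (tidy
#'   per-parameter posterior summary with R-hat and ESS), `draws` (per
#'   group, a named list of draw matrices, iterations x chains), `diagnostics`,
#'   and `converged`. Failure to reach the R-hat threshold sets
#'   `converged = FALSE` and is reported via `print()`, never silently
#'   dropped.
#' @export
fit_hierarchical <- function(plays, groups = NULL, spec = hier_spec()) {
  stopifnot(length(plays) >= 1, inherits(spec, "art_hier_spec"),
            all(vapply(plays, inherits, TRUE, "art_play")))
  if (is.null(groups))
    groups <- vapply(plays, function(p) p$group, "")
  stopifnot(length(groups) == length(plays))
  seeds <- derive_seeds(spec$seed, unique(groups))

  fits <- lapply(unique(groups), function(g) {
    idx <- which(groups == g)
    dd <- stack_decisions(plays[idx])
    bad <- !is.finite(loglik_by_subject(dd, rep(1, dd$n_subj),
                                        rep(1, dd$n_subj)))
    if (any(bad))
      stop_art("non-finite likelihood for subject(s) ",
               paste(vapply(plays[idx][bad], function(p) p$subject_id, ""),
                     collapse = ", "), " in group ", g,
               "; check the gameplay data")
    init <- init_point(dd)
    chain_seeds <- derive_seeds(seeds[[g]], paste0("chain", seq_len(spec$n_chains)))
    chains <- lapply(chain_seeds, function(s) mwg_chain(dd, spec, init, s))
    bind_group_draws(chains, vapply(plays[idx], function(p) p$subject_id, ""))
  })
  names(fits) <- unique(groups)

  summary_df <- do.call(rbind, lapply(names(fits), function(g) {
    summarize_group(fits[[g]], g)
  }))
  rownames(summary_df) <- NULL
  diagnostics <- summary_df[, c("level", "group", "subject_id", "parameter",
                                "rhat", "ess")]
  diagnostics$pass <- is.finite(diagnostics$rhat) &
    diagnostics$rhat <= spec$rhat_threshold
  structure(
    list(summary = summary_df, draws = fits, diagnostics = diagnostics,
         converged = all(diagnostics$pass), spec = spec),
    class = "art_fit"
  )
}

# Reshape per-chain output into draw matrices (iterations x chains) for
# every monitored quantity, including derived natural-scale group means.
bind_group_draws <- function(chains, subject_ids) {
  n_subj <- length(subject_ids)
  scalar <- function(name) sapply(chains, `[[`, name)
  draws <- list(
    mu_gamma = scalar("mu_gamma"), sigma_gamma = scalar("sigma_gamma"),
    mu_beta = scalar("mu_beta"), sigma_beta = scalar("sigma_beta")
  )
  draws$group_mean_gamma <- exp(draws$mu_gamma + draws$sigma_gamma^2 / 2)
  draws$group_mean_beta <- exp(draws$mu_beta + draws$sigma_beta^2 / 2)
  draws$group_avg_gamma <- sapply(chains, function(ch) rowMeans(exp(ch$theta)))
  draws$group_avg_beta <- sapply(chains, function(ch) rowMeans(exp(ch$phi)))
  for (i in seq_len(n_subj)) {
    draws[[paste0("gamma[", subject_ids[[i]], "]")]] <-
      sapply(chains, function(ch) exp(ch$theta[, i]))
    draws[[paste0("beta[", subject_ids[[i]], "]")]] <-
      sapply(chains, function(ch) exp(ch$phi[, i]))
  }
  attr(draws, "subject_ids") <- subject_ids
  draws
}

summarize_group <- function(draws, group) {
  subject_ids <- attr(draws, "subject_ids")
  rows <- lapply(names(draws), function(nm) {
    m <- draws[[nm]]
    q <- quantile(m, c(0.025, 0.975), names = FALSE)
    ind <- grepl("^(gamma|beta)\\[", nm)
    data.frame(
      level = if (ind) "individual" else "group",
      group = group,
      subject_id = if (ind) sub("^(gamma|beta)\\[(.*)\\]$", "\\2", nm)
                   else NA_character_,
      parameter = if (ind) sub("\\[.*$", "", nm) else nm,
      mean = mean(m), sd = sd(m), q2.5 = q[[1L]], q97.5 = q[[2L]],
      rhat = split_rhat(m), ess = ess_basic(m)
    )
  })
  do.call(rbind, rows)
}

#' @export
print.art_fit <- function(x, ...) {
  grp <- x$summary[x$summary$level == "group" &
                     grepl("^group_mean", x$summary$parameter), ]
  cat("Hierarchical ART model fit:", length(x$draws), "group(s),",
      sum(x$summary$level == "individual") / 2, "subjects\n")
  cat(if (x$converged) "All split R-hat <=" else "NOT CONVERGED: R-hat above",
      x$spec$rhat_threshold, "\n")
  print(grp[, c("group", "parameter", "mean", "q2.5", "q97.5", "rhat")],
        row.names = FALSE)
  invisible(x)
}

#' Posterior-mean point estimates per subject
#'
#' Extracts the per-subject posterior means of `gamma_plus` and `beta`,
#' the point estimates carried into the statistics stage.
#'
#' @param fit An [fit_hierarchical()] result.
#' @return Data frame `subject_id, group, gamma_hat, beta_hat`.
#' @export
point_estimates <- function(fit) {
  stopifnot(inherits(fit, "art_fit"))
  ind <- fit$summary[fit$summary$level == "individual", ]
  g <- ind[ind$parameter == "gamma", c("subject_id", "group", "mean")]
  b <- ind[ind$parameter == "beta", c("subject_id", "mean")]
  names(g)[names(g) == "mean"] <- "gamma_hat"
  names(b)[names(b) == "mean"] <- "beta_hat"
  merge(g, b, by = "subject_id", sort = FALSE)
}

#' Split R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half (so within-chain trends register as between-chain variance).
#'
#' @param draws Matrix of draws, iterations x chains (>= 2 chains).
#' @return The split R-hat (NA for fewer than 4 total split-halves worth of
#'   draws or zero variance).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) stop_art("R-hat requires at least 2 chains")
  n <- nrow(draws)
  half <- n %/% 2L
  if (half < 2L) return(NA_real_)
  sp <- cbind(draws[seq_len(half), , drop = FALSE],
              draws[(n - half + 1L):n, , drop = FALSE])
  W <- mean(apply(sp, 2L, var))
  B <- half * var(colMeans(sp))
  if (W == 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS pooled across chains: chain-mean-corrected
#' autocovariances are averaged over chains, converted to combined-draw
#' autocorrelations, and summed over Geyer initial-positive lag pairs.
#'
#' @param draws Matrix of draws, iterations x chains.
#' @return Estimated effective sample size.
#' @export
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  m <- ncol(draws)
  if (n < 4L) return(NA_real_)
  max_lag <- min(n - 1L, 500L)
  acov <- sapply(seq_len(m), function(j) {
    a <- acf(draws[, j], lag.max = max_lag, type = "covariance",
             plot = FALSE, demean = TRUE)$acf[, 1L, 1L]
    a
  })
  mean_acov <- rowMeans(acov)
  W <- mean_acov[[1L]] * n / (n - 1)
  B <- if (m > 1L) var(colMeans(draws)) else 0
  var_plus <- mean_acov[[1L]] * (n - 1) / n + B
  if (var_plus == 0) return(NA_real_)
  rho <- 1 - (W - mean_acov[-1L] * n / (n - 1)) / var_plus
  # Geyer initial positive sequence on paired sums
  tau <- 1
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[[t]] + rho[[t + 1L]]
    if (pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2L
  }
  min(n * m / tau, n * m)
}

#' Convergence report for a fitted model
#'
#' @param fit An `art_fit`, or a named list of draw matrices
#'   (iterations x chains).
#' @param threshold R-hat pass threshold (defaults to the fit's own).
#' @return Data frame `parameter, rhat, ess, pass` (for an `art_fit`, also
#'   `group`, `subject_id`, `level`).
#' @export
convergence_report <- function(fit, threshold = 1.05) {
  if (inherits(fit, "art_fit")) {
    out <- fit$diagnostics
    out$pass <- is.finite(out$rhat) & out$rhat <= threshold
    return(out)
  }
  stopifnot(is.list(fit), length(fit) >= 1)
  rows <- lapply(names(fit), function(nm) {
    m <- as.matrix(fit[[nm]])
    if (ncol(m) < 2L) stop_art("convergence_report requires >= 2 chains")
    data.frame(parameter = nm, rhat = split_rhat(m), ess = ess_basic(m))
  })
  out <- do.call(rbind, rows)
  out$pass <- is.finite(out$rhat) & out$rhat <= threshold
  out
}
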