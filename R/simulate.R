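#' Group specification for cohort simulation
#'
#' Individual parameters are drawn lognormally. The latent location is
#' `log(mean) - log_sd^2 / 2`, so `gamma_mean` / `beta_mean` are the
#' population means on the natural scale and directly comparable to
#' reported group means.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param gamma_mean,beta_mean Population means of gamma-plus and beta
#'   (natural scale, > 0).
#' @param log_sd_gamma,log_sd_beta Between-subject SDs on the log scale
#'   (>= 0; 0 gives identical subjects).
#' @param label Group name.
#' @return An object of class `art_group_spec`.
#' @export
group_spec <- function(n_subjects, gamma_mean, beta_mean,
                       log_sd_gamma = 0.3, log_sd_beta = 0.3,
                       label = "group") {
  stopifnot(n_subjects >= 1, gamma_mean > 0, beta_mean > 0,
            log_sd_gamma >= 0, log_sd_beta >= 0)
  structure(
    list(n_subjects = as.integer(n_subjects), gamma_mean = gamma_mean,
         beta_mean = beta_mean, log_sd_gamma = log_sd_gamma,
         log_sd_beta = log_sd_beta, label = as.character(label)),
    class = "art_group_spec"
  )
}

#' Covariate specification
#'
#' Describes one per-subject covariate (e.g. a reading raw score or a
#' TIV-corrected regional volume) with a target population correlation to a
#' generating model parameter. Correlation to `beta` is defined on the log
#' scale, matching the log transform applied in the association analyses.
#'
#' @param name Column name.
#' @param target_param One of `"gamma_plus"`, `"beta"`, `"none"`.
#' @param correlation Target correlation in \[-1, 1\] (ignored for
#'   `"none"`).
#' @param mean,sd Marginal mean and SD in natural units.
#' @return An object of class `art_covariate_spec`.
#' @export
covariate_spec <- function(name, target_param = "none", correlation = 0,
                           mean = 0, sd = 1) {
  target_param <- match.arg(target_param, c("gamma_plus", "beta", "none"))
  stopifnot(abs(correlation) <= 1, sd >= 0)
  structure(
    list(name = as.character(name), target_param = target_param,
         correlation = correlation, mean = mean, sd = sd),
    class = "art_covariate_spec"
  )
}

#' Simulate one subject playing a design
#'
#' Generative counterpart of the likelihood: at each opportunity `l` the
#' agent casts with probability [cast_probability()]; the trial ends at the
#' first collect, or by forced fail when the cast count reaches the design's
#' pre-generated `max_casts` (a yellow fish). Collected trials bank 5 points
#' per cast; forced fails bank nothing.
#'
#' @param params An [model_params()] object.
#' @param design An [generate_max_casts()] design.
#' @param seed Optional integer seed.
#' @param subject_id,group Identifiers stored in the result.
#' @return An [subject_play()] object.
#' @export
simulate_subject <- function(params, design, seed = NULL,
                             subject_id = "s1", group = "sim") {
  stopifnot(inherits(params, "art_params"), inherits(design, "art_design"))
  p <- design$schedule$p_yellow
  omega <- optimal_casts(params$gamma_plus, p)
  with_seed(seed, {
    rows <- lapply(seq_along(p), function(k) {
      m <- design$max_casts[[k]]
      casts <- 0L
      repeat {
        cast <- runif(1) < cast_probability(params$beta, omega[[k]], casts + 1L)
        if (!cast)
          return(trial_outcome(p[[k]], m, casts, "collected"))
        casts <- casts + 1L
        if (casts == m)
          return(trial_outcome(p[[k]], m, casts, "forced_fail"))
      }
    })
    subject_play(subject_id, group, design$version_label, do.call(rbind, rows))
  })
}

#' Simulate a cohort from group specifications
#'
#' Draws per-subject parameters from the lognormal hierarchy of each
#' [group_spec()], simulates every subject on `design`, and returns both
#' the plays and the ground-truth parameter table needed for recovery
#' tests.
#'
#' @param groups A single [group_spec()] or a list of them.
#' @param design An `art_design`, or a list of designs cycled over subjects
#'   (task versions).
#' @param seed Optional master seed; parameter draws and play decisions use
#'   derived substreams.
#' @return A list with `plays` (list of `art_play`) and `truth`
#'   (data frame `subject_id, group, version, gamma_true, beta_true`).
#' @export
simulate_cohort <- function(groups, design, seed = NULL) {
  if (inherits(groups, "art_group_spec")) groups <- list(groups)
  stopifnot(all(vapply(groups, inherits, TRUE, "art_group_spec")))
  designs <- if (inherits(design, "art_design")) list(design) else design
  seeds <- derive_seeds(seed, c("params", "decisions"))

  truth <- do.call(rbind, lapply(groups, function(g) {
    data.frame(
      group = g$label, n = seq_len(g$n_subjects),
      gamma_true = NA_real_, beta_true = NA_real_,
      gamma_mean = g$gamma_mean, beta_mean = g$beta_mean,
      log_sd_gamma = g$log_sd_gamma, log_sd_beta = g$log_sd_beta
    )
  }))
  truth$subject_id <- paste0(truth$group, "_", sprintf("%02d", truth$n))
  truth$version <- vapply(
    seq_len(nrow(truth)),
    function(i) designs[[(i - 1L) %% length(designs) + 1L]]$version_label, ""
  )
  with_seed(seeds$params, {
    truth$gamma_true <- exp(rnorm(
      nrow(truth), log(truth$gamma_mean) - truth$log_sd_gamma^2 / 2,
      truth$log_sd_gamma
    ))
    truth$beta_true <- exp(rnorm(
      nrow(truth), log(truth$beta_mean) - truth$log_sd_beta^2 / 2,
      truth$log_sd_beta
    ))
  })
  play_seeds <- derive_seeds(seeds$decisions, truth$subject_id)
  plays <- lapply(seq_len(nrow(truth)), function(i) {
    simulate_subject(
      model_params(truth$gamma_true[[i]], truth$beta_true[[i]]),
      designs[[(i - 1L) %% length(designs) + 1L]],
      seed = play_seeds[[i]],
      subject_id = truth$subject_id[[i]], group = truth$group[[i]]
    )
  })
  list(
    plays = plays,
    truth = truth[, c("subject_id", "group", "version",
                      "gamma_true", "beta_true")]
  )
}

#' Simulate covariates correlated with the generating parameters
#'
#' Each covariate is built from the standardized target parameter values
#' (natural scale for gamma-plus, log scale for beta) plus independent
#' Gaussian noise, so the population correlation hits the requested target;
#' `correlation = 0` or `target_param = "none"` gives pure noise.
#'
#' @param truth Ground-truth table from [simulate_cohort()].
#' @param specs A single [covariate_spec()] or a list of them.
#' @param seed Optional integer seed.
#' @return A data frame with `subject_id` and one column per covariate.
#' @export
simulate_covariates <- function(truth, specs, seed = NULL) {
  if (inherits(specs, "art_covariate_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, TRUE, "art_covariate_spec")))
  n <- nrow(truth)
  out <- data.frame(subject_id = truth$subject_id)
  with_seed(seed, {
    for (sp in specs) {
      z_t <- switch(sp$target_param,
        gamma_plus = as.numeric(scale(truth$gamma_true)),
        beta = as.numeric(scale(log(truth$beta_true))),
        none = rep(0, n)
      )
      rho <- if (sp$target_param == "none") 0 else sp$correlation
      z <- rho * z_t + sqrt(1 - rho^2) * rnorm(n)
      out[[sp$name]] <- sp$mean + sp$sd * z
    }
  })
  out
}
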