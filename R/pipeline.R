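#' Default pipeline configuration
#'
#' A fully-resolved configuration for [run_pipeline()]: the canonical task
#' design, a two-group cohort sized like the study sample (11 controls,
#' 24 dD) with group means at the reported posterior group means, two
#' illustrative covariates, the hierarchical-fit settings, and the
#' statistics options. Any field can be overridden via `...` or by an
#' entry in a JSON config file (see [read_config()]); unknown keys are
#' rejected.
#'
#' @param ... Named overrides of top-level config entries.
#' @return A named list (class `art_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = "art_run",
    log_level = "info",
    design = list(n_trials = 30L, p_start = 0.05, p_increment = 0.05,
                  block_size = 5L, n_versions = 3L),
    groups = list(
      list(label = "control", n_subjects = 11L, gamma_mean = 1.39,
           beta_mean = 0.25, log_sd_gamma = 0.3, log_sd_beta = 0.3),
      list(label = "dD", n_subjects = 24L, gamma_mean = 3.65,
           beta_mean = 0.07, log_sd_gamma = 0.3, log_sd_beta = 0.3)
    ),
    covariates = list(
      list(name = "reading_raw", target_param = "beta", correlation = 0.38,
           mean = 30, sd = 12),
      list(name = "right_caudate_tiv", target_param = "gamma_plus",
           correlation = -0.40, mean = 0.0025, sd = 0.0003)
    ),
    inference = list(n_chains = 4L, n_warmup = 1000L, n_samples = 1000L,
                     prior_mu_mean = 0, prior_mu_sd = 1.5,
                     prior_sigma_scale = 1, rhat_threshold = 1.05),
    statistics = list(cauchy_scale = 0.7071068, anova_scale = 0.5,
                      n_perm = 2000L),
    stages = list(simulate = TRUE, fit = TRUE, score = TRUE,
                  associate = TRUE, report = TRUE),
    gameplay_csv = NULL,
    covariates_csv = NULL
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop_art("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  structure(cfg, class = c("art_config", "list"))
}

#' Read a pipeline configuration from JSON
#'
#' Keys present in the file override [default_config()]; unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path JSON file.
#' @return An `art_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  do.call(default_config, raw)
}

log_msg <- function(level, msg, cfg_level = "info", json = FALSE) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  if (levels[[level]] < levels[[cfg_level]]) return(invisible())
  if (json) {
    message(jsonlite::toJSON(
      list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
           level = level, msg = msg),
      auto_unbox = TRUE))
  } else {
    message("[", level, "] ", msg)
  }
  invisible()
}

# Tiny polynomial rolling hash of a string; enough for manifest
# provenance (there is no cryptographic requirement). Kept in double
# arithmetic below 2^53 so every step is exact.
config_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 127 + b) %% 2^48
  sprintf("%06x%06x", as.integer(h %/% 2^24), as.integer(h %% 2^24))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages simulate -> fit -> score -> associate ->
#' report, writing every output, the fully-resolved configuration, and a
#' run manifest into `config$out_dir`. Re-running with the same config and
#' seed reproduces the simulation outputs byte-identically. If a stage
#' fails, the error names the stage and earlier outputs are left on disk.
#'
#' @param config An `art_config` from [default_config()] or
#'   [read_config()].
#' @return The manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(inherits(config, "art_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  path <- function(f) file.path(config$out_dir, f)
  stage <- "setup"
  st <- config$stages
  lv <- config$log_level

  result <- tryCatch({
    cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                 pretty = TRUE, null = "null")
    writeLines(cfg_json, path("config.json"))
    outputs <- c(outputs, "config.json")
    seeds <- derive_seeds(config$seed,
                          c("design", "cohort", "covariates", "fit"))

    plays <- NULL
    covs <- NULL
    if (isTRUE(st$simulate)) {
      stage <- "simulate"
      log_msg("info", "simulating design and cohort", lv)
      de <- config$design
      sched <- build_schedule(de$n_trials, de$p_start, de$p_increment,
                              de$block_size)
      base <- generate_max_casts(sched, seed = seeds$design)
      versions <- make_versions(base, de$n_versions, seed = seeds$design)
      write.csv(design_to_df(versions), path("design.csv"),
                row.names = FALSE, quote = FALSE)
      gspecs <- lapply(config$groups, function(g) do.call(group_spec, g))
      cohort <- simulate_cohort(gspecs, versions, seed = seeds$cohort)
      plays <- cohort$plays
      write_gameplay(plays, path("gameplay.csv"))
      write.csv(cohort$truth, path("truth.csv"), row.names = FALSE,
                quote = FALSE)
      cspecs <- lapply(config$covariates, function(s)
        do.call(covariate_spec, s))
      covs <- simulate_covariates(cohort$truth, cspecs,
                                  seed = seeds$covariates)
      write.csv(covs, path("covariates.csv"), row.names = FALSE,
                quote = FALSE)
      outputs <- c(outputs, "design.csv", "gameplay.csv", "truth.csv",
                   "covariates.csv")
    } else {
      stage <- "load"
      if (is.null(config$gameplay_csv))
        stop_art("simulation disabled and no `gameplay_csv` provided")
      plays <- read_gameplay(config$gameplay_csv)
      if (!is.null(config$covariates_csv))
        covs <- read.csv(config$covariates_csv)
    }

    pe <- NULL
    fit <- NULL
    if (isTRUE(st$fit)) {
      stage <- "fit"
      log_msg("info", paste("fitting hierarchical model,",
                            length(plays), "subjects"), lv)
      inf <- config$inference
      spec <- hier_spec(
        prior_mu_mean = inf$prior_mu_mean, prior_mu_sd = inf$prior_mu_sd,
        prior_sigma_scale = inf$prior_sigma_scale,
        n_chains = inf$n_chains, n_warmup = inf$n_warmup,
        n_samples = inf$n_samples, seed = seeds$fit,
        rhat_threshold = inf$rhat_threshold
      )
      fit <- fit_hierarchical(plays, spec = spec)
      write_posterior_summary(fit, path("posterior_summary.csv"))
      write_draws(fit, path("draws.csv"))
      pe <- point_estimates(fit)
      outputs <- c(outputs, "posterior_summary.csv", "draws.csv")
      if (!fit$converged)
        log_msg("warn", "fit did not reach the R-hat threshold; outputs marked unconverged",
                lv)
    }

    scores <- NULL
    if (isTRUE(st$score)) {
      stage <- "score"
      scores <- adjusted_scores(plays)
      write.csv(scores, path("scores.csv"), row.names = FALSE,
                quote = FALSE)
      outputs <- c(outputs, "scores.csv")
    }

    assoc <- NULL
    if (isTRUE(st$associate) && !is.null(pe) && !is.null(covs)) {
      stage <- "associate"
      tab <- merge(pe, covs, by = "subject_id")
      cov_names <- setdiff(names(covs), "subject_id")
      fam <- 2L * length(cov_names)
      assoc <- do.call(rbind, lapply(cov_names, function(cn) {
        rbind(
          as.data.frame(associate(tab, cn, "gamma_hat",
                                  family_size = fam)[c("x", "y", "n", "r",
                                                       "p", "transform",
                                                       "p_bonferroni")]),
          as.data.frame(associate(tab, cn, "beta_hat", transform_y = "log",
                                  family_size = fam)[c("x", "y", "n", "r",
                                                       "p", "transform",
                                                       "p_bonferroni")])
        )
      }))
      assoc$family <- fam
      write.csv(assoc, path("associations.csv"), row.names = FALSE)
      outputs <- c(outputs, "associations.csv")
    }

    if (isTRUE(st$report)) {
      stage <- "report"
      writeLines(render_report(config, fit, scores, assoc),
                 path("report.md"))
      outputs <- c(outputs, "report.md")
    }

    stage <- "manifest"
    manifest <- list(
      config_hash = config_hash(as.character(cfg_json)),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("artbayes")),
      outputs = outputs,
      started = format(t0, "%Y-%m-%dT%H:%M:%S"),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    )
    jsonlite::write_json(manifest, path("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    manifest
  }, error = function(e) {
    stop_art("pipeline failed in stage `", stage, "`: ",
             conditionMessage(e))
  })
  invisible(result)
}

# Plain-Markdown run summary with BF interpretation bands as annotations.
render_report <- function(config, fit, scores, assoc) {
  lines <- c("# ART pipeline report", "")
  if (!is.null(scores)) {
    lines <- c(lines, "## Adjusted scores", "")
    for (g in unique(scores$group)) {
      s <- scores$adjusted_score[scores$group == g]
      lines <- c(lines, sprintf(
        "- %s: n = %d, mean = %.2f, SD = %.2f (%d missing)",
        g, sum(scores$group == g), mean(s, na.rm = TRUE),
        sd(s, na.rm = TRUE), sum(is.na(s))))
    }
    gs <- split(scores$adjusted_score, scores$group)
    gs <- lapply(gs, function(v) v[!is.na(v)])
    if (length(gs) == 2L && all(vapply(gs, length, 1L) >= 2)) {
      bf <- bf_ttest(gs[[1L]], gs[[2L]],
                     config$statistics$cauchy_scale)
      pp <- permutation_test(gs[[1L]], gs[[2L]],
                             n_perm = config$statistics$n_perm,
                             seed = config$seed)
      lines <- c(lines, "",
                 sprintf("Group comparison: BF10 = %.3f (%s), permutation p = %.4f",
                         bf, bf_band(bf), pp$p_value))
    }
  }
  if (!is.null(fit)) {
    lines <- c(lines, "", "## Group-level posterior means", "")
    grp <- fit$summary[fit$summary$level == "group" &
                         grepl("^group_mean", fit$summary$parameter), ]
    lines <- c(lines, vapply(seq_len(nrow(grp)), function(i) {
      sprintf("- %s %s: %.3f (95%% CI %.3f, %.3f; R-hat %.3f)",
              grp$group[[i]], grp$parameter[[i]], grp$mean[[i]],
              grp$q2.5[[i]], grp$q97.5[[i]], grp$rhat[[i]])
    }, ""))
    lines <- c(lines, "", sprintf("Convergence: %s",
                                  if (fit$converged) "all R-hat within threshold"
                                  else "NOT converged"))
  }
  if (!is.null(assoc)) {
    lines <- c(lines, "", "## Associations", "")
    lines <- c(lines, vapply(seq_len(nrow(assoc)), function(i) {
      sprintf("- %s ~ %s%s: r = %.3f, p = %.4f (Bonferroni %.4f, family %d)",
              assoc$x[[i]], if (assoc$transform[[i]] == "log") "log " else "",
              assoc$y[[i]], assoc$r[[i]], assoc$p[[i]],
              assoc$p_bonferroni[[i]], assoc$family[[i]])
    }, ""))
  }
  lines
}
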