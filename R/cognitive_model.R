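#' Model parameters for one agent
#'
#' The two-parameter cognitive model of BART-family tasks describes an agent
#' by a risk-taking propensity `gamma_plus` (scales the internally optimal
#' number of casts) and a behavioral consistency `beta` (logistic steepness
#' of the cast/collect decision rule). Both are constrained non-negative.
#'
#' @param gamma_plus Risk-taking propensity, >= 0.
#' @param beta Behavioral consistency, >= 0.
#' @return An object of class `art_params`.
#' @export
model_params <- function(gamma_plus, beta) {
  stopifnot(length(gamma_plus) == 1L, length(beta) == 1L,
            is.finite(gamma_plus), is.finite(beta))
  if (gamma_plus < 0) stop_art("`gamma_plus` must be >= 0")
  if (beta < 0) stop_art("`beta` must be >= 0")
  structure(list(gamma_plus = gamma_plus, beta = beta), class = "art_params")
}

#' Internally optimal number of casts
#'
#' For yellow-fish probability `p` the agent's target number of casts is
#' `omega = -gamma_plus / log(1 - p)`: increasing in risk propensity,
#' decreasing in the loss probability.
#'
#' @param gamma_plus Risk propensity, >= 0 (vectorised).
#' @param p_yellow Per-cast loss probability, strictly in (0, 1)
#'   (vectorised).
#' @return `omega`, a non-negative numeric.
#' @examples
#' optimal_casts(1.39, 0.05) # about 27.1
#' @export
optimal_casts <- function(gamma_plus, p_yellow) {
  if (any(!is.finite(p_yellow)) || any(p_yellow <= 0) || any(p_yellow >= 1))
    stop_art("`p_yellow` must lie strictly in (0, 1)")
  if (any(gamma_plus < 0)) stop_art("`gamma_plus` must be >= 0")
  -gamma_plus / log1p(-p_yellow)
}

#' Probability of casting at a given opportunity
#'
#' Logistic response function `p_cast = 1 / (1 + exp(beta * (l - omega)))`.
#' Equals 0.5 when `l == omega` and for `beta == 0`; strictly decreasing in
#' the opportunity index `l` when `beta > 0`. Evaluated through `plogis()`
#' so it saturates without overflow.
#'
#' @param beta Behavioral consistency, >= 0.
#' @param omega Optimal-cast target, >= 0.
#' @param l Opportunity index (1, 2, ...).
#' @param log.p Return the log probability.
#' @return Cast probability in (0, 1) (vectorised over the longest input).
#' @examples
#' cast_probability(0.5, 10, 1) # 0.989
#' @export
cast_probability <- function(beta, omega, l, log.p = FALSE) {
  if (any(beta < 0)) stop_art("`beta` must be >= 0")
  plogis(beta * (omega - l), log.p = log.p)
}

#' Construct a trial outcome record
#'
#' @param p_yellow Trial yellow-fish probability in (0, 1).
#' @param max_casts Pre-generated cast at which the yellow fish is caught.
#' @param n_casts Casts the participant actually made.
#' @param ended_by Either `"collected"` (voluntary stop after `n_casts`
#'   casts) or `"forced_fail"` (yellow fish at `n_casts == max_casts`).
#' @param points_banked Points kept: 5 per cast when collected, 0 on a
#'   forced fail.
#' @return A one-row data frame (class `art_trial` rows are plain rows of
#'   the `trials` table inside [subject_play()]).
#' @export
trial_outcome <- function(p_yellow, max_casts, n_casts, ended_by,
                          points_banked = NULL) {
  ended_by <- match.arg(ended_by, c("collected", "forced_fail"))
  if (p_yellow <= 0 || p_yellow >= 1)
    stop_art("`p_yellow` must lie strictly in (0, 1)")
  if (n_casts > max_casts)
    stop_art("`n_casts` (", n_casts, ") exceeds `max_casts` (", max_casts, ")")
  if (ended_by == "forced_fail" && n_casts != max_casts)
    stop_art("a forced_fail trial must have n_casts == max_casts")
  if (is.null(points_banked))
    points_banked <- if (ended_by == "collected") 5L * n_casts else 0L
  data.frame(p_yellow = p_yellow, max_casts = as.integer(max_casts),
             n_casts = as.integer(n_casts), ended_by = ended_by,
             points_banked = as.integer(points_banked))
}

#' One subject's play of the task
#'
#' @param subject_id Identifier.
#' @param group Group label (e.g. `"control"`, `"dD"`).
#' @param version_label Task version played.
#' @param trials Data frame of trial rows as produced by [trial_outcome()]
#'   (columns `p_yellow, max_casts, n_casts, ended_by, points_banked`).
#' @return An object of class `art_play`.
#' @export
subject_play <- function(subject_id, group, version_label, trials) {
  need <- c("p_yellow", "max_casts", "n_casts", "ended_by", "points_banked")
  stopifnot(is.data.frame(trials), all(need %in% names(trials)))
  bad <- which(trials$n_casts > trials$max_casts |
                 !(trials$ended_by %in% c("collected", "forced_fail")) |
                 (trials$ended_by == "forced_fail" &
                    trials$n_casts != trials$max_casts))
  if (length(bad))
    stop_art("invalid trials at position(s) ", paste(bad, collapse = ", "),
             " for subject ", subject_id)
  structure(
    list(subject_id = as.character(subject_id), group = as.character(group),
         version_label = as.character(version_label),
         trials = trials[, need]),
    class = "art_play"
  )
}

#' @export
print.art_play <- function(x, ...) {
  cat("ART play: subject", x$subject_id, "(", x$group, "), version",
      x$version_label, "-", nrow(x$trials), "trials,",
      sum(x$trials$points_banked), "points\n")
  invisible(x)
}

# Flatten a play into one row per modelled binary decision.
# Cast decisions at opportunities 1..n_casts; on collected trials one
# additional collect decision at opportunity n_casts + 1. Forced-fail trials
# contribute no collect term (the collect decision is censored by the
# yellow fish).
decision_table <- function(play) {
  tr <- play$trials
  n_cast <- tr$n_casts
  n_dec <- n_cast + (tr$ended_by == "collected")
  k <- rep(seq_len(nrow(tr)), n_dec)
  l <- sequence(n_dec)
  data.frame(
    l = l,
    log_surv = log1p(-tr$p_yellow)[k], # log(1 - p), denominator of omega
    cast = l <= n_cast[k]
  )
}

#' Log-likelihood of one trial
#'
#' Under the model each opportunity is a Bernoulli cast/collect decision
#' with cast probability from [cast_probability()]. A collected trial with
#' `c` casts contributes `c` cast terms plus one collect term at
#' opportunity `c + 1`; a forced-fail trial contributes only its
#' `max_casts` cast terms (the collect decision is censored).
#'
#' @param params An [model_params()] object.
#' @param trial A one-row trial data frame ([trial_outcome()]).
#' @return The trial log-likelihood (<= 0).
#' @export
trial_loglik <- function(params, trial) {
  stopifnot(inherits(params, "art_params"))
  play <- subject_play("tmp", "tmp", "A", trial)
  subject_loglik(params, play)
}

#' Log-likelihood of a subject's full play
#'
#' Sum of [trial_loglik()] over trials (decisions are conditionally
#' independent given the parameters).
#'
#' @param params An [model_params()] object.
#' @param play An [subject_play()] object.
#' @return Total log-likelihood (<= 0; 0 for an empty trial list).
#' @export
subject_loglik <- function(params, play) {
  stopifnot(inherits(params, "art_params"), inherits(play, "art_play"))
  if (nrow(play$trials) == 0L) return(0)
  d <- decision_table(play)
  omega <- -params$gamma_plus / d$log_surv
  x <- params$beta * (omega - d$l)
  sum(plogis(ifelse(d$cast, x, -x), log.p = TRUE))
}

#' Grid-search maximum-likelihood estimate of (gamma_plus, beta)
#'
#' A deliberately simple, sampler-free estimator used as an independent
#' oracle for parameter recovery: evaluates the exact likelihood on a log
#' grid and returns the maximising pair.
#'
#' @param play An [subject_play()] object.
#' @param log_gamma_grid,log_beta_grid Grid of candidate values on the log
#'   scale.
#' @return A list with `gamma_plus`, `beta` and the attained `loglik`.
#' @export
grid_mle <- function(play,
                     log_gamma_grid = seq(-2.5, 2.5, length.out = 61),
                     log_beta_grid = seq(-4, 2, length.out = 61)) {
  stopifnot(inherits(play, "art_play"))
  d <- decision_table(play)
  s <- ifelse(d$cast, 1, -1)
  best <- c(ll = -Inf, g = NA_real_, b = NA_real_)
  for (lg in log_gamma_grid) {
    omega <- -exp(lg) / d$log_surv
    dom <- omega - d$l
    for (lb in log_beta_grid) {
      ll <- sum(plogis(s * exp(lb) * dom, log.p = TRUE))
      if (ll > best[["ll"]]) best <- c(ll = ll, g = lg, b = lb)
    }
  }
  list(gamma_plus = exp(best[["g"]]), beta = exp(best[["b"]]),
       loglik = best[["ll"]])
}
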