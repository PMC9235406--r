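#' Adjusted score of one subject
#'
#' The task's overall performance measure: the average number of casts over
#' trials ended by voluntary collection. Trials on which the yellow fish
#' was caught (forced fails) are excluded; a subject with no collected
#' trial gets `NA`, which propagates as missing through downstream
#' statistics rather than as zero.
#'
#' @param play An [subject_play()] object.
#' @return Mean casts on collected trials, or `NA_real_`.
#' @export
adjusted_score <- function(play) {
  stopifnot(inherits(play, "art_play"))
  kept <- play$trials$n_casts[play$trials$ended_by == "collected"]
  if (length(kept) == 0L) return(NA_real_)
  mean(kept)
}

#' Adjusted scores for a cohort
#'
#' @param plays List of [subject_play()] objects.
#' @return Data frame `subject_id, group, adjusted_score`.
#' @export
adjusted_scores <- function(plays) {
  data.frame(
    subject_id = vapply(plays, function(p) p$subject_id, ""),
    group = vapply(plays, function(p) p$group, ""),
    adjusted_score = vapply(plays, adjusted_score, 1)
  )
}

# Density of the default (Zellner-Siow) prior on g:
# g ~ InverseGamma(1/2, r^2/2), i.e. sqrt(g) has a half-Cauchy(r) flavour
# making the implied effect-size prior Cauchy(0, r).
dinvgamma_half <- function(g, r) {
  (r^2 / 2)^(0.5) / gamma(0.5) * g^(-1.5) * exp(-r^2 / (2 * g))
}

#' Default-prior (JZS) Bayes factor for a two-sample comparison
#'
#' Bayes factor `BF10` for a difference in means between two independent
#' samples under the Jeffreys-Zellner-Siow setup: Cauchy prior with scale
#' `cauchy_scale` on the standardized effect size, Jeffreys priors on the
#' nuisance parameters. Computed by numerical quadrature of the
#' g-representation of the marginal likelihood. Values below 1 favour the
#' null (no difference); 1-3 is anecdotal, 3-10 moderate, >10 strong
#' evidence for a difference.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param cauchy_scale Prior scale on the effect size (default
#'   `sqrt(2)/2`, the common "medium" default).
#' @return `BF10` (scalar).
#' @export
bf_ttest <- function(x, y, cauchy_scale = sqrt(2) / 2) {
  stopifnot(length(x) >= 2, length(y) >= 2,
            all(is.finite(x)), all(is.finite(y)), cauchy_scale > 0)
  n1 <- length(x); n2 <- length(y)
  nu <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / nu
  if (sp2 == 0) stop_art("zero pooled variance: Bayes factor undefined")
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  bf_ttest_from_t(t_stat, n1, n2, cauchy_scale)
}

#' @rdname bf_ttest
#' @param t_stat Observed two-sample t statistic.
#' @param n1,n2 Group sizes.
#' @export
bf_ttest_from_t <- function(t_stat, n1, n2, cauchy_scale = sqrt(2) / 2) {
  nu <- n1 + n2 - 2
  N <- n1 * n2 / (n1 + n2)
  log_h0 <- -(nu + 1) / 2 * log1p(t_stat^2 / nu)
  f <- function(g) {
    exp(-0.5 * log1p(N * g) -
          (nu + 1) / 2 * log1p(t_stat^2 / ((1 + N * g) * nu)) - log_h0) *
      dinvgamma_half(g, cauchy_scale)
  }
  int <- integrate(f, 0, Inf, rel.tol = 1e-9, abs.tol = 0)
  int$value
}

#' Default-prior one-way Bayes-factor ANOVA
#'
#' Bayes factor `BF10` against the grand-mean null for a one-way layout:
#' sum-to-zero group effects get a g-prior (`theta ~ N(0, g sigma^2 I)` on
#' an orthonormal between-group basis) with `g ~ InverseGamma(1/2,
#' prior_scale^2 / 2)`; the marginal likelihood is a one-dimensional
#' integral over `g`, evaluated by quadrature. With two groups this is
#' directionally consistent with [bf_ttest()].
#'
#' @param samples List of numeric vectors, one per group (>= 2 groups,
#'   each n >= 2).
#' @param prior_scale Scale of the effect prior (default 0.5, the common
#'   default for fixed effects).
#' @return `BF10` (scalar).
#' @export
bf_anova_oneway <- function(samples, prior_scale = 0.5) {
  stopifnot(is.list(samples), length(samples) >= 2,
            all(vapply(samples, length, 1L) >= 2), prior_scale > 0)
  y <- unlist(samples, use.names = FALSE)
  if (var(y) == 0) stop_art("degenerate data: zero total variance")
  grp <- rep(seq_along(samples), vapply(samples, length, 1L))
  f <- anova_g_integrand(y, grp)
  int <- integrate(function(g) f(g) * dinvgamma_half(g, prior_scale),
                   0, Inf, rel.tol = 1e-9, abs.tol = 0)
  int$value
}

# Conditional Bayes factor BF(g) = p(y | g) / p(y | null) for the one-way
# g-prior model, as a function usable under any prior on g. Obtained by
# analytic integration of the location, scale (Jeffreys) and effects.
anova_g_integrand <- function(y, grp) {
  n <- length(y)
  J <- max(grp)
  X <- outer(grp, seq_len(J), `==`) * 1 # n x J dummies
  P <- qr.Q(qr(cbind(1, diag(J))))[, 2:J, drop = FALSE] # sum-to-zero basis
  Xs <- scale(X %*% P, center = TRUE, scale = FALSE) # project out intercept
  yc <- y - mean(y)
  XtX <- crossprod(Xs)
  Xty <- crossprod(Xs, yc)
  ss0 <- sum(yc^2)
  function(g) {
    vapply(g, function(gi) {
      M <- diag(ncol(Xs)) / gi + XtX
      # R_g = yc' (I + g Xs Xs')^{-1} yc via Woodbury
      rg <- ss0 - drop(crossprod(Xty, solve(M, Xty)))
      det_term <- determinant(diag(ncol(Xs)) + gi * XtX, logarithm = TRUE)
      exp(-0.5 * det_term$modulus - (n - 1) / 2 * (log(rg) - log(ss0)))
    }, 1)
  }
}

#' Two-sample permutation test
#'
#' Two-sided permutation p-value for a difference between samples under
#' random relabelling, with the add-one convention
#' `p = (b + 1) / (n_perm + 1)` so p is never exactly zero.
#'
#' @param x,y Numeric samples.
#' @param statistic Test statistic; only `"mean_diff"` is implemented.
#' @param n_perm Number of random permutations (>= 100); ignored when
#'   `exact = TRUE`.
#' @param seed Optional integer seed.
#' @param exact Enumerate all label assignments instead of sampling them
#'   (feasible for small samples only); the p-value is then the exact
#'   proportion of assignments at least as extreme as the observed one.
#' @return List with `p_value`, `observed` statistic and `n_perm` (the
#'   number of assignments considered).
#' @export
permutation_test <- function(x, y, statistic = "mean_diff",
                             n_perm = 10000L, seed = NULL, exact = FALSE) {
  statistic <- match.arg(statistic, "mean_diff")
  stopifnot(length(x) >= 1, length(y) >= 1)
  pooled <- c(x, y)
  n1 <- length(x)
  obs <- mean(x) - mean(y)
  if (exact) {
    splits <- utils::combn(length(pooled), n1)
    perm <- apply(splits, 2L, function(idx) {
      mean(pooled[idx]) - mean(pooled[-idx])
    })
    b <- sum(abs(perm) >= abs(obs) - 1e-12)
    return(list(p_value = b / ncol(splits), observed = obs,
                n_perm = ncol(splits)))
  }
  stopifnot(n_perm >= 100)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), n1)
      mean(pooled[idx]) - mean(pooled[-idx])
    }, 1)
  })
  b <- sum(abs(perm) >= abs(obs) - 1e-12)
  list(p_value = (b + 1) / (n_perm + 1), observed = obs,
       n_perm = as.integer(n_perm))
}

#' Pearson association between two cohort columns
#'
#' Pearson correlation with two-sided p on complete cases, with the
#' analysis' optional log transform of the y variable (used for beta,
#' which is positively skewed). A Bonferroni-adjusted p is attached when a
#' family size is declared.
#'
#' @param table Data frame (e.g. a cohort table).
#' @param x_name,y_name Column names.
#' @param transform_y `"none"` or `"log"`.
#' @param family_size Optional number of tests in the declared family for
#'   Bonferroni adjustment.
#' @return An `art_association`: list with `x`, `y`, `n`, `r`, `p`,
#'   `transform`, and `p_bonferroni` (NA when no family declared).
#' @export
associate <- function(table, x_name, y_name, transform_y = c("none", "log"),
                      family_size = NULL) {
  transform_y <- match.arg(transform_y)
  stopifnot(is.data.frame(table), x_name %in% names(table),
            y_name %in% names(table))
  x <- table[[x_name]]
  y <- table[[y_name]]
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_art("need >= 3 complete pairs")
  if (transform_y == "log") {
    if (any(y <= 0))
      stop_art("log transform of `", y_name,
               "` requires strictly positive values")
    y <- log(y)
  }
  if (sd(x) == 0 || sd(y) == 0)
    stop_art("correlation undefined: `",
             if (sd(x) == 0) x_name else y_name, "` is constant")
  ct <- cor.test(x, y, method = "pearson")
  structure(
    list(x = x_name, y = y_name, n = length(x),
         r = unname(ct$estimate), p = ct$p.value, transform = transform_y,
         p_bonferroni = if (is.null(family_size)) NA_real_
                        else min(1, ct$p.value * family_size)),
    class = "art_association"
  )
}

#' @export
print.art_association <- function(x, ...) {
  cat(sprintf("r(%s, %s%s) = %.3f, p = %.4g, n = %d\n", x$x,
              if (x$transform == "log") "log " else "", x$y, x$r, x$p, x$n))
  invisible(x)
}

#' Correct a regional volume by total intracranial volume
#'
#' @param volume Regional volume (mm^3, >= 0).
#' @param tiv Total intracranial volume (mm^3, > 0).
#' @return The dimensionless ratio `volume / tiv` (vectorised).
#' @export
tiv_correct <- function(volume, tiv) {
  if (any(tiv <= 0)) stop_art("`tiv` must be > 0")
  if (any(volume < 0)) stop_art("`volume` must be >= 0")
  volume / tiv
}

#' Interpretation band for a Bayes factor
#'
#' Annotation only (never a decision rule): BF10 below 1 favours the null;
#' 1-3 anecdotal, 3-10 moderate, above 10 strong evidence for the
#' alternative.
#'
#' @param bf10 Bayes factor(s).
#' @return Character vector of band labels.
#' @export
bf_band <- function(bf10) {
  cut(bf10, c(-Inf, 1, 3, 10, Inf),
      labels = c("favours null", "anecdotal", "moderate", "strong"),
      right = TRUE) |> as.character()
}
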