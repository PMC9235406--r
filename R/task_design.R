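#' Build the ART yellow-fish probability schedule
#'
#' The Angling Risk Task presents a fixed per-trial probability of catching
#' a yellow fish (the loss event). The canonical design starts at 0.05 and
#' increases by 0.05 after every block of five trials, giving six probability
#' levels over 30 trials.
#'
#' @param n_trials Total number of trials; must be a multiple of
#'   `block_size`.
#' @param p_start Yellow-fish probability in the first block, in (0, 1).
#' @param p_increment Additive increment applied at each block boundary
#'   (may be 0 for a constant schedule).
#' @param block_size Number of consecutive trials sharing one probability.
#'
#' @return An object of class `art_schedule`: a list with `p_yellow`
#'   (numeric, length `n_trials`) and `block_size`.
#'
#' @examples
#' sched <- build_schedule(30, 0.05, 0.05, 5)
#' sched$p_yellow[c(1, 6, 30)] # 0.05, 0.10, 0.30
#' @export
build_schedule <- function(n_trials, p_start, p_increment, block_size) {
  stopifnot(
    length(n_trials) == 1L, n_trials >= 1, n_trials == as.integer(n_trials),
    length(block_size) == 1L, block_size >= 1,
    block_size == as.integer(block_size),
    length(p_start) == 1L, length(p_increment) == 1L
  )
  if (n_trials %% block_size != 0)
    stop_art("`n_trials` (", n_trials, ") must be divisible by `block_size` (",
             block_size, ")")
  n_blocks <- n_trials %/% block_size
  p <- p_start + (seq_len(n_blocks) - 1) * p_increment
  if (any(p <= 0) || any(p >= 1))
    stop_art("schedule probabilities must lie strictly in (0, 1); got range [",
             min(p), ", ", max(p), "]")
  structure(
    list(p_yellow = rep(p, each = block_size), block_size = as.integer(block_size)),
    class = "art_schedule"
  )
}

#' Canonical 30-trial ART schedule
#'
#' Convenience wrapper for `build_schedule(30, 0.05, 0.05, 5)`.
#' @return An `art_schedule`.
#' @export
canonical_schedule <- function() build_schedule(30L, 0.05, 0.05, 5L)

#' Expected maximum casts under a schedule
#'
#' The pre-generated maximum casts have mean equal to the reciprocal of the
#' trial's yellow-fish probability. For the canonical design the mean over
#' trials is 49/6 = 8.1667.
#'
#' @param schedule An `art_schedule`.
#' @return A list with `per_trial` (numeric vector, `1 / p_yellow`) and
#'   `design_mean` (their average over trials).
#' @export
expected_max_casts <- function(schedule) {
  stopifnot(inherits(schedule, "art_schedule"))
  per_trial <- 1 / schedule$p_yellow
  list(per_trial = per_trial, design_mean = mean(per_trial))
}

#' Pre-generate a maximum-cast sequence
#'
#' Max casts are drawn per trial from a geometric distribution on
#' \{1, 2, ...\} with success probability `p_yellow` -- the waiting time to
#' the first yellow fish under independent per-cast catches, so
#' `E[max_casts] = 1/p`.
#'
#' @param schedule An `art_schedule`.
#' @param seed Optional integer seed for reproducibility.
#' @param version_label Label for the resulting design (default `"A"`).
#' @return An object of class `art_design`: list with `schedule`,
#'   `max_casts` (positive integers) and `version_label`.
#' @export
generate_max_casts <- function(schedule, seed = NULL, version_label = "A") {
  stopifnot(inherits(schedule, "art_schedule"))
  mc <- with_seed(seed, rgeom(length(schedule$p_yellow), schedule$p_yellow) + 1L)
  new_design(schedule, mc, version_label)
}

new_design <- function(schedule, max_casts, version_label) {
  stopifnot(length(max_casts) == length(schedule$p_yellow), all(max_casts >= 1))
  structure(
    list(schedule = schedule, max_casts = as.integer(max_casts),
         version_label = as.character(version_label)),
    class = "art_design"
  )
}

#' @export
print.art_design <- function(x, ...) {
  cat("ART design, version", x$version_label, "-", length(x$max_casts),
      "trials,", length(unique(x$schedule$p_yellow)), "probability levels\n")
  invisible(x)
}

#' Derive reordered task versions
#'
#' Versions share the same multiset of maximum casts within each probability
#' block but present them in a different order; version A is the unshuffled
#' input.
#'
#' @param design An `art_design`.
#' @param n_versions Number of versions (>= 1); the first is `design` itself.
#' @param seed Optional integer seed for the within-block shuffles.
#' @return A list of `art_design` objects labelled `A`, `B`, `C`, ...
#' @export
make_versions <- function(design, n_versions, seed = NULL) {
  stopifnot(inherits(design, "art_design"), n_versions >= 1)
  n_versions <- as.integer(n_versions)
  labels <- make.unique(rep(LETTERS, length.out = n_versions), sep = "")
  block <- block_index(design$schedule)
  with_seed(seed, {
    lapply(seq_len(n_versions), function(v) {
      if (v == 1L)
        return(new_design(design$schedule, design$max_casts, labels[[1L]]))
      mc <- design$max_casts
      for (b in unique(block)) {
        idx <- which(block == b)
        mc[idx] <- mc[sample(idx)]
      }
      new_design(design$schedule, mc, labels[[v]])
    })
  })
}

block_index <- function(schedule) {
  (seq_along(schedule$p_yellow) - 1L) %/% schedule$block_size + 1L
}

#' Convert designs to/from a tidy data frame
#'
#' The interchange format is one row per trial with columns
#' `version, trial, p_yellow, max_casts`; trials are numbered from 1.
#'
#' @param designs A single `art_design` or a list of them.
#' @return A data frame.
#' @export
design_to_df <- function(designs) {
  if (inherits(designs, "art_design")) designs <- list(designs)
  do.call(rbind, lapply(designs, function(d) {
    data.frame(
      version = d$version_label,
      trial = seq_along(d$max_casts),
      p_yellow = d$schedule$p_yellow,
      max_casts = d$max_casts
    )
  }))
}

#' @rdname design_to_df
#' @param df A data frame with the design columns above.
#' @param block_size Trials per probability level (used to rebuild the
#'   schedule objects).
#' @return `df_to_designs()` returns a named list of `art_design`.
#' @export
df_to_designs <- function(df, block_size) {
  need <- c("version", "trial", "p_yellow", "max_casts")
  if (!all(need %in% names(df)))
    stop_art("design table must have columns ", paste(need, collapse = ", "))
  lapply(split(df, df$version), function(dd) {
    dd <- dd[order(dd$trial), ]
    sched <- structure(
      list(p_yellow = dd$p_yellow, block_size = as.integer(block_size)),
      class = "art_schedule"
    )
    new_design(sched, dd$max_casts, dd$version[[1L]])
  })
}
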