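#' Write gameplay data to CSV
#'
#' One row per trial with header
#' `subject_id,group,version,trial,p_yellow,max_casts,n_casts,outcome,points_banked`;
#' trials are numbered from 1.
#'
#' @param plays List of [subject_play()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gameplay <- function(plays, path) {
  df <- do.call(rbind, lapply(plays, function(p) {
    data.frame(
      subject_id = p$subject_id, group = p$group,
      version = p$version_label, trial = seq_len(nrow(p$trials)),
      p_yellow = p$trials$p_yellow, max_casts = p$trials$max_casts,
      n_casts = p$trials$n_casts, outcome = p$trials$ended_by,
      points_banked = p$trials$points_banked
    )
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gameplay data from CSV
#'
#' Parses and validates the gameplay interchange format (see
#' [write_gameplay()]). Every invariant violation is reported with the
#' offending file line numbers (header = line 1).
#'
#' @param path CSV file.
#' @return List of [subject_play()] objects, in first-appearance order of
#'   `subject_id`.
#' @export
read_gameplay <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "version", "trial", "p_yellow",
            "max_casts", "n_casts", "outcome", "points_banked")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_art("gameplay file ", path, " is missing column(s): ",
             paste(missing_cols, collapse = ", "))
  line <- seq_len(nrow(df)) + 1L
  problems <- c(
    if (length(i <- which(!(df$outcome %in% c("collected", "forced_fail")))))
      paste0("unknown outcome label at line(s) ",
             paste(line[i], collapse = ", ")),
    if (length(i <- which(df$n_casts > df$max_casts)))
      paste0("n_casts > max_casts at line(s) ",
             paste(line[i], collapse = ", ")),
    if (length(i <- which(df$outcome == "forced_fail" &
                            df$n_casts != df$max_casts)))
      paste0("forced_fail with n_casts != max_casts at line(s) ",
             paste(line[i], collapse = ", ")),
    if (length(i <- which(df$p_yellow <= 0 | df$p_yellow >= 1)))
      paste0("p_yellow outside (0,1) at line(s) ",
             paste(line[i], collapse = ", "))
  )
  if (length(problems))
    stop_art("invalid gameplay data in ", path, ":\n  ",
             paste(problems, collapse = "\n  "))
  ids <- unique(df$subject_id)
  lapply(ids, function(id) {
    dd <- df[df$subject_id == id, ]
    dd <- dd[order(dd$trial), ]
    trials <- data.frame(
      p_yellow = dd$p_yellow, max_casts = as.integer(dd$max_casts),
      n_casts = as.integer(dd$n_casts), ended_by = dd$outcome,
      points_banked = as.integer(dd$points_banked)
    )
    subject_play(id, dd$group[[1L]], dd$version[[1L]], trials)
  })
}

#' Write a posterior summary to CSV
#'
#' Tidy format `level,group,subject_id,parameter,mean,sd,q2.5,q97.5,rhat,ess`.
#'
#' @param fit An `art_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_posterior_summary <- function(fit, path) {
  stopifnot(inherits(fit, "art_fit"))
  write.csv(fit$summary, path, row.names = FALSE)
  invisible(path)
}

#' Write posterior draws to a columnar CSV
#'
#' Long format `group,chain,draw,parameter,value`, tool-agnostic and
#' loadable by any table reader.
#'
#' @param fit An `art_fit`.
#' @param path Output file.
#' @param parameters Optional subset of parameter names to write (defaults
#'   to the group-level quantities, keeping files small).
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path, parameters = NULL) {
  stopifnot(inherits(fit, "art_fit"))
  rows <- lapply(names(fit$draws), function(g) {
    dr <- fit$draws[[g]]
    keep <- parameters %||% grep("\\[", names(dr), invert = TRUE,
                                 value = TRUE)
    do.call(rbind, lapply(intersect(keep, names(dr)), function(nm) {
      m <- dr[[nm]]
      data.frame(group = g,
                 chain = rep(seq_len(ncol(m)), each = nrow(m)),
                 draw = rep(seq_len(nrow(m)), ncol(m)),
                 parameter = nm, value = as.vector(m))
    }))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
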