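#' Read an observation set from CSV
#'
#' Expects the long schema written by \code{\link{write_observations}}:
#' observable, day, t1, t2, mean, sd, n, condition, include, reason.
#' Malformed rows are reported with their row numbers; an empty file is a
#' distinct "no data" error.
#'
#' @param path CSV file.
#' @return an \code{\link{observation_set}}.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("no data in ", path))
  if (!nrow(df)) stop("no data in ", path)
  need <- c("observable", "day", "mean", "sd", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema mismatch in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  if (!"include" %in% names(df)) df$include <- TRUE
  bad <- which(df$include & (!is.finite(df$sd) | df$sd <= 0))
  if (length(bad))
    stop("non-positive sd at row(s): ", paste(bad, collapse = ", "))
  if ("reason" %in% names(df)) df$reason[is.na(df$reason)] <- ""
  observation_set(df)
}

#' Write an observation set to CSV
#'
#' Round-trip stable with \code{\link{read_observations}} to full double
#' precision.
#'
#' @param observations an \code{\link{observation_set}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_observations <- function(observations, path) {
  df <- as.data.frame(observations)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fit result as JSON
#'
#' Stores the variant, optimized parameters, log-likelihood, AIC, free
#' parameter set and convergence metadata.
#'
#' @param fit a \code{ctl_fit}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  doc <- list(
    variant = fit$variant,
    params = as.list(stats::setNames(as.numeric(fit$params),
                                     names(unclass(fit$params)))),
    logL = fit$logL, AIC = fit$AIC, n_free = fit$n_free,
    free = fit$free, convergence = fit$convergence,
    n_starts = fit$n_starts, seed = fit$seed,
    V0 = fit$V0, t_on = fit$t_on, obs_hash = fit$obs_hash
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
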