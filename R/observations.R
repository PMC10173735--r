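#' Observable names used throughout the pipeline
#' @return character vector of the eight fitted observables.
#' @export
observable_names <- function() {
  c("ctl_density", "growth_rate", "ifng", "ratio_sgm_g1",
    "pdcd1", "cd274", "lag3", "havcr2")
}

#' Construct an observation set
#'
#' A validated long table of per-observable summary measurements: means and
#' standard deviations per timepoint, with condition labels and an include
#' flag.  Growth-rate rows are interval summaries and carry the interval
#' endpoints \code{t1, t2} (with \code{day} at the midpoint); all other
#' rows are instantaneous and have \code{t1 = t2 = day}.
#'
#' @param df data.frame with columns \code{observable, day, t1, t2, mean,
#'   sd, n, condition, include, reason} (missing \code{t1/t2/n/reason}
#'   filled with defaults).
#' @return an \code{observation_set} data.frame.
#' @export
observation_set <- function(df) {
  if (!nrow(df)) stop("no data: empty observation table")
  if (!"t1" %in% names(df)) df$t1 <- df$day
  if (!"t2" %in% names(df)) df$t2 <- df$day
  if (!"n" %in% names(df)) df$n <- NA_integer_
  if (!"include" %in% names(df)) df$include <- TRUE
  if (!"reason" %in% names(df)) df$reason <- ""
  need <- c("observable", "day", "t1", "t2", "mean", "sd", "n",
            "condition", "include", "reason")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  bad <- setdiff(unique(df$observable), observable_names())
  if (length(bad)) stop("unknown observable(s): ", paste(bad, collapse = ", "))
  bad_sd <- which(df$include & !(is.finite(df$sd) & df$sd > 0))
  if (length(bad_sd))
    stop("non-positive sd for included observation(s) at row(s): ",
         paste(bad_sd, collapse = ", "))
  if (any(df$day < -1 - 1e-9 | df$day > 14 + 1e-9))
    stop("timepoints outside the study horizon (-1..14 days)")
  if (any(df$include == FALSE & !nzchar(df$reason)))
    stop("excluded observations must carry a reason code")
  class(df) <- c("observation_set", "data.frame")
  df
}

#' Standard deviation of a checkpoint expression measurement
#'
#' Single pooled arrays give one expression value per timepoint, so the
#' measurement noise is borrowed from housekeeping genes via the linear
#' mean-sd relation \code{sd = 0.054 + 0.29 * mean}.
#'
#' @param mean_expr normalized expression mean (non-negative).
#' @return estimated standard deviation.
#' @export
checkpoint_sd <- function(mean_expr) {
  if (any(mean_expr < 0)) stop("mean expression must be non-negative")
  0.054 + 0.29 * mean_expr
}

#' Map a simulated trajectory onto the observables
#'
#' ctl_density is CTL abundance E; ratio_sgm_g1 is S/G; ifng and the four
#' checkpoints are intratumoral concentrations (I/V, P/V, PL/V, L/V, H/V);
#' growth_rate rows are \code{log(V(t2)/V(t1)) / (t2 - t1)} over the row's
#' measurement interval.  Every time referenced by an observation must be
#' present in the trajectory's time grid.
#'
#' @param traj a \code{ctl_trajectory}.
#' @param observations an \code{\link{observation_set}}.
#' @return numeric vector of model predictions, one per observation row.
#' @export
map_observables <- function(traj, observations) {
  at <- function(tt, col) {
    idx <- match(round(tt, 9), round(traj$time, 9))
    if (anyNA(idx))
      stop("observation time(s) outside trajectory: ",
           paste(unique(tt[is.na(idx)]), collapse = ", "))
    traj[[col]][idx]
  }
  obs <- as.data.frame(observations)
  pred <- numeric(nrow(obs))
  for (m in unique(obs$observable)) {
    i <- which(obs$observable == m)
    pred[i] <- switch(
      m,
      ctl_density = at(obs$day[i], "E"),
      ratio_sgm_g1 = at(obs$day[i], "S") / at(obs$day[i], "G"),
      ifng = at(obs$day[i], "I") / at(obs$day[i], "V"),
      pdcd1 = at(obs$day[i], "P") / at(obs$day[i], "V"),
      cd274 = at(obs$day[i], "PL") / at(obs$day[i], "V"),
      lag3 = at(obs$day[i], "L") / at(obs$day[i], "V"),
      havcr2 = at(obs$day[i], "H") / at(obs$day[i], "V"),
      growth_rate = log(at(obs$t2[i], "V") / at(obs$t1[i], "V")) /
        (obs$t2[i] - obs$t1[i]),
      stop("unknown observable: ", m)
    )
  }
  pred
}

#' Gaussian log-likelihood of predictions against an observation set
#'
#' \deqn{\log L = -\tfrac12 \sum_m \sum_j (y_m(t_j) - \bar y_{m,j})^2 /
#'   \sigma_{m,j}^2} summed over included observations only (the additive
#' normalization constant is omitted, so a perfect fit scores 0).
#'
#' @param predictions numeric vector aligned with the observation rows.
#' @param observations an \code{\link{observation_set}}.
#' @return the log-likelihood (a non-positive number).
#' @export
log_likelihood <- function(predictions, observations) {
  obs <- as.data.frame(observations)
  if (length(predictions) != nrow(obs))
    stop("predictions and observations are not aligned")
  keep <- obs$include
  if (any(obs$sd[keep] <= 0)) stop("non-positive sd among included points")
  r <- (predictions[keep] - obs$mean[keep]) / obs$sd[keep]
  if (anyNA(r)) return(-Inf)
  -0.5 * sum(r^2)
}

#' All trajectory times an observation set requires
#'
#' @param observations an \code{\link{observation_set}}.
#' @param extra additional times to include (e.g. the start day).
#' @return sorted unique time vector.
#' @export
required_times <- function(observations, extra = numeric(0)) {
  obs <- as.data.frame(observations)
  sort(unique(round(c(obs$day, obs$t1, obs$t2, extra), 9)))
}
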