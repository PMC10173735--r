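#' Basal growth rate of the two-compartment cycle model
#'
#' Dominant eigenvalue of the linear system dS/dt = kgs G - ksg S,
#' dG/dt = -kgs G + 2 ksg S: the asymptotic exponential growth rate of the
#' untreated tumor.
#'
#' @param kgs,ksg cycle transition rates (day^-1, positive).
#' @return growth rate g (day^-1).
#' @export
basal_growth_rate <- function(kgs, ksg) {
  tr <- -(kgs + ksg)
  det <- -kgs * ksg
  unname((tr + sqrt(tr^2 - 4 * det)) / 2)
}

#' Steady-state S-G2-M : G1 ratio
#'
#' The ratio S/G along the exponentially growing eigenmode,
#' \code{kgs / (g + ksg)} with g the basal growth rate; consistent with the
#' identity g = ksg S / (S + G).
#'
#' @inheritParams basal_growth_rate
#' @return the steady-state ratio S/G.
#' @export
steady_state_ratio <- function(kgs, ksg) {
  if (any(kgs <= 0) || any(ksg <= 0)) stop("kgs and ksg must be positive")
  g <- basal_growth_rate(kgs, ksg)
  unname(kgs / (g + ksg))
}

#' Cycle transition rates from growth rate and steady-state ratio
#'
#' Inverts the exponential-growth algebra: given the measured tumor growth
#' rate g and the steady-state S-G2-M:G1 ratio r,
#' \code{ksg = g (1 + r) / r} and \code{kgs = g (1 + 2 r)}.  Round-trips
#' with \code{\link{steady_state_ratio}} and
#' \code{\link{basal_growth_rate}}.
#'
#' @param g exponential growth rate (day^-1, positive).
#' @param ratio steady-state S/G ratio (positive).
#' @return named vector \code{c(kgs, ksg)}.
#' @export
cycle_rates_from_growth <- function(g, ratio) {
  if (any(g <= 0) || any(ratio <= 0)) stop("g and ratio must be positive")
  c(kgs = unname(g * (1 + 2 * ratio)), ksg = unname(g * (1 + ratio) / ratio))
}

#' Steady-state ratio implied by g and kgs
#'
#' Convenience inverse of \code{kgs = g (1 + 2 r)}: recovers the
#' steady-state S/G ratio from the growth rate and the G1-exit rate, e.g.
#' to complete the pair (kgs, ksg) when only one rate is quoted.
#'
#' @inheritParams cycle_rates_from_growth
#' @param kgs G1 to S-G2-M transition rate (day^-1).
#' @return the steady-state ratio S/G.
#' @export
ratio_from_kgs <- function(g, kgs) {
  if (any(g <= 0) || any(kgs <= g)) stop("need kgs > g > 0")
  unname((kgs / g - 1) / 2)
}

#' Fit an exponential growth model to per-mouse tumor volumes
#'
#' Population growth rate from a linear regression of log-volume on day
#' with mouse-specific intercepts and a shared slope (pooled maximum
#' likelihood under lognormal measurement noise).  Per-mouse slopes are
#' also returned.  Mice with fewer than two timepoints are excluded with a
#' warning.
#'
#' @param volumes data.frame with columns \code{mouse_id}, \code{day},
#'   \code{volume_mm3} (positive); extra columns ignored.
#' @return an object of class \code{growth_estimate}: list with \code{g},
#'   \code{per_mouse} (data.frame mouse_id, g), \code{fit} (the lm).
#' @export
fit_exponential_growth <- function(volumes) {
  need <- c("mouse_id", "day", "volume_mm3")
  if (!all(need %in% names(volumes)))
    stop("volumes needs columns ", paste(need, collapse = ", "))
  if (any(volumes$volume_mm3 <= 0)) stop("volumes must be positive")
  n_per <- table(volumes$mouse_id)
  drop <- names(n_per)[n_per < 2]
  if (length(drop)) {
    warning("excluding single-timepoint mice: ", paste(drop, collapse = ", "))
    volumes <- volumes[!(volumes$mouse_id %in% drop), ]
  }
  if (!nrow(volumes)) stop("no usable volume series")
  volumes$mouse_id <- factor(volumes$mouse_id)
  fit <- if (nlevels(volumes$mouse_id) > 1) {
    stats::lm(log(volume_mm3) ~ 0 + mouse_id + day, data = volumes)
  } else {
    stats::lm(log(volume_mm3) ~ day, data = volumes)
  }
  per_mouse <- do.call(rbind, lapply(split(volumes, volumes$mouse_id), function(d) {
    data.frame(mouse_id = as.character(d$mouse_id[1]),
               g = unname(stats::coef(stats::lm(log(volume_mm3) ~ day, d))["day"]))
  }))
  rownames(per_mouse) <- NULL
  structure(list(g = unname(stats::coef(fit)["day"]),
                 per_mouse = per_mouse, fit = fit),
            class = "growth_estimate")
}

#' @export
print.growth_estimate <- function(x, ...) {
  cat(sprintf("Exponential growth fit: g = %.4f / day (%d mice)\n",
              x$g, nrow(x$per_mouse)))
  invisible(x)
}

#' Per-interval tumor growth rates
#'
#' For each consecutive pair of measurements of a mouse, the interval
#' growth rate \code{log(V2/V1) / (t2 - t1)}, reported at the interval
#' midpoint.  This transformation makes cohorts with different follow-up
#' comparable and is robust to mice entering/leaving the measured set.
#'
#' @inheritParams fit_exponential_growth
#' @return data.frame with columns \code{mouse_id}, \code{cohort} (if
#'   present in the input), \code{day} (midpoint), \code{t1}, \code{t2},
#'   \code{rate}.
#' @export
interval_growth_rates <- function(volumes) {
  need <- c("mouse_id", "day", "volume_mm3")
  if (!all(need %in% names(volumes)))
    stop("volumes needs columns ", paste(need, collapse = ", "))
  if (any(volumes$volume_mm3 <= 0)) stop("volumes must be positive")
  out <- lapply(split(volumes, volumes$mouse_id), function(d) {
    d <- d[order(d$day), ]
    if (nrow(d) < 2) return(NULL)
    i <- seq_len(nrow(d) - 1)
    data.frame(
      mouse_id = d$mouse_id[1],
      cohort = if ("cohort" %in% names(d)) d$cohort[1] else NA_character_,
      day = (d$day[i] + d$day[i + 1]) / 2,
      t1 = d$day[i], t2 = d$day[i + 1],
      rate = log(d$volume_mm3[i + 1] / d$volume_mm3[i]) /
        (d$day[i + 1] - d$day[i])
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Correlation between CTL counts and cell-cycle ratio across images
#'
#' Pearson correlation between per-cryosection CTL counts and S-G2-M:G1
#' ratios, with the Fisher-z 95 percent confidence interval and the
#' two-sided test of zero correlation.
#'
#' @param ctl_counts numeric vector of per-image CTL counts.
#' @param ratios matched numeric vector of per-image S-G2-M:G1 ratios.
#' @return list with \code{r}, \code{conf_int} (length 2), \code{p},
#'   \code{n}.
#' @export
correlate_ctl_ratio <- function(ctl_counts, ratios) {
  if (length(ctl_counts) != length(ratios)) stop("unpaired inputs")
  ok <- stats::complete.cases(ctl_counts, ratios)
  x <- ctl_counts[ok]; y <- ratios[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  list(r = unname(ct$estimate), conf_int = as.numeric(ct$conf.int),
       p = ct$p.value, n = length(x))
}
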