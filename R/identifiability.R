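#' Adaptive Metropolis sampling with parallel hierarchical chains
#'
#' Posterior sampler for practical-identifiability analysis.  A main chain
#' targets the posterior (log-likelihood plus a flat prior on the box
#' bounds); auxiliary chains run adaptive Metropolis on tempered versions
#' of the same target (geometric temperature ladder) and periodically
#' propose exchange moves into the main chain, helping it hop between
#' likelihood modes.  Each chain adapts its Gaussian proposal covariance
#' from its own history (Haario-style recursion, started after a warm-up).
#' Deterministic given \code{seed}.
#'
#' @param logpost function taking a parameter vector, returning the log
#'   posterior density (up to a constant); \code{-Inf} outside the support.
#' @param init_sets numeric matrix with \code{n_aux + 1} rows: starting
#'   points for the main chain (row 1) and the auxiliary chains.
#' @param lower,upper box bounds (flat prior support).
#' @param n_steps chain length (100000 reproduces a production run; the
#'   routine scale is a few thousand).
#' @param n_aux number of auxiliary chains.
#' @param n_retain main-chain samples kept from the end of the run
#'   (default: final half).
#' @param temp_factor temperature ratio between successive auxiliary
#'   chains.
#' @param swap_every steps between exchange proposals.
#' @param adapt_start step at which covariance adaptation begins.
#' @param init_scale initial proposal sd as a fraction of the box width.
#' @param seed integer seed.
#' @return a \code{ctl_posterior}: list with \code{draws} (matrix of
#'   retained main-chain samples), \code{accept_rate} (per chain),
#'   \code{swap_rate}, and the settings.
#' @export
am_phs_sample <- function(logpost, init_sets, lower, upper,
                          n_steps = 5000, n_aux = 20,
                          n_retain = floor(n_steps / 2),
                          temp_factor = 1.5, swap_every = 10,
                          adapt_start = max(100, floor(n_steps / 20)),
                          init_scale = 0.05, seed = 1) {
  init_sets <- as.matrix(init_sets)
  d <- length(lower)
  if (length(upper) != d || ncol(init_sets) != d)
    stop("dimension mismatch between bounds and init_sets")
  n_chains <- n_aux + 1
  if (nrow(init_sets) < n_chains)
    stop(sprintf("need %d initial parameter sets (1 main + %d auxiliary), got %d",
                 n_chains, n_aux, nrow(init_sets)))
  if (n_retain > n_steps) stop("n_retain exceeds n_steps")
  set.seed(seed)

  temps <- temp_factor^(0:(n_chains - 1))  # temps[1] = 1: the main chain
  width <- upper - lower

  x <- lapply(seq_len(n_chains), function(c) as.numeric(init_sets[c, ]))
  lp <- vapply(x, logpost, numeric(1))
  if (all(!is.finite(lp))) stop("no initial point has finite log posterior")

  # per-chain running mean / covariance for Haario adaptation
  mu <- x
  cv <- lapply(seq_len(n_chains), function(c) diag((init_scale * width)^2, d))
  chol_p <- lapply(cv, function(C) chol(C))
  sd_opt <- 2.38^2 / d
  eps <- 1e-10

  draws <- matrix(NA_real_, n_retain, d)
  colnames(draws) <- colnames(init_sets)
  acc <- integer(n_chains)
  swaps_prop <- 0L
  swaps_acc <- 0L
  keep_from <- n_steps - n_retain + 1

  for (step in seq_len(n_steps)) {
    for (c in seq_len(n_chains)) {
      prop <- x[[c]] + drop(stats::rnorm(d) %*% chol_p[[c]])
      if (all(prop >= lower & prop <= upper)) {
        lp_prop <- logpost(prop)
        if (is.finite(lp_prop) &&
            log(stats::runif(1)) < (lp_prop - lp[c]) / temps[c]) {
          x[[c]] <- prop
          lp[c] <- lp_prop
          acc[c] <- acc[c] + 1L
        }
      }
      # running moment update; refresh the proposal after warm-up
      w <- 1 / (step + 1)
      dev <- x[[c]] - mu[[c]]
      mu[[c]] <- mu[[c]] + w * dev
      cv[[c]] <- (1 - w) * cv[[c]] + w * tcrossprod(dev) * (1 - w)
      if (step >= adapt_start && step %% 10 == 0) {
        ch <- tryCatch(chol(sd_opt * cv[[c]] + diag(eps, d)),
                       error = function(e) NULL)
        if (!is.null(ch)) chol_p[[c]] <- ch
      }
    }
    if (n_aux > 0 && step %% swap_every == 0) {
      j <- sample(2:n_chains, 1)
      swaps_prop <- swaps_prop + 1L
      log_a <- (lp[j] - lp[1]) * (1 - 1 / temps[j])
      if (log(stats::runif(1)) < log_a) {
        tmp <- x[[1]]; x[[1]] <- x[[j]]; x[[j]] <- tmp
        tmp <- lp[1]; lp[1] <- lp[j]; lp[j] <- tmp
        swaps_acc <- swaps_acc + 1L
      }
    }
    if (step >= keep_from) draws[step - keep_from + 1, ] <- x[[1]]
  }

  structure(list(
    draws = draws,
    accept_rate = acc / n_steps,
    swap_rate = if (swaps_prop) swaps_acc / swaps_prop else NA_real_,
    lower = lower, upper = upper,
    n_steps = n_steps, n_retain = n_retain, n_aux = n_aux,
    temps = temps, seed = seed
  ), class = "ctl_posterior")
}

#' @export
print.ctl_posterior <- function(x, ...) {
  cat(sprintf("Posterior samples: %d retained draws (%d-step main chain, %d auxiliary), main acceptance %.2f\n",
              x$n_retain, x$n_steps, x$n_aux, x$accept_rate[1]))
  invisible(x)
}

#' Sample the posterior of a fitted model variant
#'
#' Convenience wrapper: builds the log posterior (the fitting
#' log-likelihood with a flat prior on the log10 box bounds) from a
#' \code{\link{multistart_fit}} result, initializes main and auxiliary
#' chains from the best multistart parameter sets, and runs
#' \code{\link{am_phs_sample}}.  Draws are on the log10 scale of the free
#' parameters.
#'
#' @param fit a \code{ctl_fit} whose \code{top_sets} has at least
#'   \code{n_aux + 1} rows.
#' @param observations the observation set the fit used.
#' @param ... passed to \code{\link{am_phs_sample}}.
#' @return a \code{ctl_posterior} with fit metadata attached.
#' @export
sample_posterior <- function(fit, observations, ...) {
  obj <- make_objective(observations, fit$variant,
                        params_template = fit$params,
                        V0 = fit$V0, t_on = fit$t_on)
  if (obj$hash != fit$obs_hash)
    stop("observations do not match the fit")
  post <- am_phs_sample(obj$fn, fit$top_sets, obj$lower, obj$upper, ...)
  post$free <- obj$free
  post$fit <- fit
  post
}

#' Posterior credible intervals
#'
#' Empirical quantile intervals (default 1--99 percent) per parameter.  An
#' interval end that touches the parameter's box constraint is not
#' determined by the data and is flagged as such.
#'
#' @param samples a \code{ctl_posterior}.
#' @param levels two quantiles, default \code{c(0.01, 0.99)}.
#' @param tol fraction of the box width within which an end counts as
#'   touching the bound.
#' @return data.frame with parameter, low, high, low_determined,
#'   high_determined.
#' @export
credible_intervals <- function(samples, levels = c(0.01, 0.99),
                               tol = 0.005) {
  if (!nrow(samples$draws)) stop("empty posterior sample")
  if (nrow(samples$draws) < 100)
    stop("need at least 100 retained draws")
  q <- t(apply(samples$draws, 2, stats::quantile, probs = levels,
               names = FALSE))
  width <- samples$upper - samples$lower
  data.frame(
    parameter = colnames(samples$draws),
    low = q[, 1], high = q[, 2],
    low_determined = q[, 1] > samples$lower + tol * width,
    high_determined = q[, 2] < samples$upper - tol * width,
    row.names = NULL
  )
}

#' Log-likelihood sweep of a single parameter
#'
#' Profile of the fitting objective over a grid of one parameter with all
#' other parameters held at the fitted values: parameters whose sweep
#' barely moves the log-likelihood are practically non-identifiable.
#'
#' @param fit a \code{ctl_fit}.
#' @param observations the observation set the fit used.
#' @param which a free parameter name.
#' @param grid values to evaluate (natural scale).
#' @return data.frame with parameter, value, logL.
#' @export
likelihood_sweep <- function(fit, observations, which, grid) {
  obj <- make_objective(observations, fit$variant,
                        params_template = fit$params,
                        V0 = fit$V0, t_on = fit$t_on)
  if (!(which %in% obj$free))
    stop("unknown or fixed parameter: ", which)
  base <- fit$par_log10
  i <- match(which, obj$free)
  logL <- vapply(grid, function(v) {
    par <- base
    par[i] <- log10(v)
    obj$fn(par)
  }, numeric(1))
  data.frame(parameter = which, value = grid, logL = logL)
}

#' Posterior-predictive trajectory ensemble
#'
#' Simulates the full model for draws from the posterior sample, tagging
#' each trajectory with its draw index so that distinct dynamic modes can
#' be inspected downstream.  Simulation failures are recorded per draw and
#' are not fatal.
#'
#' @param samples a \code{ctl_posterior} from \code{\link{sample_posterior}}.
#' @param n_draws number of draws to simulate (without replacement if
#'   possible).
#' @param seed integer seed for draw selection.
#' @param times simulation grid.
#' @return list with \code{trajectories} (data.frame with a \code{draw}
#'   column), \code{draw_index}, \code{failed} (indices).
#' @export
posterior_predictive <- function(samples, n_draws = 50, seed = 1,
                                 times = seq(-1, 14, by = 0.25)) {
  if (is.null(samples$fit) || is.null(samples$free))
    stop("samples carry no fit metadata; use sample_posterior()")
  if (n_draws == 0)
    return(list(trajectories = NULL, draw_index = integer(0),
                failed = integer(0)))
  set.seed(seed)
  n <- nrow(samples$draws)
  idx <- sample.int(n, n_draws, replace = n_draws > n)
  fit <- samples$fit
  zeroed <- variant_zeroed(fit$variant)

  out <- vector("list", length(idx))
  failed <- integer(0)
  for (k in seq_along(idx)) {
    p <- fit$params
    p[samples$free] <- 10^samples$draws[idx[k], ]
    p[zeroed] <- 0
    tr <- tryCatch(
      simulate_cohort(p, fit$V0, times, t_on = fit$t_on),
      error = function(e) NULL)
    if (is.null(tr)) {
      failed <- c(failed, idx[k])
    } else {
      tr <- as.data.frame(tr)
      tr$draw <- idx[k]
      out[[k]] <- tr
    }
  }
  list(trajectories = do.call(rbind, out), draw_index = idx, failed = failed)
}

#' Write posterior samples to CSV plus JSON metadata
#'
#' @param samples a \code{ctl_posterior}.
#' @param csv_path one row per retained draw.
#' @param meta_path JSON chain metadata.
#' @return invisibly, the two paths.
#' @export
write_posterior <- function(samples, csv_path, meta_path) {
  utils::write.csv(as.data.frame(samples$draws), csv_path, row.names = FALSE)
  meta <- list(n_steps = samples$n_steps, n_retain = samples$n_retain,
               n_aux = samples$n_aux, seed = samples$seed,
               accept_rate = as.numeric(samples$accept_rate),
               swap_rate = samples$swap_rate,
               lower = as.numeric(samples$lower),
               upper = as.numeric(samples$upper),
               parameters = colnames(samples$draws))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, meta_path))
}
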