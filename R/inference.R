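variant_names <- function() {
  c("none", "lag3_only", "havcr2_only", "pdcd1_only", "all")
}

# checkpoint weights forced to zero under each model variant
variant_zeroed <- function(variant) {
  switch(match.arg(variant, variant_names()),
         none = c("kl", "kt", "kp"),
         lag3_only = c("kt", "kp"),
         havcr2_only = c("kl", "kp"),
         pdcd1_only = c("kl", "kt"),
         all = character(0))
}

# parameters estimated when fitting the CTL-dynamics model (cycle rates are
# calibrated separately; kA/kex are fixed at 1)
fittable_names <- function() {
  c("s0", "se", "dE", "di", "ki", "ke", "kl", "kt", "kp",
    "dl", "dt", "dp", "dpl")
}

obs_hash <- function(observations) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.csv(as.data.frame(observations), f, row.names = FALSE)
  unname(tools::md5sum(f))
}

#' Build the log-likelihood objective for the full model
#'
#' Returns a function of the free parameters (log10 scale) that simulates
#' the treated-condition trajectory from day \code{t_start} (tumor at the
#' basal steady-state cycle ratio, scaled so that the volume at the CTL
#' transfer day equals \code{V0}; no CTLs, IFNG or checkpoints before
#' transfer) and scores it against the observation set.  Solver failures
#' score \code{-Inf}.
#'
#' @param observations an \code{\link{observation_set}} (treated condition).
#' @param variant model variant; checkpoint weights not in the variant are
#'   clamped to zero and removed from the free set.
#' @param params_template \code{\link{ctl_params}} carrying the calibrated
#'   cycle rates and the fixed \code{kA = kex = 1}.
#' @param V0 tumor volume at the transfer day (mm^3).
#' @param t_on CTL transfer day.
#' @return list with \code{fn(par_log10)}, \code{free} (names),
#'   \code{lower}, \code{upper} (log10 bounds), and helpers used by the
#'   fitting and sampling code.
#' @export
make_objective <- function(observations, variant = "all",
                           params_template = ctl_params(),
                           V0 = 100, t_on = 0) {
  observations <- observation_set(as.data.frame(observations))
  zeroed <- variant_zeroed(variant)
  free <- setdiff(fittable_names(), zeroed)
  b <- attr(params_template, "bounds")
  lower <- log10(b["lower", free])
  upper <- log10(b["upper", free])

  base <- params_template
  obs <- as.data.frame(observations)
  times <- required_times(observations, extra = c(t_on))
  pre <- times[times < t_on]
  post_grid <- sort(unique(c(t_on, times[times >= t_on])))
  full_times <- c(pre, post_grid)

  # precomputed row indexing into the time grid, per observation
  i_day <- match(round(obs$day, 9), round(full_times, 9))
  i_t1 <- match(round(obs$t1, 9), round(full_times, 9))
  i_t2 <- match(round(obs$t2, 9), round(full_times, 9))
  keep <- obs$include
  o_mean <- obs$mean[keep]
  o_w <- 1 / obs$sd[keep]^2
  o_type <- obs$observable[keep]
  k_day <- i_day[keep]; k_t1 <- i_t1[keep]; k_t2 <- i_t2[keep]
  dt_gr <- obs$t2[keep] - obs$t1[keep]
  free_i <- match(free, param_names())
  zero_i <- match(zeroed, param_names())
  y_names <- state_names()

  params_at <- function(par_log10) {
    p <- base
    p[free] <- 10^par_log10
    p[zeroed] <- 0
    p
  }

  # lean likelihood path: direct solver call, vectorized observable
  # mapping; tight absolute tolerance so deep tumor-volume troughs stay
  # accurate on the log scale for the interval growth-rate observable
  fn_params <- function(pv) {
    kgs <- pv[5]; ksg <- pv[6]
    g <- basal_growth_rate(kgs, ksg)
    r <- kgs / (g + ksg)
    y0 <- c(V0 * r / (1 + r), V0 / (1 + r), 0, 0, 0, 0, 0, 0)
    names(y0) <- y_names
    out <- tryCatch(suppressWarnings(
      deSolve::lsoda(y0, post_grid, "ctldyn_derivs_full",
                     parms = c(pv, t_on), dllname = "ctldyn",
                     initfunc = "ctldyn_init_full",
                     rtol = 1e-8, atol = 1e-12, maxsteps = 12000)),
      error = function(e) NULL)
    if (is.null(out) || nrow(out) < length(post_grid) ||
        (!is.null(attr(out, "istate")) && attr(out, "istate")[1] < 0))
      return(rep(1e6, length(o_mean)))
    M <- out[, -1, drop = FALSE]
    M[M < 0] <- 0
    if (length(pre)) {
      Vpre <- V0 * exp(g * (pre - t_on))
      M <- rbind(cbind(Vpre * r / (1 + r), Vpre / (1 + r),
                       0, 0, 0, 0, 0, 0), M)
    }
    S <- M[, 1]; G <- M[, 2]; V <- S + G
    pred <- numeric(length(o_type))
    for (m in unique(o_type)) {
      i <- o_type == m
      pred[i] <- switch(m,
        ctl_density = M[k_day[i], 3],
        ratio_sgm_g1 = S[k_day[i]] / G[k_day[i]],
        ifng = M[k_day[i], 4] / V[k_day[i]],
        pdcd1 = M[k_day[i], 5] / V[k_day[i]],
        cd274 = M[k_day[i], 6] / V[k_day[i]],
        lag3 = M[k_day[i], 7] / V[k_day[i]],
        havcr2 = M[k_day[i], 8] / V[k_day[i]],
        growth_rate = log(V[k_t2[i]] / V[k_t1[i]]) / dt_gr[i])
    }
    r <- (pred - o_mean) * sqrt(o_w)
    r[!is.finite(r)] <- 1e6
    r
  }

  pv_at <- function(par_log10) {
    pv <- as.numeric(base)
    pv[free_i] <- 10^par_log10
    if (length(zero_i)) pv[zero_i] <- 0
    pv
  }

  # weighted residual vector (solver failures yield a large flat penalty)
  resid <- function(par_log10) fn_params(pv_at(par_log10))

  fn <- function(par_log10) {
    r <- fn_params(pv_at(par_log10))
    if (any(r >= 1e6)) return(-Inf)
    -0.5 * sum(r^2)
  }

  simulate_at <- function(par_log10, times_out = times) {
    p <- params_at(par_log10)
    simulate_cohort(p, V0, times_out, t_on = t_on, atol = 1e-12)
  }

  list(fn = fn, resid = resid, free = free, lower = lower, upper = upper,
       params_at = params_at, simulate_at = simulate_at,
       times = times, variant = variant, observations = observations,
       hash = obs_hash(observations))
}

#' Multistart maximum-likelihood fit of a model variant
#'
#' Staged multistart: Latin-hypercube starting points over the log10 box
#' bounds are ranked by their objective value, the most promising are
#' optimized with bounded quasi-Newton (L-BFGS-B, forward-difference
#' gradients), and the best screening results are polished with
#' Levenberg-Marquardt on the weighted residuals plus a tight quasi-Newton
#' continuation.  Deterministic given \code{seed}.
#'
#' @inheritParams make_objective
#' @param n_starts number of Latin-hypercube starts (200 is the routine
#'   scale; 20000 reproduces a full production fit).
#' @param seed integer seed controlling start placement.
#' @param n_opt how many of the best-valued starts get a local
#'   optimization.
#' @param n_polish how many top screening results to polish.
#' @param top_k how many best parameter sets to retain (e.g. 21 for
#'   initializing the posterior sampler).
#' @param screen_maxit,polish_maxit iteration caps for the two phases.
#' @return a \code{ctl_fit}: list with the optimized \code{params},
#'   \code{logL}, \code{AIC}, \code{n_free}, \code{variant},
#'   \code{top_sets} (log10 free-parameter matrix), convergence info and
#'   the settings needed to rebuild the objective.
#' @export
multistart_fit <- function(observations, variant = "all", n_starts = 200,
                           seed = 1, params_template = ctl_params(),
                           V0 = 100, t_on = 0, n_opt = 50, n_polish = 6,
                           top_k = 21, screen_maxit = 60,
                           polish_maxit = 400) {
  obj <- make_objective(observations, variant, params_template, V0, t_on)
  d <- length(obj$free)
  set.seed(seed)
  u <- lhs::randomLHS(n_starts, d)
  starts <- sweep(sweep(u, 2, obj$upper - obj$lower, "*"), 2, obj$lower, "+")

  neg <- function(x) {
    v <- obj$fn(x)
    if (!is.finite(v)) 1e10 else -v
  }
  # forward-difference gradient (screening phase): half the cost of the
  # central differences optim would use internally
  gr_fwd <- function(x) {
    f0 <- neg(x)
    h <- 1e-4
    vapply(seq_along(x), function(i) {
      xi <- x
      step <- if (xi[i] + h <= obj$upper[i]) h else -h
      xi[i] <- xi[i] + step
      (neg(xi) - f0) / step
    }, numeric(1))
  }

  run_one <- function(par, maxit, factr, gr = NULL) {
    res <- tryCatch(
      stats::optim(par, neg, gr = gr, method = "L-BFGS-B",
                   lower = obj$lower, upper = obj$upper,
                   control = list(maxit = maxit, factr = factr)),
      error = function(e) NULL)
    if (is.null(res)) list(par = par, value = 1e10, convergence = 99L)
    else res
  }

  # rank all starts by raw objective value; optimize the promising ones
  v0 <- vapply(seq_len(n_starts), function(i) neg(starts[i, ]), numeric(1))
  cand <- order(v0)[seq_len(min(n_opt, n_starts))]
  screened <- lapply(cand, function(i)
    run_one(starts[i, ], screen_maxit, 1e9, gr = gr_fwd))
  vals <- vapply(screened, function(r) r$value, numeric(1))
  if (all(vals >= 1e10))
    stop("all starts failed; per-start values: ",
         paste(utils::head(vals, 20), collapse = ", "))
  ord <- order(vals)

  # polish: Levenberg-Marquardt on the weighted residuals (the natural
  # method for this least-squares objective), then a tight quasi-Newton
  # continuation; keep whichever scores better
  polish_one <- function(par0) {
    cands <- list(run_one(par0, polish_maxit, 1e4))
    lm_fit <- tryCatch(suppressWarnings(minpack.lm::nls.lm(
      par0, lower = obj$lower, upper = obj$upper, fn = obj$resid,
      control = minpack.lm::nls.lm.control(maxiter = polish_maxit,
                                           ptol = 1e-13, ftol = 1e-13))),
      error = function(e) NULL)
    if (!is.null(lm_fit)) {
      par_lm <- pmin(pmax(lm_fit$par, obj$lower), obj$upper)
      cands <- c(cands, list(run_one(par_lm, 50, 1e4)),
                 list(list(par = par_lm, value = neg(par_lm),
                           convergence = 0L)))
    }
    cands[[which.min(vapply(cands, function(r) r$value, numeric(1)))]]
  }
  polished <- lapply(ord[seq_len(min(n_polish, length(screened)))],
                     function(i) polish_one(screened[[i]]$par))
  pvals <- vapply(polished, function(r) r$value, numeric(1))
  best <- polished[[which.min(pvals)]]

  # retain the best distinct parameter sets (polished first) for MCMC init
  all_sets <- c(polished[order(pvals)], screened[ord])
  top <- t(vapply(all_sets[seq_len(min(top_k, length(all_sets)))],
                  function(r) r$par, numeric(d)))
  colnames(top) <- obj$free

  params <- obj$params_at(best$par)
  logL <- -best$value
  structure(list(
    variant = variant, params = params, logL = logL,
    n_free = d, AIC = 2 * d - 2 * logL,
    convergence = best$convergence,
    free = obj$free, par_log10 = best$par,
    lower = obj$lower, upper = obj$upper,
    top_sets = top,
    n_starts = n_starts, seed = seed,
    V0 = V0, t_on = t_on,
    obs_hash = obj$hash,
    screen_values = -vals
  ), class = "ctl_fit")
}

#' @export
print.ctl_fit <- function(x, ...) {
  cat(sprintf("Model variant '%s': logL = %.4f, AIC = %.2f (%d free params)\n",
              x$variant, x$logL, x$AIC, x$n_free))
  invisible(x)
}

#' Rank fitted model variants by AIC
#'
#' \code{AIC = 2 k - 2 logL} with \code{k} the number of free parameters of
#' the variant; rows are sorted ascending (best first) with \code{dAIC}
#' relative to the best.  All fits must target the same observation set.
#'
#' @param fits list of \code{ctl_fit} objects.
#' @return data.frame with variant, n_free, logL, AIC, dAIC.
#' @export
compare_variants <- function(fits) {
  if (!length(fits)) stop("no fits to compare")
  hashes <- vapply(fits, function(f) f$obs_hash, character(1))
  if (length(unique(hashes)) != 1)
    stop("fits were computed on different observation sets")
  df <- data.frame(
    variant = vapply(fits, function(f) f$variant, character(1)),
    n_free = vapply(fits, function(f) f$n_free, numeric(1)),
    logL = vapply(fits, function(f) f$logL, numeric(1)),
    AIC = vapply(fits, function(f) f$AIC, numeric(1))
  )
  df <- df[order(df$AIC), ]
  df$dAIC <- df$AIC - df$AIC[1]
  rownames(df) <- NULL
  df
}

#' Disable a checkpoint in a fitted model and measure the effect
#'
#' Re-simulates the fitted model with the named checkpoint's exhaustion
#' weight (\code{kl}, \code{kt} or \code{kp}) set to zero and reports the
#' per-observable divergence from the intact fit over a dense time grid.
#'
#' @param fit a \code{ctl_fit}.
#' @param which one or more of \code{"lag3"}, \code{"havcr2"},
#'   \code{"pdcd1"}.
#' @param times simulation grid (days).
#' @return list with \code{intact}, \code{ablated} trajectories and
#'   \code{divergence}: data.frame(observable, rmse, max_abs).
#' @export
ablate_inhibitor <- function(fit, which, times = seq(-1, 14, by = 0.25)) {
  wmap <- c(lag3 = "kl", havcr2 = "kt", pdcd1 = "kp")
  bad <- setdiff(which, names(wmap))
  if (length(bad)) stop("unknown checkpoint(s): ", paste(bad, collapse = ", "))
  p0 <- fit$params
  p1 <- p0
  p1[wmap[which]] <- 0
  sim <- function(p) simulate_cohort(p, fit$V0, times, t_on = fit$t_on)
  tr0 <- sim(p0)
  tr1 <- sim(p1)
  cols <- c(ctl_density = "E", ratio_sgm_g1 = "ratio_SG")
  series0 <- cbind(tr0[, cols], ifng = tr0$I / tr0$V, pdcd1 = tr0$P / tr0$V,
                   cd274 = tr0$PL / tr0$V, lag3 = tr0$L / tr0$V,
                   havcr2 = tr0$H / tr0$V, volume = tr0$V)
  series1 <- cbind(tr1[, cols], ifng = tr1$I / tr1$V, pdcd1 = tr1$P / tr1$V,
                   cd274 = tr1$PL / tr1$V, lag3 = tr1$L / tr1$V,
                   havcr2 = tr1$H / tr1$V, volume = tr1$V)
  names(series0)[1:2] <- names(series1)[1:2] <- names(cols)
  div <- data.frame(
    observable = names(series0),
    rmse = vapply(seq_along(series0), function(i)
      sqrt(mean((series0[[i]] - series1[[i]])^2, na.rm = TRUE)), numeric(1)),
    max_abs = vapply(seq_along(series0), function(i)
      max(abs(series0[[i]] - series1[[i]]), na.rm = TRUE), numeric(1))
  )
  list(intact = tr0, ablated = tr1, divergence = div)
}

#' Exhaustive grid search for the input-driven two-parameter model
#'
#' With CTL and IFNG time courses supplied as piecewise-linear inputs, only
#' the killing rate \code{ke} and the arrest sensitivity \code{ki} remain.
#' Every (ke, ki) combination on the grid (default 0--20 in steps of 0.1,
#' i.e. 201 x 201 = 40401 evaluations) is scored against the observations
#' and the full likelihood surface is returned for heatmap export.
#'
#' @param observations an \code{\link{observation_set}} restricted to the
#'   observables the input-driven model predicts (growth_rate,
#'   ratio_sgm_g1).
#' @param inputs an \code{\link{input_signals}} object.
#' @param ke_values,ki_values grid vectors.
#' @param params_template carries the calibrated cycle rates.
#' @param V0 tumor volume at the transfer day.
#' @param t_on transfer day (start volume scaled back basally as in
#'   \code{\link{make_objective}}).
#' @return list with \code{best} (named c(ke, ki)), \code{logL},
#'   \code{surface} (data.frame ke, ki, logL), \code{n_eval}.
#' @export
grid_search_basic <- function(observations, inputs,
                              ke_values = seq(0, 20, by = 0.1),
                              ki_values = seq(0, 20, by = 0.1),
                              params_template = ctl_params(),
                              V0 = 100, t_on = 0) {
  if (!length(ke_values) || !length(ki_values)) stop("empty grid")
  observations <- observation_set(as.data.frame(observations))
  times <- required_times(observations, extra = c(t_on))
  t_start <- min(times)
  g <- basal_growth_rate(params_template["kgs"], params_template["ksg"])
  r <- steady_state_ratio(params_template["kgs"], params_template["ksg"])
  pre <- times[times < t_on]
  post <- sort(unique(c(t_on, times[times >= t_on])))
  pre_rows <- if (length(pre)) {
    Vpre <- V0 * exp(g * (pre - t_on))
    data.frame(time = pre, S = Vpre * r / (1 + r), G = Vpre / (1 + r),
               E = 0, I = 0, P = 0, PL = 0, L = 0, H = 0, V = Vpre,
               ratio_SG = r, alpha = 1, R = 0)
  } else NULL

  surface <- expand.grid(ke = ke_values, ki = ki_values,
                         KEEP.OUT.ATTRS = FALSE)
  surface$logL <- NA_real_
  p <- params_template
  for (i in seq_len(nrow(surface))) {
    p["ke"] <- surface$ke[i]
    p["ki"] <- surface$ki[i]
    traj <- tryCatch(
      simulate_model(p, initial_state(p, V0), post, inputs = inputs),
      error = function(e) NULL)
    if (!is.null(traj) && !is.null(pre_rows)) {
      traj <- rbind(pre_rows, as.data.frame(traj))
      class(traj) <- c("ctl_trajectory", "data.frame")
    }
    surface$logL[i] <- if (is.null(traj)) -Inf else
      log_likelihood(map_observables(traj, observations), observations)
  }
  best <- surface[which.max(surface$logL), ]
  list(best = c(ke = best$ke, ki = best$ki), logL = best$logL,
       surface = surface, n_eval = nrow(surface))
}
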