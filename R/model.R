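#' Right-hand side of the basal tumor growth model
#'
#' Two-compartment cell-cycle model: G1 cells enter S-G2-M at rate
#' \code{kgs}; each cell leaving S-G2-M at rate \code{ksg} produces two G1
#' daughters.  Used on its own for untreated tumors; the CTL, IFNG and
#' checkpoint derivatives are returned as zero.
#'
#' @param state named numeric state; must contain \code{S} and \code{G}
#'   (other components optional and ignored).
#' @param params a \code{\link{ctl_params}} object.
#' @return named derivative vector over \code{S, G, E, I, P, PL, L, H}.
#' @export
rhs_basic <- function(state, params) {
  s <- as_state(state)
  if (any(s[c("S", "G")] < 0)) stop("negative tumor state components")
  d <- numeric(8)
  names(d) <- state_names()
  d["S"] <- params["kgs"] * s["G"] - params["ksg"] * s["S"]
  d["G"] <- -params["kgs"] * s["G"] + 2 * params["ksg"] * s["S"]
  d
}

state_names <- function() c("S", "G", "E", "I", "P", "PL", "L", "H")

as_state <- function(state) {
  s <- stats::setNames(numeric(8), state_names())
  if (is.null(names(state))) {
    if (length(state) != 8) stop("unnamed state must have all 8 components")
    s[] <- state
  } else {
    bad <- setdiff(names(state), c(state_names(), "t"))
    if (length(bad)) stop("unknown state component(s): ",
                          paste(bad, collapse = ", "))
    s[intersect(names(state), state_names())] <-
      state[intersect(names(state), state_names())]
  }
  s
}

#' IFNG-dependent G1 arrest factor
#'
#' The multiplier \eqn{(1 + k_i I / V)^{-1}} applied to the G1 to S-G2-M
#' transition rate.  \code{1/ki} is the intratumoral IFNG concentration at
#' which the transition rate is halved.
#'
#' @param I total intratumoral IFNG.
#' @param V tumor volume (must be positive).
#' @param ki arrest sensitivity (IFN^-1 mm^3).
#' @return a factor in (0, 1]; equals 1 when \code{I = 0}.
#' @export
arrest_factor <- function(I, V, ki) {
  if (any(V <= 0)) stop("tumor volume must be positive")
  if (any(I < 0) || any(ki < 0)) stop("I and ki must be non-negative")
  1 / (1 + ki * I / V)
}

#' Total exhaustion level of the intratumoral CTL population
#'
#' Weighted sum of per-CTL checkpoint expression:
#' \eqn{R = k_l L/E + k_t H/E + k_p (P/E)(P_L/V)}.  LAG3, HAVCR2 and PDCD1
#' are carried on the CTL membrane (hence the per-CTL ratios); CD274 is the
#' PDCD1 ligand and enters as an intratumoral concentration multiplying the
#' per-CTL PDCD1 density.  With no CTLs present there are no exhausted CTLs,
#' so \code{R = 0} when \code{E = 0}.
#'
#' @param state named state containing \code{E, L, H, P, PL} and the tumor
#'   compartments \code{S, G} (for \code{V = S + G}).
#' @param params a \code{\link{ctl_params}} object.
#' @return exhaustion level, a non-negative scalar.
#' @export
exhaustion_R <- function(state, params) {
  s <- as_state(state)
  if (s["E"] <= 0) return(0)
  V <- s["S"] + s["G"]
  r <- params["kl"] * s["L"] / s["E"] + params["kt"] * s["H"] / s["E"]
  if (V > 0) r <- r + params["kp"] * (s["P"] / s["E"]) * (s["PL"] / V)
  unname(r)
}

#' CTL activity as a function of exhaustion
#'
#' Maps the exhaustion level to the common activity factor
#' \eqn{\alpha = (1 + k_{ex} R)^{-1}} applied to killing, expansion and IFNG
#' production.  Unexhausted CTLs (\code{R = 0}) are fully active; at
#' \code{R = 1/kex} all effector functions are at half maximum; activity
#' vanishes as exhaustion grows without bound.
#'
#' @param R exhaustion level (non-negative).
#' @param kex half-effect scale (positive).
#' @return activity in (0, 1].
#' @export
activity_alpha <- function(R, kex) {
  if (any(R < 0)) stop("exhaustion level must be non-negative")
  if (any(kex <= 0)) stop("kex must be positive")
  1 / (1 + kex * R)
}

#' Right-hand side of the full CTL-dynamics model
#'
#' All eight derivatives: tumor compartments with IFNG arrest and
#' exhaustion-weighted killing split across compartments in proportion to
#' their share of the tumor; CTL influx (\code{s0 V}), expansion and death;
#' IFNG production by active CTLs and first-order decay; checkpoint
#' induction proportional to \code{E (1 + kA I / V)} with per-checkpoint
#' decay.  When the tumor is extinct (\code{S + G = 0}) the killing
#' fractions are defined as zero.
#'
#' @inheritParams rhs_basic
#' @param t time in days; CTL influx is active for \code{t >= t_on}.
#' @param t_on CTL transfer day (default 0).
#' @return named derivative vector.
#' @export
rhs_full <- function(state, params, t = 0, t_on = 0) {
  s <- pmax(as_state(state), 0)
  V <- s["S"] + s["G"]
  R <- exhaustion_R(s, params)
  alpha <- activity_alpha(R, params["kex"])

  # per-volume terms regularized at the ~1e-15 extinction scale so the
  # vanishing-tumor limit stays smooth and integrable
  eps <- 1e-15
  arrest <- 1 / (1 + params["ki"] * s["I"] / (V + eps))
  kill <- alpha * params["ke"] * s["E"]
  fS <- s["S"] / (V + eps)
  fG <- s["G"] / (V + eps)

  d <- numeric(8)
  names(d) <- state_names()
  d["S"] <- params["kgs"] * s["G"] * arrest - params["ksg"] * s["S"] - kill * fS
  d["G"] <- -params["kgs"] * s["G"] * arrest + 2 * params["ksg"] * s["S"] -
    kill * fG
  s0_eff <- if (t >= t_on) params["s0"] else 0
  d["E"] <- s0_eff * V + alpha * params["se"] * s["E"] - params["dE"] * s["E"]
  d["I"] <- alpha * s["E"] - params["di"] * s["I"]
  ind <- s["E"] * (1 + params["kA"] * s["I"] / (V + eps))
  d["P"] <- ind - params["dp"] * s["P"]
  d["PL"] <- ind - params["dpl"] * s["PL"]
  d["L"] <- ind - params["dl"] * s["L"]
  d["H"] <- ind - params["dt"] * s["H"]
  d
}

#' Piecewise-linear input signals for the input-driven model
#'
#' Builds clamped linear interpolants of observed CTL abundance and IFNG
#' level from (day, mean) knots, for use as external inputs replacing the
#' CTL and IFNG equations.  Evaluation at a knot returns the knot mean
#' exactly; outside the knot range the nearest knot value is held constant.
#'
#' @param knots_E data.frame with columns \code{day}, \code{value} for CTLs.
#' @param knots_I likewise for IFNG.
#' @return an object of class \code{ctl_inputs} with elements
#'   \code{E_of_t}, \code{I_of_t} (functions of day) and \code{knots}.
#' @export
input_signals <- function(knots_E, knots_I) {
  chk <- function(k, what) {
    if (!all(c("day", "value") %in% names(k)))
      stop(what, " knots need columns day, value")
    if (anyNA(k$day) || anyNA(k$value)) stop(what, " knots contain NA")
    k[order(k$day), c("day", "value")]
  }
  knots_E <- chk(knots_E, "CTL")
  knots_I <- chk(knots_I, "IFNG")
  structure(list(
    E_of_t = stats::approxfun(knots_E$day, knots_E$value, rule = 2),
    I_of_t = stats::approxfun(knots_I$day, knots_I$value, rule = 2),
    knots = list(E = knots_E, I = knots_I)
  ), class = "ctl_inputs")
}

#' Initial state at basal steady-state cycling
#'
#' Places the tumor compartments at the steady-state S:G ratio implied by
#' \code{kgs, ksg}, scaled to total volume \code{V0}, with no CTLs, IFNG or
#' checkpoints present.
#'
#' @param params a \code{\link{ctl_params}} object.
#' @param V0 initial tumor volume (mm^3-equivalents; default 100, the
#'   typical treated tumor size at transfer).
#' @return named state vector.
#' @export
initial_state <- function(params, V0 = 100) {
  r <- steady_state_ratio(params["kgs"], params["ksg"])
  s <- stats::setNames(numeric(8), state_names())
  s["S"] <- V0 * r / (1 + r)
  s["G"] <- V0 / (1 + r)
  s
}

#' Simulate the CTL-melanoma model
#'
#' Integrates either the full eight-state model or, when \code{inputs} is
#' given, the two-state tumor model driven by externally supplied CTL and
#' IFNG time courses (the CTL/IFNG/checkpoint equations are then disabled).
#' Integration uses a stiff-capable adaptive method (\code{deSolve::lsoda})
#' with compiled right-hand sides; tolerances default to rtol 1e-8 /
#' atol 1e-10 so that likelihood surfaces built on the output are smooth.
#' Small negative solver excursions are truncated to zero.
#'
#' @param params a \code{\link{ctl_params}} object.
#' @param init named initial state (see \code{\link{initial_state}}).
#' @param times strictly increasing vector of days at which to report.
#' @param inputs optional \code{\link{input_signals}} object: run the
#'   input-driven model.
#' @param t_on CTL transfer day for the full model (default 0).
#' @param rtol,atol solver tolerances.
#' @return a \code{ctl_trajectory}: data.frame with columns \code{time, S,
#'   G, E, I, P, PL, L, H, V, ratio_SG, alpha, R}.
#' @export
simulate_model <- function(params, init = initial_state(params), times,
                           inputs = NULL, t_on = 0,
                           rtol = 1e-8, atol = 1e-10) {
  validate_params(params)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  s <- as_state(init)
  if (any(s < 0)) stop("negative initial state components")

  if (is.null(inputs)) {
    p <- c(as.numeric(params[param_names()]), t_on)
    out <- deSolve::lsoda(
      y = s, times = times, func = "ctldyn_derivs_full", parms = p,
      dllname = "ctldyn", initfunc = "ctldyn_init_full",
      rtol = rtol, atol = atol, maxsteps = 20000
    )
    check_solver(out, times)
    traj <- as.data.frame(out)
    names(traj)[1] <- "time"
  } else {
    if (!inherits(inputs, "ctl_inputs")) stop("inputs must be ctl_inputs")
    p <- as.numeric(params[c("kgs", "ksg", "ki", "ke")])
    fE <- cbind(inputs$knots$E$day, inputs$knots$E$value)
    fI <- cbind(inputs$knots$I$day, inputs$knots$I$value)
    # widen the forcing tables so deSolve's linear interpolation clamps
    span <- range(times, fE[, 1], fI[, 1])
    widen <- function(m) {
      rbind(c(span[1] - 1, m[1, 2]), m, c(span[2] + 1, m[nrow(m), 2]))
    }
    out <- deSolve::lsoda(
      y = s[c("S", "G")], times = times, func = "ctldyn_derivs_forced",
      parms = p, dllname = "ctldyn", initfunc = "ctldyn_init_forced",
      initforc = "ctldyn_forc", forcings = list(widen(fE), widen(fI)),
      fcontrol = list(method = "linear", rule = 2),
      rtol = rtol, atol = atol, maxsteps = 20000
    )
    check_solver(out, times)
    traj <- as.data.frame(out)
    names(traj)[1] <- "time"
    traj$E <- inputs$E_of_t(traj$time)
    traj$I <- inputs$I_of_t(traj$time)
    traj$P <- traj$PL <- traj$L <- traj$H <- 0
  }

  for (nm in state_names()) traj[[nm]] <- pmax(traj[[nm]], 0)
  traj$V <- traj$S + traj$G
  traj$ratio_SG <- ifelse(traj$G > 0, traj$S / traj$G, NA_real_)
  if (is.null(inputs)) {
    traj$R <- vapply(seq_len(nrow(traj)), function(i) {
      exhaustion_R(unlist(traj[i, state_names()]), params)
    }, numeric(1))
    traj$alpha <- activity_alpha(traj$R, params["kex"])
  } else {
    traj$R <- 0
    traj$alpha <- 1
  }
  traj <- traj[, c("time", state_names(), "V", "ratio_SG", "alpha", "R")]
  class(traj) <- c("ctl_trajectory", "data.frame")
  traj
}

#' Simulate a cohort with the pre-transfer segment handled in closed form
#'
#' Before CTL transfer the tumor grows basally with no CTLs, IFNG or
#' checkpoints, so the pre-transfer states are written down exactly
#' (exponential growth at the dominant rate, cycle compartments at the
#' steady-state ratio) and numerical integration starts at the transfer
#' day.  This keeps the integrated right-hand side smooth, which matters
#' for likelihood optimization.
#'
#' @param params a \code{\link{ctl_params}} object.
#' @param V0 tumor volume at the transfer day.
#' @param times report days (may extend before the transfer).
#' @param t_on transfer day (default 0).
#' @param rtol,atol solver tolerances.
#' @return a \code{ctl_trajectory} over \code{times}.
#' @export
simulate_cohort <- function(params, V0, times, t_on = 0,
                            rtol = 1e-8, atol = 1e-10) {
  times <- sort(unique(round(times, 9)))
  pre <- times[times < t_on]
  post <- times[times >= t_on]
  g <- basal_growth_rate(params["kgs"], params["ksg"])
  r <- steady_state_ratio(params["kgs"], params["ksg"])

  traj_post <- NULL
  if (length(post)) {
    sim_times <- sort(unique(c(t_on, post)))
    tr <- simulate_model(params, initial_state(params, V0), sim_times,
                         t_on = t_on, rtol = rtol, atol = atol)
    traj_post <- as.data.frame(tr)[match(post, tr$time), , drop = FALSE]
  }
  traj_pre <- NULL
  if (length(pre)) {
    Vpre <- V0 * exp(g * (pre - t_on))
    traj_pre <- data.frame(time = pre, S = Vpre * r / (1 + r),
                           G = Vpre / (1 + r), E = 0, I = 0, P = 0,
                           PL = 0, L = 0, H = 0, V = Vpre, ratio_SG = r,
                           alpha = 1, R = 0)
  }
  traj <- rbind(traj_pre, traj_post)
  rownames(traj) <- NULL
  class(traj) <- c("ctl_trajectory", "data.frame")
  traj
}

check_solver <- function(out, times) {
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop(sprintf("ODE solver failed (istate %d) near t = %.4g",
                 istate[1], out[nrow(out), 1]))
  if (nrow(out) < length(times))
    stop(sprintf("ODE solver stopped early at t = %.4g", out[nrow(out), 1]))
  invisible(out)
}

#' Write a simulated trajectory to CSV
#'
#' @param traj a \code{ctl_trajectory}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
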