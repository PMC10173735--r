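# Shared fixtures, built in code.

# Reference truth: the best-fitting full-model parameter set (package default).
ref_truth <- function() ctl_params()

# A moderate-killing parameterization with well-behaved dynamics (tumor
# volume dips without near-extinction).  Used for tests that probe solver
# consistency, sampling or selection behaviour rather than the reference fit.
tame_truth <- function(...) {
  ctl_params(se = 7.3, dE = 0.59, di = 0.67, ki = 21.7, ke = 0.33,
             kl = 0.001, kt = 1.37, kp = 0.001,
             dl = 0.65, dt = 0.01, dp = 2.33, dpl = 2.48, ...)
}

# A mild parameterization (expansion below death rate) whose expression
# observables stay within the housekeeping intensity range, so microarray
# normalization is exactly invertible in the noiseless limit.
gentle_truth <- function() {
  ctl_params(se = 0.5, dE = 0.8, di = 0.67, ki = 21.7, ke = 0.5,
             kt = 1.37, kl = 0.001, kp = 0.001)
}

# Fast IFNG turnover, strong arrest, weak killing: the cycle ratio tracks
# the CTL count almost instantaneously, the co-phased regime behind
# image-level CTL-vs-ratio anticorrelation.
corr_truth <- function() {
  ctl_params(di = 10, ki = 300, ke = 0.01)
}

# HAVCR2-dominant truth (LAG3 and PDCD1/CD274 weights exactly zero) with
# well-conditioned dynamics, for model-selection and sweep experiments
havcr2_truth <- function() {
  ctl_params(se = 6, dE = 0.8, di = 0.67, ki = 21.7, ke = 0.33,
             kl = 0, kt = 2, kp = 0)
}

# noiseless per-mouse volume table growing exponentially at rate g
exact_exponential_volumes <- function(g = 0.4, n_mice = 5,
                                      days = c(-1, 1, 3, 5, 7), V0 = 100) {
  do.call(rbind, lapply(seq_len(n_mice), function(m) {
    data.frame(mouse_id = paste0("m", m), cohort = "untreated",
               day = days, volume_mm3 = V0 * exp(g * days))
  }))
}

# forced-mode fixtures: plausible CTL and IFNG input courses for the
# input-driven two-parameter model
fig4_inputs <- function() {
  input_signals(
    data.frame(day = c(0, 1, 3, 5, 7, 10, 14),
               value = c(0, 10, 30, 12, 5, 1, 0.2)),
    data.frame(day = c(0, 1, 3, 5, 7),
               value = c(0, 0.3, 1.6, 0.29, 0.01) * 100))
}

# noiseless growth-rate + cycle-ratio observations produced by the
# input-driven model at a known (ke, ki) truth
forced_observations <- function(ke, ki, inputs = fig4_inputs()) {
  p <- ctl_params(ke = ke, ki = ki)
  days <- c(-1, 1, 3, 5, 7, 10, 14)
  gdays <- data.frame(t1 = days[-length(days)], t2 = days[-1])
  times <- sort(unique(c(0, days)))
  tr <- simulate_model(p, initial_state(p, 100), times[times >= 0],
                       inputs = inputs)
  g <- basal_growth_rate(p["kgs"], p["ksg"])
  r <- steady_state_ratio(p["kgs"], p["ksg"])
  pre <- data.frame(time = -1, S = NA, G = NA, E = 0, I = 0, P = 0, PL = 0,
                    L = 0, H = 0, V = 100 * exp(-g), ratio_SG = r,
                    alpha = 1, R = 0)
  pre$S <- pre$V * r / (1 + r); pre$G <- pre$V / (1 + r)
  tr <- rbind(pre, as.data.frame(tr))
  at <- function(d, col) tr[[col]][match(d, tr$time)]
  obs <- rbind(
    data.frame(observable = "growth_rate", day = (gdays$t1 + gdays$t2) / 2,
               t1 = gdays$t1, t2 = gdays$t2,
               mean = log(at(gdays$t2, "V") / at(gdays$t1, "V")) /
                 (gdays$t2 - gdays$t1),
               sd = 0.1, condition = "treated", include = TRUE, reason = ""),
    data.frame(observable = "ratio_sgm_g1", day = days[-1], t1 = days[-1],
               t2 = days[-1], mean = at(days[-1], "S") / at(days[-1], "G"),
               sd = 0.15, condition = "treated", include = TRUE, reason = "")
  )
  observation_set(obs)
}

# a ctl_fit-shaped object built directly from known parameters, so that
# sweep / ablation / posterior machinery can be tested without refitting
fake_fit <- function(params, observations, variant = "all", V0 = 100) {
  obj <- make_objective(observations, variant, params_template = params,
                        V0 = V0)
  structure(list(variant = variant, params = params,
                 logL = obj$fn(log10(as.numeric(params[obj$free]))),
                 n_free = length(obj$free), free = obj$free,
                 par_log10 = log10(as.numeric(params[obj$free])),
                 lower = obj$lower, upper = obj$upper,
                 top_sets = NULL, V0 = V0, t_on = 0,
                 obs_hash = obj$hash),
            class = "ctl_fit")
}

# batch-means Monte Carlo standard error for an MCMC draw vector
mcse <- function(x, n_batch = 20) {
  n <- length(x)
  bs <- floor(n / n_batch)
  bm <- vapply(seq_len(n_batch), function(b)
    mean(x[((b - 1) * bs + 1):(b * bs)]), numeric(1))
  stats::sd(bm) / sqrt(n_batch)
}
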