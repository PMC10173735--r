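test_that("basal cell-cycle right-hand side matches the two-compartment algebra", {
  p <- ctl_params(kgs = 1.64, ksg = 0.66)
  d <- rhs_basic(c(S = 1, G = 1), p)
  expect_equal(unname(d["S"]), 1.64 * 1 - 0.66 * 1)
  expect_equal(unname(d["G"]), -1.64 + 2 * 0.66)
  expect_equal(unname(d[c("E", "I", "P", "PL", "L", "H")]), rep(0, 6))
  expect_error(rhs_basic(c(S = -1, G = 1), p), "negative")
})

test_that("arrest factor follows the saturating IFNG dependence", {
  expect_equal(arrest_factor(I = 5, V = 2, ki = 0), 1)
  # half-maximal arrest at the concentration 1/ki
  expect_equal(arrest_factor(I = 1 / 4.40, V = 1, ki = 4.40), 0.5)
  expect_equal(arrest_factor(I = 1.64, V = 1, ki = 8.1),
               1 / (1 + 8.1 * 1.64))
  expect_lt(arrest_factor(I = 1.64, V = 1, ki = 8.1), 0.075)
  expect_error(arrest_factor(I = 1, V = 0, ki = 1), "positive")
  # monotone decreasing in IFNG over random parameterizations
  set.seed(42)
  for (rep in 1:20) {
    ki <- runif(1, 0, 20); V <- runif(1, 1, 200)
    I <- sort(runif(10, 0, 50))
    expect_true(all(diff(arrest_factor(I, V, ki)) < 0))
  }
})

test_that("exhaustion level aggregates per-CTL checkpoint burden", {
  p0 <- ctl_params(kl = 0, kt = 0, kp = 0)
  st <- c(S = 10, G = 10, E = 1, L = 2, H = 3, P = 2, PL = 3)
  expect_equal(exhaustion_R(st, p0), 0)
  expect_equal(exhaustion_R(st, ctl_params(kl = 1, kt = 0, kp = 0)), 2)
  st2 <- c(S = 0.5, G = 0.5, E = 1, P = 2, PL = 3, L = 0, H = 0)
  expect_equal(exhaustion_R(st2, ctl_params(kl = 0, kt = 0, kp = 1)), 6)
  # no CTLs means no exhausted CTLs
  expect_equal(exhaustion_R(c(S = 1, G = 1, E = 0, L = 5), ctl_params()), 0)
})

test_that("CTL activity is maximal when unexhausted and vanishes with exhaustion", {
  expect_equal(activity_alpha(0, 1), 1)
  expect_equal(activity_alpha(1, 1), 0.5)
  expect_lt(activity_alpha(1e8, 1), 1e-7)
  set.seed(7)
  for (rep in 1:20) {
    kex <- runif(1, 0.1, 10)
    R <- sort(runif(10, 0, 100))
    expect_true(all(diff(activity_alpha(R, kex)) < 0))
  }
})

test_that("full right-hand side reduces to the basal model without CTLs", {
  p <- ctl_params(s0 = 0)   # no influx: the CTL compartment stays empty
  st <- c(S = 30, G = 20)
  expect_equal(rhs_full(st, p), rhs_basic(st, p))
})

test_that("killing is split across cycle compartments by their share", {
  p <- ctl_params(ke = 100, ki = 0, kl = 0, kt = 0, kp = 0)
  st <- c(S = 50, G = 50, E = 0.01)
  d <- rhs_full(st, p)
  db <- rhs_basic(st, p)
  # total kill rate alpha*ke*E = 1, split 0.5 / 0.5
  expect_equal(unname(d["S"] - db["S"]), -0.5)
  expect_equal(unname(d["G"] - db["G"]), -0.5)
})

test_that("reference dynamics: CTLs rise then fall, IFNG peaks no later than CTLs", {
  p <- ref_truth()
  tr <- simulate_model(p, initial_state(p, 100), times = seq(0, 14, 0.1))
  iE <- which.max(tr$E)
  expect_gt(iE, 1)                      # E rises...
  expect_lt(tr$E[nrow(tr)], max(tr$E) / 10)  # ...then falls
  expect_lte(tr$time[which.max(tr$I)], tr$time[iE])
})

test_that("without CTL influx or killing the tumor grows at the dominant eigenvalue", {
  p <- ctl_params(s0 = 0, ke = 0, ki = 0)
  V0 <- 80
  tr <- simulate_model(p, initial_state(p, V0), times = seq(0, 12, 0.5))
  lam <- max(eigen(matrix(c(-p["ksg"], 2 * p["ksg"], p["kgs"], -p["kgs"]),
                          2, 2))$values)
  expect_equal(tr$V, V0 * exp(lam * tr$time), tolerance = 1e-6)
})

test_that("input-driven and autonomous modes agree when CTLs and IFNG are absent", {
  p <- ctl_params(s0 = 0)
  inputs <- input_signals(data.frame(day = c(0, 14), value = 0),
                          data.frame(day = c(0, 14), value = 0))
  t_out <- seq(0, 10, 1)
  tr_forced <- simulate_model(p, initial_state(p, 50), t_out, inputs = inputs)
  tr_auto <- simulate_model(p, initial_state(p, 50), t_out)
  expect_equal(tr_forced$S, tr_auto$S, tolerance = 1e-8)
  expect_equal(tr_forced$G, tr_auto$G, tolerance = 1e-8)
})

test_that("forcing with the autonomous model's own CTL and IFNG courses reproduces the tumor dynamics", {
  p <- gentle_truth()
  t_dense <- seq(0, 14, 0.05)
  tr <- simulate_model(p, initial_state(p, 100), t_dense)
  # alpha-weighted killing is absorbed by handing the model an effective
  # CTL input alpha(t) * E(t): the tumor equations then match exactly
  inputs <- input_signals(
    data.frame(day = t_dense, value = tr$alpha * tr$E),
    data.frame(day = t_dense, value = tr$I))
  t_out <- seq(0, 14, 1)
  trf <- simulate_model(p, initial_state(p, 100), t_out, inputs = inputs)
  i <- match(t_out, round(tr$time, 9))
  expect_equal(trf$S, tr$S[i], tolerance = 1e-5)
  expect_equal(trf$G, tr$G[i], tolerance = 1e-5)
})

test_that("input signals interpolate linearly and clamp outside the knots", {
  inp <- input_signals(data.frame(day = c(1, 3, 7), value = c(2, 10, 4)),
                       data.frame(day = c(1, 7), value = c(0, 6)))
  expect_equal(inp$E_of_t(c(1, 3, 7)), c(2, 10, 4))   # knots exact
  expect_equal(inp$E_of_t(2), 6)                      # linear between
  expect_equal(inp$E_of_t(c(-5, 20)), c(2, 4))        # clamped outside
})

test_that("trajectories stay non-negative for random valid parameterizations", {
  set.seed(11)
  for (rep in 1:8) {
    p <- ctl_params(se = runif(1, 1, 6), dE = runif(1, 0.1, 2),
                    di = runif(1, 0.1, 5), ki = runif(1, 0, 30),
                    ke = runif(1, 0, 20), kt = runif(1, 0.2, 2),
                    kl = runif(1, 0, 2), kp = runif(1, 0, 0.1))
    tr <- suppressWarnings(
      simulate_model(p, initial_state(p, 100), seq(0, 14, 0.25)))
    expect_true(all(as.matrix(tr[, c("S", "G", "E", "I", "P", "PL", "L", "H")]) >= 0))
  }
})

test_that("an IFNG pulse in forced mode dips the cycle ratio, which then recovers", {
  p <- tame_truth(ke = 0)
  inputs <- input_signals(
    data.frame(day = c(0, 14), value = 0),
    data.frame(day = c(0, 2.9, 3, 3.1, 14), value = c(0, 0, 30, 0, 0)))
  tr <- simulate_model(p, initial_state(p, 100), seq(0, 14, 0.1),
                       inputs = inputs)
  r0 <- tr$ratio_SG[1]
  expect_lt(min(tr$ratio_SG[tr$time > 3 & tr$time < 5]), 0.9 * r0)
  expect_gt(tr$ratio_SG[nrow(tr)], 0.99 * r0)
})

test_that("checkpoint decay rates do not feed back on tumor or CTLs when weights are zero", {
  p1 <- tame_truth(kl = 0, kt = 0, kp = 0, se = 2, dE = 1,
                   dl = 0.1, dt = 0.1, dp = 0.1, dpl = 0.1)
  p2 <- tame_truth(kl = 0, kt = 0, kp = 0, se = 2, dE = 1,
                   dl = 5, dt = 5, dp = 5, dpl = 5)
  t_out <- seq(0, 10, 0.5)
  tr1 <- simulate_model(p1, initial_state(p1, 100), t_out)
  tr2 <- simulate_model(p2, initial_state(p2, 100), t_out)
  for (v in c("S", "G", "E", "I"))
    expect_equal(tr1[[v]], tr2[[v]], tolerance = 1e-6)
})

test_that("cohort simulation handles the pre-transfer segment in closed form", {
  p <- tame_truth()
  tr <- simulate_cohort(p, V0 = 100, times = c(-1, 0, 1, 3), t_on = 0)
  g <- basal_growth_rate(p["kgs"], p["ksg"])
  expect_equal(tr$V[tr$time == -1], 100 * exp(-g), tolerance = 1e-10)
  expect_equal(tr$E[tr$time <= 0], c(0, 0))
  expect_equal(tr$V[tr$time == 0], 100)
})

test_that("trajectory CSV export carries the tidy column set", {
  p <- tame_truth()
  tr <- simulate_model(p, initial_state(p, 100), 0:3)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read.csv(f)
  expect_identical(names(back),
                   c("time", "S", "G", "E", "I", "P", "PL", "L", "H",
                     "V", "ratio_SG", "alpha", "R"))
  unlink(f)
})
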