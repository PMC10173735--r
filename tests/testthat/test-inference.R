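test_that("grid search recovers input-driven killing and arrest parameters", {
  obs <- forced_observations(ke = 0.9, ki = 8.1)
  gs <- grid_search_basic(obs, fig4_inputs(),
                          ke_values = seq(0, 2, 0.1),
                          ki_values = seq(7.1, 9.1, 0.1))
  expect_equal(gs$n_eval, 21 * 21)
  expect_equal(unname(gs$best["ke"]), 0.9, tolerance = 1e-9)
  expect_equal(unname(gs$best["ki"]), 8.1, tolerance = 1e-9)
  expect_equal(gs$logL, 0, tolerance = 1e-6)
})

test_that("grid search equals an independent brute-force double loop", {
  obs <- forced_observations(ke = 0.9, ki = 8.1)
  inputs <- fig4_inputs()
  ke_v <- seq(0, 2, 0.1)
  ki_v <- seq(7.1, 9.1, 0.1)
  gs <- grid_search_basic(obs, inputs, ke_v, ki_v)

  # oracle: explicit loop over the same grid through the public pieces
  best <- c(NA, NA); best_ll <- -Inf
  times <- required_times(obs, extra = 0)
  for (ke in ke_v) for (ki in ki_v) {
    p <- ctl_params(ke = ke, ki = ki)
    tr <- simulate_model(p, initial_state(p, 100),
                         times[times >= 0], inputs = inputs)
    g <- basal_growth_rate(p["kgs"], p["ksg"])
    r <- steady_state_ratio(p["kgs"], p["ksg"])
    pre <- data.frame(time = -1, S = NA, G = NA, E = 0, I = 0, P = 0,
                      PL = 0, L = 0, H = 0, V = 100 * exp(-g),
                      ratio_SG = r, alpha = 1, R = 0)
    pre$S <- pre$V * r / (1 + r); pre$G <- pre$V / (1 + r)
    tr <- rbind(pre, as.data.frame(tr))
    ll <- log_likelihood(map_observables(tr, obs), obs)
    if (ll > best_ll) { best_ll <- ll; best <- c(ke, ki) }
  }
  expect_equal(unname(gs$best), best, tolerance = 1e-12)
  expect_equal(gs$logL, best_ll, tolerance = 1e-9)
  expect_equal(max(gs$surface$logL), best_ll, tolerance = 1e-9)
})

test_that("data generated without arrest put the optimum at the ki boundary", {
  obs <- forced_observations(ke = 1.2, ki = 0)
  gs <- grid_search_basic(obs, fig4_inputs(),
                          ke_values = seq(0.8, 1.6, 0.2),
                          ki_values = seq(0, 2, 0.5))
  expect_equal(unname(gs$best["ki"]), 0)
  expect_error(grid_search_basic(obs, fig4_inputs(), numeric(0), 1),
               "empty grid")
})

test_that("multistart fitting is deterministic given the seed", {
  obs <- observe_model(tame_truth())
  f1 <- multistart_fit(obs, "all", n_starts = 3, seed = 42, n_polish = 1,
                       screen_maxit = 15, polish_maxit = 30)
  f2 <- multistart_fit(obs, "all", n_starts = 3, seed = 42, n_polish = 1,
                       screen_maxit = 15, polish_maxit = 30)
  expect_identical(f1$par_log10, f2$par_log10)
  expect_identical(f1$logL, f2$logL)
  expect_identical(f1$top_sets, f2$top_sets)
  expect_equal(f1$AIC, 2 * f1$n_free - 2 * f1$logL)
})

test_that("a no-checkpoint variant cannot explain exhaustion-driven data", {
  obs <- observe_model(havcr2_truth())
  f_none <- multistart_fit(obs, "none", n_starts = 12, seed = 5,
                           n_polish = 2, screen_maxit = 60)
  f_all <- multistart_fit(obs, "all", n_starts = 12, seed = 5,
                          n_polish = 2, screen_maxit = 60)
  expect_lt(f_none$logL, f_all$logL - 20)
})

test_that("AIC comparison ranks by penalized likelihood and guards inputs", {
  obs <- observe_model(tame_truth())
  fit_a <- fake_fit(tame_truth(), obs, "all")
  fit_a$logL <- 0; fit_a$n_free <- 2; fit_a$AIC <- 4
  fit_b <- fake_fit(tame_truth(), obs, "none")
  fit_b$logL <- -10; fit_b$n_free <- 13
  fit_b$AIC <- 2 * 13 - 2 * fit_b$logL
  tab <- compare_variants(list(fit_b, fit_a))
  expect_equal(tab$variant, c("all", "none"))
  expect_equal(tab$AIC[1], 4)                 # k = 2, logL = 0
  expect_equal(tab$dAIC, c(0, 42))

  # equal fit, different parameter counts: dAIC = 2 * dk
  fit_c <- fit_b; fit_c$variant <- "lag3_only"
  fit_c$logL <- -10; fit_c$n_free <- 11; fit_c$AIC <- 2 * 11 + 20
  tab2 <- compare_variants(list(fit_b, fit_c))
  expect_equal(tab2$dAIC[2], 4)

  other <- observe_model(havcr2_truth())
  fit_d <- fake_fit(havcr2_truth(), other, "all")
  expect_error(compare_variants(list(fit_a, fit_d)), "different observation")
})

test_that("checkpoint ablation isolates the dominant inhibitor", {
  # HAVCR2-dominant but mild dynamics: ablation must stay integrable
  truth <- gentle_truth()
  truth["kl"] <- 0
  truth["kp"] <- 0
  obs <- observe_model(truth)
  fit <- fake_fit(truth, obs, "all")

  # ablating a checkpoint whose weight is already zero changes nothing
  ab0 <- ablate_inhibitor(fit, "pdcd1")
  expect_lt(max(ab0$divergence$max_abs), 1e-10)

  ab_t <- ablate_inhibitor(fit, "havcr2")
  expect_gt(max(ab_t$divergence$rmse), 1e3 * max(ab0$divergence$rmse + 1e-12))

  # disabling all three reproduces the no-checkpoint variant dynamics
  ab_all <- ablate_inhibitor(fit, c("lag3", "havcr2", "pdcd1"))
  p_none <- truth; p_none[c("kl", "kt", "kp")] <- 0
  tr_none <- simulate_cohort(p_none, 100, ab_all$ablated$time)
  expect_equal(ab_all$ablated$E, tr_none$E, tolerance = 1e-8)

  expect_error(ablate_inhibitor(fit, "ctla4"), "unknown checkpoint")
})
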