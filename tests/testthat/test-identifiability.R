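test_that("sampler recovers a two-dimensional Gaussian target", {
  mu <- c(1, -2)
  S <- matrix(c(1, 0.6, 0.6, 2), 2)
  Si <- solve(S)
  logpost <- function(x) -0.5 * drop(t(x - mu) %*% Si %*% (x - mu))
  init <- matrix(rnorm(6 * 2, sd = 0.3), 6, 2,
                 dimnames = list(NULL, c("a", "b")))
  init <- sweep(init, 2, mu, "+")
  post <- am_phs_sample(logpost, init, lower = c(-20, -20),
                        upper = c(20, 20), n_steps = 6000, n_aux = 5,
                        seed = 3)
  for (j in 1:2) {
    se <- mcse(post$draws[, j])
    expect_lt(abs(mean(post$draws[, j]) - mu[j]), 3 * se)
  }
  expect_gt(post$accept_rate[1], 0.1)
  expect_lt(post$accept_rate[1], 0.6)
})

test_that("sampler is calibrated on a flat target and deterministic by seed", {
  logpost <- function(x) 0
  init <- matrix(runif(4), 4, 1)
  run <- function(seed) am_phs_sample(logpost, init, lower = 0, upper = 1,
                                      n_steps = 8000, n_aux = 3, seed = seed)
  p1 <- run(11)
  # flat posterior on [0,1]: thinned marginal should be uniform (thinning
  # reduces the autocorrelation the iid KS test does not account for)
  thin <- p1$draws[seq(1, nrow(p1$draws), by = 10), 1]
  set.seed(99)
  expect_gt(stats::ks.test(jitter(thin, amount = 1e-9),
                           "punif")$p.value, 0.01)
  p2 <- run(11)
  expect_identical(p1$draws, p2$draws)

  expect_error(am_phs_sample(logpost, init, 0, 1, n_steps = 100, n_aux = 10),
               "initial parameter sets")
})

test_that("credible intervals report quantiles and flag bound-limited ends", {
  draws <- matrix(0.5, 500, 1, dimnames = list(NULL, "x"))
  s <- structure(list(draws = draws, lower = 0, upper = 1),
                 class = "ctl_posterior")
  ci <- credible_intervals(s)
  expect_equal(c(ci$low, ci$high), c(0.5, 0.5))
  expect_true(ci$low_determined && ci$high_determined)

  set.seed(2)
  draws_u <- matrix(runif(10000), ncol = 1, dimnames = list(NULL, "x"))
  s_u <- structure(list(draws = draws_u, lower = -5, upper = 5),
                   class = "ctl_posterior")
  ci_u <- credible_intervals(s_u)
  expect_lt(abs(ci_u$low - 0.01), 0.01)
  expect_lt(abs(ci_u$high - 0.99), 0.01)

  # draws piled at the lower box bound: lower end undetermined
  draws_b <- matrix(c(rep(0, 300), runif(700)), ncol = 1,
                    dimnames = list(NULL, "x"))
  s_b <- structure(list(draws = draws_b, lower = 0, upper = 1),
                   class = "ctl_posterior")
  expect_false(credible_intervals(s_b)$low_determined)

  expect_error(credible_intervals(structure(
    list(draws = draws[0, , drop = FALSE], lower = 0, upper = 1),
    class = "ctl_posterior")), "empty")
})

test_that("likelihood sweeps expose identifiable and irrelevant parameters", {
  truth <- tame_truth()
  obs_full <- observe_model(truth)
  fit <- fake_fit(truth, obs_full, "all")

  # profile through an identifiable parameter peaks at the reference value
  sw <- likelihood_sweep(fit, obs_full, "ki",
                         grid = truth["ki"] * c(0.5, 0.8, 1, 1.25, 2))
  expect_equal(which.max(sw$logL), 3)
  expect_lt(max(sw$logL[-3]), sw$logL[3])

  # a decay rate with zero upstream weight and no matching observable rows
  # is flat: drop the lag3 rows and sweep dl with kl = 0
  truth0 <- truth; truth0["kl"] <- 0
  obs_sub <- observation_set(
    as.data.frame(observe_model(truth0))[
      as.data.frame(observe_model(truth0))$observable != "lag3", ])
  fit0 <- fake_fit(truth0, obs_sub, "all")
  sw0 <- likelihood_sweep(fit0, obs_sub, "dl", grid = c(0.05, 0.5, 5, 50))
  expect_lt(diff(range(sw0$logL)), 1e-8)

  expect_error(likelihood_sweep(fit, obs_full, "kex", grid = 1),
               "unknown or fixed")
})

test_that("HAVCR2-dominant data constrain its decay rate more than LAG3's", {
  truth <- havcr2_truth()
  obs <- observe_model(truth)
  fit <- fake_fit(truth, obs, "all")
  grid_t <- truth["dt"] * c(1, 10, 100, 1000)
  grid_l <- truth["dl"] * c(1, 10, 100, 1000)
  drop_t <- diff(range(likelihood_sweep(fit, obs, "dt", grid_t)$logL))
  drop_l <- diff(range(likelihood_sweep(fit, obs, "dl", grid_l)$logL))
  expect_gt(drop_t, drop_l)
})

test_that("posterior-predictive ensembles tag draws and tolerate edge cases", {
  truth <- tame_truth()
  obs <- observe_model(truth)
  fit <- multistart_fit(obs, "all", n_starts = 2, seed = 8, n_polish = 1,
                        screen_maxit = 10, polish_maxit = 10)
  post <- sample_posterior(fit, obs, n_steps = 300, n_aux = 1,
                           n_retain = 150, seed = 4)
  expect_true(all(post$draws >= matrix(post$lower, 150, ncol(post$draws),
                                       byrow = TRUE)))

  pp0 <- posterior_predictive(post, n_draws = 0)
  expect_null(pp0$trajectories)

  # identical draws yield identical trajectories
  post2 <- post
  post2$draws <- post$draws[rep(1, 120), , drop = FALSE]
  pp <- posterior_predictive(post2, n_draws = 3, seed = 1,
                             times = seq(0, 5, 1))
  sp <- split(pp$trajectories[, c("E", "V")], pp$trajectories$draw)
  expect_equal(sp[[1]], sp[[2]], ignore_attr = TRUE)
  expect_length(pp$failed, 0)
})
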