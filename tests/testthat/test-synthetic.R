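test_that("study design validates overrides and fixes the cohort structure", {
  d <- study_design()
  expect_equal(d$untreated_experiments, c(5, 5))
  expect_equal(d$treated_experiments, c(5, 5, 2))
  expect_equal(d$imaging_days, c(1, 3, 5, 7, 10, 14))
  expect_error(study_design(bogus = 1), "unknown design field")
  expect_equal(study_design(V0 = 60)$V0, 60)
})

test_that("generated volumes are deterministic and noiseless untreated growth is exponential", {
  truth <- tame_truth()
  v1 <- generate_volumes(truth, seed = 7)
  v2 <- generate_volumes(truth, seed = 7)
  expect_identical(v1, v2)
  expect_false(identical(v1, generate_volumes(truth, seed = 8)))

  d0 <- study_design(init_sd = 0)
  v0 <- generate_volumes(truth, d0, noise_sd = 0, seed = 1)
  un <- v0[v0$cohort == "untreated", ]
  r <- interval_growth_rates(un)
  g <- basal_growth_rate(truth["kgs"], truth["ksg"])
  expect_equal(r$rate, rep(g, nrow(r)), tolerance = 1e-6)
})

test_that("treated interval rates dip after transfer and recover later", {
  truth <- ref_truth()
  v <- generate_volumes(truth, study_design(init_sd = 0), noise_sd = 0,
                        seed = 1)
  r <- interval_growth_rates(v[v$cohort == "treated", ])
  g <- basal_growth_rate(truth["kgs"], truth["ksg"])
  mid <- tapply(r$rate, r$day, mean)
  expect_lt(min(mid[names(mid) %in% c("2", "4", "6")]), 0)  # arrest window
  expect_gt(mid[["12"]], 0.25)                              # late regrowth
})

test_that("cryosection counts reproduce model ratios in the zero-dispersion limit", {
  truth <- tame_truth()
  cs <- generate_cryosections(truth, dispersion = 0, seed = 1)
  tr <- simulate_cohort(truth, 100, study_design()$imaging_days)
  d3 <- cs[cs$condition == "treated" & cs$day == 3, ]
  expect_equal(unique(d3$sgm_count / d3$g1_count),
               tr$S[tr$time == 3] / tr$G[tr$time == 3], tolerance = 1e-9)
  expect_equal(unique(d3$ctl_count), tr$E[tr$time == 3], tolerance = 1e-9)

  cs1 <- generate_cryosections(truth, dispersion = 0.1, seed = 3)
  expect_identical(cs1, generate_cryosections(truth, dispersion = 0.1,
                                              seed = 3))
})

test_that("arrested dynamics anticorrelate cycle ratio with CTL count across images", {
  truth <- corr_truth()
  cs <- generate_cryosections(truth, dispersion = 0.05, seed = 21)
  tr <- cs[cs$condition == "treated" & cs$g1_count > 0, ]
  out <- correlate_ctl_ratio(tr$ctl_count, tr$sgm_count / tr$g1_count)
  expect_lt(out$r, 0)
  expect_lt(out$conf_int[2], 0)
})

test_that("expression noise reproduces the housekeeping mean-sd relation", {
  truth <- tame_truth()
  # more sampling days -> more replicates per probe for the regression
  d <- study_design(expression_days = seq(1, 14, 0.5))
  ex <- generate_expression(truth, d, seed = 5, scale_sd = 0, bio_sd = 0)
  pt <- ex$probe_table
  hk <- pt$type == "housekeeping"
  m <- rowMeans(ex$intensities[hk, ])
  s <- apply(ex$intensities[hk, ], 1, sd)
  co <- coef(lm(s ~ m))
  expect_lt(abs(co[[1]] - 0.054), 0.05)
  expect_lt(abs(co[[2]] - 0.29), 0.08)

  expect_error(
    generate_expression(truth, probe_table = data.frame(
      probe_id = "x", gene = "Mystery", type = "signal", base_mean = NA)),
    "unmapped probe")
})

test_that("microarray preprocessing filters flagged probes and is scale invariant", {
  x <- matrix(c(1, 2, 3, 4, 5,
                2, 4, 6, 8, 10,
                1, 2, 3, 4, 5), 5, 3,
              dimnames = list(paste0("p", 1:5), c("s1", "s2", "s3")))
  flags <- matrix(1L, 5, 3, dimnames = dimnames(x))
  flags[4, ] <- 0L      # dark in all samples: dropped
  flags[5, ] <- 0L
  flags[1, 1] <- 0L     # dark in one sample only: retained
  out <- preprocess_microarray(list(intensities = x, flags = flags))
  expect_identical(rownames(out$intensities), c("p1", "p2", "p3"))

  # doubling one sample pre-normalization changes nothing
  x2 <- x; x2[, 2] <- x2[, 2] * 2
  out2 <- preprocess_microarray(list(intensities = x2, flags = flags))
  expect_equal(out$intensities, out2$intensities, tolerance = 1e-12)

  expect_error(preprocess_microarray(
    list(intensities = matrix(0, 2, 1), flags = matrix(1, 2, 1))),
    "all-zero")
})

test_that("full dataset bundle: determinism, observable coverage, exclusions", {
  truth <- tame_truth()
  ds <- generate_full_dataset(truth, seed = 3)
  ds2 <- generate_full_dataset(truth, seed = 3)
  expect_identical(ds$observations, ds2$observations)
  expect_identical(ds$volumes, ds2$volumes)

  obs <- as.data.frame(ds$observations)
  expect_setequal(unique(obs$observable), observable_names())
  late <- obs$observable == "growth_rate" & obs$t1 >= 10
  expect_true(all(!obs$include[late]))
  expect_true(all(nzchar(obs$reason[late])))
  expect_true(all(obs$include[obs$observable != "growth_rate"]))
})

test_that("noiseless bundle summaries coincide with the exact model observables", {
  truth <- gentle_truth()
  d <- study_design(init_sd = 0)
  ds <- generate_full_dataset(truth, d, seed = 2, volume_sd = 0,
                              dispersion = 0, expression_noise = FALSE)
  exact <- as.data.frame(observe_model(truth, d))
  got <- as.data.frame(ds$observations)
  key <- function(x) paste(x$observable, x$day)
  m <- match(key(exact), key(got))
  expect_false(anyNA(m))
  expect_equal(got$mean[m], exact$mean, tolerance = 1e-6)
})

test_that("expression table export round-trips probes, samples and flags", {
  ex <- generate_expression(tame_truth(), seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_expression_table(ex, f)
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(ex$intensities))
  expect_equal(back$t_d1, unname(ex$intensities[, "t_d1"]), tolerance = 1e-6)
  expect_equal(back$t_d1_gIsWellAboveBG, unname(ex$flags[, "t_d1"]))
  unlink(f)
})
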