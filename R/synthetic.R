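#' Study design for the synthetic data generator
#'
#' Encodes the structure of the adoptive-transfer study the generator
#' emulates: two untreated experiments of 5 mice with volume measurements
#' up to day 7; three treated experiments (5, 5 and 2 mice), the small one
#' followed to day 14; cryosection imaging on days 1, 3, 5, 7, 10, 14; one
#' pooled expression sample per timepoint and condition on days 1, 3, 5, 7.
#' CTL transfer is day 0.
#'
#' @param ... named overrides of any design field.
#' @return a \code{study_design} list.
#' @export
study_design <- function(...) {
  design <- list(
    untreated_experiments = c(5, 5),
    treated_experiments = c(5, 5, 2),
    untreated_days = c(-1, 1, 3, 5, 7),
    treated_days = list(c(-1, 1, 3, 5, 7), c(-1, 1, 3, 5, 7),
                        c(-1, 1, 3, 5, 7, 10, 14)),
    imaging_days = c(1, 3, 5, 7, 10, 14),
    images_per_day = 5,
    expression_days = c(1, 3, 5, 7),
    pool_range = c(3, 4),
    V0 = 100,              # treated tumor volume at transfer (mm^3)
    init_sd = 0.15,        # mouse-level lognormal initial-volume factor
    count_scale = 30,      # nuclei counted per mm^3-equivalent per section
    # untreated expression baselines (normalized units) per gene
    baselines = c(Ifng = 0.05, Pdcd1 = 0.10, Cd274 = 0.20, Lag3 = 0.10,
                  Havcr2 = 0.10, Cd8a = 0.10, Stat1 = 0.50, Socs1 = 0.20),
    cd8a_scale = 0.01,     # expression units per intratumoral CTL
    stat1_scale = 1, socs1_scale = 0.5,  # IFNG-pathway tracker scales
    # summary-level noise floors (measurement uncertainty scales)
    ctl_sd0 = 0.5, ctl_cv = 0.1, ratio_sd = 0.15, growth_sd = 0.1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(design))
  if (length(bad)) stop("unknown design field(s): ", paste(bad, collapse = ", "))
  design[names(over)] <- over
  structure(design, class = "study_design")
}

# simulate the treated / untreated cohort trajectory for a design
cohort_trajectory <- function(truth, design, condition, times) {
  p <- truth
  if (condition == "untreated") p["s0"] <- 0
  simulate_cohort(p, design$V0, times, t_on = 0)
}

#' Generate per-mouse tumor volume series
#'
#' Simulates the cohort trajectory (treated: full model with CTL transfer
#' at day 0; untreated: no CTL influx, hence basal exponential growth) and
#' overlays a mouse-level lognormal initial-volume factor plus independent
#' lognormal measurement noise per observation.  \code{noise_sd = 0}
#' together with \code{init_sd = 0} in the design yields noiseless,
#' exactly model-valued volumes.
#'
#' @param truth a \code{\link{ctl_params}} truth set.
#' @param design a \code{\link{study_design}}.
#' @param noise_sd lognormal measurement noise sd.
#' @param seed integer seed.
#' @return data.frame(mouse_id, cohort, experiment, day, volume_mm3).
#' @export
generate_volumes <- function(truth, design = study_design(),
                             noise_sd = 0.2, seed = 1) {
  set.seed(seed)
  out <- list()
  mk <- function(cohort, experiment, mouse, days, traj) {
    V <- traj$V[match(days, traj$time)]
    f_init <- exp(stats::rnorm(1, 0, design$init_sd))
    eps <- exp(stats::rnorm(length(days), 0, noise_sd))
    data.frame(mouse_id = sprintf("%s_e%d_m%d", substr(cohort, 1, 1),
                                  experiment, mouse),
               cohort = cohort, experiment = experiment, day = days,
               volume_mm3 = V * f_init * eps)
  }
  un_days <- design$untreated_days
  tr_all_days <- sort(unique(unlist(design$treated_days)))
  traj_u <- cohort_trajectory(truth, design, "untreated", un_days)
  traj_t <- cohort_trajectory(truth, design, "treated", tr_all_days)
  for (e in seq_along(design$untreated_experiments))
    for (m in seq_len(design$untreated_experiments[e]))
      out[[length(out) + 1]] <- mk("untreated", e, m, un_days, traj_u)
  for (e in seq_along(design$treated_experiments))
    for (m in seq_len(design$treated_experiments[e]))
      out[[length(out) + 1]] <- mk("treated", e, m,
                                   design$treated_days[[e]], traj_t)
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Generate per-cryosection nuclei and CTL counts
#'
#' Per imaging day and image, draws G1 nuclei, S-G2-M nuclei and CTL
#' counts from negative-binomial sampling distributions whose means are
#' proportional to the model's G, S and E at that day (raw counts across
#' images are overdispersed relative to Poisson).  With
#' \code{dispersion = 0} the counts equal their means exactly
#' (deterministic, real-valued), which is the noiseless limit used for
#' pipeline round trips.
#'
#' @inheritParams generate_volumes
#' @param dispersion negative-binomial extra-dispersion (0 = deterministic).
#' @param conditions which cohorts to image.
#' @return data.frame(image_id, condition, day, ctl_count, g1_count,
#'   sgm_count).
#' @export
generate_cryosections <- function(truth, design = study_design(),
                                  dispersion = 0.15, seed = 1,
                                  conditions = c("treated", "untreated")) {
  set.seed(seed)
  draw <- function(mu, n) {
    if (dispersion <= 0) return(rep(mu, n))
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  }
  out <- list()
  for (cond in conditions) {
    traj <- cohort_trajectory(truth, design, cond, design$imaging_days)
    for (d in design$imaging_days) {
      i <- match(d, traj$time)
      n <- design$images_per_day
      out[[length(out) + 1]] <- data.frame(
        image_id = sprintf("%s_d%g_i%d", substr(cond, 1, 1), d, seq_len(n)),
        condition = cond, day = d,
        ctl_count = draw(traj$E[i], n),
        g1_count = draw(design$count_scale * traj$G[i], n),
        sgm_count = draw(design$count_scale * traj$S[i], n)
      )
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Default probe table for the expression generator
#'
#' Eight signal genes with three probes each (IFNG, the four checkpoints,
#' the CTL tracker Cd8a and the IFNG-pathway trackers Stat1/Socs1), forty
#' housekeeping probes with constant means spanning 0.5--10 normalized
#' units, and six dark probes that never rise above background.
#'
#' @return data.frame(probe_id, gene, type, base_mean).
#' @export
default_probe_table <- function() {
  genes <- c("Ifng", "Pdcd1", "Cd274", "Lag3", "Havcr2",
             "Cd8a", "Stat1", "Socs1")
  sig <- data.frame(
    probe_id = paste0(rep(genes, each = 3), "_p", 1:3),
    gene = rep(genes, each = 3), type = "signal", base_mean = NA_real_)
  hk <- data.frame(
    probe_id = sprintf("HK%02d", 1:40), gene = "housekeeping",
    type = "housekeeping",
    base_mean = exp(seq(log(0.5), log(10), length.out = 40)))
  dark <- data.frame(
    probe_id = sprintf("DARK%d", 1:6), gene = "background",
    type = "dark", base_mean = 0.01)
  rbind(sig, hk, dark)
}

# gene-level expression value implied by the model state at day t
gene_signal <- function(gene, traj, i, design) {
  V <- traj$V[i]
  base <- design$baselines[[gene]]
  base + switch(gene,
    Ifng = traj$I[i] / V,
    Pdcd1 = traj$P[i] / V,
    Cd274 = traj$PL[i] / V,
    Lag3 = traj$L[i] / V,
    Havcr2 = traj$H[i] / V,
    Cd8a = design$cd8a_scale * traj$E[i],
    Stat1 = design$stat1_scale * traj$I[i] / V,
    Socs1 = design$socs1_scale * traj$I[i] / V,
    stop("unmapped gene: ", gene))
}

#' Generate a probe-by-sample expression matrix with flags
#'
#' One pooled sample per expression day and condition.  Signal probes
#' track the model observables (intratumoral concentrations plus the
#' CTL-proportional Cd8a and IFNG-proportional Stat1/Socs1 trackers) on
#' top of configurable untreated baselines; pooling averages 3--4
#' simulated tumors with tumor-level lognormal variation.  Measurement
#' noise is Gaussian with the housekeeping mean-sd relation
#' \code{sd = 0.054 + 0.29 mean}.  Raw intensities are drawn
#' pre-normalization (per-sample scale factors); dark probes carry
#' all-zero above-background flags.
#'
#' @inheritParams generate_volumes
#' @param probe_table see \code{\link{default_probe_table}}.
#' @param noise logical; FALSE yields deterministic, unscaled values.
#' @param bio_sd tumor-level lognormal sd entering the pool.
#' @param scale_sd per-sample lognormal scale-factor sd (pre-normalization).
#' @param flag_dropout probability that a non-dark probe's flag is zero in
#'   any one sample (exercises the all-samples filter rule).
#' @return list(intensities, flags, samples, probe_table).
#' @export
generate_expression <- function(truth, design = study_design(),
                                probe_table = default_probe_table(),
                                seed = 1, noise = TRUE, bio_sd = 0.1,
                                scale_sd = 0.1, flag_dropout = 0.03) {
  set.seed(seed)
  known <- c("Ifng", "Pdcd1", "Cd274", "Lag3", "Havcr2", "Cd8a", "Stat1",
             "Socs1", "housekeeping", "background")
  bad <- setdiff(unique(probe_table$gene), known)
  if (length(bad)) stop("unmapped probe gene(s): ", paste(bad, collapse = ", "))

  samples <- expand.grid(condition = c("treated", "untreated"),
                         day = design$expression_days,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_d%g", substr(samples$condition, 1, 1),
                               samples$day)

  trajs <- list(treated = cohort_trajectory(truth, design, "treated",
                                            design$expression_days),
                untreated = cohort_trajectory(truth, design, "untreated",
                                              design$expression_days))
  np <- nrow(probe_table)
  ns <- nrow(samples)
  intensities <- matrix(NA_real_, np, ns,
                        dimnames = list(probe_table$probe_id,
                                        samples$sample_id))
  flags <- matrix(1L, np, ns, dimnames = dimnames(intensities))

  for (j in seq_len(ns)) {
    traj <- trajs[[samples$condition[j]]]
    i <- match(samples$day[j], traj$time)
    n_pool <- if (noise) sample(design$pool_range[1]:design$pool_range[2], 1)
              else design$pool_range[1]
    for (k in seq_len(np)) {
      type <- probe_table$type[k]
      mu <- if (type == "signal") {
        g <- gene_signal(probe_table$gene[k], traj, i, design)
        if (samples$condition[j] == "untreated")
          g <- design$baselines[[probe_table$gene[k]]]
        g
      } else probe_table$base_mean[k]
      if (noise && type != "dark") {
        pooled <- mean(mu * exp(stats::rnorm(n_pool, 0, bio_sd)))
        val <- pooled + stats::rnorm(1, 0, checkpoint_sd(pooled))
      } else val <- mu
      intensities[k, j] <- max(val, 1e-6)
    }
    flags[probe_table$type == "dark", j] <- 0L
    if (noise && flag_dropout > 0) {
      nd <- which(probe_table$type != "dark")
      drop <- nd[stats::runif(length(nd)) < flag_dropout]
      flags[drop, j] <- 0L
    }
  }
  if (noise && scale_sd > 0) {
    sf <- exp(stats::rnorm(ns, 0, scale_sd))
    intensities <- sweep(intensities, 2, sf, "*")
  }
  list(intensities = intensities, flags = flags, samples = samples,
       probe_table = probe_table)
}

#' Filter and percentile-normalize an expression matrix
#'
#' Discards probes whose above-background flag is zero in every sample
#' (probes flagged zero in only some samples are retained), then scales
#' each sample so its 75th percentile equals a common target, by default
#' the across-sample median of 75th percentiles.  The median target makes
#' the output robust to (and, for a minority of rescaled samples, exactly
#' invariant to) per-sample scale factors.
#'
#' @param expr list with \code{intensities} (non-negative matrix) and
#'   \code{flags} (same shape), as from \code{\link{generate_expression}}.
#' @param target normalization target for the 75th percentile; default the
#'   median of the per-sample 75th percentiles.
#' @return the list with filtered, normalized \code{intensities} (and
#'   filtered \code{flags}, \code{probe_table} if present).
#' @export
preprocess_microarray <- function(expr, target = NULL) {
  x <- expr$intensities
  flags <- expr$flags
  if (any(x < 0)) stop("negative intensities")
  if (any(colSums(x) == 0)) stop("sample with all-zero intensities")
  keep <- rowSums(flags != 0) > 0
  x <- x[keep, , drop = FALSE]
  q <- apply(x, 2, stats::quantile, probs = 0.75, names = FALSE)
  if (any(q <= 0)) stop("sample with non-positive 75th percentile")
  if (is.null(target)) target <- stats::median(q)
  x <- sweep(x, 2, target / q, "*")
  out <- expr
  out$intensities <- x
  out$flags <- flags[keep, , drop = FALSE]
  if (!is.null(out$probe_table))
    out$probe_table <- out$probe_table[keep, , drop = FALSE]
  out
}

# gene-level summary of a normalized expression object: mean over probes
summarize_expression <- function(expr) {
  pt <- expr$probe_table
  sig <- pt$type == "signal"
  genes <- unique(pt$gene[sig])
  val <- t(vapply(genes, function(g) {
    colMeans(expr$intensities[pt$gene == g & sig, , drop = FALSE])
  }, numeric(ncol(expr$intensities))))
  rownames(val) <- genes
  list(values = val, samples = expr$samples)
}

# expression-derived observation rows: treated values, untreated-baseline
# corrected, with the housekeeping mean-sd relation for uncertainties
expression_observations <- function(expr_summary) {
  gene_obs <- c(Ifng = "ifng", Pdcd1 = "pdcd1", Cd274 = "cd274",
                Lag3 = "lag3", Havcr2 = "havcr2")
  s <- expr_summary$samples
  v <- expr_summary$values
  rows <- list()
  for (g in intersect(names(gene_obs), rownames(v))) {
    base <- mean(v[g, s$condition == "untreated"])
    tr <- which(s$condition == "treated")
    m <- v[g, tr] - base
    rows[[g]] <- data.frame(
      observable = gene_obs[[g]], day = s$day[tr],
      mean = unname(m), sd = checkpoint_sd(pmax(unname(m), 0)),
      n = 1L, condition = "treated", include = TRUE, reason = "")
  }
  do.call(rbind, rows)
}

#' Exact (noise-free) observation set implied by a truth parameter set
#'
#' Maps the simulated treated-cohort trajectory directly onto the eight
#' fitted observables at the design's measurement days, with the
#' generator's summary-level uncertainty scales as standard deviations
#' (expression observables use the housekeeping mean-sd relation).
#' Growth-rate intervals within days 10--14 are pre-flagged as excluded.
#'
#' @inheritParams generate_volumes
#' @return an \code{\link{observation_set}}.
#' @export
observe_model <- function(truth, design = study_design()) {
  days_all <- sort(unique(unlist(design$treated_days)))
  times <- sort(unique(c(-1, 0, days_all, design$imaging_days,
                         design$expression_days)))
  traj <- cohort_trajectory(truth, design, "treated", times)
  at <- function(d, col) traj[[col]][match(d, traj$time)]

  i <- seq_len(length(days_all) - 1)
  t1 <- days_all[i]; t2 <- days_all[i + 1]
  growth <- data.frame(
    observable = "growth_rate", day = (t1 + t2) / 2, t1 = t1, t2 = t2,
    mean = log(at(t2, "V") / at(t1, "V")) / (t2 - t1),
    sd = design$growth_sd, n = NA_integer_, condition = "treated",
    include = !(t1 >= 10), reason = ifelse(t1 >= 10, "days_10_14_two_mice", ""))

  inst <- function(obs, days, mean, sd) {
    data.frame(observable = obs, day = days, t1 = days, t2 = days,
               mean = mean, sd = sd, n = NA_integer_,
               condition = "treated", include = TRUE, reason = "")
  }
  im <- design$imaging_days
  ex <- design$expression_days
  conc <- function(col) at(ex, col) / at(ex, "V")
  df <- rbind(
    growth,
    inst("ctl_density", im, at(im, "E"),
         design$ctl_sd0 + design$ctl_cv * at(im, "E")),
    inst("ratio_sgm_g1", im, at(im, "S") / at(im, "G"), design$ratio_sd),
    inst("ifng", ex, conc("I"), checkpoint_sd(conc("I"))),
    inst("pdcd1", ex, conc("P"), checkpoint_sd(conc("P"))),
    inst("cd274", ex, conc("PL"), checkpoint_sd(conc("PL"))),
    inst("lag3", ex, conc("L"), checkpoint_sd(conc("L"))),
    inst("havcr2", ex, conc("H"), checkpoint_sd(conc("H")))
  )
  observation_set(df)
}

#' Generate a full synthetic dataset bundle
#'
#' Produces the raw tables (per-mouse volumes, per-image counts,
#' probe-by-sample expression with flags) plus the summarized observation
#' set with the days-10--14 growth-rate exclusion pre-applied.  A single
#' seed determines everything.  With all noise switched off the summary
#' means coincide with \code{\link{observe_model}}.
#'
#' @inheritParams generate_volumes
#' @param volume_sd lognormal volume measurement noise.
#' @param dispersion cryosection count overdispersion.
#' @param expression_noise logical.
#' @return a \code{ctl_dataset} list: volumes, cryosections, expression,
#'   observations, design, truth, seed.
#' @export
generate_full_dataset <- function(truth, design = study_design(), seed = 1,
                                  volume_sd = 0.2, dispersion = 0.15,
                                  expression_noise = TRUE) {
  volumes <- generate_volumes(truth, design, noise_sd = volume_sd,
                              seed = seed)
  sections <- generate_cryosections(truth, design, dispersion = dispersion,
                                    seed = seed + 1)
  expr <- generate_expression(truth, design, seed = seed + 2,
                              noise = expression_noise)
  norm <- preprocess_microarray(expr)
  expr_rows <- expression_observations(summarize_expression(norm))

  # treated growth-rate summaries across mice, with the exclusion rule
  rates <- interval_growth_rates(volumes[volumes$cohort == "treated", ])
  key <- paste(rates$t1, rates$t2)
  growth <- do.call(rbind, lapply(split(rates, key), function(d) {
    data.frame(observable = "growth_rate", day = d$day[1],
               t1 = d$t1[1], t2 = d$t2[1], mean = mean(d$rate),
               sd = max(stats::sd(d$rate), design$growth_sd, na.rm = TRUE),
               n = nrow(d), condition = "treated",
               include = !(d$t1[1] >= 10),
               reason = if (d$t1[1] >= 10) "days_10_14_two_mice" else "")
  }))

  tr_sec <- sections[sections$condition == "treated", ]
  by_day <- split(tr_sec, tr_sec$day)
  ctl <- do.call(rbind, lapply(by_day, function(d) {
    data.frame(observable = "ctl_density", day = d$day[1],
               mean = mean(d$ctl_count),
               sd = max(stats::sd(d$ctl_count),
                        design$ctl_sd0 + design$ctl_cv * mean(d$ctl_count),
                        na.rm = TRUE),
               n = nrow(d), condition = "treated", include = TRUE,
               reason = "")
  }))
  ratio <- do.call(rbind, lapply(by_day, function(d) {
    r <- d$sgm_count / d$g1_count
    data.frame(observable = "ratio_sgm_g1", day = d$day[1], mean = mean(r),
               sd = max(stats::sd(r), design$ratio_sd, na.rm = TRUE),
               n = nrow(d), condition = "treated", include = TRUE,
               reason = "")
  }))

  obs <- observation_set(rbind(
    growth,
    merge_defaults(ctl), merge_defaults(ratio), merge_defaults(expr_rows)))

  structure(list(volumes = volumes, cryosections = sections,
                 expression = expr, observations = obs,
                 design = design, truth = truth, seed = seed),
            class = "ctl_dataset")
}

merge_defaults <- function(df) {
  if (!"t1" %in% names(df)) df$t1 <- df$day
  if (!"t2" %in% names(df)) df$t2 <- df$day
  df[, c("observable", "day", "t1", "t2", "mean", "sd", "n", "condition",
         "include", "reason")]
}

#' Write the expression object as a tab-delimited feature-extraction table
#'
#' Probe-by-sample intensities with a per-sample above-background flag
#' column next to each intensity column.
#'
#' @param expr as from \code{\link{generate_expression}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  df <- data.frame(probe_id = rownames(expr$intensities))
  for (j in seq_len(ncol(expr$intensities))) {
    sid <- colnames(expr$intensities)[j]
    df[[sid]] <- expr$intensities[, j]
    df[[paste0(sid, "_gIsWellAboveBG")]] <- expr$flags[, j]
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
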