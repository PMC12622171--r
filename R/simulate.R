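#' Simulation configuration for two-group urine metabolomics cohorts
#'
#' The generator draws, per metabolite, a shared log-normal baseline on the
#' creatinine-normalized scale. A subset of ASD participants additionally
#' carries an extreme multiplicative elevation: the elevation event for
#' metabolite `m` in participant `i` fires with marginal probability
#' `elevation_prob[m]`, and events within a biochemical family are coupled
#' through a per-participant latent "family dysbiosis" indicator with mixture
#' weight `family_coupling` (0 = independent events, 1 = all-or-none per
#' family). Fired events multiply the baseline by a log-uniform fold from
#' `fold_range` (divide, for low-direction markers). Creatinine is log-normal
#' per participant; raw concentrations are baseline x creatinine, so
#' creatinine normalization recovers the baseline exactly. Per-metabolite
#' LODs are placed at `lod_quantile[m]` of the pooled raw marginal and cells
#' below them are censored and flagged.
#'
#' @param n_asd,n_td Group sizes.
#' @param panel An `mdm_panel`.
#' @param log_mean Named numeric, per-metabolite baseline log-mean
#'   (normalized scale).
#' @param log_sd Per-metabolite baseline log-sd; scalar recycled.
#' @param elevation_prob Named numeric in `[0, 1]`, per-metabolite marginal
#'   probability of an extreme elevation in an ASD participant.
#' @param fold_range Length-2 positive numeric `(low, high)`, `low > 1`;
#'   elevation multipliers are log-uniform on this interval.
#' @param family_coupling Mixture weight in `[0, 1]` for the per-family
#'   latent indicator.
#' @param creatinine_log_mean,creatinine_log_sd Log-normal creatinine
#'   parameters (mmol/L).
#' @param lod_quantile Named numeric in `[0, 1)`, per-metabolite censoring
#'   quantile; scalar recycled; 0 disables censoring.
#' @param age_range Ages are drawn uniformly on this interval (years).
#' @param seed Integer master seed; every draw derives from it through named
#'   substreams, so adding a metabolite does not reshuffle the draws of the
#'   others.
#' @return A validated list of class `mdm_sim_config`.
#' @export
sim_config <- function(n_asd, n_td, panel,
                       log_mean, log_sd = 1,
                       elevation_prob,
                       fold_range = c(10, 1000),
                       family_coupling = 0.5,
                       creatinine_log_mean = log(8), creatinine_log_sd = 0.5,
                       lod_quantile = 0,
                       age_range = c(2, 11),
                       seed = 1L) {
  stopifnot(inherits(panel, "mdm_panel"))
  ids <- panel$metabolite_id
  expand <- function(x, what) {
    if (length(x) == 1 && is.null(names(x))) x <- stats::setNames(rep(x, length(ids)), ids)
    if (is.null(names(x)) && length(x) == length(ids)) names(x) <- ids
    missing <- setdiff(ids, names(x))
    if (length(missing) > 0) {
      stop(what, " missing for metabolite(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    x[ids]
  }
  log_mean <- expand(log_mean, "log_mean")
  log_sd <- expand(log_sd, "log_sd")
  elevation_prob <- expand(elevation_prob, "elevation_prob")
  lod_quantile <- expand(lod_quantile, "lod_quantile")

  if (n_asd < 1 || n_td < 2) stop("need n_asd >= 1 and n_td >= 2", call. = FALSE)
  if (any(elevation_prob < 0 | elevation_prob > 1)) {
    stop("elevation_prob must lie in [0, 1]", call. = FALSE)
  }
  if (length(fold_range) != 2 || fold_range[1] <= 1 ||
      fold_range[2] < fold_range[1]) {
    stop("fold_range must be (low, high) with 1 < low <= high", call. = FALSE)
  }
  if (family_coupling < 0 || family_coupling > 1) {
    stop("family_coupling must lie in [0, 1]", call. = FALSE)
  }
  if (any(lod_quantile < 0 | lod_quantile >= 1)) {
    stop("lod_quantile must lie in [0, 1)", call. = FALSE)
  }
  if (any(log_sd <= 0)) stop("log_sd must be positive", call. = FALSE)

  structure(
    list(n_asd = as.integer(n_asd), n_td = as.integer(n_td), panel = panel,
         log_mean = log_mean, log_sd = log_sd,
         elevation_prob = elevation_prob, fold_range = fold_range,
         family_coupling = family_coupling,
         creatinine_log_mean = creatinine_log_mean,
         creatinine_log_sd = creatinine_log_sd,
         lod_quantile = lod_quantile, age_range = age_range,
         seed = as.integer(seed)),
    class = "mdm_sim_config"
  )
}

# Deterministic integer substream seed from (master seed, stream name).
# Simple polynomial string hash mod a Mersenne prime; keeps all derived
# seeds below 2^31 so set.seed() accepts them on every platform.
substream_seed <- function(seed, key) {
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

with_substream <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, key))
  force(expr)
}

#' Generate a synthetic two-group cohort with ground truth
#'
#' @param config An `mdm_sim_config`.
#' @return A list of class `mdm_synthetic_cohort`:
#' \describe{
#'   \item{`cohort`}{an `mdm_cohort` whose panel carries the realized LODs;}
#'   \item{`truth`}{named list, per ASD participant, of the metabolite ids
#'     whose elevation event actually fired;}
#'   \item{`multipliers`}{ASD x metabolites matrix of applied folds (1 where
#'     no event fired);}
#'   \item{`latent_factors`}{ASD x families logical matrix of the family
#'     dysbiosis indicators.}
#' }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "mdm_sim_config"))
  panel <- config$panel
  ids <- panel$metabolite_id
  n_asd <- config$n_asd; n_td <- config$n_td; n <- n_asd + n_td
  seed <- config$seed

  pid <- c(sprintf("ASD%03d", seq_len(n_asd)), sprintf("TD%03d", seq_len(n_td)))
  group <- rep(c("ASD", "TD"), c(n_asd, n_td))

  creatinine <- with_substream(seed, "creatinine",
    stats::rlnorm(n, config$creatinine_log_mean, config$creatinine_log_sd))
  age <- with_substream(seed, "age",
    stats::runif(n, config$age_range[1], config$age_range[2]))
  sex <- with_substream(seed, "sex",
    ifelse(stats::runif(n) < ifelse(group == "ASD", 0.79, 0.43), "M", "F"))

  # family latent dysbiosis indicators: fire with probability equal to the
  # largest marginal elevation probability in the family, so that gated
  # per-metabolite draws can preserve every marginal exactly
  fams <- mdm_families()
  fam_of <- stats::setNames(panel$family, ids)
  pi_f <- vapply(fams, function(f) {
    p <- config$elevation_prob[ids[fam_of == f]]
    if (length(p) == 0) 0 else max(p)
  }, numeric(1))
  latent <- sapply(fams, function(f) {
    with_substream(seed, paste0("family:", f), stats::runif(n_asd)) < pi_f[[f]]
  })
  latent <- matrix(latent, nrow = n_asd, dimnames = list(pid[seq_len(n_asd)], fams))

  ratio <- is_ratio_metabolite(panel)
  norm_vals <- matrix(NA_real_, n, length(ids), dimnames = list(pid, ids))
  mult <- matrix(1, n_asd, length(ids),
                 dimnames = list(pid[seq_len(n_asd)], ids))
  lfr <- log(config$fold_range)

  for (j in seq_along(ids)) {
    m <- ids[j]
    draws <- with_substream(seed, paste0("met:", m), {
      list(base = stats::rlnorm(n, config$log_mean[[m]], config$log_sd[[m]]),
           u_gate = stats::runif(n_asd),
           u_fire_gated = stats::runif(n_asd),
           u_fire_indep = stats::runif(n_asd),
           u_fold = stats::runif(n_asd))
    })
    p_m <- config$elevation_prob[[m]]
    f <- fam_of[[m]]
    gated <- draws$u_gate < config$family_coupling
    fire_gated <- latent[, f] & (draws$u_fire_gated < p_m / max(pi_f[[f]], p_m, 1e-300))
    fire_indep <- draws$u_fire_indep < p_m
    fired <- ifelse(gated, fire_gated, fire_indep)
    fold <- exp(lfr[1] + draws$u_fold * (lfr[2] - lfr[1]))
    if (panel$direction[j] == "low") fold <- 1 / fold
    mult[fired, j] <- fold[fired]
    vals <- draws$base
    vals[seq_len(n_asd)] <- vals[seq_len(n_asd)] * mult[, j]
    norm_vals[, j] <- vals
  }

  # raw concentrations: baseline tracks hydration through creatinine, so
  # raw = normalized x creatinine (ratios are already dimensionless)
  raw <- norm_vals * ifelse(matrix(ratio, n, length(ids), byrow = TRUE),
                            1, creatinine)

  # censoring: LOD at the requested quantile of the pooled raw marginal
  flags <- matrix(FALSE, n, length(ids), dimnames = list(pid, ids))
  lods <- rep(NA_real_, length(ids))
  for (j in seq_along(ids)) {
    q <- config$lod_quantile[[ids[j]]]
    if (q > 0) {
      lods[j] <- as.numeric(stats::quantile(raw[, j], q, names = FALSE))
      flags[, j] <- raw[, j] < lods[j]
    }
  }
  panel$lod <- lods
  raw[flags] <- NA_real_

  participants <- data.frame(
    participant_id = pid, group = group, age_years = age, sex = sex,
    creatinine = creatinine, stringsAsFactors = FALSE)
  cohort <- mdm_cohort(participants, raw, flags, panel)

  truth <- lapply(seq_len(n_asd), function(i) ids[mult[i, ] != 1])
  names(truth) <- pid[seq_len(n_asd)]

  structure(
    list(cohort = cohort, truth = truth, multipliers = mult,
         latent_factors = latent, config = config),
    class = "mdm_synthetic_cohort"
  )
}

#' @export
print.mdm_synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<mdm_synthetic_cohort> seed %d; %d/%d ASD participants carry >=1 true elevation\n",
    x$config$seed, sum(lengths(x$truth) > 0), x$config$n_asd))
  print(x$cohort)
  invisible(x)
}

#' Write a synthetic cohort (cohort CSV + truth sidecar JSON)
#' @param sim An `mdm_synthetic_cohort`.
#' @param cohort_path CSV output path; truth goes to `<cohort_path>.truth.json`.
#' @return `cohort_path`, invisibly.
#' @export
write_synthetic_cohort <- function(sim, cohort_path) {
  write_cohort(sim$cohort, cohort_path)
  jsonlite::write_json(
    list(seed = sim$config$seed, truth = sim$truth),
    paste0(cohort_path, ".truth.json"), auto_unbox = TRUE)
  invisible(cohort_path)
}

#' Probability model of strict exceedance over a finite TD reference maximum
#'
#' For a metabolite with baseline log-sd `s` and elevation folds log-uniform
#' on `fold_range`, estimates by Monte Carlo the probability `h` that an
#' elevated draw exceeds the maximum of `n_td` reference draws. The
#' companion quantity, the probability that a *non*-elevated fresh draw
#' exceeds that maximum, is the exact order-statistic leakage
#' `1 / (n_td + 1)` for continuous marginals.
#'
#' @param n_td Reference-group size.
#' @param log_sd Baseline log-sd (location cancels).
#' @param fold_range Elevation fold interval.
#' @param n_rep Monte Carlo replicates.
#' @param seed Seed for the estimate.
#' @return List with `h` (elevated-exceedance probability), `leakage`
#'   (`1/(n_td+1)`).
#' @export
exceedance_model <- function(n_td, log_sd = 1, fold_range = c(10, 1000),
                             n_rep = 4000, seed = 7L) {
  stopifnot(n_td >= 2)
  h <- with_substream(seed, sprintf("exceedance:%d:%g", n_td, log_sd), {
    ref_max <- matrix(stats::rlnorm(n_rep * n_td, 0, log_sd), n_rep)
    ref_max <- apply(ref_max, 1, max)
    fold <- exp(stats::runif(n_rep, log(fold_range[1]), log(fold_range[2])))
    mean(stats::rlnorm(n_rep, 0, log_sd) * fold > ref_max)
  })
  list(h = h, leakage = 1 / (n_td + 1))
}

#' Calibrate elevation probabilities to target exceedance fractions
#'
#' Inverts the exceedance model: the observed fraction of ASD participants
#' above a finite TD reference maximum mixes true elevations (rate `h` per
#' event) with order-statistic leakage `1/(n_td+1)` from non-elevated
#' values. Solving `target = p * h + (1 - p) * leakage` for each metabolite
#' gives the marginal elevation probability `p`; targets below the leakage
#' floor clamp to `p = 0` (their achieved exceedance is then the leakage
#' itself).
#'
#' @param targets Named numeric in `[0, 1]`: per-metabolite target fraction
#'   of ASD participants above the TD reference maximum.
#' @param n_asd,n_td Group sizes.
#' @param panel An `mdm_panel` covering `names(targets)`.
#' @param log_mean Baseline log-means (see [sim_config()]).
#' @param log_sd Baseline log-sd.
#' @param fold_range Elevation fold interval.
#' @param ... Further arguments passed to [sim_config()] (coupling,
#'   creatinine, LOD quantiles, seed).
#' @param n_rep Monte Carlo replicates for the exceedance model.
#' @return An `mdm_sim_config` whose `$calibration` element records the
#'   model (`h`, `leakage`) and the achieved expected exceedance per
#'   metabolite next to its target.
#' @export
calibrate_to_table <- function(targets, n_asd, n_td, panel, log_mean,
                               log_sd = 1, fold_range = c(10, 1000), ...,
                               n_rep = 4000) {
  if (any(targets < 0 | targets > 1)) {
    stop("targets must lie in [0, 1]", call. = FALSE)
  }
  model <- exceedance_model(n_td, log_sd = log_sd, fold_range = fold_range,
                            n_rep = n_rep)
  infeasible <- targets > model$h
  if (any(infeasible)) {
    stop("target exceedance infeasible under fold_range (max achievable ",
         sprintf("%.3f", model$h), ") for: ",
         paste(names(targets)[infeasible], collapse = ", "), call. = FALSE)
  }
  p <- pmax(0, (targets - model$leakage) / (model$h - model$leakage))
  config <- sim_config(n_asd = n_asd, n_td = n_td, panel = panel,
                       log_mean = log_mean, log_sd = log_sd,
                       elevation_prob = p, fold_range = fold_range, ...)
  config$calibration <- list(
    h = model$h, leakage = model$leakage,
    target = targets,
    achieved = p * model$h + (1 - p) * model$leakage)
  config
}

#' Default calibrated study configuration
#'
#' The configuration the package treats as its reference study conditions:
#' 52 ASD vs 47 TD participants aged 2 to 11, the 24-metabolite quantitative
#' panel, baseline levels anchored at typical TD creatinine-normalized
#' concentrations, per-metabolite exceedance targets and censoring
#' fractions from the targeted assay, elevations of 10-1000 fold, and
#' within-family coupling of the elevation events.
#'
#' @param seed Master seed.
#' @param family_coupling Mixture weight of the per-family latent indicator.
#' @return An `mdm_sim_config`.
#' @export
default_sim_config <- function(seed = 1L, family_coupling = 0.7) {
  anchors <- mdm_study_anchors()
  panel <- default_panel()
  log_sd <- 1
  calibrate_to_table(
    targets = stats::setNames(anchors$target_exceedance, anchors$metabolite_id),
    n_asd = 52, n_td = 47, panel = panel,
    log_mean = stats::setNames(log(anchors$td_level) - log_sd^2 / 2,
                               anchors$metabolite_id),
    log_sd = log_sd,
    fold_range = c(10, 1000),
    family_coupling = family_coupling,
    lod_quantile = stats::setNames(anchors$censor_frac, anchors$metabolite_id),
    seed = seed
  )
}
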