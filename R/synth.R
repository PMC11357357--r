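## Synthetic cohort generation with known ground truth.
##
## The generator emulates a four-cohort longitudinal mental-training design
## (two 9-month training cohorts, one single-module active-control cohort,
## one retest control cohort; timepoints T0..T3 three months apart) and
## plants user-configured effects: standardized module-specific shifts on
## subfield volume change, a latent-factor coupling between CA1-3 volume
## change and change in total diurnal cortisol output, a coupling with hair
## cortisol change, and per-subfield "true" connectivity networks mixed into
## the parcel time series.

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so simulation helpers do not
#' disturb an enclosing random sequence.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' Builds and validates the parameter set of the synthetic cohort generator.
#' Defaults reproduce the design of the emulated study: cohort sizes
#' TC1=80, TC2=81, TC3=81, RCC=90; age 40.7 +/- 9.2 years truncated to
#' 20-55; 59% women; a standardized `Affect`-module effect of d = 0.35 on
#' bilateral CA1-3 volume change; and a latent coupling of r = -0.23 between
#' CA1-3 volume change and change in measured total diurnal cortisol output
#' (AUCg), r = -0.37 with hair cortisol change.
#'
#' @param n_per_cohort named integer vector of cohort sizes.
#' @param age_mean,age_sd,age_range age distribution (years), truncated
#'   normal via resampling.
#' @param sex_ratio fraction of female participants.
#' @param volume_baseline_mean,volume_baseline_sd named vectors (per
#'   subfield: `SUB`, `CA13`, `CA4DG`) of baseline volume mean and
#'   between-subject SD in mm^3 (template space; both hemispheres share
#'   them).
#' @param volume_change_sd named vector: SD of the 3-month volume change in
#'   mm^3 per subfield. Standardized module effects are expressed on this
#'   scale.
#' @param subject_change_frac fraction of change variance attributable to a
#'   stable per-subject plasticity trait (induces within-subject correlation
#'   of change scores across intervals).
#' @param module_effects named numeric vector of standardized effects on
#'   volume change, names `"Module:Subfield"` with subfield one of
#'   `L_SUB`, ..., `R_CA4DG` (e.g. `c("Affect:L_CA13" = 0.35)`).
#' @param cortisol list of diurnal curve parameters on the natural-log
#'   nmol/l scale: `level` (awakening mean), `subject_sd` (stable
#'   between-subject level SD), `car_amp` (awakening-response amplitude at
#'   30 min), `car60_frac` (fraction of the amplitude remaining at 60 min),
#'   `decay_per_min` (linear log-scale diurnal decline per minute, i.e.
#'   exponential decay of raw concentration), `noise_sd` (per-sample
#'   measurement noise SD), `state_sd` (SD of the per-interval change in a
#'   subject's diurnal level, the quantity the brain coupling acts on).
#' @param coupling_r target Pearson correlation between subfield CA1-3
#'   volume change and *measured* AUCg change over the same interval. The
#'   generator compensates internally for attenuation by saliva measurement
#'   noise.
#' @param hair_coupling_r target correlation between CA1-3 volume change and
#'   hair log-cortisol change.
#' @param hair list: `level_log` mean log pg/mg, `subject_sd`, `change_sd`
#'   (log-scale SD of the per-interval change), `cortisone_ratio_log`,
#'   `cortisone_noise_sd`.
#' @param fmri list: `n_timepoints` frames per scan (after the dummy
#'   volumes an acquisition discards), `network_size` parcels per planted
#'   ipsilateral network, `seed_coupling` mixing weight of the latent seed
#'   signal into its network parcels, `seed_noise_sd`, `coupling_noise_sd`,
#'   `fd_mean`, `fd_sd` framewise-displacement distribution (mm),
#'   `spike_rate` probability of a motion spike per frame, `spike_size` mm,
#'   `high_motion_rate` fraction of scans drawn from a high-motion regime
#'   (`fd_mean_high`).
#' @param fmri_effects named numeric vector (names `"Module:Subfield"`):
#'   additive increments on the seed-network mixing weight per trained
#'   interval.
#' @param missing_rate fraction of subject-timepoint records deleted
#'   completely at random by [inject_missingness()] (applied by
#'   [run_pipeline()]; `simulate_cohort()` itself returns complete data).
#' @param seed integer root seed.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_per_cohort = c(TC1 = 80L, TC2 = 81L, TC3 = 81L,
                                        RCC = 90L),
                       age_mean = 40.7, age_sd = 9.2, age_range = c(20, 55),
                       sex_ratio = 197 / 332,
                       volume_baseline_mean = c(SUB = 1500, CA13 = 2200,
                                                CA4DG = 1100),
                       volume_baseline_sd = c(SUB = 180, CA13 = 250,
                                              CA4DG = 140),
                       volume_change_sd = c(SUB = 120, CA13 = 170,
                                            CA4DG = 90),
                       subject_change_frac = 0.2,
                       module_effects = c("Affect:L_CA13" = 0.35,
                                          "Affect:R_CA13" = 0.35),
                       cortisol = list(),
                       coupling_r = -0.23,
                       hair_coupling_r = -0.37,
                       hair = list(),
                       fmri = list(),
                       fmri_effects = c("Affect:R_CA13" = 0.05),
                       missing_rate = 0,
                       seed = 1L) {
  cort_def <- list(level = 2.7, subject_sd = 0.25, car_amp = 0.4,
                   car60_frac = 0.6, decay_per_min = 1 / 300,
                   noise_sd = 0.15, state_sd = 0.3)
  hair_def <- list(level_log = 1.6, subject_sd = 0.4, change_sd = 0.3,
                   cortisone_ratio_log = 0.7, cortisone_noise_sd = 0.2)
  fmri_def <- list(n_timepoints = 205L, network_size = 20L,
                   seed_coupling = 0.5, seed_noise_sd = 0.5,
                   coupling_noise_sd = 0.05, fd_mean = 0.15, fd_sd = 0.05,
                   spike_rate = 0.02, spike_size = 0.8,
                   high_motion_rate = 0.03, fd_mean_high = 0.45)
  cortisol <- utils::modifyList(cort_def, cortisol)
  hair     <- utils::modifyList(hair_def, hair)
  fmri     <- utils::modifyList(fmri_def, fmri)

  cfg <- list(n_per_cohort = n_per_cohort, age_mean = age_mean,
              age_sd = age_sd, age_range = age_range, sex_ratio = sex_ratio,
              volume_baseline_mean = volume_baseline_mean,
              volume_baseline_sd = volume_baseline_sd,
              volume_change_sd = volume_change_sd,
              subject_change_frac = subject_change_frac,
              module_effects = module_effects, cortisol = cortisol,
              coupling_r = coupling_r, hair_coupling_r = hair_coupling_r,
              hair = hair, fmri = fmri, fmri_effects = fmri_effects,
              missing_rate = missing_rate, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!all(COHORTS %in% names(cfg$n_per_cohort)))
    stop("n_per_cohort must name all of ", paste(COHORTS, collapse = ", "))
  if (any(cfg$n_per_cohort <= 0)) stop("all cohort counts must be > 0")
  if (cfg$age_sd <= 0) stop("age_sd must be > 0")
  if (cfg$sex_ratio < 0 || cfg$sex_ratio > 1) stop("sex_ratio must be in [0,1]")
  for (nm in c("volume_baseline_mean", "volume_baseline_sd",
               "volume_change_sd")) {
    v <- cfg[[nm]]
    if (!all(SUBFIELDS %in% names(v)))
      stop(nm, " must name all of ", paste(SUBFIELDS, collapse = ", "))
    if (any(v <= 0)) stop(nm, " entries must be > 0")
  }
  if (cfg$subject_change_frac < 0 || cfg$subject_change_frac >= 1)
    stop("subject_change_frac must be in [0,1)")
  if (abs(cfg$coupling_r) >= 1 || abs(cfg$hair_coupling_r) >= 1)
    stop("coupling correlations must satisfy |r| < 1")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0,1)")
  bad <- setdiff(sub(":.*", "", names(cfg$module_effects)), MODULES)
  if (length(bad)) stop("unknown module in module_effects: ", bad[1])
  bad <- setdiff(sub(".*:", "", names(cfg$module_effects)), SUBFIELD_LABELS)
  if (length(bad)) stop("unknown subfield in module_effects: ", bad[1])
  with(cfg$cortisol, stopifnot(noise_sd > 0, state_sd > 0, subject_sd >= 0))
  mix <- coupling_mixers(cfg)  # errors if infeasible
  stopifnot(is.finite(mix$lambda_vol))
  cfg
}

## Latent-factor mixing weights realizing the configured couplings.
##
## Volume change over an interval is built as
##   dV = sd * (d + a*G + l_v*L + c*Z),  a^2 + l_v^2 + c^2 = 1,
## with G a stable subject plasticity trait and L the interval-specific
## latent shared with cortisol. The diurnal level change is
##   dc = state_sd * (l_c*L + sqrt(1-l_c^2)*W),
## and measured AUCg change equals 600*dc plus trapezoid-weighted sample
## noise, which attenuates the observable correlation by the factor alpha
## below. Choosing l_v = l_c = sqrt(|r|/alpha) makes the *measured*
## correlation equal r.
#' @keywords internal
coupling_mixers <- function(cfg) {
  w <- aucg_trapezoid_weights(AUCG_OFFSETS)
  noise_var <- sum(w^2) * cfg$cortisol$noise_sd^2 / 2  # two-day averaging
  denom <- 600 * cfg$cortisol$state_sd
  alpha <- denom / sqrt(denom^2 + noise_var)
  lam <- sqrt(abs(cfg$coupling_r) / alpha)
  a <- sqrt(cfg$subject_change_frac)
  if (lam^2 + a^2 >= 1)
    stop("infeasible coupling: |coupling_r|/attenuation + ",
         "subject_change_frac must be < 1", call. = FALSE)
  lam_hair <- if (lam > 0) abs(cfg$hair_coupling_r) / lam else 0
  if (lam_hair > 1)
    stop("infeasible hair coupling: |hair_coupling_r| must not exceed the ",
         "volume-side mixing weight ", signif(lam, 3), call. = FALSE)
  list(alpha = alpha, lambda_vol = lam,
       lambda_cort = sign(cfg$coupling_r) * lam,
       lambda_hair = sign(cfg$hair_coupling_r) * lam_hair,
       subject_frac = a)
}

## Trapezoid weights of the area-under-curve with respect to ground: the
## area is the weighted sum of the sampled values with these weights.
#' @keywords internal
aucg_trapezoid_weights <- function(offsets) {
  gaps <- diff(offsets)
  w <- numeric(length(offsets))
  w[1] <- gaps[1] / 2
  w[length(w)] <- gaps[length(gaps)] / 2
  if (length(offsets) > 2)
    w[2:(length(w) - 1)] <- (gaps[-length(gaps)] + gaps[-1]) / 2
  w
}

#' Simulate a synthetic longitudinal cohort
#'
#' Generates subjects, per-timepoint subfield volumes, two-day diurnal
#' saliva profiles, hair steroid segments and parcel-level functional scans
#' under the design and ground-truth effects in a [sim_config()]. Identical
#' seed and arguments yield an identical dataset.
#'
#' @param config a [sim_config()].
#' @param include character subset of
#'   `c("volumes", "saliva", "hair", "fmri")`; omit blocks you do not need
#'   (full-size functional scans are memory-heavy).
#' @return An object of class `cohort_dataset`: a list with elements
#'   `subjects`, `volumes`, `saliva`, `hair` (data.tables), `fmri` (named
#'   list of scans, each `list(parcel_ts, seed_ts, motion)`), and `truth`
#'   (generating parameters: config, latent interval factors, planted
#'   network membership, mixing weights).
#' @export
simulate_cohort <- function(config = sim_config(),
                            include = c("volumes", "saliva", "hair",
                                        "fmri")) {
  validate_sim_config(config)
  include <- match.arg(include, several.ok = TRUE)
  with_seed(config$seed, {
    block_seeds <- sample.int(.Machine$integer.max - 1L, 6L)

    subjects <- with_seed(block_seeds[1], gen_subjects(config))
    latents  <- with_seed(block_seeds[2], gen_latents(config, subjects))
    mix <- coupling_mixers(config)

    ds <- list(subjects = subjects)
    if ("volumes" %in% include)
      ds$volumes <- with_seed(block_seeds[3],
                              gen_volumes(config, subjects, latents, mix))
    if ("saliva" %in% include)
      ds$saliva <- with_seed(block_seeds[4],
                             gen_saliva(config, subjects, latents, mix))
    if ("hair" %in% include)
      ds$hair <- with_seed(block_seeds[5],
                           gen_hair(config, subjects, latents, mix))
    truth_networks <- planted_networks(config)
    if ("fmri" %in% include)
      ds$fmri <- with_seed(block_seeds[6],
                           gen_fmri(config, subjects, latents,
                                    truth_networks))
    ds$truth <- list(config = config, latents = latents, mixers = mix,
                     networks = truth_networks)
    class(ds) <- "cohort_dataset"
    ds
  })
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset>\n")
  cat("  subjects:", nrow(x$subjects), "in cohorts",
      paste(names(table(x$subjects$cohort)), table(x$subjects$cohort),
            sep = "=", collapse = ", "), "\n")
  for (blk in c("volumes", "saliva", "hair"))
    if (!is.null(x[[blk]]))
      cat(sprintf("  %-8s %d rows\n", paste0(blk, ":"), nrow(x[[blk]])))
  if (!is.null(x$fmri)) cat("  fmri:   ", length(x$fmri), "scans\n")
  invisible(x)
}

#' @keywords internal
gen_subjects <- function(cfg) {
  n <- sum(cfg$n_per_cohort[COHORTS])
  cohort <- rep(COHORTS, times = cfg$n_per_cohort[COHORTS])
  age <- stats::rnorm(n, cfg$age_mean, cfg$age_sd)
  for (i in which(age < cfg$age_range[1] | age > cfg$age_range[2])) {
    repeat {
      a <- stats::rnorm(1, cfg$age_mean, cfg$age_sd)
      if (a >= cfg$age_range[1] && a <= cfg$age_range[2]) break
    }
    age[i] <- a
  }
  data.table::data.table(
    subject_id = sprintf("S%04d", seq_len(n)),
    cohort = cohort,
    age = round(age, 1),
    sex = ifelse(stats::runif(n) < cfg$sex_ratio, "F", "M"))
}

## One row per subject x consecutive interval: the module trained, the
## shared latent factor L driving brain--cortisol coupling, and the stable
## subject plasticity trait G.
#' @keywords internal
gen_latents <- function(cfg, subjects) {
  G <- stats::rnorm(nrow(subjects))
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    iv <- cohort_intervals(subjects$cohort[i])
    data.table::data.table(
      subject_id = subjects$subject_id[i],
      t_a = vapply(iv, `[`, "", 1L), t_b = vapply(iv, `[`, "", 2L),
      module = vapply(iv, function(p)
        module_schedule(subjects$cohort[i], p), ""),
      G = G[i])
  })
  out <- data.table::rbindlist(rows)
  out[, L := stats::rnorm(.N)]
  out[]
}

#' @keywords internal
effect_lookup <- function(effects, module, subfield_label) {
  key <- paste0(module, ":", subfield_label)
  val <- effects[key]
  ifelse(is.na(val), 0, val)
}

#' @keywords internal
gen_volumes <- function(cfg, subjects, latents, mix) {
  sub_type <- sub(".*_", "", SUBFIELD_LABELS)  # SUB / CA13 / CA4DG
  base <- data.table::CJ(subject_id = subjects$subject_id,
                         subfield = SUBFIELD_LABELS, sorted = FALSE)
  typ <- sub(".*_", "", base$subfield)
  base[, baseline := cfg$volume_baseline_mean[typ] +
         stats::rnorm(.N, 0, cfg$volume_baseline_sd[typ])]

  inc <- latents[, data.table::CJ(subfield = SUBFIELD_LABELS,
                                  sorted = FALSE),
                 by = .(subject_id, t_a, t_b, module, G, L)]
  typ <- sub(".*_", "", inc$subfield)
  sd_chg <- cfg$volume_change_sd[typ]
  d <- effect_lookup(cfg$module_effects, inc$module, inc$subfield)
  d[inc$module == "retest"] <- 0
  lam <- ifelse(grepl("_CA13$", inc$subfield), mix$lambda_vol, 0)
  resid_sd <- sqrt(pmax(0, 1 - mix$subject_frac^2 - lam^2))
  inc[, delta := sd_chg * (d + mix$subject_frac * G + lam * L +
                             resid_sd * stats::rnorm(.N))]

  ## accumulate increments onto the baseline
  inc[, k := match(t_b, TIMEPOINTS)]
  data.table::setorder(inc, subject_id, subfield, k)
  inc[, cum := cumsum(delta), by = .(subject_id, subfield)]
  later <- inc[, .(subject_id, subfield, timepoint = t_b, cum)]
  first <- base[, .(subject_id, subfield, timepoint = TIMEPOINTS[1], cum = 0)]
  vol <- rbind(first, later)
  vol <- merge(vol, base, by = c("subject_id", "subfield"), sort = FALSE)
  vol[, volume_mm3 := baseline + cum]
  out <- vol[, .(subject_id, timepoint, subfield, volume_mm3)]
  data.table::setorder(out, subject_id, timepoint, subfield)
  out[]
}

## Diurnal curve on the log scale at a nominal offset (minutes after
## awakening): awakening level + awakening-response bump at 30/60 min +
## linear log-scale decline (exponential decay of raw concentration).
#' @keywords internal
diurnal_mean_log <- function(offset, cortisol) {
  bump <- numeric(length(offset))
  bump[offset == 30] <- cortisol$car_amp
  bump[offset == 60] <- cortisol$car_amp * cortisol$car60_frac
  cortisol$level + bump - cortisol$decay_per_min * offset
}

#' @keywords internal
gen_saliva <- function(cfg, subjects, latents, mix) {
  ct <- cfg$cortisol
  ## per-subject stable level and per-timepoint diurnal state offset
  u <- stats::rnorm(nrow(subjects), 0, ct$subject_sd)
  names(u) <- subjects$subject_id
  state <- data.table::data.table(
    subject_id = subjects$subject_id, timepoint = TIMEPOINTS[1],
    c_state = stats::rnorm(nrow(subjects), 0, ct$state_sd))
  inc <- latents[, .(subject_id, timepoint = t_b,
                     dc = ct$state_sd * (mix$lambda_cort * L +
                            sqrt(1 - mix$lambda_cort^2) * stats::rnorm(.N)))]
  inc[, k := match(timepoint, TIMEPOINTS)]
  data.table::setorder(inc, subject_id, k)
  inc[, c_state := cumsum(dc) , by = subject_id]
  inc <- merge(inc, state[, .(subject_id, c0 = c_state)], by = "subject_id")
  inc[, c_state := c_state + c0]
  state <- rbind(state, inc[, .(subject_id, timepoint, c_state)])

  tp_tab <- data.table::rbindlist(lapply(seq_len(nrow(subjects)), function(i)
    data.table::data.table(subject_id = subjects$subject_id[i],
                           timepoint = cohort_timepoints(subjects$cohort[i]))))
  grid <- tp_tab[, data.table::CJ(day = 1:2, offset_min = SALIVA_OFFSETS,
                                  sorted = FALSE),
                 by = .(subject_id, timepoint)]
  grid <- merge(grid, state, by = c("subject_id", "timepoint"), sort = FALSE)
  mu <- diurnal_mean_log(grid$offset_min, ct)
  logval <- mu + u[grid$subject_id] + grid$c_state +
    stats::rnorm(nrow(grid), 0, ct$noise_sd)
  grid[, nmol_l := exp(logval)]
  ## sampling-time jitter (+/- 15 min) on the non-morning occasions; the
  ## morning probes are taken at awakening-anchored times
  jit <- ifelse(grid$offset_min >= 240,
                round(stats::runif(nrow(grid), -15, 15)), 0)
  grid[, actual_min := offset_min + jit]
  out <- grid[, .(subject_id, timepoint, day, offset_min, nmol_l, actual_min)]
  data.table::setorder(out, subject_id, timepoint, day, offset_min)
  out[]
}

#' @keywords internal
gen_hair <- function(cfg, subjects, latents, mix) {
  hp <- cfg$hair
  u <- stats::rnorm(nrow(subjects), 0, hp$subject_sd)
  names(u) <- subjects$subject_id
  base <- data.table::data.table(
    subject_id = subjects$subject_id, timepoint = TIMEPOINTS[1],
    log_cort = hp$level_log + u)
  inc <- latents[, .(subject_id, timepoint = t_b,
                     dh = hp$change_sd * (mix$lambda_hair * L +
                            sqrt(1 - mix$lambda_hair^2) * stats::rnorm(.N)))]
  inc[, k := match(timepoint, TIMEPOINTS)]
  data.table::setorder(inc, subject_id, k)
  inc[, log_cort := hp$level_log + u[subject_id] + cumsum(dh),
      by = subject_id]
  hair <- rbind(base, inc[, .(subject_id, timepoint, log_cort)])
  hair[, cortisol_pg_mg := exp(log_cort)]
  hair[, cortisone_pg_mg := exp(log_cort + hp$cortisone_ratio_log +
                                  stats::rnorm(.N, 0, hp$cortisone_noise_sd))]
  out <- hair[, .(subject_id, timepoint, cortisol_pg_mg, cortisone_pg_mg)]
  data.table::setorder(out, subject_id, timepoint)
  out[]
}

#' Planted ground-truth networks
#'
#' Disjoint blocks of ipsilateral parcels (Schaefer-400 convention: parcels
#' 1-200 left, 201-400 right) that receive the seed's latent signal.
#' @keywords internal
planted_networks <- function(cfg) {
  k <- cfg$fmri$network_size
  nets <- list()
  for (h in seq_along(HEMIS)) {
    offs <- (h - 1L) * 200L
    for (s in seq_along(SUBFIELDS)) {
      lab <- paste(HEMIS[h], SUBFIELDS[s], sep = "_")
      nets[[lab]] <- offs + ((s - 1L) * k + 1L):(s * k)
    }
  }
  nets
}

#' @keywords internal
gen_fmri <- function(cfg, subjects, latents, networks) {
  fp <- cfg$fmri
  T_ <- fp$n_timepoints
  scans <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    tps <- cohort_timepoints(subjects$cohort[i])
    ## cumulative module-driven increments on the mixing weight
    lat_i <- latents[subject_id == sid]
    w_sub <- stats::rnorm(length(SUBFIELD_LABELS), 0, fp$coupling_noise_sd)
    names(w_sub) <- SUBFIELD_LABELS
    for (tp in tps) {
      k <- match(tp, TIMEPOINTS)
      cum_eff <- vapply(SUBFIELD_LABELS, function(sf) {
        if (k == 1L) return(0)
        done <- lat_i[match(t_b, TIMEPOINTS) <= k & module != "retest"]
        sum(effect_lookup(cfg$fmri_effects, done$module, sf))
      }, 0)
      w <- pmax(0.05, fp$seed_coupling + w_sub + cum_eff)
      names(w) <- SUBFIELD_LABELS

      parcel_ts <- matrix(stats::rnorm(T_ * 400L), T_, 400L)
      seed_ts <- list()
      for (sf in SUBFIELD_LABELS) {
        g <- stats::rnorm(T_)
        seed_ts[[sf]] <- g + stats::rnorm(T_, 0, fp$seed_noise_sd)
        idx <- networks[[sf]]
        parcel_ts[, idx] <- parcel_ts[, idx] + w[sf] * g
      }
      motion <- gen_motion(T_, fp)
      scans[[paste(sid, tp, sep = ".")]] <-
        list(subject_id = sid, timepoint = tp, parcel_ts = parcel_ts,
             seed_ts = seed_ts, motion = motion)
    }
  }
  scans
}

## Motion parameters constructed so the Power framewise displacement of the
## series equals a drawn per-frame target exactly (half carried by the x
## translation, half by the x rotation at the 50 mm head-radius convention).
#' @keywords internal
gen_motion <- function(T_, fp) {
  high <- stats::runif(1) < fp$high_motion_rate
  mu <- if (high) fp$fd_mean_high else fp$fd_mean
  fd <- pmax(0.005, stats::rnorm(T_ - 1L, mu, fp$fd_sd))
  spikes <- stats::runif(T_ - 1L) < fp$spike_rate
  fd[spikes] <- fd[spikes] + fp$spike_size
  signs_t <- sample(c(-1, 1), T_ - 1L, replace = TRUE)
  signs_r <- sample(c(-1, 1), T_ - 1L, replace = TRUE)
  motion <- matrix(0, T_, 6L)
  motion[-1L, 1L] <- cumsum(signs_t * fd / 2)
  motion[-1L, 4L] <- cumsum(signs_r * fd / (2 * 50))
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  motion
}

#' Delete subject-timepoint records completely at random
#'
#' Emulates attrition by removing whole subject-timepoint records (volumes,
#' saliva, hair and scans alike) with probability `rate`, never removing all
#' timepoints of a subject. Deterministic for a given `seed`.
#'
#' @param dataset a `cohort_dataset`.
#' @param rate deletion probability in `[0, 1)`.
#' @param seed integer seed.
#' @return The dataset with records removed; the deleted
#'   subject-timepoints are recorded in `attr(, "deleted")`.
#' @export
inject_missingness <- function(dataset, rate, seed = 1L) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (rate < 0 || rate >= 1) stop("rate must be in [0,1)")
  if (rate == 0) {
    attr(dataset, "deleted") <- data.table::data.table(
      subject_id = character(), timepoint = character())
    return(dataset)
  }
  recs <- data.table::rbindlist(lapply(seq_len(nrow(dataset$subjects)),
    function(i) data.table::data.table(
      subject_id = dataset$subjects$subject_id[i],
      timepoint = cohort_timepoints(dataset$subjects$cohort[i]))))
  with_seed(seed, {
    recs[, drop := stats::runif(.N) < rate]
    ## never orphan a subject entirely: keep one random timepoint
    all_gone <- recs[, .(gone = all(drop)), by = subject_id][gone == TRUE]
    for (sid in all_gone$subject_id) {
      keep <- sample(which(recs$subject_id == sid), 1L)
      recs$drop[keep] <- FALSE
    }
  })
  deleted <- recs[drop == TRUE, .(subject_id, timepoint)]
  key <- function(s, t) paste(s, t, sep = ".")
  bad <- key(deleted$subject_id, deleted$timepoint)
  for (blk in c("volumes", "saliva", "hair")) {
    if (!is.null(dataset[[blk]])) {
      tb <- dataset[[blk]]
      dataset[[blk]] <- tb[!key(tb$subject_id, tb$timepoint) %in% bad]
    }
  }
  if (!is.null(dataset$fmri))
    dataset$fmri <- dataset$fmri[!names(dataset$fmri) %in% bad]
  attr(dataset, "deleted") <- deleted
  dataset
}
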