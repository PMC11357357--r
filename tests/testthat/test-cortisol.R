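# Diurnal cortisol cleaning and summary indices.

test_that("log transform maps concentrations and flags invalid samples", {
  tab <- data.table::data.table(subject_id = "S1", timepoint = "T0",
                                day = 1, offset_min = c(0, 30, 60),
                                nmol_l = c(1, exp(2), 0))
  expect_warning(out <- log_transform(tab), "non-positive")
  expect_equal(out$log_nmol, c(0, 2))
  expect_identical(nrow(out), 2L)
})

test_that("winsorization clips at the single-pass mean +/- k SD boundary", {
  expect_identical(winsorize_3sd(rep(5, 10)), rep(5, 10))
  ## oracle: recompute mean/SD of the final vector directly
  set.seed(1)
  x <- c(scale(rnorm(50)))  # exact mean 0, sd 1
  x_out <- c(x, 50)
  m <- mean(x_out); s <- sd(x_out)
  w <- winsorize_3sd(x_out)
  expect_equal(w[length(w)], m + 3 * s)
  expect_equal(w[-length(w)], x_out[-length(w)])  # inliers untouched
  ## low outlier symmetric
  y <- c(x, -50)
  expect_equal(winsorize_3sd(y)[length(y)], mean(y) - 3 * sd(y))
  ## missing propagates; short input errors
  expect_true(is.na(winsorize_3sd(c(1, 2, 3, NA))[4]))
  expect_error(winsorize_3sd(c(1, NA, NA)), "at least 3")
  ## idempotent when mean/SD are frozen from the first pass
  z <- winsorize_3sd(x_out)
  expect_equal(winsorize_3sd(z, center = m, scale = s), z)
})

test_that("day averaging uses available days and keeps missing missing", {
  tab <- rbind(
    data.table::data.table(subject_id = "S1", timepoint = "T0", day = 1,
                           offset_min = c(0, 30, 240), log_nmol = c(2, 1, 3)),
    data.table::data.table(subject_id = "S1", timepoint = "T0", day = 2,
                           offset_min = c(0, 60), log_nmol = c(4, NA)))
  avg <- average_days(tab)
  expect_equal(avg[offset_min == 0, log_nmol], 3)    # (2+4)/2
  expect_equal(avg[offset_min == 30, log_nmol], 1)   # day 1 only
  expect_equal(avg[offset_min == 240, log_nmol], 3)
  expect_false(60 %in% avg$offset_min)               # NA on its only day
})

test_that("awakening response follows the individual-peak rule", {
  s <- function(v) stats::setNames(v, c(0, 30, 60))
  expect_equal(compute_car(s(c(10, 15, 12))), 5)   # peak at 30
  expect_equal(compute_car(s(c(10, 12, 15))), 5)   # peak at 60
  expect_equal(compute_car(s(c(15, 12, 10))), -3)  # peak at S0: use 30 min
  expect_true(is.na(compute_car(stats::setNames(c(12, 10), c(30, 60)))))
  expect_equal(compute_car(stats::setNames(c(10, 13), c(0, 60))), 3)
  ## values after 60 min never enter
  full <- stats::setNames(c(10, 15, 12, 99, 99, 99, 99), SALIVA_OFFSETS)
  expect_equal(compute_car(full), 5)
})

test_that("diurnal slope is the awakening-to-600-min change score", {
  s <- stats::setNames(c(10, 12, 11, 8, 7, 5, 4), SALIVA_OFFSETS)
  expect_equal(compute_slope(s), -6)
  expect_equal(compute_slope(stats::setNames(rep(2, 7), SALIVA_OFFSETS)), 0)
  expect_true(is.na(compute_slope(s[-7])))
  ## only the endpoints matter
  s2 <- s; s2[c("30", "240")] <- c(99, -99)
  expect_equal(compute_slope(s2), -6)
})

test_that("area under the curve matches the trapezoid and exclusion rules", {
  s <- stats::setNames(c(3, 9, 9, 3, 3, 3, 3), SALIVA_OFFSETS)
  expect_equal(compute_aucg(s), 600 * 3)  # constant on included occasions
  vals <- stats::setNames(c(10, 0, 0, 6, 5, 4, 3), SALIVA_OFFSETS)
  expect_equal(compute_aucg(vals), 3540)  # frozen fine-grid oracle value
  ## the 30/60-min samples never enter
  vals2 <- vals; vals2[c("30", "60")] <- c(1e6, -1e6)
  expect_equal(compute_aucg(vals2), compute_aucg(vals))
  ## any missing included occasion -> undefined
  expect_true(is.na(compute_aucg(vals[-4])))
})

test_that("diurnal_indices composes cleaning and indices per profile", {
  ## noise-free generator: indices equal closed-form curve values
  cfg <- small_config(seed = 8L, tc1 = 5L, tc2 = 5L, tc3 = 2L, rcc = 2L,
                      cortisol = list(subject_sd = 0, noise_sd = 1e-9,
                                      state_sd = 1e-9),
                      coupling_r = 0, hair_coupling_r = 0)
  ds <- simulate_cohort(cfg, include = "saliva")
  idx <- diurnal_indices(ds$saliva)
  ct <- cfg$cortisol
  ## peak at 30 min: bump minus the diurnal decline accrued over 30 min
  car_exp <- ct$car_amp - 30 * ct$decay_per_min
  expect_equal(idx$car, rep(car_exp, nrow(idx)), tolerance = 1e-6)
  expect_equal(idx$slope, rep(-600 * ct$decay_per_min, nrow(idx)),
               tolerance = 1e-6)
  w <- c(120, 180, 120, 120, 60)  # trapezoid weights at the design offsets
  aucg_exp <- sum(w * (ct$level - ct$decay_per_min * AUCG_OFFSETS))
  expect_equal(idx$aucg, rep(aucg_exp, nrow(idx)), tolerance = 1e-4)
  expect_true(all(idx$n_aucg == 5L))

  ## empty input -> empty table
  expect_identical(nrow(diurnal_indices(ds$saliva[0])), 0L)

  ## missing 480-min occasion on both days: CAR and slope defined, area not
  miss <- ds$saliva[!(subject_id == "S0001" & timepoint == "T0" &
                        offset_min == 480)]
  idx2 <- diurnal_indices(miss)
  row <- idx2[subject_id == "S0001" & timepoint == "T0"]
  expect_false(is.na(row$car))
  expect_false(is.na(row$slope))
  expect_true(is.na(row$aucg))
  expect_identical(row$n_aucg, 4L)
})

test_that("index pipeline is invariant to subject order", {
  ds <- simulate_cohort(small_config(seed = 21L), include = "saliva")
  idx1 <- diurnal_indices(ds$saliva)
  shuf <- ds$saliva[sample(nrow(ds$saliva))]
  idx2 <- diurnal_indices(shuf)
  data.table::setkey(idx1, subject_id, timepoint)
  data.table::setkey(idx2, subject_id, timepoint)
  expect_equal(as.data.frame(idx1), as.data.frame(idx2))
})

test_that("hair change scores difference consecutive segments", {
  hair <- data.table::data.table(
    subject_id = rep("S1", 3), timepoint = c("T0", "T1", "T2"),
    cortisol_pg_mg = c(exp(1), exp(3), exp(3)),
    cortisone_pg_mg = c(10, 10, 12.5))
  hc <- hair_change(hair, log = TRUE)
  expect_equal(hc[t_a == "T0", d_cortisol], 2)
  expect_equal(hc[t_a == "T1", d_cortisol], 0)
  raw <- hair_change(hair, log = FALSE)
  expect_equal(raw[t_a == "T1", d_cortisone], 2.5)
  ## missing segment -> no record
  hc2 <- hair_change(hair[timepoint != "T1"])
  expect_identical(nrow(hc2), 0L)
})
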