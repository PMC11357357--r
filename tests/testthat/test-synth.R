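# Synthetic cohort generator: schedule, determinism, ground-truth recovery.

test_that("module_schedule maps every cohort-interval pair correctly", {
  cases <- list(
    list("TC1", c("T0", "T1"), "Presence"),
    list("TC1", c("T1", "T2"), "Affect"),
    list("TC1", c("T2", "T3"), "Perspective"),
    list("TC2", c("T0", "T1"), "Presence"),
    list("TC2", c("T1", "T2"), "Perspective"),
    list("TC2", c("T2", "T3"), "Affect"),
    list("TC3", c("T0", "T1"), "Affect"),
    list("RCC", c("T0", "T1"), "retest"),
    list("RCC", c("T2", "T3"), "retest"))
  for (cs in cases)
    expect_identical(module_schedule(cs[[1]], cs[[2]]), cs[[3]])
  expect_error(module_schedule("TC9", c("T0", "T1")))
  expect_error(module_schedule("TC1", c("T0", "T2")), "consecutive")
  expect_error(module_schedule("TC3", c("T1", "T2")), "no training")
  expect_identical(cohort_timepoints("TC3"), c("T0", "T1"))
  expect_length(cohort_intervals("TC1"), 3L)
})

test_that("sim_config validates fields and defaults to the design sizes", {
  cfg <- sim_config()
  expect_identical(unname(cfg$n_per_cohort[c("TC1", "TC2", "TC3", "RCC")]),
                   c(80L, 81L, 81L, 90L))
  expect_error(sim_config(n_per_cohort = c(TC1 = 0L, TC2 = 1L, TC3 = 1L,
                                           RCC = 1L)), "> 0")
  expect_error(sim_config(coupling_r = 1.2), "|r| < 1", fixed = TRUE)
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(module_effects = c("Bogus:L_CA13" = 0.2)),
               "unknown module")
})

test_that("identical seeds give identical datasets", {
  cfg <- small_config(seed = 11L, tc1 = 4L, tc2 = 4L, tc3 = 2L, rcc = 2L,
                      n_fmri = 40L)
  d1 <- simulate_cohort(cfg)
  d2 <- simulate_cohort(cfg)
  expect_identical(d1$subjects, d2$subjects)
  expect_identical(d1$volumes, d2$volumes)
  expect_identical(d1$saliva, d2$saliva)
  expect_identical(d1$hair, d2$hair)
  expect_identical(d1$fmri, d2$fmri)
  d3 <- simulate_cohort(small_config(seed = 12L, tc1 = 4L, tc2 = 4L,
                                     tc3 = 2L, rcc = 2L, n_fmri = 40L))
  expect_false(identical(d1$volumes, d3$volumes))
})

test_that("cohort structure matches the design", {
  ds <- simulate_cohort(small_config(seed = 3L),
                        include = c("volumes", "saliva"))
  expect_identical(nrow(ds$subjects), 33L)
  ## TC3 measured at T0/T1 only; others at all four timepoints
  tc3 <- ds$subjects[cohort == "TC3", subject_id]
  expect_identical(sort(unique(ds$volumes[subject_id %in% tc3, timepoint])),
                   c("T0", "T1"))
  tc1 <- ds$subjects[cohort == "TC1", subject_id]
  expect_identical(sort(unique(ds$volumes[subject_id %in% tc1, timepoint])),
                   c("T0", "T1", "T2", "T3"))
  expect_true(all(ds$volumes$volume_mm3 > 0))
  expect_true(all(ds$saliva$nmol_l > 0))
  expect_true(all(ds$subjects$age >= 20 & ds$subjects$age <= 55))
})

test_that("configured volume effect is recovered at large n", {
  ## standardized mean change over Affect intervals within +/- 0.05 of d
  cfg <- sim_config(n_per_cohort = c(TC1 = 5000L, TC2 = 5000L, TC3 = 5L,
                                     RCC = 5L), seed = 42L)
  ds <- simulate_cohort(cfg, include = "volumes")
  ch <- build_change_records(measures_from_volumes(ds$volumes), ds$subjects)
  for (m in c("volume:L_CA13", "volume:R_CA13")) {
    aff <- ch[measure == m & module == "Affect"]
    expect_equal(mean(aff$delta) / sd(aff$delta), 0.35, tolerance = 0.05 / 0.35)
  }
  ## untargeted subfield and untrained module stay null
  per <- ch[measure == "volume:L_SUB" & module == "Perspective"]
  expect_lt(abs(mean(per$delta) / sd(per$delta)), 0.05)
})

test_that("brain-cortisol coupling is recovered at large n", {
  cfg <- sim_config(n_per_cohort = c(TC1 = 5L, TC2 = 5L, TC3 = 10000L,
                                     RCC = 5L), seed = 2L)
  ds <- simulate_cohort(cfg, include = c("volumes", "saliva", "hair"))
  idx <- diurnal_indices(ds$saliva)
  ch <- build_change_records(rbind(measures_from_volumes(ds$volumes),
                                   measures_from_indices(idx)),
                             ds$subjects)
  w <- data.table::dcast(
    ch[measure %in% c("volume:R_CA13", "cortisol:aucg")],
    subject_id + t_a ~ measure, value.var = "delta")
  r <- cor(w[["volume:R_CA13"]], w[["cortisol:aucg"]],
           use = "complete.obs")
  expect_equal(r, -0.23, tolerance = 0.05 / 0.23)
  ## hair coupling
  hc <- hair_change(ds$hair)
  w2 <- merge(ch[measure == "volume:L_CA13", .(subject_id, dvol = delta)],
              hc[, .(subject_id, d_cortisol)], by = "subject_id")
  expect_equal(cor(w2$dvol, w2$d_cortisol), -0.37, tolerance = 0.05 / 0.37)
})

test_that("inject_missingness is deterministic, binomial, and never orphans", {
  ds <- simulate_cohort(small_config(seed = 5L, tc1 = 100L, tc2 = 100L,
                                     tc3 = 50L, rcc = 50L),
                        include = c("volumes", "saliva"))
  expect_identical(inject_missingness(ds, 0)$volumes, ds$volumes)
  m1 <- inject_missingness(ds, 0.2, seed = 9L)
  m2 <- inject_missingness(ds, 0.2, seed = 9L)
  expect_identical(m1$volumes, m2$volumes)
  expect_identical(attr(m1, "deleted"), attr(m2, "deleted"))
  ## ~binomial(n_records, 0.2) deletions
  n_rec <- sum(vapply(ds$subjects$cohort,
                      function(co) length(cohort_timepoints(co)), 0L))
  del <- nrow(attr(m1, "deleted"))
  expect_gt(del, n_rec * 0.2 - 2 * sqrt(n_rec * 0.2 * 0.8))
  expect_lt(del, n_rec * 0.2 + 2 * sqrt(n_rec * 0.2 * 0.8))
  ## no subject loses every timepoint
  left <- unique(m1$volumes$subject_id)
  expect_setequal(left, ds$subjects$subject_id)
  expect_error(inject_missingness(ds, 1.0), "rate")
})
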