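# Shared fixtures: small configs and hand-built tables.

null_effects <- stats::setNames(numeric(0), character(0))

small_config <- function(seed = 1L, ..., tc1 = 10L, tc2 = 10L, tc3 = 5L,
                         rcc = 8L, n_fmri = 60L) {
  sim_config(n_per_cohort = c(TC1 = as.integer(tc1), TC2 = as.integer(tc2),
                              TC3 = as.integer(tc3), RCC = as.integer(rcc)),
             fmri = list(n_timepoints = as.integer(n_fmri)),
             seed = seed, ...)
}

# One subject-timepoint saliva block (both days) with given log-scale values
# per occasion; values may be a single vector (reused for both days) or a
# list of two vectors.
make_saliva <- function(subject_id = "S1", timepoint = "T0", log_values,
                        offsets = c(0, 30, 60, 240, 360, 480, 600)) {
  if (!is.list(log_values)) log_values <- list(log_values, log_values)
  data.table::rbindlist(lapply(1:2, function(d)
    data.table::data.table(subject_id = subject_id, timepoint = timepoint,
                           day = d, offset_min = offsets,
                           nmol_l = exp(log_values[[d]]))))
}

# Change-record table for contrast tests: one delta per subject and module.
make_records <- function(deltas_a, deltas_b, module_a = "Affect",
                         module_b = "Perspective", within = FALSE,
                         seed = 1L) {
  n1 <- length(deltas_a); n2 <- length(deltas_b)
  ids_a <- sprintf("A%03d", seq_len(n1))
  ids_b <- if (within) ids_a[seq_len(n2)] else sprintf("B%03d", seq_len(n2))
  set.seed(seed)
  ages <- round(runif(n1 + n2, 25, 55), 1)
  sexes <- sample(c("F", "M"), n1 + n2, replace = TRUE)
  data.table::data.table(
    subject_id = c(ids_a, ids_b),
    cohort = "TC1",
    module = c(rep(module_a, n1), rep(module_b, n2)),
    t_a = c(rep("T1", n1), rep("T2", n2)),
    t_b = c(rep("T2", n1), rep("T3", n2)),
    measure = "volume:R_CA13",
    delta = c(deltas_a, deltas_b),
    age = ages[c(seq_len(n1), if (within) seq_len(n2) else n1 + seq_len(n2))],
    sex = sexes[c(seq_len(n1), if (within) seq_len(n2) else n1 + seq_len(n2))])
}

# All permutations of 1..n (tiny n), for exhaustive permutation oracles.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
    out <- rbind(out, block)
  }
  out
}
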