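# Behavioral PLS: residualization, normalization, SVD, permutation,
# bootstrap, per-group expression.

test_that("residualization matches the hat-matrix oracle", {
  set.seed(6)
  n <- 20
  X <- matrix(rnorm(n * 3), n, 3)
  age <- runif(n, 20, 55)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  subj <- rep(sprintf("S%02d", 1:10), each = 2)
  ## oracle: explicit projection using a pivoted full-rank design
  M <- model.matrix(~ age + sex + factor(subj))
  q <- qr(M)
  Mr <- M[, q$pivot[seq_len(q$rank)], drop = FALSE]
  H <- Mr %*% solve(crossprod(Mr)) %*% t(Mr)
  R_oracle <- X - H %*% X
  R_pkg <- residualize_brain(X, age, sex, subj)
  expect_equal(R_pkg, R_oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(colMeans(R_pkg), rep(0, 3), tolerance = 1e-10)
  ## projection idempotence
  expect_equal(residualize_brain(R_pkg, age, sex, subj), R_pkg,
               tolerance = 1e-10, ignore_attr = TRUE)
  ## exact linear function of age -> residuals vanish
  X_age <- cbind(2 * age + 1, -age)
  expect_equal(max(abs(residualize_brain(X_age, age, sex, subj))), 0,
               tolerance = 1e-10)
  ## saturated subject design falls back with a warning
  expect_warning(residualize_brain(X, age, sex, seq_len(n)), "saturate")
})

test_that("within-group normalization z-scores per group", {
  set.seed(8)
  M <- matrix(rnorm(12 * 2), 12, 2)
  g <- rep(c("a", "b"), each = 6)
  Z <- normalize_within_group(M, g)
  for (gr in c("a", "b")) {
    expect_equal(colMeans(Z[g == gr, ]), c(0, 0), tolerance = 1e-12)
    expect_equal(apply(Z[g == gr, ], 2, sd), c(1, 1), tolerance = 1e-12)
  }
  ## group offsets are removed: shifted copies normalize identically
  M2 <- M; M2[g == "b", ] <- M2[g == "b", ] + 100
  expect_equal(normalize_within_group(M2, g), Z, tolerance = 1e-10)
  ## single group is the ordinary z-score
  expect_equal(normalize_within_group(M),
               apply(M, 2, function(x) (x - mean(x)) / sd(x)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_warning(normalize_within_group(cbind(M[, 1], 5)), "zero")
})

test_that("pls_fit matches a dense SVD oracle", {
  set.seed(10)
  X <- matrix(rnorm(12 * 3), 12, 3)
  Y <- matrix(rnorm(12 * 2), 12, 2)
  fit <- pls_fit(X, Y)
  sv <- svd(crossprod(Y, X) / 11)
  expect_equal(fit$s, sv$d[1:2], tolerance = 1e-10)
  for (i in 1:2) {
    ## equal up to sign
    expect_equal(abs(fit$U[, i]), abs(sv$u[, i]), tolerance = 1e-10)
    expect_equal(abs(fit$V[, i]), abs(sv$v[, i]), tolerance = 1e-10)
    ## orientation: dominant behavior salience positive
    expect_gt(fit$U[which.max(abs(fit$U[, i])), i], 0)
  }
  expect_equal(sum(fit$covexp), 100)
  expect_equal(fit$Lx, X %*% fit$V)
  ## scores/loadings against direct correlation
  expect_equal(fit$brain_loadings[1, 1], cor(X[, 1], fit$Lx[, 1]),
               tolerance = 1e-12)
  ## X/Y symmetry of singular values; column-permutation invariance
  expect_equal(pls_fit(Y, X)$s, fit$s, tolerance = 1e-12)
  expect_equal(pls_fit(X[, c(3, 1, 2)], Y[, 2:1])$s, fit$s,
               tolerance = 1e-12)
  ## p = q = 1 on centered input: singular value is |sample covariance|
  x1 <- scale(X[, 1], scale = FALSE); y1 <- scale(Y[, 1], scale = FALSE)
  expect_equal(pls_fit(x1, y1)$s, abs(cov(X[, 1], Y[, 1])),
               tolerance = 1e-12)
  expect_equal(pls_fit(x1, y1)$covexp, 100)
  ## exactly orthogonal blocks -> all singular values 0
  Xo <- cbind(c(1, -1, 0, 0), c(0, 0, 1, -1))
  Yo <- cbind(c(1, 1, -1, -1))
  expect_equal(pls_fit(Xo, Yo)$s, 0, tolerance = 1e-12)
  expect_error(pls_fit(cbind(c(1, NA, 3)), cbind(1:3)), "missing")
})

test_that("permutation p-values behave at the extremes and under seed", {
  set.seed(11)
  X <- matrix(rnorm(12 * 3), 12, 3)
  Y <- X[, 1:2] # perfectly predicted
  perm <- permutation_test(X, Y, n_perm = 1000, seed = 5L)
  expect_equal(perm$p[1], 1 / 1001)
  perm2 <- permutation_test(X, Y, n_perm = 1000, seed = 5L)
  expect_identical(perm$perm_s, perm2$perm_s)
  expect_true(all(perm$q >= perm$p))
  expect_error(permutation_test(X, Y, n_perm = 0), "n_perm")
})

test_that("null permutation p-values are approximately uniform", {
  set.seed(12)
  p1 <- replicate(200, {
    X <- matrix(rnorm(30), 30, 1)
    Y <- matrix(rnorm(30), 30, 1)
    permutation_test(X, Y, n_perm = 99,
                     seed = sample.int(1e6, 1))$p[1]
  })
  ks <- suppressWarnings(ks.test(p1, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("bootstrap CIs are deterministic, tight when noise-free, and valid", {
  set.seed(14)
  n <- 40
  X <- matrix(rnorm(n * 2), n, 2)
  Y <- X %*% matrix(c(1, 0.5), 2, 1)  # deterministic rank-1 relation
  b1 <- bootstrap_loadings(X, Y, n_boot = 50, seed = 3L)
  b2 <- bootstrap_loadings(X, Y, n_boot = 50, seed = 3L)
  expect_identical(b1$brain_ci, b2$brain_ci)
  ## behavior loading of the single Y variable on LC1 is exactly 1 in
  ## every resample
  expect_lt(b1$behavior_ci[1, 1, "hi"] - b1$behavior_ci[1, 1, "lo"], 1e-10)
  expect_error(bootstrap_loadings(X[1:5, ], Y[1:5, , drop = FALSE],
                                  n_boot = 5), "at least 10")
})

test_that("per-group expression equals direct correlation", {
  set.seed(15)
  n <- 30
  X <- matrix(rnorm(n * 2), n, 2)
  Y <- 0.5 * X + matrix(rnorm(n * 2), n, 2)
  g <- rep(c("Presence", "Affect", "Perspective"), each = 10)
  fit <- pls_fit(X, Y)
  expr <- per_group_expression(fit, g)
  for (gr in unique(g)) {
    i <- which(g == gr)
    expect_equal(expr[group == gr & lc == 1, r],
                 cor(fit$Lx[i, 1], fit$Ly[i, 1]), tolerance = 1e-12)
  }
  expect_equal(expr[group == "Overall" & lc == 1, r],
               cor(fit$Lx[, 1], fit$Ly[, 1]), tolerance = 1e-12)
  expect_error(per_group_expression(fit, c(rep("a", 28), "b", "b")),
               "fewer than 3")
})

test_that("planted coupling drives LC1 and the CA1-3 loadings", {
  ## default generator; one medium cohort: LC1 significant and CA1-3
  ## dominant among brain loadings
  cfg <- sim_config(n_per_cohort = c(TC1 = 60L, TC2 = 60L, TC3 = 5L,
                                     RCC = 5L), seed = 77L)
  ds <- simulate_cohort(cfg, include = c("volumes", "saliva"))
  idx <- diurnal_indices(ds$saliva)
  ch <- build_change_records(rbind(measures_from_volumes(ds$volumes),
                                   measures_from_indices(idx)),
                             ds$subjects)
  pin <- assemble_pls_input(ch, model = "all")
  fit <- behavioral_pls(pin$X, pin$Y, pin$groups, pin$age, pin$sex,
                        pin$subject, n_perm = 500, n_boot = 50, seed = 1L)
  expect_lt(fit$perm_q[1], 0.05)
  lead <- which.max(abs(fit$brain_loadings[, 1]))
  expect_match(colnames(pin$X)[lead], "CA13")
  ## AUCg carries the dominant behavior loading and opposes the volume sign
  ybig <- which.max(abs(fit$behavior_loadings[, 1]))
  expect_identical(colnames(pin$Y)[ybig], "cortisol:aucg")
  expect_lt(fit$behavior_loadings[ybig, 1] * fit$brain_loadings[lead, 1], 0)
})
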