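## Behavioral partial least squares: SVD of the brain-change x
## cortisol-change cross-covariance, with permutation significance per
## latent component and bootstrap confidence intervals on loading
## correlations.

#' Residualize a brain-change matrix on covariates and subject
#'
#' Per-column ordinary least squares residuals against age, sex and subject
#' indicator variables (fixed-effect absorption of the subject random
#' effect). If the subject indicators saturate the design (at least as many
#' parameters as rows), falls back to age and sex only, with a warning.
#'
#' @param X n x p numeric matrix.
#' @param age,sex length-n covariates.
#' @param subject length-n subject identifiers (a subject spanning several
#'   rows contributes several intervals).
#' @return The residual matrix (column means ~ 0).
#' @export
residualize_brain <- function(X, age, sex, subject = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  dat <- data.frame(age = age, sex = factor(sex))
  form <- ~ age + sex
  if (!is.null(subject) && length(unique(subject)) > 1L) {
    dat$subject <- factor(subject)
    if (nlevels(dat$subject) + 3L >= n) {
      warning("subject indicators would saturate the design; ",
              "residualizing on age and sex only")
    } else form <- ~ age + sex + subject
  }
  M <- stats::model.matrix(form, dat)
  ## qr.resid tolerates the rank deficiency of subject dummies together
  ## with subject-constant covariates (age, sex)
  qr.resid(qr(M), X)
}

#' Z-score columns within groups
#'
#' Each column is centered and scaled to unit SD within each group
#' (removing group mean offsets so that the later permutation can shuffle
#' rows freely). A column constant within a group is left centered only,
#' with a warning.
#'
#' @param M n x p numeric matrix.
#' @param groups length-n group labels (a single group gives the ordinary
#'   column z-score).
#' @return The normalized matrix.
#' @export
normalize_within_group <- function(M, groups = rep(1L, nrow(M))) {
  M <- as.matrix(M)
  stopifnot(length(groups) == nrow(M))
  for (g in unique(groups)) {
    i <- which(groups == g)
    if (length(i) < 2L) stop("each group needs at least 2 rows")
    mu <- colMeans(M[i, , drop = FALSE])
    sdv <- apply(M[i, , drop = FALSE], 2L, stats::sd)
    if (any(sdv == 0)) {
      warning("zero within-group SD in column(s) ",
              paste(which(sdv == 0), collapse = ", "),
              "; centered only")
      sdv[sdv == 0] <- 1
    }
    M[i, ] <- sweep(sweep(M[i, , drop = FALSE], 2L, mu), 2L, sdv, "/")
  }
  M
}

#' Fit the deterministic part of a behavioral PLS
#'
#' Singular value decomposition of the cross-covariance
#' `R = t(Y) %*% X / (n - 1)` of normalized brain (`X`) and behavior
#' (`Y`) matrices. Latent components are oriented so that the
#' largest-magnitude behavior salience of each component is positive.
#'
#' @param X n x p normalized brain-change matrix.
#' @param Y n x q normalized behavior-change matrix.
#' @return An object of class `pls_result`: singular values `s`
#'   (descending), percent cross-covariance explained `covexp`, brain
#'   saliences `V` (p x k), behavior saliences `U` (q x k), brain scores
#'   `Lx = X V`, behavior scores `Ly = Y U`, and loading correlations
#'   `brain_loadings` (p x k: each X column vs each brain score) and
#'   `behavior_loadings` (q x k).
#' @export
pls_fit <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  if (anyNA(X) || anyNA(Y)) stop("PLS input contains missing values")
  n <- nrow(X)
  R <- crossprod(Y, X) / (n - 1)          # q x p
  k <- min(ncol(X), ncol(Y))
  sv <- svd(R, nu = k, nv = k)
  U <- sv$u; V <- sv$v; s <- sv$d[seq_len(k)]
  ## sign convention: dominant behavior salience positive per component
  for (i in seq_len(k)) {
    j <- which.max(abs(U[, i]))
    if (U[j, i] < 0) { U[, i] <- -U[, i]; V[, i] <- -V[, i] }
  }
  Lx <- X %*% V
  Ly <- Y %*% U
  safe_cor <- function(A, B) {
    out <- suppressWarnings(stats::cor(A, B))
    out[is.na(out)] <- 0
    out
  }
  res <- list(s = s, covexp = 100 * s^2 / sum(s^2), U = U, V = V,
              Lx = Lx, Ly = Ly,
              brain_loadings = safe_cor(X, Lx),
              behavior_loadings = safe_cor(Y, Ly),
              n = n, p = ncol(X), q = ncol(Y))
  class(res) <- "pls_result"
  res
}

#' @export
print.pls_result <- function(x, ...) {
  cat("<pls_result>", x$n, "rows,", x$p, "brain x", x$q,
      "behavior variables\n")
  tab <- data.frame(LC = seq_along(x$s), singular_value = round(x$s, 4),
                    covexp_pct = round(x$covexp, 1))
  if (!is.null(x$perm_p)) {
    tab$perm_p <- signif(x$perm_p, 3)
    tab$fdr_q <- signif(x$perm_q, 3)
  }
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Permutation test of latent component significance
#'
#' Rows of `Y` are permuted uniformly (optionally within groups); each
#' component's observed singular value is compared with the permutation
#' distribution of the same-rank singular value. p-values use the add-one
#' convention `(1 + #{s_perm >= s_obs}) / (n_perm + 1)` and are FDR
#' corrected across components.
#'
#' @param X,Y normalized input matrices.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed (deterministic).
#' @param groups optional group labels for within-group permutation.
#' @param within_group permute within groups only (default FALSE: groups
#'   are already absorbed by within-group normalization).
#' @return A list: `p`, `q` (per component), `s_obs`, `perm_s`
#'   (n_perm x k matrix).
#' @export
permutation_test <- function(X, Y, n_perm = 1000, seed = 1L,
                             groups = NULL, within_group = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  k <- min(ncol(X), ncol(Y))
  s_obs <- svd(crossprod(Y, X) / (n - 1), nu = 0, nv = 0)$d[seq_len(k)]
  perm_s <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(b) {
      idx <- if (within_group && !is.null(groups)) {
        out <- seq_len(n)
        for (g in unique(groups)) {
          i <- which(groups == g)
          out[i] <- i[sample.int(length(i))]
        }
        out
      } else sample.int(n)
      svd(crossprod(Y[idx, , drop = FALSE], X) / (n - 1),
          nu = 0, nv = 0)$d[seq_len(k)]
    }, numeric(k)))
  })
  if (k == 1L) perm_s <- matrix(perm_s, ncol = 1L)
  p <- vapply(seq_len(k), function(i)
    (1 + sum(perm_s[, i] >= s_obs[i])) / (n_perm + 1), 0)
  list(p = p, q = correct_multiplicity(p, "bh"), s_obs = s_obs,
       perm_s = perm_s)
}

#' Bootstrap confidence intervals of PLS loading correlations
#'
#' Resamples rows with replacement (whole subject blocks when a subject
#' spans several rows), refits the PLS, aligns each component's sign to the
#' original solution by the congruence of behavior saliences, and returns
#' 2.5/97.5 percentile intervals of the brain and behavior loading
#' correlations. A resample that leaves any column constant is redrawn (at
#' most 10 retries).
#'
#' @param X,Y normalized input matrices.
#' @param n_boot number of bootstrap samples (default 100).
#' @param seed integer seed.
#' @param subject optional length-n subject identifiers for block
#'   resampling.
#' @return A list: `brain_ci` and `behavior_ci` (arrays variable x
#'   component x c(lo, hi)), plus the bootstrap draws.
#' @export
bootstrap_loadings <- function(X, Y, n_boot = 100, seed = 1L,
                               subject = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 10) stop("bootstrap needs at least 10 rows")
  orig <- pls_fit(X, Y)
  k <- length(orig$s)
  blocks <- if (is.null(subject)) as.list(seq_len(n))
            else split(seq_len(n), subject)
  nb <- length(blocks)
  draw_rows <- function() unlist(blocks[sample.int(nb, nb, replace = TRUE)],
                                 use.names = FALSE)
  bl <- array(NA_real_, c(ncol(X), k, n_boot))
  yl <- array(NA_real_, c(ncol(Y), k, n_boot))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      for (try in 1:10) {
        idx <- draw_rows()
        Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
        ok <- all(apply(Xb, 2, stats::sd) > 0) &&
              all(apply(Yb, 2, stats::sd) > 0)
        if (ok) break
      }
      if (!ok) stop("degenerate bootstrap resample after 10 retries")
      fit <- pls_fit(Xb, Yb)
      for (i in seq_len(k)) {
        if (sum(fit$U[, i] * orig$U[, i]) < 0) {
          fit$U[, i] <- -fit$U[, i]; fit$V[, i] <- -fit$V[, i]
          fit$brain_loadings[, i] <- -fit$brain_loadings[, i]
          fit$behavior_loadings[, i] <- -fit$behavior_loadings[, i]
        }
      }
      bl[, , b] <- fit$brain_loadings
      yl[, , b] <- fit$behavior_loadings
    }
  })
  ci <- function(a) {
    out <- array(NA_real_, c(dim(a)[1], dim(a)[2], 2),
                 dimnames = list(NULL, NULL, c("lo", "hi")))
    for (i in seq_len(dim(a)[1])) for (j in seq_len(dim(a)[2]))
      out[i, j, ] <- stats::quantile(a[i, j, ], c(0.025, 0.975),
                                     names = FALSE)
    out
  }
  list(brain_ci = ci(bl), behavior_ci = ci(yl),
       brain_draws = bl, behavior_draws = yl)
}

#' Latent score correlations overall and per group
#'
#' Pearson correlation between the brain and behavior scores of each
#' latent component, computed over all rows and within each group's rows.
#'
#' @param result a [pls_fit()] result.
#' @param groups length-n group labels.
#' @return data.table: `group` (including `"Overall"`), `lc`, `r`.
#' @export
per_group_expression <- function(result, groups) {
  stopifnot(inherits(result, "pls_result"))
  k <- length(result$s)
  rows <- list()
  grps <- c("Overall", unique(as.character(groups)))
  for (g in grps) {
    i <- if (g == "Overall") seq_len(result$n) else which(groups == g)
    if (g != "Overall" && length(i) < 3L)
      stop("group ", g, " has fewer than 3 rows")
    for (lc in seq_len(k))
      rows[[paste(g, lc)]] <- data.table::data.table(
        group = g, lc = lc,
        r = stats::cor(result$Lx[i, lc], result$Ly[i, lc]))
  }
  data.table::rbindlist(rows)
}

#' Full behavioral PLS analysis
#'
#' Convenience wrapper: residualizes the brain matrix on age, sex and
#' subject, z-scores both matrices within training groups, fits the PLS,
#' and runs the permutation and bootstrap inference.
#'
#' @param X raw brain-change matrix (n x p, complete cases).
#' @param Y raw behavior-change matrix (n x q).
#' @param groups training-module label per row.
#' @param age,sex,subject covariates per row.
#' @param n_perm,n_boot inference sizes.
#' @param seed integer seed.
#' @param within_group_perm permute within groups.
#' @return A `pls_result` augmented with `perm_p`, `perm_q`, `boot`
#'   (loading CIs) and `expression` (per-group score correlations).
#' @export
behavioral_pls <- function(X, Y, groups, age, sex, subject,
                           n_perm = 1000, n_boot = 100, seed = 1L,
                           within_group_perm = FALSE) {
  Xr <- residualize_brain(X, age, sex, subject)
  Xn <- normalize_within_group(Xr, groups)
  Yn <- normalize_within_group(as.matrix(Y), groups)
  fit <- pls_fit(Xn, Yn)
  perm <- permutation_test(Xn, Yn, n_perm = n_perm, seed = seed,
                           groups = groups, within_group = within_group_perm)
  fit$perm_p <- perm$p
  fit$perm_q <- perm$q
  fit$boot <- bootstrap_loadings(Xn, Yn, n_boot = n_boot, seed = seed + 1L,
                                 subject = subject)
  fit$expression <- per_group_expression(fit, groups)
  fit
}
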