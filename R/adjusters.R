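# Pairwise batch-effect adjusters.
#
# All three back-ends share the location/scale model
#   y_fj = alpha_f + x_j' beta_f + gamma_{b(j),f} + delta_{b(j),f} e_fj
# for feature f, sample j in batch b(j), with categorical covariates in x_j.
# Moments are always taken over observed entries only, with per-feature
# per-batch observed counts replacing n in every estimator, so arbitrary
# missingness is tolerated as long as each (feature, batch) block holds
# either none or at least two numeric values.

EB_TOL <- 1e-6
EB_MAX_ITER <- 100L

# ---- linear (limma-style) -------------------------------------------------

# OLS correction for any number of batches. Features whose observation
# pattern spans fewer than two batches are returned unchanged. Only the
# batch-term contribution of the fit is subtracted; intercept and covariate
# contributions are retained.
linear_adjust <- function(Y, batch, covdata = NULL) {
  obs <- !is.na(Y)
  grp <- vctrs::vec_group_id(as.data.frame(obs))
  out <- Y
  for (g in unique(grp)) {
    rows <- which(grp == g)
    s <- obs[rows[1L], ]
    if (!any(s)) next
    bs <- batch[s]
    counts <- table(bs)
    if (any(counts == 1L)) {
      abort("internal: singleton (feature, batch) block reached the linear adjuster; run remove_singletons first.")
    }
    if (length(counts) < 2L) next  # propagate: batch effect unidentifiable
    Xb <- batch_contrast_cols(bs)
    Xc <- covariate_cols_matrix(if (is.null(covdata)) NULL else covdata[s, , drop = FALSE])
    X <- cbind(`(Intercept)` = 1, Xb, Xc)
    qr_x <- check_full_rank(X, "linear-model design")
    Ys <- t(Y[rows, s, drop = FALSE])
    coef <- qr.coef(qr_x, Ys)
    batch_part <- Xb %*% coef[colnames(Xb), , drop = FALSE]
    out[rows, s] <- t(Ys - batch_part)
  }
  out
}

# ---- ComBat-style empirical Bayes ----------------------------------------

# Parametric empirical-Bayes location/scale adjustment for exactly two
# batches. `Y` must contain only eligible features (>= 2 numeric values per
# batch). Returns list(values, skipped) where `skipped` indexes features
# propagated because their pooled residual variance was zero.
combat_adjust <- function(Y, batch, covdata = NULL) {
  f <- factor(batch, levels = unique(batch))
  stopifnot(nlevels(f) == 2L)
  n_feat <- nrow(Y)
  Xb <- stats::model.matrix(~ f - 1)
  colnames(Xb) <- paste0("batch_", levels(f))
  Xc <- covariate_cols_matrix(covdata)
  X <- cbind(Xb, Xc)
  check_full_rank(X, "batch/covariate design")
  coef <- fit_ols_patterns(Y, X, "batch/covariate design")

  obs <- !is.na(Y)
  cols1 <- which(f == levels(f)[1L])
  cols2 <- which(f == levels(f)[2L])
  n1 <- rowSums(obs[, cols1, drop = FALSE])
  n2 <- rowSums(obs[, cols2, drop = FALSE])
  n_tot <- n1 + n2

  fitted <- t(X %*% coef)            # features x samples
  alpha <- (n1 * coef[1L, ] + n2 * coef[2L, ]) / n_tot
  batch_means <- t(Xb %*% coef[seq_len(2L), , drop = FALSE])
  stand_mean <- fitted - batch_means + alpha
  resid <- Y - fitted
  var_pooled <- rowSums(resid^2, na.rm = TRUE) / n_tot

  # scale-aware zero test: exact zeros surface as ~1e-31 after the QR fit
  tiny <- 1e-12 * (1 + rowMeans(Y^2, na.rm = TRUE))
  skipped <- which(var_pooled <= tiny)
  if (length(skipped)) {
    warn(paste0(length(skipped),
                " feature(s) with zero pooled variance propagated unchanged."))
    if (length(skipped) == n_feat) {
      return(list(values = Y, skipped = skipped))
    }
  }
  keep <- setdiff(seq_len(n_feat), skipped)
  Yk <- Y[keep, , drop = FALSE]
  sm <- stand_mean[keep, , drop = FALSE]
  sdp <- sqrt(var_pooled[keep])
  z <- (Yk - sm) / sdp

  if (length(keep) < 2L) {
    abort("empirical-Bayes priors need at least 2 eligible features.")
  }

  out <- Yk
  for (i in 1:2) {
    cols <- if (i == 1L) cols1 else cols2
    zi <- z[, cols, drop = FALSE]
    ni <- rowSums(!is.na(zi))
    gamma_hat <- rowMeans(zi, na.rm = TRUE)
    delta_hat <- rowSums((zi - gamma_hat)^2, na.rm = TRUE) / (ni - 1)
    g_bar <- mean(gamma_hat)
    t2 <- var(gamma_hat)
    m <- mean(delta_hat)
    s2 <- var(delta_hat)
    if (!is.finite(t2) || t2 <= 0 || !is.finite(s2) || s2 <= 0) {
      abort("empirical-Bayes prior estimation failed: no variation across features.")
    }
    aprior <- (2 * s2 + m^2) / s2
    bprior <- (m * s2 + m^3) / s2
    post <- eb_posterior(zi, gamma_hat, delta_hat, ni, g_bar, t2, aprior, bprior)
    out[, cols] <- (zi - post$gamma_star) / sqrt(post$delta_star)
  }
  out <- out * sdp + sm
  res <- Y
  res[keep, ] <- out
  list(values = res, skipped = skipped)
}

# Iterative joint posterior solution for the EB location (normal prior) and
# scale (inverse-gamma prior) parameters, vectorized over features.
eb_posterior <- function(zi, gamma_hat, delta_hat, ni, g_bar, t2,
                         aprior, bprior) {
  g_old <- gamma_hat
  d_old <- delta_hat
  for (iter in seq_len(EB_MAX_ITER)) {
    g_new <- (t2 * ni * gamma_hat + d_old * g_bar) / (t2 * ni + d_old)
    sum2 <- rowSums((zi - g_new)^2, na.rm = TRUE)
    d_new <- (0.5 * sum2 + bprior) / (ni / 2 + aprior - 1)
    change <- max(abs(g_new - g_old), abs(d_new - d_old))
    g_old <- g_new
    d_old <- d_new
    if (change < EB_TOL) break
  }
  list(gamma_star = g_old, delta_star = d_old)
}

# ---- reference-based ------------------------------------------------------

# Estimate the batch shift on reference samples only (OLS, sum-to-zero batch
# coding, optional covariates of the references), then subtract the same
# per-batch shift from every sample of the pair. `Y` must contain only
# eligible features (>= 2 numeric reference values per batch).
reference_adjust <- function(Y, batch, is_ref, covdata = NULL) {
  f <- factor(batch, levels = unique(batch))
  stopifnot(nlevels(f) == 2L)
  if (any(tapply(is_ref, f, sum) == 0)) {
    abort("each batch of a pair must contain at least one reference sample.")
  }
  refs <- which(is_ref)
  Yr <- Y[, refs, drop = FALSE]
  Xb_ref <- batch_contrast_cols(as.character(f[refs]), levels = levels(f))
  Xc_ref <- covariate_cols_matrix(if (is.null(covdata)) NULL else covdata[refs, , drop = FALSE])
  X <- cbind(`(Intercept)` = 1, Xb_ref, Xc_ref)
  coef <- fit_ols_patterns(Yr, X, "reference design")
  gamma <- coef["batch1", ]                 # shift coefficient per feature
  x_all <- batch_contrast_cols(as.character(f), levels = levels(f))[, 1L]
  Y - outer(gamma, x_all)
}
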