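# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the vectorized implementation.

# Pairwise-complete rescaled Euclidean distance, double loop.
naive_dist <- function(values) {
  n <- ncol(values)
  f_total <- nrow(values)
  d <- matrix(0, n, n, dimnames = list(colnames(values), colnames(values)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- which(!is.na(values[, i]) & !is.na(values[, j]))
      stopifnot(length(shared) > 0)
      ss <- sum((values[shared, i] - values[shared, j])^2)
      d[i, j] <- sqrt(ss * f_total / length(shared))
    }
  }
  d
}

# Textbook silhouette from a distance matrix, loops only.
naive_asw <- function(d, grouping) {
  keep <- !is.na(grouping)
  d <- d[keep, keep, drop = FALSE]
  g <- as.character(grouping[keep])
  s <- numeric(length(g))
  for (i in seq_along(g)) {
    own <- setdiff(which(g == g[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- Inf
    for (h in setdiff(unique(g), g[i])) {
      b <- min(b, mean(d[i, which(g == h)]))
    }
    s[i] <- (b - a) / max(a, b)
    if (!is.finite(s[i])) s[i] <- 0
  }
  mean(s)
}

# Per-feature OLS batch correction via stats::lm with sum-to-zero batch
# contrasts; subtracts the fitted batch term only.
naive_linear_correct <- function(values, batch, covdata = NULL) {
  out <- values
  bf <- factor(batch, levels = unique(batch))
  for (f in seq_len(nrow(values))) {
    y <- values[f, ]
    obs <- which(!is.na(y))
    dat <- data.frame(y = y[obs], batch = droplevels(bf[obs]))
    if (nlevels(dat$batch) < 2) next
    form <- y ~ batch
    if (!is.null(covdata)) {
      for (cv in names(covdata)) dat[[cv]] <- factor(covdata[[cv]][obs])
      form <- stats::as.formula(paste("y ~ batch +", paste(names(covdata), collapse = "+")))
    }
    fit <- stats::lm(form, data = dat, contrasts = list(batch = "contr.sum"))
    mm <- stats::model.matrix(fit)
    bcols <- grep("^batch", colnames(mm))
    out[f, obs] <- y[obs] - mm[, bcols, drop = FALSE] %*% stats::coef(fit)[bcols]
  }
  out
}

# Scalar transcription of the parametric empirical-Bayes location/scale
# adjustment for two batches, no covariates, complete or blockwise data.
naive_combat_pair <- function(values, batch, tol = 1e-6, max_iter = 100) {
  bf <- factor(batch, levels = unique(batch))
  stopifnot(nlevels(bf) == 2)
  idx <- split(seq_along(batch), bf)
  nfeat <- nrow(values)
  alpha <- numeric(nfeat); var_pooled <- numeric(nfeat)
  bm <- matrix(NA_real_, nfeat, 2)
  n_if <- matrix(0, nfeat, 2)
  for (f in seq_len(nfeat)) {
    for (i in 1:2) {
      v <- values[f, idx[[i]]]
      n_if[f, i] <- sum(!is.na(v))
      bm[f, i] <- mean(v, na.rm = TRUE)
    }
    alpha[f] <- (n_if[f, 1] * bm[f, 1] + n_if[f, 2] * bm[f, 2]) / sum(n_if[f, ])
    res2 <- 0
    for (i in 1:2) {
      v <- values[f, idx[[i]]]
      res2 <- res2 + sum((v - bm[f, i])^2, na.rm = TRUE)
    }
    var_pooled[f] <- res2 / sum(n_if[f, ])
  }
  z <- (values - alpha) / sqrt(var_pooled)
  out <- values
  for (i in 1:2) {
    cols <- idx[[i]]
    g_hat <- d_hat <- numeric(nfeat)
    for (f in seq_len(nfeat)) {
      zv <- z[f, cols]
      g_hat[f] <- mean(zv, na.rm = TRUE)
      d_hat[f] <- sum((zv - g_hat[f])^2, na.rm = TRUE) / (n_if[f, i] - 1)
    }
    g_bar <- mean(g_hat); t2 <- var(g_hat)
    m <- mean(d_hat); s2 <- var(d_hat)
    aprior <- (2 * s2 + m^2) / s2
    bprior <- (m * s2 + m^3) / s2
    g_old <- g_hat; d_old <- d_hat
    for (it in seq_len(max_iter)) {
      g_new <- d_new <- numeric(nfeat)
      for (f in seq_len(nfeat)) {
        ni <- n_if[f, i]
        g_new[f] <- (t2 * ni * g_hat[f] + d_old[f] * g_bar) / (t2 * ni + d_old[f])
        sum2 <- sum((z[f, cols] - g_new[f])^2, na.rm = TRUE)
        d_new[f] <- (0.5 * sum2 + bprior) / (ni / 2 + aprior - 1)
      }
      change <- max(abs(g_new - g_old), abs(d_new - d_old))
      g_old <- g_new; d_old <- d_new
      if (change < tol) break
    }
    for (f in seq_len(nfeat)) {
      out[f, cols] <- (z[f, cols] - g_old[f]) / sqrt(d_old[f]) *
        sqrt(var_pooled[f]) + alpha[f]
    }
  }
  out
}

# Small labelled matrix + metadata builders for toy cases.
toy_matrix <- function(values, n_features = NULL) {
  m <- if (is.matrix(values)) values else matrix(values, nrow = 1)
  rownames(m) <- paste0("f", seq_len(nrow(m)))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

toy_meta <- function(batch, label = NULL, is_reference = NULL, ...) {
  meta <- tibble::tibble(sample_id = paste0("s", seq_along(batch)),
                         batch = batch, ...)
  if (!is.null(label)) meta$label <- label
  if (!is.null(is_reference)) meta$is_reference <- is_reference
  meta
}
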