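# Hierarchical regression of reading skill on connectivity metrics, exact
# LMG relative-importance decomposition, and bootstrap contrasts between
# predictor importances.

nuisance_cols <- c("age_months", "latency_ms", "accuracy")

validate_subjects <- function(subjects) {
  req <- c("subject_id", nuisance_cols, "pde")
  if (!all(req %in% names(subjects)))
    stop2("subject table lacks column(s): ",
          paste(setdiff(req, names(subjects)), collapse = ", "))
  if (anyDuplicated(subjects$subject_id))
    stop2("duplicate subject_id in subject table")
  if (anyNA(subjects[req]))
    stop2("missing values in modeled subject columns")
  subjects
}

# R-squared of an OLS fit of y on X (with intercept), via QR.
rsq <- function(X, y) {
  fit <- stats::lm.fit(cbind(1, X), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

ols_table <- function(df, outcome, predictors) {
  f <- stats::as.formula(paste(outcome, "~",
                               paste(sprintf("`%s`", predictors), collapse = " + ")))
  fit <- stats::lm(f, data = df)
  if (any(is.na(stats::coef(fit))))
    stop2("predictors are rank deficient; collinear column(s): ",
          paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  sm <- summary(fit)
  co <- sm$coefficients
  n <- nrow(df)
  dfres <- fit$df.residual
  # standardized beta: coefficient of the z-scored predictor on z-scored outcome
  sds <- vapply(df[predictors], stats::sd, numeric(1))
  beta_std <- co[-1, "Estimate"] * sds / stats::sd(df[[outcome]])
  # signed partial correlation of each predictor with the outcome given the rest
  tvals <- co[-1, "t value"]
  partial_r <- tvals / sqrt(tvals^2 + dfres)
  coef_table <- data.frame(
    term = rownames(co),
    B = co[, "Estimate"], SE = co[, "Std. Error"],
    beta = c(NA, beta_std),
    association = c(NA, partial_r),        # signed partial r (see docs)
    association_sq = c(NA, partial_r^2),
    p = co[, "Pr(>|t|)"],
    row.names = NULL)
  fstat <- sm$fstatistic
  list(fit = fit,
       coef = coef_table,
       r2 = sm$r.squared,
       adj_r2 = sm$adj.r.squared,
       F = unname(fstat[1]), df1 = unname(fstat[2]), df2 = unname(fstat[3]),
       p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
       n = n)
}

#' Two-step hierarchical regression of reading skill on network metrics
#'
#' Step 1 regresses the pseudo-word decoding efficiency (PDE) outcome on the
#' nuisance variables (age in months, task response latency, task accuracy);
#' step 2 adds the nine connectivity predictors (three measures x three
#' presentation modalities) for one thresholding scheme. The step-2 increment
#' is tested with the nested F statistic
#' \eqn{F = ((R^2_2 - R^2_1)/q) / ((1 - R^2_2)/df_2)}.
#'
#' Each step's table reports the raw coefficient B with its SE, the
#' standardized beta, and — as the per-predictor association column — the
#' signed partial correlation of the predictor with the outcome given all
#' other terms in that step (its square is reported alongside).
#'
#' @param subjects Subject table with subject_id, age_months, accuracy,
#'   latency_ms, pde.
#' @param metrics Winsorized subject-level metrics table (long format from
#'   [winsorize_metrics()]), or an already-wide table from [metrics_wide()].
#' @param scheme Thresholding scheme to model ("significance" or "mcc").
#' @return A `hierarchical_fit` list: `step1`, `step2` (each with coef table,
#'   R2, adjusted R2, overall F/df/p), `delta` (nested F, df, p, delta R2)
#'   and `data` (the merged modeling frame).
#' @export
fit_hierarchical <- function(subjects, metrics, scheme = c("significance", "mcc")) {
  scheme <- match.arg(scheme)
  subjects <- validate_subjects(subjects)
  wide <- if (!is.null(metrics$scheme)) metrics_wide(metrics, scheme) else metrics
  df <- merge(subjects, wide, by = "subject_id")
  if (nrow(df) < nrow(subjects))
    stop2("metrics table lacks rows for some subjects")
  conn_cols <- setdiff(names(wide), "subject_id")
  n <- nrow(df)
  p_total <- length(nuisance_cols) + length(conn_cols)
  if (n <= p_total + 1L)
    stop2(sprintf("need n > %d subjects for %d predictors; have %d",
                  p_total + 1L, p_total, n))

  step1 <- ols_table(df, "pde", nuisance_cols)
  step2 <- ols_table(df, "pde", c(nuisance_cols, conn_cols))

  q <- length(conn_cols)
  df2 <- step2$fit$df.residual
  f_delta <- ((step2$r2 - step1$r2) / q) / ((1 - step2$r2) / df2)
  delta <- list(F = f_delta, df1 = q, df2 = df2,
                p = stats::pf(f_delta, q, df2, lower.tail = FALSE),
                delta_r2 = step2$r2 - step1$r2)
  structure(list(step1 = step1, step2 = step2, delta = delta,
                 scheme = scheme, connectivity_predictors = conn_cols,
                 data = df),
            class = "hierarchical_fit")
}

#' @export
print.hierarchical_fit <- function(x, ...) {
  cat(sprintf("<hierarchical_fit> scheme = %s, n = %d\n", x$scheme, x$step1$n))
  cat(sprintf("  step 1 (nuisance): F(%d,%d) = %.2f, p = %.3f, adjR2 = %.3f\n",
              x$step1$df1, x$step1$df2, x$step1$F, x$step1$p, x$step1$adj_r2))
  cat(sprintf("  step 2 (+9 metrics): F(%d,%d) = %.2f, p = %.3f, adjR2 = %.3f\n",
              x$step2$df1, x$step2$df2, x$step2$F, x$step2$p, x$step2$adj_r2))
  cat(sprintf("  increment: F(%d,%d) = %.2f, p = %.3f\n",
              x$delta$df1, x$delta$df2, x$delta$F, x$delta$p))
  invisible(x)
}

#' Exact LMG relative-importance decomposition
#'
#' The LMG share of predictor k is its sequential contribution to the model
#' R-squared averaged over all orderings of the predictors, computed exactly
#' through the subset identity: a weighted sum over all subsets S not
#' containing k of \eqn{R^2(S \cup k) - R^2(S)} with weight
#' \eqn{|S|!\,(p-1-|S|)!/p!}. Shares are nonnegative and sum to the
#' full-model R-squared. Exact enumeration over \eqn{2^p} subsets; p is
#' capped at 20.
#'
#' @param y Outcome vector.
#' @param X Numeric predictor matrix (columns named).
#' @param normalized Also return shares rescaled to sum to 1.
#' @return An `importance_result`: data.frame `shares` (predictor, lmg,
#'   lmg_normalized) plus `r2` of the full model.
#' @export
lmg_importance <- function(y, X, normalized = FALSE) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 1L) stop2("need at least one predictor")
  if (p > 20L) stop2("exact LMG enumeration capped at 20 predictors; got ", p)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  # R^2 for every subset, via normal equations on the correlation matrix.
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  Sxx <- crossprod(Xc)
  Sxy <- crossprod(Xc, yc)
  Syy <- sum(yc^2)
  n_sub <- bitwShiftL(1L, p)
  r2s <- numeric(n_sub)                   # r2s[mask + 1]
  bits <- bitwShiftL(1L, seq_len(p) - 1L)
  for (mask in seq_len(n_sub - 1L)) {
    idx <- which(bitwAnd(mask, bits) > 0L)
    sol <- tryCatch(solve(Sxx[idx, idx, drop = FALSE], Sxy[idx, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(sol)) {
      # singular subset: use pseudo-inverse projection
      sol <- qr.coef(qr(Xc[, idx, drop = FALSE]), yc)
      sol[is.na(sol)] <- 0
      sol <- matrix(sol, ncol = 1)
    }
    r2s[mask + 1L] <- sum(Sxy[idx] * sol) / Syy
  }

  sizes <- vapply(0:(n_sub - 1L), function(m) sum(bitwAnd(m, bits) > 0L),
                  numeric(1))
  lf <- lgamma(1:(p + 1L))                # lf[k+1] = log(k!)
  # weight for subset size s in 0..p-1: s! (p-1-s)! / p!
  w_by_size <- exp(lf[(0:(p - 1L)) + 1L] + lf[(p - 1L - (0:(p - 1L))) + 1L] - lf[p + 1L])

  shares <- numeric(p)
  for (k in seq_len(p)) {
    bk <- bits[k]
    without_k <- which(bitwAnd(0:(n_sub - 1L), bk) == 0L) - 1L
    s <- sizes[without_k + 1L]
    gain <- r2s[without_k + bk + 1L] - r2s[without_k + 1L]
    shares[k] <- sum(w_by_size[s + 1L] * gain)
  }
  res <- data.frame(predictor = colnames(X), lmg = shares,
                    lmg_normalized = if (sum(shares) > 0) shares / sum(shares) else NA_real_)
  structure(list(shares = res, r2 = r2s[n_sub], normalized = normalized),
            class = "importance_result")
}

# LMG shares of the connectivity predictors within the full model
# (nuisance + connectivity), returned as a named vector.
conn_lmg_shares <- function(df, conn_cols) {
  X <- as.matrix(df[, c(nuisance_cols, conn_cols)])
  imp <- lmg_importance(df$pde, X)
  stats::setNames(imp$shares$lmg, imp$shares$predictor)[conn_cols]
}

# The two contrast layouts: within-metric-across-modalities and
# within-modality-across-metrics.
contrast_pairs <- function(conn_cols) {
  split_cols <- strsplit(conn_cols, "_", fixed = TRUE)
  modality <- vapply(split_cols, `[`, "", 1L)
  metric <- vapply(split_cols, function(x) paste(x[-1], collapse = "_"), "")
  pairs <- list()
  for (m in unique(metric)) {
    mods <- modality[metric == m]
    if (length(mods) >= 2L)
      for (cmb in utils::combn(mods, 2L, simplify = FALSE))
        pairs[[length(pairs) + 1L]] <- data.frame(
          layout = "within_metric", group = m,
          a = paste(cmb[1], m, sep = "_"), b = paste(cmb[2], m, sep = "_"))
  }
  for (mo in unique(modality)) {
    mets <- metric[modality == mo]
    if (length(mets) >= 2L)
      for (cmb in utils::combn(mets, 2L, simplify = FALSE))
        pairs[[length(pairs) + 1L]] <- data.frame(
          layout = "within_modality", group = mo,
          a = paste(mo, cmb[1], sep = "_"), b = paste(mo, cmb[2], sep = "_"))
  }
  do.call(rbind, pairs)
}

#' Bootstrap contrasts between LMG importances of connectivity predictors
#'
#' Resamples subjects with replacement, recomputes the exact LMG shares of
#' the full model on every resample, and reports percentile confidence
#' intervals for the pairwise share differences in two layouts: same metric
#' across presentation modalities, and same modality across metrics. A
#' contrast is flagged significant when its CI excludes zero. Degenerate
#' (rank-deficient) resamples are redrawn and counted.
#'
#' @param fit A [fit_hierarchical()] result.
#' @param B Number of bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @param normalized Contrast normalized (sum-to-1) shares instead of raw
#'   (sum-to-R-squared) shares.
#' @return Data frame: layout, group, contrast, difference (point estimate on
#'   the original sample), ci_lo, ci_hi, significant; attribute `n_redrawn`.
#' @export
importance_contrasts <- function(fit, B = 1000L, conf = 0.95, seed = 1L,
                                 normalized = FALSE) {
  stopifnot(inherits(fit, "hierarchical_fit"))
  df <- fit$data
  conn_cols <- fit$connectivity_predictors
  n <- nrow(df)
  pairs <- contrast_pairs(conn_cols)

  get_shares <- function(d) {
    X <- as.matrix(d[, c(nuisance_cols, conn_cols)])
    imp <- lmg_importance(d$pde, X)
    sh <- stats::setNames(imp$shares$lmg, imp$shares$predictor)[conn_cols]
    if (normalized) sh / sum(stats::setNames(imp$shares$lmg, NULL)) else sh
  }
  point <- get_shares(df)

  boot <- matrix(NA_real_, B, length(conn_cols),
                 dimnames = list(NULL, conn_cols))
  n_redrawn <- 0L
  with_seed(derive_seed(seed, "bootstrap"), {
    b <- 1L
    while (b <= B) {
      idx <- sample.int(n, n, replace = TRUE)
      d <- df[idx, , drop = FALSE]
      Xb <- as.matrix(d[, c(nuisance_cols, conn_cols)])
      ok <- qr(cbind(1, scale(Xb, scale = FALSE)))$rank == ncol(Xb) + 1L &&
        stats::sd(d$pde) > 0
      if (!ok) { n_redrawn <- n_redrawn + 1L; next }
      boot[b, ] <- get_shares(d)
      b <- b + 1L
    }
  })

  lo <- (1 - conf) / 2
  out <- pairs
  out$contrast <- paste(out$a, "-", out$b)
  out$difference <- point[out$a] - point[out$b]
  diffs <- boot[, out$a, drop = FALSE] - boot[, out$b, drop = FALSE]
  cis <- t(vapply(seq_len(nrow(out)), function(i)
    stats::quantile(diffs[, i], probs = c(lo, 1 - lo), names = FALSE),
    numeric(2)))
  out$ci_lo <- cis[, 1]
  out$ci_hi <- cis[, 2]
  out$significant <- out$ci_lo > 0 | out$ci_hi < 0
  rownames(out) <- NULL
  out <- out[c("layout", "group", "contrast", "difference", "ci_lo", "ci_hi",
               "significant")]
  attr(out, "n_redrawn") <- n_redrawn
  out
}

#' Cohort-level behavioral summary
#'
#' @param subjects Subject table.
#' @return List with mean and range of task accuracy and response latency.
#' @export
behavioral_summary <- function(subjects) {
  subjects <- validate_subjects(subjects)
  list(accuracy_mean = mean(subjects$accuracy),
       accuracy_range = range(subjects$accuracy),
       latency_mean = mean(subjects$latency_ms),
       latency_range = range(subjects$latency_ms),
       n = nrow(subjects))
}
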