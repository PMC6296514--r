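# Fixture: a subject table plus wide metrics with known generating model.
make_subjects <- function(n = 24, seed = 1) {
  withr::with_seed(seed, data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    age_months = round(runif(n, 94, 164)),
    accuracy = round(runif(n, 0.51, 0.85), 3),
    latency_ms = round(runif(n, 900, 1863)),
    pde = rnorm(n, 90, 9)))
}

make_wide_metrics <- function(n = 24, seed = 2) {
  cols <- as.vector(outer(c("VV", "AV", "AA"),
                          c("modularity", "transitivity", "global_efficiency"),
                          paste, sep = "_"))
  withr::with_seed(seed, {
    out <- data.frame(subject_id = sprintf("s%02d", seq_len(n)))
    for (cl in cols) out[[cl]] <- runif(n, 0.1, 0.9)
    out
  })
}

test_that("a noiseless linear outcome is recovered exactly at step 2", {
  subj <- make_subjects()
  wide <- make_wide_metrics()
  betas <- c(VV_modularity = 3, AA_transitivity = -2, AV_global_efficiency = 5)
  subj$pde <- 80 + 0.1 * subj$age_months +
    as.matrix(wide[names(betas)]) %*% betas
  fit <- suppressWarnings(fit_hierarchical(subj, wide))
  expect_equal(fit$step2$r2, 1, tolerance = 1e-8)
  co <- fit$step2$coef
  expect_equal(co$B[co$term == "VV_modularity"], 3, tolerance = 1e-8)
  expect_equal(co$B[co$term == "AA_transitivity"], -2, tolerance = 1e-8)
  expect_equal(co$B[co$term == "AV_global_efficiency"], 5, tolerance = 1e-8)
  expect_equal(co$B[co$term == "age_months"], 0.1, tolerance = 1e-8)
})

test_that("nested F from the R2 identity equals the RSS formulation and anova", {
  subj <- make_subjects(seed = 5)
  wide <- make_wide_metrics(seed = 6)
  fit <- fit_hierarchical(subj, wide)
  # RSS formulation
  rss1 <- sum(residuals(fit$step1$fit)^2)
  rss2 <- sum(residuals(fit$step2$fit)^2)
  q <- fit$delta$df1; df2 <- fit$delta$df2
  f_rss <- ((rss1 - rss2) / q) / (rss2 / df2)
  expect_equal(fit$delta$F, f_rss, tolerance = 1e-10)
  av <- anova(fit$step1$fit, fit$step2$fit)
  expect_equal(fit$delta$F, av$F[2], tolerance = 1e-10)
  expect_equal(fit$delta$p, av$`Pr(>F)`[2], tolerance = 1e-10)
  # adjusted R2 identity
  n <- nrow(subj); p2 <- 12
  expect_equal(fit$step2$adj_r2,
               1 - (1 - fit$step2$r2) * (n - 1) / (n - p2 - 1),
               tolerance = 1e-12)
  expect_gte(fit$step2$r2, fit$step1$r2)
})

test_that("standardized betas and partial correlations match direct computation", {
  subj <- make_subjects(seed = 9)
  wide <- make_wide_metrics(seed = 10)
  fit <- fit_hierarchical(subj, wide)
  df <- fit$data
  zfit <- lm(scale(pde) ~ scale(age_months) + scale(latency_ms) + scale(accuracy),
             data = df)
  expect_equal(unname(fit$step1$coef$beta[-1]), unname(coef(zfit)[-1]),
               tolerance = 1e-10)
  # partial r of age given the other nuisance terms, by residualization
  r_y <- residuals(lm(pde ~ latency_ms + accuracy, df))
  r_x <- residuals(lm(age_months ~ latency_ms + accuracy, df))
  expect_equal(fit$step1$coef$association[fit$step1$coef$term == "age_months"],
               cor(r_y, r_x), tolerance = 1e-10)
})

test_that("rank-deficient or undersized designs are hard errors", {
  subj <- make_subjects()
  wide <- make_wide_metrics()
  wide$AA_modularity <- wide$VV_modularity   # collinear
  expect_error(fit_hierarchical(subj, wide), "rank deficient|collinear")
  expect_error(fit_hierarchical(make_subjects(n = 12),
                                make_wide_metrics(n = 12)), "need n >")
})

test_that("LMG shares: base cases and exact properties", {
  withr::with_seed(11, {
    x1 <- rnorm(40); y <- 2 * x1 + rnorm(40)
  })
  # single predictor: share equals model R2
  imp1 <- lmg_importance(y, cbind(x1 = x1))
  expect_equal(imp1$shares$lmg, imp1$r2, tolerance = 1e-12)
  expect_equal(imp1$r2, summary(lm(y ~ x1))$r.squared, tolerance = 1e-12)

  # duplicated predictors split their joint contribution equally
  imp2 <- lmg_importance(y, cbind(a = x1, b = x1))
  expect_equal(imp2$shares$lmg[1], imp2$shares$lmg[2], tolerance = 1e-10)
  expect_equal(sum(imp2$shares$lmg), imp2$r2, tolerance = 1e-10)
})

test_that("orthogonal predictors get closed-form shares r1^2, r2^2", {
  withr::with_seed(12, {
    z1 <- scale(rnorm(60), scale = FALSE)
    z2 <- residuals(lm(rnorm(60) ~ z1))     # centered, exactly uncorrelated
    x <- cbind(as.vector(z1), as.vector(z2))
    y <- 0.8 * x[, 1] - 0.4 * x[, 2] + rnorm(60, 0, 0.6)
  })
  expect_equal(cor(x[, 1], x[, 2]), 0, tolerance = 1e-12)
  imp <- lmg_importance(y, cbind(p1 = x[, 1], p2 = x[, 2]))
  expect_equal(imp$shares$lmg[1], cor(y, x[, 1])^2, tolerance = 1e-10)
  expect_equal(imp$shares$lmg[2], cor(y, x[, 2])^2, tolerance = 1e-10)
  # verified independently by averaging the two orderings
  r2_1 <- summary(lm(y ~ x[, 1]))$r.squared
  r2_2 <- summary(lm(y ~ x[, 2]))$r.squared
  r2_12 <- summary(lm(y ~ x))$r.squared
  expect_equal(imp$shares$lmg[1],
               mean(c(r2_1, r2_12 - r2_2)), tolerance = 1e-10)
})

test_that("LMG shares are nonnegative, order-invariant and sum to R2", {
  withr::with_seed(13, {
    X <- matrix(rnorm(30 * 6), 30)
    colnames(X) <- paste0("v", 1:6)
    y <- X %*% runif(6, -1, 1) + rnorm(30)
  })
  imp <- lmg_importance(y, X)
  expect_true(all(imp$shares$lmg >= -1e-12))
  expect_equal(sum(imp$shares$lmg), imp$r2, tolerance = 1e-10)
  perm <- c(4, 2, 6, 1, 3, 5)
  imp_p <- lmg_importance(y, X[, perm])
  expect_equal(imp_p$shares$lmg[match(colnames(X), imp_p$shares$predictor)],
               imp$shares$lmg, tolerance = 1e-12)
  expect_error(lmg_importance(y, matrix(rnorm(30 * 21), 30)), "capped at 20")
})

test_that("bootstrap contrasts: exchangeable predictors are not flagged", {
  # two connectivity predictors with identical relationships to the outcome
  n <- 40
  subj <- make_subjects(n = n, seed = 21)
  withr::with_seed(22, {
    wide <- data.frame(subject_id = subj$subject_id,
                       VV_modularity = rnorm(n), AV_modularity = rnorm(n))
    subj$pde <- wide$VV_modularity + wide$AV_modularity + rnorm(n, 0, 1.5)
  })
  fit <- fit_hierarchical(subj, wide)
  ct <- importance_contrasts(fit, B = 400, seed = 3)
  row <- ct[grepl("AV_modularity", ct$contrast) &
            grepl("VV_modularity", ct$contrast), ]
  expect_equal(nrow(row), 1)
  expect_false(row$significant)
  expect_true(row$ci_lo <= 0 && row$ci_hi >= 0)
})

test_that("bootstrap contrasts detect a dominant planted predictor", {
  # one predictor carries the outcome; its contrasts should exclude zero
  n <- 200
  subj <- make_subjects(n = n, seed = 31)
  withr::with_seed(32, {
    wide <- data.frame(subject_id = subj$subject_id,
                       VV_modularity = rnorm(n), AV_modularity = rnorm(n),
                       AA_modularity = rnorm(n))
    subj$pde <- 3 * wide$AV_modularity + rnorm(n)
  })
  fit <- fit_hierarchical(subj, wide)
  ct <- importance_contrasts(fit, B = 400, seed = 4)
  dom <- ct[grepl("AV_modularity", ct$contrast), ]
  expect_true(all(dom$significant))
  null_row <- ct[grepl("AA_modularity", ct$contrast) &
                 grepl("VV_modularity", ct$contrast), ]
  expect_false(null_row$significant)
})

test_that("contrasts are reproducible given the seed and count redraws", {
  subj <- make_subjects(seed = 41)
  wide <- make_wide_metrics(seed = 42)
  fit <- fit_hierarchical(subj, wide)
  c1 <- importance_contrasts(fit, B = 60, seed = 9)
  c2 <- importance_contrasts(fit, B = 60, seed = 9)
  expect_identical(c1, c2)
  expect_true(is.integer(attr(c1, "n_redrawn")))
  # both table layouts present with the expected pair counts
  expect_equal(sum(c1$layout == "within_metric"), 9)
  expect_equal(sum(c1$layout == "within_modality"), 9)
})

test_that("behavioral summary returns means and ranges", {
  subj <- make_subjects(n = 2, seed = 51)
  subj$accuracy <- c(0.5, 0.7)
  bs <- behavioral_summary(subj)
  expect_equal(bs$accuracy_mean, 0.6)
  expect_equal(bs$latency_mean, mean(subj$latency_ms))
  one <- behavioral_summary(make_subjects(n = 1, seed = 52))
  expect_equal(one$accuracy_mean, one$accuracy_range[1])
  expect_equal(one$n, 1)
})
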