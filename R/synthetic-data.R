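# Synthetic cohorts with planted modular covariance.
#
# The generator emulates the study design the pipeline targets: 24 subjects,
# three presentation-modality conditions (VV, AV, AA), two runs per condition,
# 43-node networks, ~200 time points per run (a ~6:45 run at TR = 2 s), and a
# participant-level reading-skill outcome generated linearly from the true
# (noiseless) network metrics plus Gaussian noise. Time points are i.i.d.
# draws from a zero-mean multivariate normal whose correlation matrix is
# block-structured: within_r inside planted communities and between_r across
# them, drawn per subject and modality, plus small per-pair heterogeneity
# (pair_jitter_sd) so that network metrics vary continuously across the
# cohort rather than as step functions of the block parameters.

#' Configuration of a synthetic cohort
#'
#' Defaults state the emulated study design. `within_r` and `between_r` may
#' each be a scalar, a length-`n_subjects` vector (recycled across
#' modalities), or `NULL` to be drawn uniformly per (subject, modality) from
#' the corresponding `*_range`; per-subject variation in the within/between
#' gap is what plants the individual differences the downstream regression
#' feeds on.
#'
#' @param n_subjects Number of subjects (default 24).
#' @param n_nodes Number of network nodes (default 43; use 154 for an
#'   outside-network cohort).
#' @param n_timepoints Time points per run (default 202).
#' @param n_runs_per_modality Runs per modality condition (default 2).
#' @param modalities Ordered modality labels (default VV, AV, AA).
#' @param n_modules Number of planted communities (default 4, mirroring the
#'   four anatomical regions a reading network divides into).
#' @param within_r Within-community target correlation(s); scalar,
#'   length-`n_subjects` vector, or `NULL` to draw from `within_r_range`.
#' @param within_r_range Uniform range for `within_r` draws (default
#'   c(0.45, 0.60), comfortably above the T = 202 significance boundary
#'   |r| ~ 0.138 so planted modules survive thresholding; kept narrow so the
#'   within/between gap is dominated by between-module variation).
#' @param between_r Between-community target correlation(s); scalar, vector,
#'   or `NULL` to draw from `between_r_range`.
#' @param between_r_range Uniform range for `between_r` draws (default
#'   c(0.05, 0.35), straddling the significance boundary so cross-module
#'   connectivity — and hence segregation — varies across the cohort).
#' @param pair_jitter_sd SD of seeded Gaussian heterogeneity added to each
#'   pairwise correlation before PSD repair (default 0.06, about one
#'   sampling-error unit at T = 202); set 0 for exact block structure.
#' @param outcome_intercept Outcome intercept (default 90.5, the cohort mean
#'   of the standardized pseudo-word decoding efficiency score).
#' @param outcome_betas Named numeric vector of linear weights on true
#'   metrics; names are `<modality>_<metric>`, e.g. `AV_modularity`. Default:
#'   a single positive weight of 20 on AV modularity.
#' @param outcome_noise_sd Residual SD of the outcome (default 5, chosen with
#'   the default beta so the planted model's population R-squared is near
#'   0.5).
#' @param ar1 Optional AR(1) coefficient for temporal autocorrelation
#'   (default 0 = i.i.d. across time; provided for robustness checks only).
#' @param seed Master integer seed; every (subject, modality, run) unit
#'   receives a distinct deterministic sub-seed derived from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 24L, n_nodes = 43L, n_timepoints = 202L,
                         n_runs_per_modality = 2L,
                         modalities = c("VV", "AV", "AA"),
                         n_modules = 4L,
                         within_r = NULL, within_r_range = c(0.45, 0.60),
                         between_r = NULL, between_r_range = c(0.05, 0.35),
                         pair_jitter_sd = 0.06,
                         outcome_intercept = 90.5,
                         outcome_betas = c(AV_modularity = 20),
                         outcome_noise_sd = 5,
                         ar1 = 0, seed = 1L) {
  if (n_modules < 1L || n_modules > n_nodes)
    stop2("n_modules must lie in [1, n_nodes]")
  for (v in list(within_r, between_r))
    if (!is.null(v) && !length(v) %in% c(1L, n_subjects))
      stop2("within_r / between_r must be NULL, scalar, or length n_subjects")
  rng <- c(if (is.null(within_r)) within_r_range else within_r,
           if (is.null(between_r)) between_r_range else between_r)
  if (any(rng <= -1) || any(rng >= 1))
    stop2("correlations must lie in (-1, 1)")
  if (!is.null(within_r) && !is.null(between_r) &&
      any(rep(between_r, length.out = n_subjects) >
          rep(within_r, length.out = n_subjects)))
    stop2("between_r must not exceed within_r")
  structure(
    list(n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
         n_timepoints = as.integer(n_timepoints),
         n_runs_per_modality = as.integer(n_runs_per_modality),
         modalities = as.character(modalities),
         n_modules = as.integer(n_modules),
         within_r = within_r, within_r_range = within_r_range,
         between_r = between_r, between_r_range = between_r_range,
         pair_jitter_sd = pair_jitter_sd,
         outcome_intercept = outcome_intercept,
         outcome_betas = outcome_betas,
         outcome_noise_sd = outcome_noise_sd,
         ar1 = ar1, seed = as.integer(seed)),
    class = "synth_config")
}

#' Block-structured correlation matrix with planted communities
#'
#' Entry (i, j) equals `within_r` when i and j share a module and `between_r`
#' otherwise, with unit diagonal. If that matrix is not positive
#' semi-definite it is shrunk toward the identity — the smallest convex
#' combination `(1 - s) * M + s * I` that is PSD — and the shrinkage `s` is
#' recorded in the `"shrinkage"` attribute (0 when no repair was needed).
#'
#' @param n_nodes Number of nodes.
#' @param module_assignment Integer vector mapping each node to its module.
#' @param within_r,between_r Target correlations inside / across modules.
#' @return Correlation matrix with attributes `shrinkage` and
#'   `module_assignment`.
#' @export
planted_covariance <- function(n_nodes, module_assignment, within_r, between_r) {
  if (length(module_assignment) != n_nodes)
    stop2("module_assignment must have one entry per node")
  same <- outer(module_assignment, module_assignment, "==")
  m <- ifelse(same, within_r, between_r)
  diag(m) <- 1
  ev_min <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  shrink <- 0
  if (ev_min < -1e-12) {
    # (1-s) ev_min + s >= 0  =>  s >= -ev_min / (1 - ev_min)
    shrink <- -ev_min / (1 - ev_min) + 1e-10
    if (shrink >= 1)
      stop2(sprintf("planted correlation matrix not repairable (within_r=%g, between_r=%g)",
                    within_r, between_r))
    m <- (1 - shrink) * m
    diag(m) <- 1
    ev2 <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    if (ev2 < -1e-12)
      stop2(sprintf("PSD repair failed (within_r=%g, between_r=%g)", within_r, between_r))
  }
  attr(m, "shrinkage") <- shrink
  attr(m, "module_assignment") <- as.integer(module_assignment)
  m
}

# Add seeded symmetric Gaussian heterogeneity to the off-diagonal entries,
# clip to (-0.99, 0.99), and project back to the PSD cone (eigenvalue clip +
# correlation rescale). Keeps the block structure recognizable while making
# each subject-modality structure unique.
jitter_correlations <- function(m, sd, seed) {
  if (sd == 0) return(m)
  n <- nrow(m)
  eps <- with_seed(seed, {
    e <- matrix(stats::rnorm(n * n, 0, sd), n, n)
    (e + t(e)) / 2
  })
  diag(eps) <- 0
  out <- pmin(pmax(unclass(m) + eps, -0.99), 0.99)
  es <- eigen(out, symmetric = TRUE)
  if (min(es$values) < 0) {
    out <- es$vectors %*% (pmax(es$values, 1e-8) * t(es$vectors))
    d <- sqrt(diag(out))
    out <- out / outer(d, d)
  }
  diag(out) <- 1
  attr(out, "module_assignment") <- attr(m, "module_assignment")
  out
}

#' Sample one run of node time series from a planted correlation matrix
#'
#' Draws `n_timepoints` i.i.d. (or AR(1)-correlated, if `ar1 != 0`)
#' zero-mean multivariate-normal samples with the given correlation matrix,
#' via its symmetric eigen square root (so positive *semi*-definite inputs
#' are valid). Bit-reproducible given `seed`.
#'
#' @param cov Symmetric PSD correlation/covariance matrix.
#' @param n_timepoints Number of time points (columns).
#' @param seed Integer seed.
#' @param ar1 AR(1) coefficient of the innovations process (default 0).
#' @param ... Identity fields passed to [run_time_series()].
#' @return A [run_time_series()].
#' @export
sample_run <- function(cov, n_timepoints, seed, ar1 = 0, ...) {
  check_square_symmetric(cov, "cov")
  n <- nrow(cov)
  if (n_timepoints < n + 3L)
    warning("n_timepoints < n_nodes + 3: downstream correlation significance unstable",
            call. = FALSE)
  es <- eigen(cov, symmetric = TRUE)
  if (min(es$values) < -1e-8) stop2("cov is not positive semi-definite")
  root <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
  x <- with_seed(seed, {
    z <- matrix(stats::rnorm(n * n_timepoints), nrow = n)
    if (ar1 != 0) {
      for (t in 2:n_timepoints)
        z[, t] <- ar1 * z[, t - 1] + sqrt(1 - ar1^2) * z[, t]
    }
    root %*% z
  })
  run_time_series(x, ...)
}

# True (noiseless) metrics of a subject-modality generating structure under
# the significance scheme: the planted correlation matrix is binarized
# exactly as an observed one would be, but without sampling noise.
true_structure_metrics <- function(cov, n_timepoints, alpha = 0.05, seed = 1L) {
  corr <- structure(list(values = unclass(cov), n_timepoints = n_timepoints),
                    class = "correlation_matrix")
  net <- significance_threshold(corr, alpha)
  network_metrics(net, seed = seed)
}

#' Generate a full synthetic cohort
#'
#' Produces one [run_time_series()] per subject x modality x run, a subject
#' table with nuisance regressors and the generated outcome, and a ground
#' truth record sufficient to recompute every subject's expected outcome.
#'
#' The outcome is `intercept + sum(outcome_betas * true metrics) + noise`,
#' where the true metrics are computed on each subject-modality noiseless
#' generating correlation matrix binarized by the significance rule (the
#' pipeline applied to the structure itself, with no sampling noise).
#' Nuisance columns are drawn uniformly from the emulated study's reported
#' ranges: age 94-164 months, accuracy 0.51-0.85, latency 900-1863 ms; they
#' carry no planted relation to the outcome.
#'
#' @param config A [synth_config()].
#' @return List with elements `runs` (list of `run_time_series`), `subjects`
#'   (data.frame: subject_id, age_months, accuracy, latency_ms, pde) and
#'   `ground_truth` (module assignment, per-subject x modality generating
#'   correlations with shrinkage and jitter seeds, true metrics, outcome
#'   model, nuisance ranges, config).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n_sub <- config$n_subjects
  subjects <- sprintf("s%02d", seq_len(n_sub))
  modules <- sort(rep(seq_len(config$n_modules), length.out = config$n_nodes))
  n_mod <- length(config$modalities)

  draw_param <- function(value, range, tag) {
    if (!is.null(value))
      matrix(rep(value, length.out = n_sub), n_sub, n_mod)
    else
      with_seed(derive_seed(config$seed, tag),
                matrix(stats::runif(n_sub * n_mod, range[1], range[2]),
                       n_sub, n_mod))
  }
  within <- draw_param(config$within_r, config$within_r_range, "within_r")
  between <- draw_param(config$between_r, config$between_r_range, "between_r")
  between <- pmin(between, within)   # per-draw ordering when ranges overlap

  runs <- vector("list", n_sub * n_mod * config$n_runs_per_modality)
  ri <- 0L
  metric_names <- c("modularity", "transitivity", "global_efficiency")
  true_metrics <- matrix(
    NA_real_, n_sub, 3L * n_mod,
    dimnames = list(subjects,
                    paste(rep(config$modalities, each = 3L), metric_names,
                          sep = "_")))
  gen_corr <- expand.grid(subject_id = subjects, modality = config$modalities,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gen_corr <- gen_corr[order(gen_corr$subject_id, match(gen_corr$modality, config$modalities)), ]
  rownames(gen_corr) <- NULL
  gen_corr$within_r <- NA_real_
  gen_corr$between_r <- NA_real_
  gen_corr$shrinkage <- NA_real_
  gen_corr$jitter_seed <- NA_integer_

  for (s in seq_len(n_sub)) {
    for (mi in seq_len(n_mod)) {
      mod <- config$modalities[mi]
      base_cov <- planted_covariance(config$n_nodes, modules,
                                     within[s, mi], between[s, mi])
      jseed <- derive_seed(config$seed, "jitter", subjects[s], mod)
      cov <- jitter_correlations(base_cov, config$pair_jitter_sd, jseed)
      row <- which(gen_corr$subject_id == subjects[s] & gen_corr$modality == mod)
      gen_corr$within_r[row] <- within[s, mi]
      gen_corr$between_r[row] <- between[s, mi]
      gen_corr$shrinkage[row] <- attr(base_cov, "shrinkage")
      gen_corr$jitter_seed[row] <- jseed
      tm <- true_structure_metrics(cov, config$n_timepoints,
                                   seed = derive_seed(config$seed, "truemet", s, mod))
      true_metrics[s, paste(mod, metric_names, sep = "_")] <- tm
      for (r in seq_len(config$n_runs_per_modality)) {
        ri <- ri + 1L
        runs[[ri]] <- sample_run(
          cov, config$n_timepoints,
          seed = derive_seed(config$seed, subjects[s], mod, r),
          ar1 = config$ar1,
          subject_id = subjects[s], modality = mod, run_index = r)
      }
    }
  }

  nuisance_ranges <- list(age_months = c(94, 164), accuracy = c(0.51, 0.85),
                          latency_ms = c(900, 1863))
  nuis <- with_seed(derive_seed(config$seed, "nuisance"), data.frame(
    subject_id = subjects,
    age_months = round(stats::runif(n_sub, 94, 164)),
    accuracy = round(stats::runif(n_sub, 0.51, 0.85), 3),
    latency_ms = round(stats::runif(n_sub, 900, 1863))))

  betas <- config$outcome_betas
  signal <- rep(0, n_sub)
  if (length(betas)) {
    unknown <- setdiff(names(betas), colnames(true_metrics))
    if (length(unknown))
      stop2("outcome_betas name(s) not a <modality>_<metric> column: ",
            paste(unknown, collapse = ", "))
    signal <- as.vector(true_metrics[, names(betas), drop = FALSE] %*% betas)
  }
  noise <- with_seed(derive_seed(config$seed, "outcome"),
                     stats::rnorm(n_sub, 0, config$outcome_noise_sd))
  nuis$pde <- config$outcome_intercept + signal + noise

  list(runs = runs,
       subjects = nuis,
       ground_truth = list(
         module_assignment = modules,
         generating_correlations = gen_corr,
         true_metrics = true_metrics,
         outcome_intercept = config$outcome_intercept,
         outcome_betas = betas,
         outcome_noise_sd = config$outcome_noise_sd,
         expected_outcome = config$outcome_intercept + signal,
         nuisance_ranges = nuisance_ranges,
         config = config))
}

#' Write a cohort to disk in plain-text form
#'
#' Each run becomes `<subject>_<modality>_run<k>.tsv` (nodes x time,
#' tab-separated, no header); the subject table `subjects.csv`; the ground
#' truth a JSON sidecar `ground_truth.json`.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (run in cohort$runs) {
    fn <- sprintf("%s_%s_run%d.tsv", run$subject_id, run$modality, run$run_index)
    write_run_matrix(run, file.path(dir, fn))
  }
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  gt <- cohort$ground_truth
  gt$true_metrics <- cbind(subject_id = rownames(gt$true_metrics),
                           as.data.frame(gt$true_metrics))
  gt$config <- unclass(gt$config)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `*_run<k>.tsv` files and `subjects.csv`.
#' @return List with `runs` and `subjects` (no ground truth required).
#' @export
read_cohort <- function(dir) {
  files <- list.files(dir, pattern = "_run[0-9]+\\.tsv$", full.names = TRUE)
  if (!length(files)) stop2("no run matrices (*_run<k>.tsv) found in ", dir)
  runs <- lapply(files, function(f) {
    base <- sub("\\.tsv$", "", basename(f))
    parts <- strsplit(base, "_")[[1]]
    if (length(parts) < 3L) stop2("unparseable run filename: ", basename(f))
    read_run_matrix(f,
                    subject_id = paste(parts[1:(length(parts) - 2)], collapse = "_"),
                    modality = parts[length(parts) - 1],
                    run_index = as.integer(sub("run", "", parts[length(parts)])))
  })
  subj_path <- file.path(dir, "subjects.csv")
  subjects <- if (file.exists(subj_path)) utils::read.csv(subj_path) else NULL
  list(runs = runs, subjects = subjects)
}
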