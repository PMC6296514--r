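# Run-level metric computation and subject-level aggregation: compute the
# three measures per run and scheme, average the two runs of each modality,
# then replace outliers beyond mean +/- 2 SD with the boundary value
# (winsorization), per metric x modality x scheme column across subjects.

metric_cols <- c("modularity", "transitivity", "global_efficiency")

#' Compute run-level network metrics for a collection of runs
#'
#' Applies correlation, thresholding (one or both schemes) and the three
#' graph measures to every run, yielding the long-format metrics table the
#' aggregation and regression stages consume.
#'
#' @param runs List of [run_time_series()] objects.
#' @param schemes Character subset of `c("significance", "mcc")`.
#' @param alpha Significance level for the significance scheme.
#' @param resolution Modularity resolution parameter (default 1).
#' @param seed Seed for the modularity search.
#' @param restarts Modularity search restarts per network.
#' @param mcc_rank Edge ranking for the MCC scheme (`"signed"` or `"abs"`).
#' @return Data frame with columns subject_id, modality, run_index, scheme,
#'   modularity, transitivity, global_efficiency and a `stage = "raw"`
#'   attribute column.
#' @export
compute_run_metrics <- function(runs, schemes = c("significance", "mcc"),
                                alpha = 0.05, resolution = 1, seed = 1L,
                                restarts = 10L, mcc_rank = "signed") {
  schemes <- match.arg(schemes, c("significance", "mcc"), several.ok = TRUE)
  rows <- vector("list", length(runs) * length(schemes))
  k <- 0L
  for (run in runs) {
    corr <- correlation_matrix(run)
    for (scheme in schemes) {
      net <- if (scheme == "significance") significance_threshold(corr, alpha)
             else mcc_threshold(corr, rank = mcc_rank, quiet = TRUE)
      met <- network_metrics(net, resolution = resolution,
                             seed = derive_seed(seed, run$subject_id,
                                                run$modality, run$run_index,
                                                scheme),
                             restarts = restarts)
      k <- k + 1L
      rows[[k]] <- data.frame(subject_id = run$subject_id,
                              modality = run$modality,
                              run_index = run$run_index, scheme = scheme,
                              modularity = met[["modularity"]],
                              transitivity = met[["transitivity"]],
                              global_efficiency = met[["global_efficiency"]])
    }
  }
  out <- do.call(rbind, rows)
  out$stage <- "raw"
  out
}

#' Average run-level metrics within subject and modality
#'
#' Arithmetic mean of each measure across the runs of every
#' (subject, modality, scheme) cell; every cell must contain the same number
#' of runs.
#'
#' @param run_metrics Data frame from [compute_run_metrics()] (stage "raw").
#' @return Data frame with one row per (subject_id, modality, scheme) and
#'   stage "run_averaged".
#' @export
average_runs <- function(run_metrics) {
  req <- c("subject_id", "modality", "scheme", metric_cols)
  if (!all(req %in% names(run_metrics)))
    stop2("run_metrics lacks required columns: ",
          paste(setdiff(req, names(run_metrics)), collapse = ", "))
  key <- interaction(run_metrics$subject_id, run_metrics$modality,
                     run_metrics$scheme, drop = TRUE)
  counts <- table(key)
  if (length(unique(counts)) != 1L)
    stop2("unequal run counts per (subject, modality, scheme); missing run for: ",
          paste(names(counts)[counts < max(counts)], collapse = ", "))
  agg <- stats::aggregate(run_metrics[metric_cols],
                          by = run_metrics[c("subject_id", "modality", "scheme")],
                          FUN = mean)
  agg <- agg[order(agg$subject_id, agg$modality, agg$scheme), ]
  rownames(agg) <- NULL
  agg$stage <- "run_averaged"
  agg
}

#' Replace outlier metric values with the 2-SD boundary (winsorization)
#'
#' Within each (metric, modality, scheme) column across subjects, values
#' above `mean + k*SD` are set to `mean + k*SD` and values below
#' `mean - k*SD` to `mean - k*SD`. Mean and SD (sample, n-1 denominator) are
#' computed once from the pre-replacement values. With `group = "pooled"`
#' the statistics pool modalities within each (metric, scheme) instead.
#'
#' @param metrics Data frame from [average_runs()] (stage "run_averaged").
#' @param k Number of SDs defining the boundary (default 2).
#' @param group `"per_column"` (default) or `"pooled"`.
#' @param quiet Suppress notes about zero-SD groups.
#' @return Data frame with stage "winsorized" and an attribute
#'   `"n_replaced"` counting replaced values.
#' @export
winsorize_metrics <- function(metrics, k = 2, group = c("per_column", "pooled"),
                              quiet = FALSE) {
  group <- match.arg(group)
  out <- metrics
  n_replaced <- 0L
  gkey <- if (group == "per_column")
    interaction(metrics$modality, metrics$scheme, drop = TRUE)
  else
    factor(metrics$scheme)
  for (m in metric_cols) {
    for (g in levels(gkey)) {
      idx <- which(gkey == g)
      if (length(idx) < 3L)
        stop2("winsorization needs >= 3 subjects per group (", m, ", ", g, ")")
      v <- metrics[[m]][idx]
      mu <- mean(v); sdv <- stats::sd(v)
      if (sdv == 0) {
        if (!quiet) message("winsorize_metrics: zero SD for ", m, " in ", g,
                            "; values unchanged")
        next
      }
      lo <- mu - k * sdv; hi <- mu + k * sdv
      n_replaced <- n_replaced + sum(v < lo | v > hi)
      out[[m]][idx] <- pmin(pmax(v, lo), hi)
    }
  }
  out$stage <- "winsorized"
  attr(out, "n_replaced") <- n_replaced
  out
}

#' Pivot a subject-level metrics table to one row per subject
#'
#' Produces the wide predictor layout the regression consumes: one
#' `<modality>_<metric>` column per combination, for a single scheme.
#'
#' @param metrics Aggregated (and typically winsorized) metrics table.
#' @param scheme Which thresholding scheme's rows to pivot.
#' @return Data frame with subject_id plus 3 x n_modalities metric columns.
#' @export
metrics_wide <- function(metrics, scheme = c("significance", "mcc")) {
  scheme <- match.arg(scheme)
  sub <- metrics[metrics$scheme == scheme, , drop = FALSE]
  if (!nrow(sub)) stop2("no rows for scheme ", scheme)
  modalities <- unique(sub$modality)
  out <- data.frame(subject_id = sort(unique(sub$subject_id)))
  for (mod in modalities) {
    for (m in metric_cols) {
      col <- sub[sub$modality == mod, c("subject_id", m)]
      out[[paste(mod, m, sep = "_")]] <-
        col[[m]][match(out$subject_id, col$subject_id)]
    }
  }
  if (anyNA(out)) stop2("missing (subject, modality) cells for scheme ", scheme)
  out
}
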