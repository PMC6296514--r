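#' Construct a run-level node time-series object
#'
#' A `run_time_series` holds one fMRI run's node-by-time activity matrix
#' together with its identity within a cohort: subject, presentation modality
#' (`VV`, `AV` or `AA` in the rhyming-task design) and run index.
#'
#' @param data Numeric matrix, nodes in rows and time points in columns.
#' @param subject_id Subject label.
#' @param modality Presentation-modality label (e.g. `"VV"`, `"AV"`, `"AA"`).
#' @param run_index Run number within the modality (1 or 2 in the study design).
#' @param node_labels Optional character vector of unique node names; defaults
#'   to the matrix rownames or `node01 ...`.
#' @return An object of class `run_time_series`.
#' @export
run_time_series <- function(data, subject_id = "s01", modality = "VV",
                            run_index = 1L, node_labels = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop2("time-series data must be numeric")
  if (anyNA(data)) stop2("time-series data contains missing values")
  if (nrow(data) < 2L) stop2("need at least 2 nodes")
  if (ncol(data) < 4L) stop2("need at least 4 time points")
  if (is.null(node_labels)) {
    node_labels <- rownames(data)
    if (is.null(node_labels))
      node_labels <- sprintf("node%02d", seq_len(nrow(data)))
  }
  if (anyDuplicated(node_labels)) stop2("node labels must be unique")
  if (length(node_labels) != nrow(data))
    stop2("node_labels length must match the number of rows")
  rownames(data) <- node_labels
  structure(
    list(data = data, subject_id = as.character(subject_id),
         modality = as.character(modality), run_index = as.integer(run_index),
         node_labels = node_labels),
    class = "run_time_series")
}

#' @export
print.run_time_series <- function(x, ...) {
  cat(sprintf("<run_time_series> subject %s, modality %s, run %d: %d nodes x %d time points\n",
              x$subject_id, x$modality, x$run_index,
              nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Zero-lag correlation adjacency matrix of a run
#'
#' Computes the Pearson correlation between every pair of node time series.
#' This is the weighted adjacency matrix from which binary networks are
#' derived; only zero-lag correlations are considered.
#'
#' @param run A [run_time_series()] object (or a bare nodes-by-time matrix).
#' @return A `correlation_matrix`: list with `values` (node-by-node Pearson
#'   correlations, unit diagonal) and `n_timepoints`.
#' @export
correlation_matrix <- function(run) {
  mat <- if (inherits(run, "run_time_series")) run$data else as.matrix(run)
  sds <- apply(mat, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(mat)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop2("zero-variance time series for node(s): ",
          paste(bad, collapse = ", "))
  }
  vals <- stats::cor(t(mat))
  diag(vals) <- 1
  structure(list(values = vals, n_timepoints = ncol(mat)),
            class = "correlation_matrix")
}

r_crit <- function(alpha, n) {
  tcrit <- stats::qt(1 - alpha / 2, df = n - 2L)
  tcrit / sqrt(n - 2L + tcrit^2)
}

as_correlation_matrix <- function(corr) {
  if (inherits(corr, "correlation_matrix")) return(corr)
  stop2("expected a correlation_matrix (see correlation_matrix())")
}

new_binary_network <- function(adj, scheme, provenance) {
  check_square_symmetric(adj, "adjacency")
  diag(adj) <- 0
  structure(list(adjacency = adj, scheme = scheme, provenance = provenance),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges, scheme = %s\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$scheme))
  invisible(x)
}

#' Binarize a correlation matrix by uncorrected significance
#'
#' An edge is kept when the two-sided p-value of the Pearson correlation is
#' below `alpha`, using the exact t transform
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom; no
#' multiple-comparison correction is applied. Correlations of exactly
#' \eqn{\pm 1} are treated as p = 0 (edge present). By default both positive
#' and negative significant correlations produce edges (the test is
#' two-sided); `positive_only = TRUE` restricts edges to positive
#' correlations for sensitivity analyses.
#'
#' @param corr A `correlation_matrix`.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param positive_only Keep only significant positive correlations.
#' @return A `binary_network` with `scheme = "significance"`. The provenance
#'   records `alpha`, the implied critical |r|, and `n_timepoints`.
#' @export
significance_threshold <- function(corr, alpha = 0.05, positive_only = FALSE) {
  corr <- as_correlation_matrix(corr)
  if (!(alpha > 0 && alpha < 1)) stop2("alpha must lie in (0, 1)")
  n <- corr$n_timepoints
  if (n < 4L) stop2("need at least 4 time points for the significance test")
  r <- corr$values
  df <- n - 2L
  tval <- abs(r) * sqrt(df / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(tval, df = df, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0          # degenerate perfect correlation: p = 0
  adj <- (p < alpha) * 1
  if (positive_only) adj <- adj * (r > 0)
  adj <- (adj + t(adj) > 1) * 1  # enforce exact symmetry
  new_binary_network(adj, "significance",
                     list(alpha = alpha, r_crit = r_crit(alpha, n),
                          n_timepoints = n, positive_only = positive_only))
}

#' Binarize a correlation matrix by its minimum connected component
#'
#' Builds the sparsest descending-weight binary subgraph that spans all nodes:
#' off-diagonal edges are ranked by weight in descending order and inserted one
#' weight level at a time until the graph first forms a single connected
#' component covering every node. All edges tied with the stopping weight are
#' included, making the result independent of node ordering; ties at the
#' stopping weight trigger a logged notice. By default the ranking uses the
#' signed correlation (strongest positive coupling first); `rank = "abs"`
#' ranks by absolute value.
#'
#' @param corr A `correlation_matrix` (or a bare symmetric weight matrix).
#' @param rank `"signed"` (default) or `"abs"`.
#' @param quiet Suppress tie/degeneracy notices.
#' @return A `binary_network` with `scheme = "mcc"`; the provenance records
#'   the stopping weight and the number of tied edges at it. The adjacency is
#'   always one connected component spanning all nodes.
#' @export
mcc_threshold <- function(corr, rank = c("signed", "abs"), quiet = FALSE) {
  rank <- match.arg(rank)
  w <- if (inherits(corr, "correlation_matrix")) corr$values else as.matrix(corr)
  check_square_symmetric(w, "weight matrix")
  n <- nrow(w)
  if (n < 2L) stop2("need at least 2 nodes")
  key <- if (rank == "abs") abs(w) else w
  ut <- which(upper.tri(w), arr.ind = TRUE)
  ord <- order(key[ut], decreasing = TRUE)
  ut <- ut[ord, , drop = FALSE]
  keyv <- key[cbind(ut[, 1], ut[, 2])]

  # Insert whole descending weight levels; stop at the level that first
  # connects the graph. Union-find tracks components.
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  n_comp <- n
  adj <- matrix(0, n, n, dimnames = dimnames(w))
  stop_w <- NA_real_
  i <- 1L
  n_edges_total <- nrow(ut)
  while (i <= n_edges_total && n_comp > 1L) {
    lev <- keyv[i]
    j <- i
    while (j <= n_edges_total && keyv[j] == lev) j <- j + 1L
    for (k in i:(j - 1L)) {
      a <- ut[k, 1]; b <- ut[k, 2]
      adj[a, b] <- adj[b, a] <- 1
      ra <- find(a); rb <- find(b)
      if (ra != rb) { parent[ra] <- rb; n_comp <- n_comp - 1L }
    }
    if (n_comp == 1L) {
      stop_w <- lev
      if (!quiet && (j - i) > 1L)
        message(sprintf("mcc_threshold: %d edges tied at stopping weight %.6g; all included",
                        j - i, lev))
    }
    i <- j
  }
  if (n_comp > 1L)
    stop2("weight matrix does not admit a spanning connected subgraph")
  if (!quiet && length(unique(keyv)) == 1L && n > 2L)
    message("mcc_threshold: all weights tied; network degenerates to the complete graph")
  new_binary_network(adj, "mcc",
                     list(rank = rank, stop_weight = stop_w,
                          n_tied_at_stop = sum(keyv == stop_w)))
}

#' Read a delimited node-by-time matrix
#'
#' Accepts tab- or comma-separated plain-text matrices; a header row of node
#' labels in the first *column* orientation is not expected — rows are nodes,
#' columns are time points. A non-numeric first row is auto-detected and used
#' as column names (and dropped from the data).
#'
#' @param path File path.
#' @param ... Passed to [run_time_series()] (subject_id, modality, run_index).
#' @return A [run_time_series()].
#' @export
read_run_matrix <- function(path, ...) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(fields)))
  tab <- utils::read.table(path, sep = sep, header = has_header,
                           check.names = FALSE)
  run_time_series(as.matrix(tab), ...)
}

#' Write a run's node-by-time matrix as tab-separated text (no header)
#'
#' @param run A [run_time_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_matrix <- function(run, path) {
  utils::write.table(run$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an adjacency (or correlation) matrix as delimited text
#'
#' @param net A `binary_network`, `correlation_matrix`, or square matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(net, path) {
  m <- if (inherits(net, "binary_network")) net$adjacency
       else if (inherits(net, "correlation_matrix")) net$values
       else as.matrix(net)
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !is.null(colnames(m)))
  invisible(path)
}
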