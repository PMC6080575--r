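#' Construct a measurement table
#'
#' A measurement table holds one time point's subject-by-ROI matrix of a
#' regional morphometric measure (e.g., mean cortical thickness in mm per
#' AAL region), together with per-subject covariates used as confounds.
#'
#' @param values numeric matrix, subjects x ROIs; no missing values.
#' @param timepoint_label scalar ordinal label for the time point (e.g., age
#'   in years).
#' @param covariates optional data.frame of per-subject covariates (numeric
#'   or factor/character), same row count as \code{values}.
#' @param roi_names ROI identifiers; defaults to \code{colnames(values)}.
#' @return an object of class \code{measurement_table}.
#' @export
measurement_table <- function(values, timepoint_label, covariates = NULL,
                              roi_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values))
    dm_stop("measurement table for time point '%s' contains missing values",
            "devmeta_validation_error", timepoint_label)
  if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(ncol(values)))
  if (length(roi_names) != ncol(values))
    dm_stop("roi_names length (%d) does not match ROI count (%d)",
            "devmeta_validation_error", length(roi_names), ncol(values))
  colnames(values) <- roi_names
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(values))
      dm_stop("covariates have %d rows but values have %d subjects",
              "devmeta_validation_error", nrow(covariates), nrow(values))
  }
  structure(list(values = values, covariates = covariates,
                 timepoint_label = timepoint_label, roi_names = roi_names),
            class = "measurement_table")
}

#' @export
print.measurement_table <- function(x, ...) {
  cat(sprintf("measurement_table: %d subjects x %d ROIs, time point '%s'\n",
              nrow(x$values), ncol(x$values), x$timepoint_label))
  invisible(x)
}

#' Regress confounds out of a measurement table
#'
#' Removes the linear effect of the named covariates (e.g., gender and
#' overall mean thickness) from every ROI column by ordinary least squares:
#' each ROI's measurements are replaced with the residuals of a regression on
#' an intercept plus the confounds. Categorical confounds are dummy-coded
#' with a first-level reference. Residuals have zero mean per ROI and are
#' uncorrelated with every numeric confound.
#'
#' @param table a \code{\link{measurement_table}}.
#' @param confound_names character vector of covariate column names.
#' @return a \code{measurement_table} holding the residuals (covariates kept).
#' @export
regress_confounds <- function(table, confound_names) {
  stopifnot(inherits(table, "measurement_table"))
  if (length(confound_names) == 0)
    dm_stop("no confounds named", "devmeta_config_error")
  cov <- table$covariates
  missing <- setdiff(confound_names, colnames(cov))
  if (length(missing) > 0)
    dm_stop("confound(s) not found in covariates: %s",
            "devmeta_config_error", paste(missing, collapse = ", "))
  n <- nrow(table$values)
  if (n < length(confound_names) + 2)
    dm_stop("need at least %d subjects to regress %d confounds, have %d",
            "devmeta_insufficient_sample_error",
            length(confound_names) + 2, length(confound_names), n)
  cf <- cov[, confound_names, drop = FALSE]
  for (j in seq_along(cf)) if (is.character(cf[[j]])) cf[[j]] <- factor(cf[[j]])
  design <- stats::model.matrix(~ ., data = cf)
  # constant covariates are absorbed by the intercept: drop them (the
  # regression then reduces to mean removal), keep the degenerate-design
  # error for genuine collinearity among varying confounds
  assign_idx <- attr(design, "assign")
  constant <- c(FALSE, apply(design[, -1, drop = FALSE], 2,
                             function(x) stats::sd(x) == 0))
  design <- design[, !constant, drop = FALSE]
  assign_idx <- assign_idx[!constant]
  # find the covariate whose columns add no rank (aliased with earlier ones)
  qr_full <- qr(design)
  if (qr_full$rank < ncol(design)) {
    r <- 1L
    for (j in 2:ncol(design)) {
      rj <- qr(design[, seq_len(j), drop = FALSE])$rank
      if (rj == r) {
        bad <- confound_names[assign_idx[j]]
        dm_stop("degenerate design: confound '%s' is collinear with the others",
                "devmeta_degenerate_design_error", bad)
      }
      r <- rj
    }
  }
  resid <- qr.resid(qr_full, table$values)
  measurement_table(resid, table$timepoint_label, covariates = cov,
                    roi_names = table$roi_names)
}

#' Construct a network object
#'
#' A weighted undirected network on named nodes, stored as a symmetric
#' non-negative matrix with zero diagonal. Inputs asymmetric by more than
#' \code{tol} are rejected; smaller asymmetries are symmetrized by averaging.
#'
#' @param weights square numeric matrix, entries in \code{[0, 1]}.
#' @param node_names node identifiers; defaults to the matrix dimnames.
#' @param timepoint_label ordinal time label.
#' @param tol asymmetry tolerance (max |A - t(A)|).
#' @return an object of class \code{network}.
#' @export
network <- function(weights, node_names = rownames(weights),
                    timepoint_label = NA, tol = 1e-8) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    dm_stop("network matrix must be square", "devmeta_validation_error")
  if (max(abs(weights - t(weights))) > tol)
    dm_stop("network matrix is asymmetric beyond tolerance %g",
            "devmeta_validation_error", tol)
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (any(weights < 0))
    dm_stop("network weights must be non-negative", "devmeta_validation_error")
  if (is.null(node_names)) node_names <- paste0("ROI", seq_len(nrow(weights)))
  dimnames(weights) <- list(node_names, node_names)
  structure(list(weights = weights, node_names = node_names,
                 timepoint_label = timepoint_label),
            class = "network")
}

#' @export
print.network <- function(x, ...) {
  cat(sprintf("network: %d nodes, time point '%s', mean weight %.3f\n",
              length(x$node_names), x$timepoint_label, mean(x$weights)))
  invisible(x)
}

#' Build an absolute-correlation network from a measurement table
#'
#' Edge weights are the absolute Pearson correlations between the subject
#' vectors of every ROI pair; the diagonal is zero. This is the standard
#' structural-covariance construction for cross-sectional morphometry.
#'
#' @param table a \code{\link{measurement_table}} (typically confound-
#'   regressed first; see \code{\link{regress_confounds}}).
#' @return a \code{\link{network}} with weights in \code{[0, 1]}.
#' @export
build_correlation_network <- function(table) {
  stopifnot(inherits(table, "measurement_table"))
  v <- table$values
  if (nrow(v) < 3)
    dm_stop("Pearson correlation needs at least 3 subjects, have %d",
            "devmeta_insufficient_sample_error", nrow(v))
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    dm_stop("zero-variance ROI(s): %s", "devmeta_validation_error",
            paste(table$roi_names[sds == 0], collapse = ", "))
  w <- abs(stats::cor(v))
  diag(w) <- 0
  network(w, node_names = table$roi_names,
          timepoint_label = table$timepoint_label)
}

#' Vectorize a network into its upper-triangle connection vector
#'
#' Extracts the strict upper triangle in row-major order (i < j), the
#' canonical edge ordering used throughout the package; a symmetric N-node
#' network yields N(N-1)/2 connections.
#'
#' @param net a \code{\link{network}}.
#' @return named numeric vector of length \code{N*(N-1)/2}; names are
#'   \code{"a--b"} node-pair labels.
#' @export
vectorize_network <- function(net) {
  stopifnot(inherits(net, "network"))
  w <- net$weights
  # column-major traversal of the lower triangle == row-major upper triangle
  v <- w[lower.tri(w)]
  names(v) <- edge_names(net$node_names)
  v
}

#' Edge labels for the canonical vectorization order
#' @param node_names ordered node identifiers
#' @return character vector of \code{"a--b"} labels, row-major upper triangle
#' @export
edge_names <- function(node_names) {
  n <- length(node_names)
  idx <- which(lower.tri(diag(n)), arr.ind = TRUE)  # (j, i) with j > i
  paste0(node_names[idx[, 2]], "--", node_names[idx[, 1]])
}

#' Endpoint indices of each connection in vectorization order
#' @param n node count
#' @return two-column integer matrix (node_a, node_b), node_a < node_b
#' @export
edge_endpoints <- function(n) {
  idx <- which(lower.tri(diag(n)), arr.ind = TRUE)
  cbind(node_a = idx[, 2], node_b = idx[, 1])
}

#' Rebuild a network from a connection vector
#'
#' Inverse of \code{\link{vectorize_network}} (exact round-trip).
#'
#' @param v connection vector of length \code{N*(N-1)/2}.
#' @param node_names node identifiers of length N.
#' @param timepoint_label ordinal time label.
#' @return a \code{\link{network}}.
#' @export
devectorize_network <- function(v, node_names, timepoint_label = NA) {
  n <- length(node_names)
  if (length(v) != n * (n - 1) / 2)
    dm_stop("connection vector length %d does not match %d nodes",
            "devmeta_validation_error", length(v), n)
  w <- matrix(0, n, n)
  w[lower.tri(w)] <- v
  w <- w + t(w)
  network(w, node_names = node_names, timepoint_label = timepoint_label)
}

#' Assemble an ordered network sequence into a developmental-networks stack
#'
#' Stacks the vectorized networks column-wise into the M x tau matrix X whose
#' i-th column is the connection vector of the i-th time point.
#'
#' @param nets list of \code{\link{network}} objects with identical node sets
#'   and strictly increasing time labels.
#' @return an object of class \code{developmental_networks} with fields
#'   \code{X} (M x tau), \code{N}, \code{M}, \code{tau}, \code{time_labels},
#'   \code{node_names}, \code{edge_names}.
#' @export
assemble_developmental_networks <- function(nets) {
  stopifnot(length(nets) >= 1, all(vapply(nets, inherits, TRUE, "network")))
  ref <- nets[[1]]$node_names
  for (net in nets[-1]) {
    if (!identical(net$node_names, ref)) {
      diff <- c(setdiff(ref, net$node_names), setdiff(net$node_names, ref))
      if (length(diff) > 0)
        dm_stop("networks disagree on node sets; symmetric difference: %s",
                "devmeta_validation_error", paste(diff, collapse = ", "))
      dm_stop("networks share nodes but in different order",
              "devmeta_validation_error")
    }
  }
  labels <- vapply(nets, function(n) as.double(n$timepoint_label), 0)
  if (length(labels) > 1 && any(diff(labels) <= 0))
    dm_stop("time labels must be strictly increasing",
            "devmeta_validation_error")
  X <- vapply(nets, vectorize_network, numeric(length(ref) * (length(ref) - 1) / 2))
  X <- matrix(X, ncol = length(nets))
  dimnames(X) <- list(edge_names(ref), labels)
  developmental_networks(X, node_names = ref, time_labels = labels)
}

#' Construct a developmental-networks stack directly from a matrix
#'
#' @param X M x tau non-negative matrix of vectorized networks, one column
#'   per time point in chronological order.
#' @param node_names ordered node identifiers (N of them, M = N(N-1)/2).
#' @param time_labels ordered numeric time labels (default 1..tau).
#' @return an object of class \code{developmental_networks}.
#' @export
developmental_networks <- function(X, node_names, time_labels = seq_len(ncol(X))) {
  X <- as.matrix(X)
  n <- length(node_names)
  m <- n * (n - 1) / 2
  if (nrow(X) != m)
    dm_stop("X has %d rows but %d nodes imply M = %d",
            "devmeta_validation_error", nrow(X), n, m)
  if (any(X < 0))
    dm_stop("developmental networks must be non-negative",
            "devmeta_validation_error")
  if (length(time_labels) != ncol(X))
    dm_stop("time_labels length does not match tau", "devmeta_validation_error")
  en <- edge_names(node_names)
  dimnames(X) <- list(en, time_labels)
  structure(list(X = X, N = n, M = m, tau = ncol(X),
                 time_labels = as.double(time_labels),
                 node_names = node_names, edge_names = en),
            class = "developmental_networks")
}

#' @export
print.developmental_networks <- function(x, ...) {
  cat(sprintf("developmental_networks: %d nodes, %d connections, %d time points (%s..%s)\n",
              x$N, x$M, x$tau, x$time_labels[1], x$time_labels[x$tau]))
  invisible(x)
}
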