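#' Consensus k-means clustering of the network sequence
#'
#' Runs k-means with randomized (k-means++) initialization \code{n_runs}
#' times on the tau vectorized networks (columns of X) and records, for
#' every pair of time points, the fraction of runs in which they land in
#' the same cluster.
#'
#' @param X a \code{\link{developmental_networks}} stack.
#' @param G number of clusters (candidate stage count), \code{2 <= G <= tau}.
#' @param n_runs number of randomized k-means runs (default 100).
#' @param seed optional integer; makes the run sequence deterministic.
#' @return an object of class \code{consensus_result}: \code{n_clusters},
#'   \code{consensus} (tau x tau co-clustering fractions), \code{runs}
#'   (n_runs x tau label matrix), \code{inertia} (per-run total
#'   within-cluster sum of squares), \code{dispersion}.
#' @export
consensus_cluster <- function(X, G, n_runs = 100, seed = NULL) {
  stopifnot(inherits(X, "developmental_networks"))
  tau <- X$tau
  if (G < 2 || G > tau)
    dm_stop("G = %d outside valid range [2, tau = %d]",
            "devmeta_parameter_error", G, tau)
  if (n_runs < 1)
    dm_stop("n_runs must be >= 1", "devmeta_parameter_error")
  if (!is.null(seed)) set.seed(seed)
  pts <- t(X$X)
  runs <- matrix(0L, n_runs, tau)
  inertia <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    km <- stats::kmeans(pts, centers = kmeanspp_centers(pts, G),
                        iter.max = 100)
    runs[r, ] <- km$cluster
    inertia[r] <- km$tot.withinss
  }
  consensus <- matrix(0, tau, tau)
  for (r in seq_len(n_runs)) {
    lab <- runs[r, ]
    consensus <- consensus + (outer(lab, lab, "==") * 1)
  }
  consensus <- consensus / n_runs
  structure(list(n_clusters = G, consensus = consensus, runs = runs,
                 inertia = inertia,
                 dispersion = dispersion_coefficient(consensus)),
            class = "consensus_result")
}

# k-means++ seeding: first center uniform among the points, each further
# center sampled with probability proportional to squared distance from the
# nearest chosen center. Randomized (the consensus varies across runs) but
# far less prone to the degenerate starts of uniform seeding.
kmeanspp_centers <- function(pts, k) {
  n <- nrow(pts)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((pts - matrix(pts[idx[1], ], n, ncol(pts), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    idx[j] <- sample.int(n, 1, prob = pmax(d2, 1e-300))
    d2 <- pmin(d2, rowSums((pts - matrix(pts[idx[j], ], n, ncol(pts),
                                         byrow = TRUE))^2))
  }
  pts[idx, , drop = FALSE]
}

#' Dispersion coefficient of a consensus matrix
#'
#' rho = (1/tau^2) * sum_{i,j} 4 (C_ij - 1/2)^2. Equals 1 when every run
#' produced the same partition (all entries 0 or 1) and approaches 0 for a
#' maximally inconsistent consensus (all off-diagonal entries 1/2).
#'
#' @param consensus symmetric tau x tau matrix with entries in \code{[0, 1]}.
#' @return scalar in \code{[0, 1]}.
#' @export
dispersion_coefficient <- function(consensus) {
  consensus <- as.matrix(consensus)
  if (any(consensus < 0 | consensus > 1))
    dm_stop("consensus entries must lie in [0, 1]", "devmeta_validation_error")
  mean(4 * (consensus - 0.5)^2)
}

#' Build a stage partition from labels
#'
#' @param labels integer stage assignment of the tau time points; stages are
#'   renumbered chronologically by each stage's earliest time index.
#' @param time_labels optional numeric time labels (default 1..tau).
#' @return an object of class \code{stage_partition}: \code{G},
#'   \code{labels}, \code{blocks} (list of ordered time indices per stage),
#'   \code{n_t}, \code{time_labels}.
#' @export
stage_partition <- function(labels, time_labels = seq_along(labels)) {
  labels <- as.integer(labels)
  tau <- length(labels)
  first <- vapply(unique(labels), function(g) min(which(labels == g)), 0L)
  relabel <- order(first)
  new_labels <- match(labels, unique(labels)[relabel])
  G <- length(unique(new_labels))
  blocks <- lapply(seq_len(G), function(g) which(new_labels == g))
  contiguous <- all(vapply(blocks, function(b) all(diff(b) == 1), TRUE))
  if (!contiguous)
    dm_warn("stage partition is not contiguous in time (stages: %s)",
            paste(new_labels, collapse = " "))
  structure(list(G = G, labels = new_labels, blocks = blocks,
                 n_t = lengths(blocks), time_labels = as.double(time_labels)),
            class = "stage_partition")
}

#' @export
print.stage_partition <- function(x, ...) {
  cat(sprintf("stage_partition: %d stages over %d time points\n",
              x$G, length(x$labels)))
  for (g in seq_len(x$G))
    cat(sprintf("  stage %d: time points %s\n", g,
                paste(x$time_labels[x$blocks[[g]]], collapse = ", ")))
  invisible(x)
}

# finest-granularity rule: among the candidates attaining the maximal
# dispersion coefficient (up to numerical slack), prefer the largest G
pick_finest_G <- function(G_range, dispersion) {
  max(G_range[dispersion >= max(dispersion) - 1e-12])
}

#' Select the developmental-stage partition by consensus clustering
#'
#' Runs \code{\link{consensus_cluster}} for each candidate stage count and
#' selects, among the candidates attaining the maximal dispersion
#' coefficient, the largest G (finest granularity). The final labels come
#' from the best-inertia run at the selected G.
#'
#' @param X a \code{\link{developmental_networks}} stack.
#' @param G_range integer vector of candidate stage counts.
#' @param n_runs randomized runs per candidate (default 100).
#' @param seed optional integer seed.
#' @return a list with \code{partition} (a \code{\link{stage_partition}}),
#'   \code{dispersion} (named per-G curve), and \code{consensus}
#'   (list of \code{consensus_result} per candidate).
#' @export
select_stage_partition <- function(X, G_range = 2:7, n_runs = 100, seed = NULL) {
  stopifnot(inherits(X, "developmental_networks"))
  if (length(G_range) == 0)
    dm_stop("G_range must be non-empty", "devmeta_parameter_error")
  G_range <- sort(unique(as.integer(G_range)))
  results <- vector("list", length(G_range))
  for (i in seq_along(G_range)) {
    s <- if (is.null(seed)) NULL else child_seed(seed, i)
    results[[i]] <- consensus_cluster(X, G_range[i], n_runs = n_runs, seed = s)
  }
  disp <- vapply(results, function(r) r$dispersion, 0)
  names(disp) <- G_range
  sel <- pick_finest_G(G_range, disp)
  res <- results[[match(sel, G_range)]]
  labels <- res$runs[which.min(res$inertia), ]
  list(partition = stage_partition(labels, time_labels = X$time_labels),
       dispersion = disp, consensus = results)
}
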