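#' Split a network sequence into odd- and even-position halves
#'
#' Divides the chronologically ordered time points into half A (1st, 3rd,
#' 5th, ... — e.g., the odd-numbered ages) and half B (2nd, 4th, ...). Each
#' half inherits the full-sequence stage labels restricted to its time
#' points; a stage left empty in a half is merged into its chronological
#' neighbour for that half (with a warning).
#'
#' @param X a \code{\link{developmental_networks}} stack with tau >= 4.
#' @param partition a \code{\link{stage_partition}} of the full sequence.
#' @return list with \code{half_A}, \code{half_B} (each a list of
#'   \code{networks} — a \code{developmental_networks} stack — and
#'   \code{partition}).
#' @export
split_half <- function(X, partition) {
  stopifnot(inherits(X, "developmental_networks"),
            inherits(partition, "stage_partition"))
  if (X$tau < 4)
    dm_stop("split-half needs at least 4 time points, have %d",
            "devmeta_parameter_error", X$tau)
  make_half <- function(idx) {
    nets <- developmental_networks(X$X[, idx, drop = FALSE],
                                   node_names = X$node_names,
                                   time_labels = X$time_labels[idx])
    labels <- partition$labels[idx]
    present <- sort(unique(labels))
    missing <- setdiff(seq_len(partition$G), present)
    if (length(missing) > 0)
      dm_warn("stage(s) %s empty in one half; merged with chronological neighbours",
              paste(missing, collapse = ", "))
    part <- suppressWarnings(stage_partition(labels,
                                             time_labels = X$time_labels[idx]))
    list(networks = nets, partition = part)
  }
  idx_A <- seq(1, X$tau, by = 2)
  idx_B <- seq(2, X$tau, by = 2)
  list(half_A = make_half(idx_A), half_B = make_half(idx_B))
}

# stack the stage states of each meta-network into one M*G vector per DM
stack_dm_vectors <- function(result) {
  p <- ncol(result$V)
  vapply(seq_len(p), function(r) as.numeric(dm_states(result, r)),
         numeric(nrow(result$U[[1]]) * length(result$U)))
}

#' Match two sets of meta-networks by Hungarian assignment
#'
#' Each meta-network is represented by its stage states concatenated into a
#' single vector (a component is its whole evolution); the permutation
#' maximizing total cosine similarity between the two sets is found by the
#' Hungarian algorithm.
#'
#' @param result_A,result_B \code{dmd_result} objects with equal p and M.
#' @return an object of class \code{match_result}: \code{permutation}
#'   (index map A -> B), \code{similarity_U} (per-pair cosines in matched
#'   order), \code{similarity_matrix} (full p x p cosines).
#' @export
match_components <- function(result_A, result_B) {
  if (ncol(result_A$V) != ncol(result_B$V))
    dm_stop("cannot match component sets with different p (%d vs %d)",
            "devmeta_validation_error", ncol(result_A$V), ncol(result_B$V))
  SA <- stack_dm_vectors(result_A)
  SB <- stack_dm_vectors(result_B)
  if (nrow(SA) != nrow(SB))
    dm_stop("component sets have different stacked dimensions",
            "devmeta_validation_error")
  p <- ncol(SA)
  sim <- matrix(0, p, p)
  for (a in seq_len(p)) for (b in seq_len(p))
    sim[a, b] <- cosine_sim(SA[, a], SB[, b])
  perm <- solve_assignment(sim, maximize = TRUE)
  structure(list(permutation = perm,
                 similarity_U = sim[cbind(seq_len(p), perm)],
                 similarity_matrix = sim),
            class = "match_result")
}

#' Split-half reproducibility scores
#'
#' Matches the meta-networks of two independently fitted halves by Hungarian
#' assignment on stacked-state cosine similarity, then compares the
#' trajectory columns under the same permutation. Cosine similarity judges
#' orientation rather than magnitude, which suits halves offset by one time
#' step.
#'
#' @param result_A,result_B \code{dmd_result} objects fitted on the two
#'   halves (equal p).
#' @return list with \code{mean_similarity_U}, \code{mean_similarity_V},
#'   \code{table} (per-DM data.frame of matched indices and similarities),
#'   and the underlying \code{match} object.
#' @export
reproducibility_scores <- function(result_A, result_B) {
  m <- match_components(result_A, result_B)
  p <- ncol(result_A$V)
  sim_V <- vapply(seq_len(p), function(r)
    cosine_sim(result_A$V[, r], result_B$V[, m$permutation[r]]), 0)
  list(mean_similarity_U = mean(m$similarity_U),
       mean_similarity_V = mean(sim_V),
       table = data.frame(dm_A = seq_len(p), dm_B = m$permutation,
                          similarity_U = m$similarity_U,
                          similarity_V = sim_V),
       match = m)
}

#' Split-half reproducibility experiment
#'
#' Splits the sequence into odd/even halves, fits the factorization
#' independently on each (optionally re-estimating stages per half), and
#' returns the matched similarity scores.
#'
#' @param X a \code{\link{developmental_networks}} stack.
#' @param partition full-sequence \code{\link{stage_partition}}.
#' @param config a \code{\link{dmd_config}}.
#' @param re_estimate_stages if TRUE, each half re-runs stage selection
#'   instead of inheriting the full-sequence partition (default FALSE, which
#'   isolates factorization reproducibility from clustering variance).
#' @param G_range,n_runs stage-selection settings used only when
#'   \code{re_estimate_stages} is TRUE.
#' @return list of scores as in \code{\link{reproducibility_scores}}, plus
#'   \code{fit_A} and \code{fit_B}.
#' @export
split_half_reproducibility <- function(X, partition, config,
                                       re_estimate_stages = FALSE,
                                       G_range = 2:5, n_runs = 100) {
  halves <- split_half(X, partition)
  fit_one <- function(half, k) {
    part <- half$partition
    cfg <- config
    if (!is.null(config$seed)) cfg$seed <- child_seed(config$seed, k)
    if (re_estimate_stages) {
      sel <- select_stage_partition(half$networks, G_range = G_range,
                                    n_runs = n_runs, seed = cfg$seed)
      part <- sel$partition
    }
    dmd_fit(half$networks, part, cfg)
  }
  fit_A <- fit_one(halves$half_A, 1L)
  fit_B <- fit_one(halves$half_B, 2L)
  c(reproducibility_scores(fit_A, fit_B), list(fit_A = fit_A, fit_B = fit_B))
}
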