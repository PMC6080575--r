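#' Stage-state matrix of one meta-network
#'
#' Collects the r-th column of every stage state U^t into one M x G matrix,
#' the per-connection strength profile of meta-network r across stages.
#'
#' @param result a \code{dmd_result} from \code{\link{dmd_fit}}.
#' @param r meta-network index.
#' @return M x G matrix.
#' @export
dm_states <- function(result, r) {
  stopifnot(inherits(result, "dmd_result"))
  out <- vapply(result$U, function(u) u[, r], numeric(nrow(result$U[[1]])))
  matrix(out, ncol = length(result$U),
         dimnames = list(result$edge_names, NULL))
}

#' Normalized divergence of connections across stage states
#'
#' For every connection m, the sum over all ordered stage pairs (k, l) of
#' |U_r(m,k) - U_r(m,l)|, divided by the connection's mean strength across
#' stages. Connections constant across stages have divergence 0; connections
#' with zero mean get +Inf (never "stable"). The measure is invariant to
#' positive rescaling of U_r.
#'
#' @param U_r M x G stage-state matrix of one meta-network (G >= 2).
#' @return numeric vector of length M (possibly containing Inf).
#' @export
normalized_divergence <- function(U_r) {
  U_r <- as.matrix(U_r)
  G <- ncol(U_r)
  if (G < 2)
    dm_stop("divergence undefined for fewer than 2 stages",
            "devmeta_parameter_error")
  div <- numeric(nrow(U_r))
  for (k in seq_len(G - 1)) for (l in (k + 1):G)
    div <- div + 2 * abs(U_r[, k] - U_r[, l])  # ordered pairs count twice
  means <- rowMeans(U_r)
  omega <- ifelse(means > 0, div / means, Inf)
  # constant zero rows have div = 0 too, but zero mean strength: still Inf
  names(omega) <- rownames(U_r)
  omega
}

#' Adaptive strength threshold (quadratic mean)
#'
#' The root mean square of all G*M entries of the stage-state matrix,
#' delta_r = sqrt(||U_r||_F^2 / (G*M)); used to exclude insignificant
#' connections from the stable set.
#'
#' @param U_r M x G stage-state matrix.
#' @return scalar threshold >= 0.
#' @export
strength_threshold <- function(U_r) {
  sqrt(mean(as.matrix(U_r)^2))
}

#' Stable connections of one meta-network
#'
#' Ranks connections by ascending normalized divergence (ties broken toward
#' higher mean strength), drops connections whose mean strength falls below
#' the adaptive threshold delta_r, and returns the top fraction of the M
#' connections that survive.
#'
#' @param U_r M x G stage-state matrix of one meta-network.
#' @param top_fraction fraction of M to keep (default 0.02, i.e., top 2
#'   percent).
#' @param node_names optional node identifiers for endpoint labelling.
#' @return data.frame with columns \code{edge} (index in vectorization
#'   order), \code{node_a}, \code{node_b}, \code{omega},
#'   \code{mean_strength}, and one \code{stage_<t>} column per stage;
#'   attributes \code{threshold} (delta_r) carry the cutoff used.
#' @export
stable_connections <- function(U_r, top_fraction = 0.02, node_names = NULL) {
  U_r <- as.matrix(U_r)
  M <- nrow(U_r)
  omega <- normalized_divergence(U_r)
  means <- rowMeans(U_r)
  delta <- strength_threshold(U_r)
  keep <- which(means >= delta)
  n_sel <- floor(top_fraction * M)
  if (length(keep) == 0) {
    dm_warn("no connections reach the strength threshold %.4g; empty stable set",
            delta)
    sel <- integer(0)
  } else {
    ord <- keep[order(omega[keep], -means[keep])]
    sel <- utils::head(ord, n_sel)
  }
  ep <- edge_endpoints(node_count_from_edges(M))
  df <- data.frame(edge = sel,
                   node_a = if (is.null(node_names)) ep[sel, 1] else node_names[ep[sel, 1]],
                   node_b = if (is.null(node_names)) ep[sel, 2] else node_names[ep[sel, 2]],
                   omega = unname(omega[sel]),
                   mean_strength = unname(means[sel]),
                   stringsAsFactors = FALSE)
  states <- U_r[sel, , drop = FALSE]
  colnames(states) <- paste0("stage_", seq_len(ncol(U_r)))
  df <- cbind(df, as.data.frame(states, row.names = NULL))
  attr(df, "threshold") <- delta
  df
}

# invert M = N(N-1)/2
node_count_from_edges <- function(M) {
  n <- (1 + sqrt(1 + 8 * M)) / 2
  if (abs(n - round(n)) > 1e-9)
    dm_stop("%d is not a valid connection count N(N-1)/2", "devmeta_validation_error", M)
  as.integer(round(n))
}

#' Stage contributions of the meta-networks
#'
#' Averages each meta-network's trajectory within each stage: vbar(t, r) =
#' mean over the stage-t time points of V(., r).
#'
#' @param V tau x p trajectory matrix.
#' @param partition a \code{\link{stage_partition}}.
#' @return G x p matrix of stage contributions.
#' @export
stage_contributions <- function(V, partition) {
  V <- as.matrix(V)
  out <- t(vapply(partition$blocks,
                  function(idx) colMeans(V[idx, , drop = FALSE]),
                  numeric(ncol(V))))
  matrix(out, nrow = partition$G, dimnames = list(NULL, colnames(V)))
}

#' Rapidly-changing connections of one meta-network
#'
#' For each adjacent stage transition t -> t+1, computes the per-connection
#' strength change Delta u = U_r(., t+1) - U_r(., t) and the
#' stage-contribution change Delta vbar. When the contribution rises, the
#' most-increased connections (largest positive Delta u) are reported; when
#' it falls, the most-decreased; a transition with exactly zero contribution
#' change yields an empty selection.
#'
#' @param U_r M x G stage-state matrix (G >= 2).
#' @param vbar_r length-G stage-contribution vector of the same meta-network.
#' @param top_fraction fraction of M to keep per transition (default 0.02).
#' @param node_names optional node identifiers.
#' @return list with one element per transition, each a list of
#'   \code{direction} ("increased", "decreased" or "none"),
#'   \code{delta_vbar}, and \code{edges} (data.frame with \code{edge},
#'   \code{node_a}, \code{node_b}, \code{delta_u}).
#' @export
rapidly_changing_connections <- function(U_r, vbar_r, top_fraction = 0.02,
                                         node_names = NULL) {
  U_r <- as.matrix(U_r)
  G <- ncol(U_r)
  if (G < 2)
    dm_stop("need at least 2 stages for stage transitions",
            "devmeta_parameter_error")
  M <- nrow(U_r)
  n_sel <- floor(top_fraction * M)
  ep <- edge_endpoints(node_count_from_edges(M))
  lapply(seq_len(G - 1), function(t) {
    du <- U_r[, t + 1] - U_r[, t]
    dv <- vbar_r[t + 1] - vbar_r[t]
    if (dv > 0) {
      cand <- which(du > 0)
      sel <- cand[order(du[cand], decreasing = TRUE)]
      direction <- "increased"
    } else if (dv < 0) {
      cand <- which(du < 0)
      sel <- cand[order(du[cand])]
      direction <- "decreased"
    } else {
      sel <- integer(0)
      direction <- "none"
    }
    sel <- utils::head(sel, n_sel)
    list(direction = direction, delta_vbar = dv,
         edges = data.frame(
           edge = sel,
           node_a = if (is.null(node_names)) ep[sel, 1] else node_names[ep[sel, 1]],
           node_b = if (is.null(node_names)) ep[sel, 2] else node_names[ep[sel, 2]],
           delta_u = unname(du[sel]),
           stringsAsFactors = FALSE))
  })
}

#' Characterize every meta-network of a fit
#'
#' Convenience wrapper producing, per meta-network, the stable-connection
#' table and the per-transition rapidly-changing connection reports.
#'
#' @param result a \code{dmd_result}.
#' @param top_fraction selection fraction for both reports (default 0.02).
#' @return list with elements \code{stable} (list of data.frames, one per
#'   meta-network), \code{rapid} (nested lists), and \code{contributions}
#'   (G x p stage-contribution matrix).
#' @export
characterize_dms <- function(result, top_fraction = 0.02) {
  stopifnot(inherits(result, "dmd_result"))
  p <- ncol(result$V)
  vbar <- stage_contributions(result$V, result$partition)
  stable <- lapply(seq_len(p), function(r)
    stable_connections(dm_states(result, r), top_fraction,
                       node_names = result$node_names))
  rapid <- if (result$partition$G >= 2) {
    lapply(seq_len(p), function(r)
      rapidly_changing_connections(dm_states(result, r), vbar[, r],
                                   top_fraction,
                                   node_names = result$node_names))
  } else list()
  list(stable = stable, rapid = rapid, contributions = vbar)
}
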