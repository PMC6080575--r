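#' Generate developmental networks with planted meta-network structure
#'
#' Emulates the generative model behind the factorization: per stage t, the
#' noiseless stack block is U*^t V*^tT, where the planted stage states U*^t
#' have p disjoint edge supports (hence exactly orthonormal columns) that
#' drift smoothly across stages by swapping a fraction of each support's
#' edges, and the planted trajectories V* are smooth distinct curves
#' (decaying, rising, unimodal, flat). Gaussian noise is added and the
#' result truncated at zero to stay in the non-negative domain.
#'
#' @param N node count (default 40).
#' @param tau number of time points (default 12).
#' @param G number of planted stages, contiguous near-equal blocks
#'   (default 3).
#' @param p number of planted meta-networks (default 3).
#' @param drift fraction of each support's edges swapped at every stage
#'   transition (default 0.1).
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (default 0.02).
#' @param seed optional integer seed; same seed gives bit-identical output.
#' @param edges_per_dm support size per meta-network; default
#'   \code{max(p, floor(0.02 * M))}, i.e., each meta-network occupies the
#'   top-2-percent edge budget used downstream for stable-connection
#'   selection.
#' @param noise_kind \code{"gaussian"} (additive N(0, sd), result truncated
#'   at zero) or \code{"halfnormal"} (additive |N(0, sd)|).
#' @return list with \code{networks} (a
#'   \code{\link{developmental_networks}} stack) and \code{model} (class
#'   \code{planted_model}: \code{U_star} list of G M x p states,
#'   \code{V_star} tau x p, \code{partition}, \code{supports} per stage,
#'   \code{noise_sd}, \code{seed}).
#' @export
generate_planted_networks <- function(N = 40, tau = 12, G = 3, p = 3,
                                      drift = 0.1, noise_sd = 0.02,
                                      seed = NULL, edges_per_dm = NULL,
                                      noise_kind = c("gaussian", "halfnormal")) {
  noise_kind <- match.arg(noise_kind)
  if (G > tau)
    dm_stop("G = %d exceeds tau = %d", "devmeta_parameter_error", G, tau)
  M <- N * (N - 1) / 2
  if (is.null(edges_per_dm)) edges_per_dm <- max(p, floor(0.02 * M))
  # the 4th meta-network (flat trajectory) is a global background pattern
  # with a much broader edge support, emulating the dominant shared
  # covariance of real structural correlation networks
  support_sizes <- rep(edges_per_dm, p)
  if (p >= 4) support_sizes[4] <- min(8 * edges_per_dm,
                                      M - (p - 1) * edges_per_dm)
  if (sum(support_sizes) > M)
    dm_stop("total support size %d exceeds the %d available connections",
            "devmeta_parameter_error", sum(support_sizes), M)
  if (!is.null(seed)) set.seed(seed)

  # disjoint supports at stage 1, then smooth drift by edge swaps
  pool <- sample.int(M)
  bounds <- cumsum(c(0, support_sizes))
  supports <- vector("list", G)
  supports[[1]] <- lapply(seq_len(p), function(r)
    sort(pool[(bounds[r] + 1):bounds[r + 1]]))
  for (t in seq_len(G - 1) + 1) {
    prev <- supports[[t - 1]]
    free <- setdiff(seq_len(M), unlist(prev))
    cur <- prev
    for (r in seq_len(p)) {
      n_swap <- round(drift * support_sizes[r])
      if (n_swap > 0 && length(free) >= n_swap) {
        out <- sample(cur[[r]], n_swap)
        inn <- sample(free, n_swap)
        cur[[r]] <- sort(c(setdiff(cur[[r]], out), inn))
        free <- c(setdiff(free, inn), out)
      }
    }
    supports[[t]] <- cur
  }
  U_star <- lapply(supports, function(sup) {
    U <- matrix(0, M, p)
    for (r in seq_len(p)) U[sup[[r]], r] <- 1 / sqrt(length(sup[[r]]))
    U
  })

  sizes <- rep(tau %/% G, G)
  extra <- tau - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  labels <- rep(seq_len(G), times = sizes)
  partition <- stage_partition(labels, time_labels = seq_len(tau))
  V_star <- planted_trajectories(tau, p, labels)

  S <- matrix(0, M, tau)
  for (i in seq_len(tau))
    S[, i] <- U_star[[labels[i]]] %*% V_star[i, ]
  noise <- matrix(stats::rnorm(M * tau, sd = noise_sd), M, tau)
  X <- switch(noise_kind,
              gaussian = pmax(S + noise, 0),
              halfnormal = S + abs(noise))
  nets <- developmental_networks(X, node_names = paste0("ROI", seq_len(N)),
                                 time_labels = seq_len(tau))
  model <- structure(list(N = N, tau = tau, G = G, p = p,
                          U_star = U_star, V_star = V_star,
                          partition = partition, supports = supports,
                          signal = S, drift = drift, noise_sd = noise_sd,
                          seed = seed),
                     class = "planted_model")
  list(networks = nets, model = model)
}

# smooth, distinct trajectory curves: decaying, rising, unimodal, flat,
# then shifted bumps for larger p. Curves are logistic blends whose
# transitions sit at the planted stage boundaries, so loadings form
# within-stage plateaus (strongly separated stage clusters) while still
# changing smoothly in time. Non-flat curves span [0.05, 1.2], nearly
# vanishing somewhere, which keeps the planted non-negative factorization
# identifiable (every meta-network is effectively "off" at some time
# points).
planted_trajectories <- function(tau, p, labels) {
  s <- if (tau > 1) (seq_len(tau) - 1) / (tau - 1) else 0.5
  # normalized positions of the stage boundaries (midpoints between the
  # last time point of one stage and the first of the next)
  cuts <- which(diff(labels) != 0)
  bd <- if (length(cuts) > 0) (cuts - 0.5) / (tau - 1) else 0.5
  t1 <- bd[1]
  t2 <- bd[length(bd)]
  w <- 0.08
  sig <- function(z) 1 / (1 + exp(-z / w))
  shapes <- list(
    function(s) 0.05 + 1.15 * sig(t1 - s),             # decaying
    function(s) 0.05 + 1.15 * sig(s - t2),             # rising
    function(s) 0.05 + 1.15 * sig(s - t1) * sig(t2 - s), # unimodal
    function(s) rep(0.8, length(s))                    # flat
  )
  V <- matrix(0, tau, p)
  for (r in seq_len(p)) {
    if (r <= length(shapes)) {
      V[, r] <- shapes[[r]](s)
    } else {
      centre <- (r - length(shapes)) / (p - length(shapes) + 1)
      V[, r] <- 0.05 + 1.15 * exp(-((s - centre) / 0.12)^2)
    }
  }
  V
}

#' @export
print.planted_model <- function(x, ...) {
  cat(sprintf("planted_model: %d nodes, %d time points, %d stages, %d meta-networks, noise sd %g\n",
              x$N, x$tau, x$G, x$p, x$noise_sd))
  invisible(x)
}

#' Generate synthetic per-age thickness tables
#'
#' Emulates the upstream inputs of the pipeline: one subject-by-ROI table
#' per age, where subject measurements are driven by shared latent factors
#' (ROIs in the same factor group correlate), plus a gender offset, a
#' per-subject global scaling, and measurement noise. Running
#' \code{\link{regress_confounds}} followed by
#' \code{\link{build_correlation_network}} approximately recovers the
#' block-structured absolute-correlation pattern.
#'
#' @param n_roi number of ROIs (default 78).
#' @param ages integer vector of age labels, one table each (default 3:20).
#' @param subjects_per_age subjects per table (default 45); scalar or
#'   vector per age.
#' @param n_factors number of latent ROI groups (default 4).
#' @param factor_sd latent factor effect size (default 0.3 mm).
#' @param gender_effect additive offset for one gender (default 0.15 mm).
#' @param global_sd sd of the per-subject global thickness component
#'   (default 0.2 mm).
#' @param noise_sd measurement noise sd (default 0.1 mm).
#' @param baseline mean thickness (default 2.5 mm).
#' @param seed optional integer seed.
#' @return list of \code{\link{measurement_table}} objects; each carries
#'   covariates \code{gender} (factor) and \code{mean_thickness} (the
#'   subject's overall mean), the standard confounds.
#' @export
generate_thickness_tables <- function(n_roi = 78, ages = 3:20,
                                      subjects_per_age = 45, n_factors = 4,
                                      factor_sd = 0.3, gender_effect = 0.15,
                                      global_sd = 0.2, noise_sd = 0.1,
                                      baseline = 2.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_sub <- rep(subjects_per_age, length.out = length(ages))
  if (any(n_sub < 4))
    dm_stop("need at least 4 subjects per age", "devmeta_parameter_error")
  group <- rep(seq_len(n_factors), length.out = n_roi)
  roi_names <- paste0("ROI", seq_len(n_roi))
  lapply(seq_along(ages), function(a) {
    ns <- n_sub[a]
    z <- matrix(stats::rnorm(ns * n_factors), ns, n_factors)
    gender <- factor(sample(c("F", "M"), ns, replace = TRUE),
                     levels = c("F", "M"))
    global <- stats::rnorm(ns, sd = global_sd)
    values <- baseline + factor_sd * z[, group, drop = FALSE] +
      gender_effect * (gender == "M") + global +
      matrix(stats::rnorm(ns * n_roi, sd = noise_sd), ns, n_roi)
    colnames(values) <- roi_names
    measurement_table(values, timepoint_label = ages[a],
                      covariates = data.frame(
                        gender = gender,
                        mean_thickness = rowMeans(values)))
  })
}
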