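#' Configuration for the meta-network factorization
#'
#' @param p number of developmental meta-networks (components).
#' @param lambda ridge weight on the trajectory matrix V (the nuclear-norm
#'   surrogate of the low-rank reconstruction); >= 0, default 0.1.
#' @param alpha stage-smoothness weight on U across adjacent stages; >= 0,
#'   default 0.1.
#' @param beta trajectory-smoothness weight on V across adjacent time
#'   points; >= 0, default 0.1.
#' @param n_init number of random restarts, keeping the least-cost fit
#'   (default 100).
#' @param max_iter maximum multiplicative-update iterations per restart.
#' @param tol relative objective-change convergence threshold.
#' @param epsilon guard added to update denominators.
#' @param seed optional integer seed making the whole fit deterministic.
#' @return an object of class \code{dmd_config}.
#' @export
dmd_config <- function(p, lambda = 0.1, alpha = 0.1, beta = 0.1,
                       n_init = 100, max_iter = 1000, tol = 1e-6,
                       epsilon = 1e-12, seed = NULL) {
  if (p < 1) dm_stop("p must be >= 1", "devmeta_parameter_error")
  if (lambda < 0 || alpha < 0 || beta < 0)
    dm_stop("lambda, alpha, beta must be non-negative", "devmeta_parameter_error")
  if (tol <= 0) dm_stop("tol must be > 0", "devmeta_parameter_error")
  structure(list(p = as.integer(p), lambda = lambda, alpha = alpha,
                 beta = beta, n_init = as.integer(n_init),
                 max_iter = as.integer(max_iter), tol = tol,
                 epsilon = epsilon, seed = seed),
            class = "dmd_config")
}

#' Chain-topology smoothness graphs for stages and time points
#'
#' The stage adjacency W_U links chronologically consecutive stages with
#' weight 1; the time adjacency W_V links consecutive time points with
#' weight 1; D_V is the diagonal degree matrix of W_V. These graphs drive
#' the temporal-smoothness regularizer of the factorization.
#'
#' @param partition a \code{\link{stage_partition}}.
#' @param tau number of time points (default: length of the partition labels).
#' @return a list with \code{W_U} (G x G), \code{W_V} (tau x tau),
#'   \code{D_V} (tau x tau diagonal).
#' @export
build_smoothness_graphs <- function(partition, tau = length(partition$labels)) {
  G <- partition$G
  W_U <- matrix(0, G, G)
  if (G > 1) for (g in seq_len(G - 1)) W_U[g, g + 1] <- W_U[g + 1, g] <- 1
  W_V <- matrix(0, tau, tau)
  if (tau > 1) for (i in seq_len(tau - 1)) W_V[i, i + 1] <- W_V[i + 1, i] <- 1
  D_V <- diag(rowSums(W_V), tau)
  list(W_U = W_U, W_V = W_V, D_V = D_V)
}

#' Regularized factorization objective
#'
#' J = sum_t 1/2 ||X^t - U^t V^tT||_F^2 + lambda/2 ||V||_F^2
#'     + alpha/4 sum_{k,l} W_U(k,l) ||U^k - U^l||_F^2
#'     + beta/4 sum_{i,j} W_V(i,j) ||v_i - v_j||^2
#'
#' where V^t is the stage-t row block of V and v_i is row i of V.
#'
#' @param X a \code{\link{developmental_networks}} stack (or plain M x tau
#'   matrix).
#' @param partition a \code{\link{stage_partition}}.
#' @param U list of G non-negative M x p stage-state matrices.
#' @param V non-negative tau x p trajectory matrix.
#' @param graphs smoothness graphs from \code{\link{build_smoothness_graphs}}.
#' @param config a \code{\link{dmd_config}} (only lambda, alpha, beta used).
#' @return scalar objective value J >= 0.
#' @export
dmd_objective <- function(X, partition, U, V, graphs, config) {
  Xm <- if (inherits(X, "developmental_networks")) X$X else as.matrix(X)
  G <- partition$G
  if (length(U) != G || nrow(V) != ncol(Xm))
    dm_stop("U/V shapes inconsistent with partition", "devmeta_validation_error")
  p <- ncol(V)
  if (any(vapply(U, ncol, 0L) != p))
    dm_stop("all U^t must have p = %d columns", "devmeta_validation_error", p)
  J <- 0.5 * config$lambda * sum(V^2)
  for (t in seq_len(G)) {
    idx <- partition$blocks[[t]]
    Vt <- V[idx, , drop = FALSE]
    J <- J + 0.5 * sum((Xm[, idx, drop = FALSE] - U[[t]] %*% t(Vt))^2)
  }
  if (config$alpha > 0 && G > 1) {
    for (k in seq_len(G)) for (l in seq_len(G)) if (graphs$W_U[k, l] > 0)
      J <- J + config$alpha / 4 * graphs$W_U[k, l] * sum((U[[k]] - U[[l]])^2)
  }
  if (config$beta > 0 && nrow(V) > 1) {
    W <- graphs$W_V
    for (i in seq_len(nrow(V))) for (j in seq_len(nrow(V))) if (W[i, j] > 0)
      J <- J + config$beta / 4 * W[i, j] * sum((V[i, ] - V[j, ])^2)
  }
  J
}

#' One multiplicative update of the stage-state matrices U
#'
#' Applies, stage by stage, the elementwise update
#' U^t <- U^t * [X^t V^t + alpha sum_k W_U(t,k) U^k] /
#'              [U^t (V^tT X^tT U^t) + alpha d_t U^t + eps]
#' where d_t = sum_k W_U(t,k). The reconstruction part of the denominator,
#' U^t (V^tT X^tT U^t), is the orthogonality-enforcing form: at alpha = 0 it
#' is the classic orthogonal-NMF update, with the exact factorization
#' X^t = U^t V^tT (orthonormal U^t) as a fixed point. The smoothness part
#' uses the graph-Laplacian split of the regularizer gradient (negative part
#' in the numerator, degree term in the denominator), the standard stable
#' treatment in graph-regularized NMF. Non-negativity is preserved and
#' exact zeros stay zero.
#'
#' @inheritParams dmd_objective
#' @return updated list of U matrices.
#' @export
update_U <- function(X, partition, U, V, graphs, config) {
  Xm <- if (inherits(X, "developmental_networks")) X$X else as.matrix(X)
  if (any(Xm < 0) || any(V < 0) || any(vapply(U, function(u) any(u < 0), TRUE)))
    dm_stop("update_U requires non-negative inputs", "devmeta_validation_error")
  G <- partition$G
  Unew <- U
  for (t in seq_len(G)) {
    step <- update_U_stage(Xm, partition, U, V, graphs, config, t)
    Unew[[t]] <- U[[t]] * step$R
  }
  Unew
}

# multiplier R = num/(den + eps) of the U^t update, shared by update_U and
# the damped sweep used inside dmd_fit
update_U_stage <- function(Xm, partition, U, V, graphs, config, t) {
  idx <- partition$blocks[[t]]
  Xt <- Xm[, idx, drop = FALSE]
  Vt <- V[idx, , drop = FALSE]
  Ut <- U[[t]]
  num <- Xt %*% Vt
  den <- Ut %*% (t(Vt) %*% t(Xt) %*% Ut)
  if (config$alpha > 0 && partition$G > 1) {
    d_t <- sum(graphs$W_U[t, ])
    for (k in seq_len(partition$G)) {
      w <- graphs$W_U[t, k]
      if (w > 0) num <- num + config$alpha * w * U[[k]]
    }
    den <- den + config$alpha * d_t * Ut
  }
  list(R = num / (den + config$epsilon), Xt = Xt, Vt = Vt)
}

#' One multiplicative update of the trajectory matrix V
#'
#' Applies the single global elementwise update
#' V <- V * [sum_t H^t X^tT U^t + beta W_V V] /
#'          [sum_t H^t H^tT V U^tT U^t + lambda V + beta D_V V + eps]
#' where H^t is the 0/1 mask selecting the stage-t rows of V. Non-negativity
#' is preserved and exact zeros stay zero.
#'
#' @inheritParams dmd_objective
#' @return updated tau x p matrix V.
#' @export
update_V <- function(X, partition, U, V, graphs, config) {
  Xm <- if (inherits(X, "developmental_networks")) X$X else as.matrix(X)
  if (any(Xm < 0) || any(V < 0) || any(vapply(U, function(u) any(u < 0), TRUE)))
    dm_stop("update_V requires non-negative inputs", "devmeta_validation_error")
  G <- partition$G
  num <- matrix(0, nrow(V), ncol(V))
  den <- config$lambda * V
  for (t in seq_len(G)) {
    idx <- partition$blocks[[t]]
    Xt <- Xm[, idx, drop = FALSE]
    Ut <- U[[t]]
    num[idx, ] <- num[idx, ] + t(Xt) %*% Ut
    den[idx, ] <- den[idx, ] + V[idx, , drop = FALSE] %*% (t(Ut) %*% Ut)
  }
  if (config$beta > 0 && nrow(V) > 1) {
    num <- num + config$beta * graphs$W_V %*% V
    den <- den + config$beta * graphs$D_V %*% V
  }
  V * num / (den + config$epsilon)
}

# stage-t coordinate objective: reconstruction plus the U-smoothness terms
# that involve U^t (each unordered stage pair appears twice in the sum)
stage_objective_U <- function(Ut, t, Xt, Vt, U, W_U, alpha) {
  f <- 0.5 * sum((Xt - Ut %*% t(Vt))^2)
  if (alpha > 0) {
    for (k in seq_along(U)) if (k != t && W_U[t, k] > 0)
      f <- f + alpha / 2 * W_U[t, k] * sum((Ut - U[[k]])^2)
  }
  f
}

# damped multiplicative U sweep used inside dmd_fit: applies the update_U
# multiplier R stage-by-stage as U^t * R^eta starting at eta = 1/2 (the
# square-root damping standard for orthogonality-enforcing multiplicative
# updates: it corrects a pure column-scale error in one step instead of
# oscillating), halving eta further if the stage coordinate objective would
# increase, and keeping U^t unchanged when no exponent descends. Exponent
# damping preserves the update's fixed points exactly (R = 1 <=> R^eta = 1).
update_U_damped <- function(Xm, partition, U, V, graphs, config,
                            eta0 = 0.5, max_halvings = 7) {
  for (t in seq_len(partition$G)) {
    s <- update_U_stage(Xm, partition, U, V, graphs, config, t)
    Ut <- U[[t]]
    f0 <- stage_objective_U(Ut, t, s$Xt, s$Vt, U, graphs$W_U, config$alpha)
    eta <- eta0
    for (h in seq_len(max_halvings)) {
      cand <- Ut * s$R^eta
      if (stage_objective_U(cand, t, s$Xt, s$Vt, U, graphs$W_U,
                            config$alpha) <= f0) {
        U[[t]] <- cand
        break
      }
      eta <- eta / 2
    }
  }
  U
}

# random non-negative initialization at a comparable objective scale:
# U columns unit-norm, V rescaled by the global least-squares constant
dmd_init <- function(Xm, partition, p) {
  M <- nrow(Xm)
  tau <- ncol(Xm)
  G <- partition$G
  U <- lapply(seq_len(G), function(t) {
    u <- matrix(stats::runif(M * p, min = .Machine$double.eps, max = 1), M, p)
    sweep(u, 2, sqrt(colSums(u^2)), "/")
  })
  V <- matrix(stats::runif(tau * p, min = .Machine$double.eps, max = 1), tau, p)
  recon <- matrix(0, M, tau)
  for (t in seq_len(G)) {
    idx <- partition$blocks[[t]]
    recon[, idx] <- U[[t]] %*% t(V[idx, , drop = FALSE])
  }
  cc <- sum(Xm * recon) / sum(recon^2)
  V <- V * max(cc, .Machine$double.eps)
  list(U = U, V = V)
}

#' Fit the developmental meta-network factorization
#'
#' Decomposes the staged network sequence X = [X^1 ... X^G] into G
#' non-negative stage-state matrices U^t (M x p, columns near-orthonormal)
#' and one shared non-negative trajectory matrix V (tau x p), by alternating
#' multiplicative updates from random starts and keeping the restart with
#' the least final objective. The U sweep applies the \code{\link{update_U}}
#' multiplier with a damped exponent (1/2, halved further by a per-stage
#' backtracking check), which preserves the update's fixed points while
#' guaranteeing a non-increasing objective trace; the V step is the plain
#' \code{\link{update_V}}, which is monotone as is.
#'
#' @param X a \code{\link{developmental_networks}} stack.
#' @param partition a \code{\link{stage_partition}}.
#' @param config a \code{\link{dmd_config}}.
#' @return an object of class \code{dmd_result}: \code{U} (list of G M x p
#'   matrices), \code{V} (tau x p), \code{objective_trace} of the winning
#'   restart, \code{orthogonality_gap} (per-stage ||U^tT U^t - I||_F),
#'   \code{chosen_restart}, \code{final_objective}, plus the partition and
#'   config used.
#' @export
dmd_fit <- function(X, partition, config) {
  stopifnot(inherits(X, "developmental_networks"),
            inherits(partition, "stage_partition"),
            inherits(config, "dmd_config"))
  Xm <- X$X
  p <- config$p
  if (p > X$M || p > X$tau)
    dm_stop("p = %d exceeds the problem size (M = %d, tau = %d)",
            "devmeta_parameter_error", p, X$M, X$tau)
  if (p > min(partition$n_t))
    dm_warn("p = %d exceeds the smallest stage size (%d); stage blocks are rank-deficient",
            p, min(partition$n_t))
  graphs <- build_smoothness_graphs(partition, tau = X$tau)
  if (!is.null(config$seed)) set.seed(config$seed)
  best <- NULL
  for (r in seq_len(config$n_init)) {
    init <- dmd_init(Xm, partition, p)
    U <- init$U; V <- init$V
    trace <- dmd_objective(Xm, partition, U, V, graphs, config)
    for (it in seq_len(config$max_iter)) {
      U <- update_U_damped(Xm, partition, U, V, graphs, config)
      V <- update_V(Xm, partition, U, V, graphs, config)
      J <- dmd_objective(Xm, partition, U, V, graphs, config)
      Jprev <- trace[length(trace)]
      trace <- c(trace, J)
      if (Jprev > 0 && abs(Jprev - J) / Jprev < config$tol) break
    }
    if (is.null(best) || trace[length(trace)] < best$final) {
      best <- list(U = U, V = V, trace = trace, restart = r,
                   final = trace[length(trace)])
    }
  }
  gap <- vapply(best$U, function(u) {
    g <- crossprod(u) - diag(p)
    sqrt(sum(g^2))
  }, 0)
  structure(list(U = best$U, V = best$V,
                 objective_trace = best$trace,
                 orthogonality_gap = gap,
                 chosen_restart = best$restart,
                 final_objective = best$final,
                 partition = partition, config = config,
                 edge_names = X$edge_names, node_names = X$node_names,
                 time_labels = X$time_labels),
            class = "dmd_result")
}

#' @export
print.dmd_result <- function(x, ...) {
  cat(sprintf("dmd_result: %d meta-networks, %d stages, %d time points\n",
              ncol(x$V), length(x$U), nrow(x$V)))
  cat(sprintf("  final objective %.6g after %d iterations (restart %d of %d)\n",
              x$final_objective, length(x$objective_trace) - 1,
              x$chosen_restart, x$config$n_init))
  cat(sprintf("  orthogonality gap per stage: %s\n",
              paste(sprintf("%.3f", x$orthogonality_gap), collapse = ", ")))
  invisible(x)
}

#' Minimal trajectory distance (MTD)
#'
#' The minimum over component pairs of the Euclidean distance between
#' L2-normalized trajectory columns. Larger values mean more separable
#' trajectories; maximized over candidate p to choose the number of
#' meta-networks.
#'
#' @param V tau x p non-negative trajectory matrix, p >= 2.
#' @return scalar MTD >= 0 (at most sqrt(2) for non-negative columns).
#' @export
compute_mtd <- function(V) {
  V <- as.matrix(V)
  p <- ncol(V)
  if (p < 2)
    dm_stop("MTD undefined for fewer than 2 trajectories", "devmeta_parameter_error")
  norms <- sqrt(colSums(V^2))
  Vn <- sweep(V, 2, pmax(norms, .Machine$double.eps), "/")
  mtd <- Inf
  for (r in seq_len(p - 1)) for (s in (r + 1):p)
    mtd <- min(mtd, sqrt(sum((Vn[, r] - Vn[, s])^2)))
  mtd
}

#' Select the number of meta-networks by maximizing MTD
#'
#' Fits the factorization for each candidate p and returns the p attaining
#' the largest minimal trajectory distance (smallest p on ties).
#'
#' @param X a \code{\link{developmental_networks}} stack.
#' @param partition a \code{\link{stage_partition}}.
#' @param p_range integer candidates, all >= 2.
#' @param config a \code{\link{dmd_config}} template (its \code{p} is
#'   overridden per candidate; per-candidate child seeds derive from
#'   \code{config$seed}).
#' @return list with \code{p} (the selected count), \code{mtd} (named
#'   per-candidate curve), and \code{fits} (list of \code{dmd_result}).
#' @export
select_num_dms <- function(X, partition, p_range, config) {
  p_range <- sort(unique(as.integer(p_range)))
  if (any(p_range < 2))
    dm_stop("all candidate p must be >= 2", "devmeta_parameter_error")
  fits <- vector("list", length(p_range))
  mtd <- numeric(length(p_range))
  for (i in seq_along(p_range)) {
    cfg <- config
    cfg$p <- p_range[i]
    if (!is.null(config$seed)) cfg$seed <- child_seed(config$seed, i)
    fits[[i]] <- dmd_fit(X, partition, cfg)
    mtd[i] <- compute_mtd(fits[[i]]$V)
  }
  names(mtd) <- p_range
  sel <- p_range[which.max(mtd)]  # which.max returns the first (smallest p) tie
  list(p = sel, mtd = mtd, fits = fits)
}
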