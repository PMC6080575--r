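# shared test helpers: planted-model matching and small fixture builders

# Hungarian-match fitted components to a planted model; returns matched
# cosine similarities for the stacked stage-states and for the trajectories
match_to_planted <- function(fit, model) {
  p <- ncol(fit$V)
  stack <- function(U, r) as.numeric(vapply(U, function(u) u[, r],
                                            numeric(nrow(U[[1]]))))
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sim <- matrix(0, p, p)
  for (a in seq_len(p)) for (b in seq_len(p))
    sim[a, b] <- cosv(stack(fit$U, a), stack(model$U_star, b))
  perm <- solve_assignment(sim, maximize = TRUE)
  list(permutation = perm,
       cos_U = sim[cbind(seq_len(p), perm)],
       cos_V = vapply(seq_len(p), function(r)
         cosv(fit$V[, r], model$V_star[, perm[r]]), 0))
}

# all permutations of 1..n as a matrix (one per row); brute-force oracle
# for assignment problems
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, ifelse(sub >= i, sub + 1L, sub))))
}

# small random symmetric non-negative zero-diagonal network
random_network <- function(n, timepoint_label = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(runif(n * n), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  network(w, node_names = paste0("R", seq_len(n)),
          timepoint_label = timepoint_label)
}

# random developmental stack plus contiguous stage partition, for
# optimizer property tests
random_instance <- function(seed, max_nodes = 8, max_tau = 8, max_G = 3,
                            max_p = 4) {
  set.seed(seed)
  nn <- sample(4:max_nodes, 1)
  tau <- sample(4:max_tau, 1)
  G <- sample(1:min(max_G, floor(tau / 2)), 1)
  sizes <- rep(tau %/% G, G)
  extra <- tau - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  p <- sample(1:min(max_p, min(sizes)), 1)
  X <- developmental_networks(
    matrix(runif(nn * (nn - 1) / 2 * tau), nn * (nn - 1) / 2, tau),
    node_names = paste0("n", seq_len(nn)))
  list(X = X, partition = stage_partition(rep(seq_len(G), times = sizes)),
       p = p)
}

# noise level equal to a fraction of the planted model's mean signal
signal_scaled_noise <- function(seed, fraction = 0.05, ...) {
  noiseless <- generate_planted_networks(noise_sd = 0, seed = seed, ...)
  fraction * mean(noiseless$model$signal[noiseless$model$signal > 0])
}
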