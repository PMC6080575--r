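#' @keywords internal
dm_stop <- function(msg, class, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "devmeta_error", "error", "condition")))
}

#' @keywords internal
dm_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

#' Derive a child seed from a parent seed
#'
#' A fixed derivation rule so pipeline stages can be rerun in isolation
#' reproducibly from one top-level seed. Stays within 32-bit integer range.
#'
#' @param seed integer parent seed
#' @param k integer stage index (>= 1)
#' @return an integer seed
#' @export
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 10007) %% 2147483647)
}

# cosine similarity of two vectors; 0-vector convention: similarity 0
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
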