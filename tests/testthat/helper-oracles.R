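# Shared fixtures and independent brute-force oracles. The oracles are kept
# deliberately naive (explicit loops / exhaustive enumeration) so they stay
# independent of the vectorised implementation paths they check.

tiny_phantom <- function(seed = 1, shape = c(32, 32, 20), ...) {
  generate_phantom(phantom_spec(shape = shape, seed = seed, ...))
}

# voxel-counting Dice by explicit iteration
oracle_dice <- function(a, b) {
  na <- 0
  nb <- 0
  nab <- 0
  for (i in seq_along(a)) {
    if (a[i] == 1) na <- na + 1
    if (b[i] == 1) nb <- nb + 1
    if (a[i] == 1 && b[i] == 1) nab <- nab + 1
  }
  2 * nab / (na + nb)
}

oracle_pseudo_dice <- function(a, b, eps, variant = "as_printed") {
  na <- sum(a == 1)
  nb <- sum(b == 1)
  nab <- sum(a == 1 & b == 1)
  if (variant == "as_printed") {
    2 * (nab + eps) / (na + nb + eps)
  } else {
    (2 * nab + eps) / (na + nb + eps)
  }
}

# exhaustive top-k: evaluate all subsets of size k, maximize the score sum
# with lexicographic tie-break among maximizers
oracle_top_k <- function(scores, k) {
  n <- length(scores)
  k <- min(k, n)
  subsets <- utils::combn(n, k)
  sums <- apply(subsets, 2, function(idx) sum(scores[idx]))
  best <- which(sums == max(sums))
  # combn enumerates in lexicographic order, so the first maximizer wins
  sort(subsets[, best[1]])
}

random_mask_pair <- function(shape = c(6, 6, 6), p = NULL) {
  p <- p %||% runif(1, 0.05, 0.6)
  a <- array(as.integer(runif(prod(shape)) < p), shape)
  b <- array(as.integer(runif(prod(shape)) < p), shape)
  list(a = a, b = b)
}
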