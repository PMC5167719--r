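# Shared fixtures and independent brute-force oracles used across tests.

# small, fast simulation setup shared by most tests
test_config <- function(...) growth_config(...)
test_weather <- function() synthetic_weather()

# intercept-genotype parameters of the packaged model
intercept_params <- function() predict_parameters(rep(0, 31))

# brute-force front ranking by repeated peeling with the scalar `dominates`
brute_front_ranks <- function(obj, violation = NULL) {
  n <- nrow(obj)
  if (is.null(violation)) violation <- numeric(n)
  rank <- integer(n)
  remaining <- rep(TRUE, n)
  r <- 1L
  while (any(remaining)) {
    idx <- which(remaining)
    nd <- vapply(idx, function(i) {
      !any(vapply(idx, function(j) {
        j != i && dominates(obj[j, ], obj[i, ], violation[j], violation[i])
      }, logical(1)))
    }, logical(1))
    rank[idx[nd]] <- r
    remaining[idx[nd]] <- FALSE
    r <- r + 1L
  }
  rank
}

# brute-force non-dominated filter (indices kept)
brute_nondominated <- function(obj) {
  n <- nrow(obj)
  vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j) {
      j != i && dominates(obj[j, ], obj[i, ])
    }, logical(1)))
  }, logical(1))
}

# Monte-Carlo hypervolume estimate (minimization) inside the box
# [lower, ref]; independent check of the slicing algorithm
mc_hypervolume <- function(pts, ref, lower, n = 2e5) {
  m <- length(ref)
  U <- vapply(seq_len(m), function(k) runif(n, lower[k], ref[k]), numeric(n))
  dominated <- rep(FALSE, n)
  for (i in seq_len(nrow(pts))) {
    inside <- rep(TRUE, n)
    for (k in seq_len(m)) inside <- inside & U[, k] >= pts[i, k]
    dominated <- dominated | inside
  }
  mean(dominated) * prod(ref - lower)
}

# a genotype violating every inseparable pair: alleles alternate along each
# haplotype block
alternating_genotype <- function(pairs = peach_inseparable_pairs()) {
  g <- rep(0, 31)
  for (b in build_blocks(pairs)) {
    g[b] <- rep_len(c(0, 1), length(b))
  }
  g
}
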