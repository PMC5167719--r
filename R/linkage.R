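# Linkage constraints: loci closer than 12.5 cM are treated as inseparable.
# The 14 printed pairs chain into haplotype blocks (union-find), and the
# constrained allele space is reparameterised as one bit per block.

#' Inseparable locus pairs of the peach genetic model
#'
#' The 14 pairs of loci closer than 12.5 cM on the genetic map, which must
#' carry the same allele in any genetically feasible genotype. Pairs chain
#' (e.g. 16-17, 17-18, 18-19), so the transitive closure defines haplotype
#' blocks; see [build_blocks()].
#'
#' @param epsilon Feasibility tolerance used by the constraint-domination
#'   formulation (a genotype is feasible when its total violation is below
#'   `epsilon`).
#' @return A tibble with columns `pair`, `locus1`, `locus2` and attribute
#'   `epsilon`.
#' @export
peach_inseparable_pairs <- function(epsilon = 1e-9) {
  p <- tibble(
    pair = 1:14,
    locus1 = c(4L, 6L, 7L, 10L, 13L, 14L, 16L, 17L, 18L, 21L, 23L, 24L, 25L, 28L),
    locus2 = c(5L, 7L, 8L, 11L, 14L, 15L, 17L, 18L, 19L, 22L, 24L, 25L, 26L, 29L)
  )
  attr(p, "epsilon") <- epsilon
  p
}

as_pairs <- function(pairs) {
  pairs <- as_tibble(pairs)
  stopifnot(all(c("locus1", "locus2") %in% names(pairs)))
  pairs
}

#' Count linkage-constraint violations of genotypes
#'
#' A genotype violates a pair when the two inseparable loci carry different
#' alleles; it is genetically feasible iff the count is zero.
#'
#' @param genotypes Genotypes as accepted by [predict_parameters()].
#' @param pairs Pair table as from [peach_inseparable_pairs()].
#' @param n_loci Number of loci per genotype.
#' @return Integer vector, one violation count per individual.
#' @export
linkage_violations <- function(genotypes, pairs = peach_inseparable_pairs(),
                               n_loci = 31L) {
  g <- as_genotype_matrix(genotypes, n_loci)
  pairs <- as_pairs(pairs)
  if (nrow(pairs) == 0) return(rep(0L, nrow(g)))
  as.integer(rowSums(abs(g[, pairs$locus1, drop = FALSE] -
                           g[, pairs$locus2, drop = FALSE])))
}

#' Haplotype blocks from inseparable pairs
#'
#' Computes the transitive closure (union-find) of the pair list, partitioning
#' the loci into haplotype blocks; loci not touched by any pair become
#' singleton blocks. With the packaged peach pairs this gives 8 multi-locus
#' blocks and 9 singletons: 17 free binary dimensions.
#'
#' @inheritParams linkage_violations
#' @return An object of class `haplotype_blocks`: a list of sorted integer
#'   locus vectors, ordered by smallest member, covering `1..n_loci` exactly
#'   once.
#' @examples
#' length(build_blocks(peach_inseparable_pairs())) # 17
#' @export
build_blocks <- function(pairs = peach_inseparable_pairs(), n_loci = 31L) {
  pairs <- as_pairs(pairs)
  parent <- seq_len(n_loci)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs$locus1[k]); b <- find(pairs$locus2[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n_loci), find, integer(1))
  blocks <- unname(split(seq_len(n_loci), roots))
  blocks <- blocks[order(vapply(blocks, min, integer(1)))]
  structure(lapply(blocks, as.integer),
            class = "haplotype_blocks", n_loci = as.integer(n_loci))
}

#' @export
print.haplotype_blocks <- function(x, ...) {
  sizes <- lengths(x)
  cat("<haplotype_blocks>", length(x), "blocks over", attr(x, "n_loci"),
      "loci (", sum(sizes > 1), "multi-locus,", sum(sizes == 1), "singleton )\n")
  for (b in x[sizes > 1]) cat("  {", paste(b, collapse = ","), "}\n")
  invisible(x)
}

# block -> loci incidence matrix (n_blocks x n_loci)
block_incidence <- function(blocks) {
  n_loci <- attr(blocks, "n_loci")
  B <- matrix(0, nrow = length(blocks), ncol = n_loci)
  for (k in seq_along(blocks)) B[k, blocks[[k]]] <- 1
  B
}

#' Encode / decode genotypes on the haplotype-block representation
#'
#' The linkage-constrained allele space is reparameterised with one bit per
#' haplotype block: `decode_blocks()` expands block bits to full genotypes
#' (which by construction have zero linkage violations) and
#' `encode_blocks()` is its inverse on feasible genotypes.
#'
#' @param genotypes Feasible genotypes (zero violations w.r.t. the blocks).
#' @param block_bits 0/1 matrix (or vector) with one column per block.
#' @param blocks A [build_blocks()] result.
#' @return `encode_blocks()`: a tibble `block1..blockK`; `decode_blocks()`: a
#'   genotype tibble `loc1..locN`.
#' @export
encode_blocks <- function(genotypes, blocks = build_blocks()) {
  n_loci <- attr(blocks, "n_loci")
  g <- as_genotype_matrix(genotypes, n_loci)
  first <- vapply(blocks, function(b) b[1], integer(1))
  ok <- vapply(seq_along(blocks), function(k) {
    b <- blocks[[k]]
    all(g[, b, drop = FALSE] == g[, b[1]])
  }, logical(1))
  if (!all(ok)) {
    abort("Genotypes are infeasible: alleles differ within haplotype block(s).")
  }
  bits <- g[, first, drop = FALSE]
  colnames(bits) <- paste0("block", seq_along(blocks))
  as_tibble(bits)
}

#' @rdname encode_blocks
#' @export
decode_blocks <- function(block_bits, blocks = build_blocks()) {
  if (is.data.frame(block_bits)) block_bits <- as.matrix(block_bits)
  if (!is.matrix(block_bits)) block_bits <- matrix(block_bits, nrow = 1)
  if (ncol(block_bits) != length(blocks)) {
    abort(sprintf("Expected %d block bits, got %d.", length(blocks), ncol(block_bits)))
  }
  storage.mode(block_bits) <- "double"
  if (anyNA(block_bits) || !all(block_bits %in% c(0, 1))) {
    abort("Block bits must all be 0 or 1.")
  }
  genotype_tibble(block_bits %*% block_incidence(blocks))
}

#' Enumerate all block-feasible genotypes
#'
#' Expands every combination of block bits (2^K genotypes for K blocks) into
#' full genotypes. With the packaged peach blocks this is the whole
#' linkage-feasible search space: 2^17 = 131,072 genotypes.
#'
#' @param blocks A [build_blocks()] result.
#' @param as_matrix Return a bare 0/1 matrix instead of a tibble (cheaper for
#'   downstream linear algebra).
#' @return Genotypes, one row per block-bit combination, ordered by the
#'   binary value of the block bits (block 1 is the least significant bit).
#' @export
enumerate_block_genotypes <- function(blocks = build_blocks(), as_matrix = FALSE) {
  k <- length(blocks)
  idx <- 0:(2^k - 1)
  bits <- vapply(seq_len(k) - 1L, function(j) bitwAnd(bitwShiftR(idx, j), 1L),
                 integer(length(idx)))
  g <- bits %*% block_incidence(blocks)
  if (as_matrix) g else genotype_tibble(g)
}
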