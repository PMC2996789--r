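# Brute-force local-alignment oracle, independent of the DP implementation.
#
# Every local alignment is determined by the ordered sets of query and
# target positions placed in aligned (residue-residue) columns; the gaps
# between consecutive aligned columns are priced at their cheapest affine
# arrangement, gap_open + gap_extend * L per maximal run. Optimal local
# alignments never carry terminal gaps (trimming them raises the score), so
# maximizing over all equal-size position subsets of both sequences — plus
# the empty alignment at score 0 — enumerates the full search space.

sw_oracle <- function(a, b, S, gap_open = 11, gap_extend = 1) {
  ac <- strsplit(a, "", fixed = TRUE)[[1L]]
  bc <- strsplit(b, "", fixed = TRUE)[[1L]]
  m <- length(ac)
  n <- length(bc)
  gap_cost <- function(L) sum(gap_open + gap_extend * L[L > 0])
  best <- 0
  for (p in seq_len(min(m, n))) {
    ia_all <- utils::combn(m, p)
    ib_all <- utils::combn(n, p)
    nb <- ncol(ib_all)
    # cheapest internal gap cost on the target side, per subset
    gcost_b <- vapply(seq_len(nb), function(j) {
      if (p > 1) gap_cost(diff(ib_all[, j]) - 1L) else 0
    }, numeric(1))
    for (i in seq_len(ncol(ia_all))) {
      ia <- ia_all[, i]
      gcost_a <- if (p > 1) gap_cost(diff(ia) - 1L) else 0
      M <- S[ac[ia], bc, drop = FALSE] # p x n substitution slice
      col_scores <- colSums(matrix(
        M[cbind(rep(seq_len(p), nb), as.vector(ib_all))],
        nrow = p
      ))
      cand <- max(col_scores - gcost_b) - gcost_a
      if (cand > best) best <- cand
    }
  }
  best
}
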