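# Seeded random inputs for property-style tests.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1L]]

random_protein <- function(n, seed, id = "rnd", alphabet = AA20) {
  withr::with_seed(seed, {
    protein_sequence(id, paste(sample(alphabet, n, replace = TRUE),
      collapse = ""
    ))
  })
}

# Construct a disorder_profile object directly from a score vector, for
# tests that need exact, hand-specified score tracks.
fake_profile <- function(scores, seq_id = "fake", residues = NULL,
                         window = 1L, threshold = 0.5) {
  if (is.null(residues)) residues <- strrep("A", length(scores))
  structure(
    list(
      seq_id = seq_id, residues = residues, scores = scores,
      window = window, scale_name = "constructed", threshold = threshold
    ),
    class = "disorder_profile"
  )
}

# Construct an sw_alignment object from two gapped strings.
fake_alignment <- function(q, t, orientation = "normal") {
  qs <- gsub("-", "", q, fixed = TRUE)
  ts <- gsub("-", "", t, fixed = TRUE)
  aln <- structure(
    list(
      query_id = "q", target_id = "t",
      aligned_query = q, aligned_target = t, score = 1,
      q_start = 1L, q_end = nchar(qs), t_start = 1L, t_end = nchar(ts),
      identity_pct = NA_real_, orientation = orientation
    ),
    class = "sw_alignment"
  )
  if (nzchar(q)) aln$identity_pct <- percent_identity(aln)
  aln
}
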