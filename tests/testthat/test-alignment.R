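test_that("a perfect short match scores the summed diagonal", {
  aln <- sw_align("LLLL", "LLLL") # BLOSUM62 L/L = 4, over 4 columns
  expect_equal(aln$score, 16)
  expect_equal(aln$identity_pct, 100)
  expect_equal(c(aln$q_start, aln$q_end, aln$t_start, aln$t_end), c(1L, 4L, 1L, 4L))
  expect_equal(aln$aligned_query, "LLLL")
})

test_that("sequences with no positively scoring pair give the empty alignment", {
  aln <- sw_align("G", "W") # BLOSUM62 G/W = -2
  expect_equal(aln$score, 0)
  expect_equal(aln$aligned_query, "")
  expect_true(is.na(aln$q_start))
  expect_error(percent_identity(aln), "empty alignment")
})

test_that("alignment strings reproduce the claimed ungapped subsequences", {
  for (i in 1:40) {
    a <- random_protein(sample(15:40, 1L), seed = 7000 + i)
    b <- random_protein(sample(15:40, 1L), seed = 7500 + i)
    aln <- sw_align(a, b)
    if (aln$score == 0) next
    q <- gsub("-", "", aln$aligned_query, fixed = TRUE)
    t <- gsub("-", "", aln$aligned_target, fixed = TRUE)
    expect_equal(q, substr(a$residues, aln$q_start, aln$q_end))
    expect_equal(t, substr(b$residues, aln$t_start, aln$t_end))
    expect_equal(nchar(aln$aligned_query), nchar(aln$aligned_target))
    cols <- cbind(
      strsplit(aln$aligned_query, "")[[1L]],
      strsplit(aln$aligned_target, "")[[1L]]
    )
    expect_false(any(cols[, 1L] == "-" & cols[, 2L] == "-"))
  }
})

test_that("scores match the brute-force enumeration oracle on small pairs", {
  S <- substitution_matrix("BLOSUM62")
  reduced <- c("L", "S", "K", "E")
  for (i in 1:60) {
    a <- random_protein(sample(3:8, 1L), seed = 8000 + i, alphabet = reduced)
    b <- random_protein(sample(3:8, 1L), seed = 8500 + i, alphabet = reduced)
    expect_equal(
      sw_align(a, b)$score,
      sw_oracle(a$residues, b$residues, S),
      info = paste(a$residues, b$residues)
    )
  }
})

test_that("scores agree with an independent affine-gap local aligner", {
  S <- substitution_matrix("BLOSUM62")
  for (i in 1:40) {
    a <- random_protein(sample(20:60, 1L), seed = 9000 + i)
    b <- random_protein(sample(20:60, 1L), seed = 9500 + i)
    ours <- sw_align(a, b)$score
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a$residues), Biostrings::AAString(b$residues),
      substitutionMatrix = S, gapOpening = 11, gapExtension = 1,
      type = "local", scoreOnly = TRUE
    )
    if (ours > 0) expect_equal(ours, ref, info = paste("pair", i))
  }
})

test_that("score is symmetric and monotone under sequence extension", {
  for (i in 1:25) {
    a <- random_protein(sample(10:30, 1L), seed = 10000 + i)
    b <- random_protein(sample(10:30, 1L), seed = 10500 + i)
    expect_equal(sw_align(a, b)$score, sw_align(b, a)$score)
    ext <- protein_sequence("ext", paste0(b$residues, "WLK"))
    expect_gte(sw_align(a, ext)$score, sw_align(a, b)$score)
  }
})

test_that("percent identity counts gap columns in the denominator", {
  expect_equal(percent_identity(fake_alignment("LVKQEAERLS", "LVKQEAERLS")), 100)
  expect_equal(percent_identity(fake_alignment("LVKQEAERLS", "LVKQEAWWWW")), 60)
  expect_equal(percent_identity(fake_alignment("LVKQEAERL-", "LVKQEAERLS")), 90)
})

test_that("empirical p-values follow the add-one formula and never hit zero", {
  q <- random_protein(15, seed = 21)
  t <- random_protein(80, seed = 22)
  # a score above every achievable decoy score
  ev_hi <- empirical_evalue(q, t, score = 1e6, n_shuffles = 999, db_size = 1, seed = 3)
  expect_equal(ev_hi$p_emp, 1 / 1000)
  expect_equal(ev_hi$evalue, 1 / 1000)
  # a score at the floor: every decoy ties or beats it
  ev_lo <- empirical_evalue(q, t, score = -1, n_shuffles = 99, db_size = 5, seed = 3)
  expect_equal(ev_lo$p_emp, 1)
  expect_equal(ev_lo$evalue, 5)
  expect_gt(ev_lo$p_emp, 0)
  expect_gte(ev_lo$evalue, ev_lo$p_emp)
  expect_error(empirical_evalue(q, t, 10, n_shuffles = 50, seed = 1), "at least 99")
})

test_that("empirical E-values are deterministic for a fixed seed", {
  q <- random_protein(20, seed = 31)
  t <- random_protein(100, seed = 32)
  s <- sw_align(q, t)$score
  e1 <- empirical_evalue(q, t, s, n_shuffles = 199, seed = 17)
  e2 <- empirical_evalue(q, t, s, n_shuffles = 199, seed = 17)
  expect_identical(e1$n_ge, e2$n_ge)
  expect_identical(e1$p_emp, e2$p_emp)
})

test_that("unknown residues error unless permissive mapping is requested", {
  expect_error(sw_align("MK1", "MKV"), "absent from the substitution matrix")
  # a reduced matrix lacking W: strict encoding fails, permissive maps W -> X
  keep <- c("M", "K", "V", "X")
  S4 <- substitution_matrix("BLOSUM62")[keep, keep]
  expect_error(sw_align("MKWV", "MKVV", matrix = S4), "absent")
  aln <- sw_align("MKWV", "MKVV", matrix = S4, permissive = TRUE)
  expect_true(aln$score > 0)
})
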