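test_that("residue classes partition the 20-letter alphabet", {
  classes <- residue_classes()
  expect_setequal(names(classes)[classes != "special"], AA20)
  expect_equal(anyDuplicated(names(classes)), 0L)
})

test_that("pattern similarity is the class-match column fraction", {
  expect_equal(pattern_similarity(fake_alignment("KLMV", "KLMV")), 1.0)
  # K,R both positive; L,V both hydrophobic
  expect_equal(pattern_similarity(fake_alignment("KL", "RV")), 1.0)
  # K positive vs D negative; L hydrophobic vs E negative
  expect_equal(pattern_similarity(fake_alignment("KL", "DE")), 0.0)
  # gap column counts as mismatch in the denominator
  expect_equal(pattern_similarity(fake_alignment("KL-V", "RVSV")), 0.75)
  expect_error(pattern_similarity(fake_alignment("", "")), "empty")
})

test_that("identity match implies class match, so similarity >= identity/100", {
  for (i in 1:50) {
    a <- random_protein(sample(15:40, 1L), seed = 11000 + i)
    b <- random_protein(sample(15:40, 1L), seed = 11500 + i)
    aln <- sw_align(a, b)
    if (aln$score == 0) next
    expect_gte(
      pattern_similarity(aln) + 1e-12, aln$identity_pct / 100
    )
  }
})

test_that("hydrophobic moment vanishes on homopolymers over whole turns", {
  # 18 residues x 100 degrees = 5 full turns: unit vectors cancel exactly
  expect_equal(hydrophobic_moment(strrep("L", 18), delta_deg = 100), 0,
    tolerance = 1e-12
  )
  expect_equal(hydrophobic_moment(strrep("K", 18), delta_deg = 100), 0,
    tolerance = 1e-12
  )
})

test_that("two-residue windows at 180 degrees give |h1 - h2| / 2", {
  hp <- get_scale("hydrophobicity")
  h <- hp$values
  expect_equal(
    hydrophobic_moment("IR", delta_deg = 180, hydropathy = hp),
    abs(h[["I"]] - h[["R"]]) / 2
  )
  expect_equal(
    hydrophobic_moment("LK", delta_deg = 180, hydropathy = hp),
    abs(h[["L"]] - h[["K"]]) / 2
  )
  expect_error(hydrophobic_moment("L"), "at least 2")
})

test_that("hydrophobic moment is invariant under window reversal", {
  for (i in 1:100) {
    w <- random_protein(sample(5:30, 1L), seed = 12000 + i)
    expect_equal(
      hydrophobic_moment(w$residues),
      hydrophobic_moment(reverse_sequence(w)$residues),
      tolerance = 1e-12
    )
  }
})

test_that("an idealized amphipathic helix has a larger moment than a scramble", {
  # hydrophobic every ~3.6 residues: one face hydrophobic
  amphipathic <- "LKKLLKKLLKKLLKKLLK"
  scrambled <- shuffle_sequence(protein_sequence("a", amphipathic), seed = 4)
  expect_gt(
    hydrophobic_moment(amphipathic),
    hydrophobic_moment(scrambled$residues)
  )
})

test_that("PPII motif finders match the class I and class II patterns", {
  hits1 <- find_ppii_motifs("ARTTPQAPG")
  expect_equal(nrow(hits1), 1L)
  expect_equal(hits1$class, "I")
  expect_equal(hits1$motif, "RTTPQAP")
  expect_equal(c(hits1$start, hits1$end), c(2L, 8L))

  hits2 <- find_ppii_motifs("GPATPLRG")
  expect_equal(nrow(hits2), 1L)
  expect_equal(hits2$class, "II")
  expect_equal(hits2$motif, "PATPLR")
  expect_equal(c(hits2$start, hits2$end), c(2L, 7L))

  expect_equal(nrow(find_ppii_motifs("GARKLMEFWSTD")), 0L)
})

test_that("overlapping PPII occurrences are all reported", {
  # hand enumeration by direct position checks, independent of the regex
  enumerate <- function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    n <- length(ch)
    out <- list()
    for (i in seq_len(max(n - 6L, 0L))) {
      if (ch[i] == "R" && ch[i + 3L] == "P" && ch[i + 6L] == "P") {
        out[[length(out) + 1L]] <- c("I", i, i + 6L)
      }
    }
    for (i in seq_len(max(n - 5L, 0L))) {
      if (ch[i] == "P" && ch[i + 3L] == "P" && ch[i + 5L] == "R") {
        out[[length(out) + 1L]] <- c("II", i, i + 5L)
      }
    }
    out
  }
  strings <- c(
    "RPPPRPPPPP", # overlapping class I and II hits
    "PPRPPRPPRPPR",
    "RAAPAAPAAPAAP", # chained class I
    withr::with_seed(13, paste(
      sample(c("P", "R", "A", "L"), 40, replace = TRUE),
      collapse = ""
    ))
  )
  for (s in strings) {
    truth <- enumerate(s)
    hits <- find_ppii_motifs(s)
    expect_equal(nrow(hits), length(truth), info = s)
    got <- Map(c, hits$class, hits$start, hits$end)
    expect_setequal(
      vapply(got, paste, "", collapse = ":"),
      vapply(truth, paste, "", collapse = ":")
    )
  }
})

test_that("disorder context separates the four situations", {
  # span centred in a 100-residue disordered run between ordered domains
  prof <- fake_profile(c(rep(0.2, 50), rep(0.8, 100), rep(0.2, 50)))
  expect_equal(disorder_context(c(90, 110), prof), "flanked_by_disorder")
  # a ~25-residue disordered run connecting ordered domains is a linker
  prof_linker <- fake_profile(c(rep(0.2, 50), rep(0.8, 25), rep(0.2, 50)))
  expect_equal(disorder_context(c(55, 70), prof_linker), "short_linker")
  # a 40-residue run is still a linker under the 50-residue convention
  prof_40 <- fake_profile(c(rep(0.2, 50), rep(0.8, 40), rep(0.2, 50)))
  expect_equal(disorder_context(c(60, 80), prof_40), "short_linker")
  # a terminal disordered run of 60 residues is a tail
  prof_tail <- fake_profile(c(rep(0.8, 60), rep(0.2, 100)))
  expect_equal(disorder_context(c(10, 30), prof_tail), "disordered_tail")
  # fully ordered surroundings
  prof_ord <- fake_profile(rep(0.2, 100))
  expect_equal(disorder_context(c(40, 60), prof_ord), "ordered")
  # a structure-prone dip bordered by long disordered runs on both sides
  prof_dip <- fake_profile(c(rep(0.8, 60), rep(0.2, 15), rep(0.8, 60)))
  expect_equal(disorder_context(c(61, 75), prof_dip), "flanked_by_disorder")
  expect_error(disorder_context(c(90, 200), prof_ord), "outside")
})

test_that("the three-criterion verdict follows its stated gates", {
  pos <- classify_ribs(65, 0.8, "flanked_by_disorder")
  expect_equal(pos$label, "retro_morf_candidate")
  expect_true(all(c(pos$criterion1, pos$criterion2, pos$criterion3)))
  expect_length(pos$reasons, 0L)

  normal <- classify_ribs(65, 0.8, "disordered_tail", orientation = "normal")
  expect_equal(normal$label, "morf_match")

  # identity exactly at the boundary is rejected: the criterion is strict
  edge <- classify_ribs(60.0, 0.9, "flanked_by_disorder")
  expect_equal(edge$label, "rejected")
  expect_false(edge$criterion1)
  expect_match(edge$reasons[1], "identity")

  ordered <- classify_ribs(90, 0.9, "ordered")
  expect_equal(ordered$label, "rejected")
  expect_false(ordered$criterion3)
  expect_match(paste(ordered$reasons, collapse = " "), "context")

  linker <- classify_ribs(90, 0.9, "short_linker")
  expect_false(linker$criterion3)
})

test_that("verdicts are monotone and recomputable from their booleans", {
  contexts <- c("flanked_by_disorder", "disordered_tail", "short_linker", "ordered")
  for (i in 1:60) {
    set1 <- withr::with_seed(13000 + i, list(
      id = runif(1, 0, 100), ps = runif(1), ctx = sample(contexts, 1L)
    ))
    v <- classify_ribs(set1$id, set1$ps, set1$ctx)
    expect_equal(
      v$label != "rejected",
      v$criterion1 && v$criterion2 && v$criterion3
    )
    if (v$label == "rejected") expect_gt(length(v$reasons), 0L)
    # raising identity and similarity never flips positive -> rejected
    v_up <- classify_ribs(min(set1$id + 20, 100), min(set1$ps + 0.2, 1), set1$ctx)
    if (v$label != "rejected") expect_true(v_up$label != "rejected")
  }
})
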