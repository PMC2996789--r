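# A small deterministic scenario used across the pipeline tests: one query
# fragment whose exact reversed copy is planted inside a long disordered
# background target.
make_planted_scene <- function(seed = 101, n_decoys = 3L) {
  motif <- random_motif(15, seed = seed, id = "frag")
  bg <- generate_background(400, seed = seed + 1, id = "T1")
  planted <- plant_motif(bg, motif, 200, reversed = TRUE, seed = seed + 2)
  decoys <- lapply(seq_len(n_decoys), function(i) {
    generate_background(350, seed = seed + 10 + i, id = paste0("D", i))
  })
  list(query = motif, db = c(list(planted$seq), decoys), truth = planted$truth)
}

test_that("an exact reversed copy is found as a positive reversed hit", {
  scene <- make_planted_scene()
  res <- scan_database(scene$query, scene$db, "both", scan_params(seed = 7))
  hits <- res$hits
  planted_hits <- hits[hits$target_id == "T1" & hits$orientation == "reversed", ]
  expect_equal(nrow(planted_hits), 1L)
  expect_equal(planted_hits$identity_pct, 100)
  expect_equal(planted_hits$label, "retro_morf_candidate")
  expect_equal(c(planted_hits$t_start, planted_hits$t_end), c(200L, 214L))
  expect_true(all(
    planted_hits$criterion1 & planted_hits$criterion2 & planted_hits$criterion3
  ))
})

test_that("orientation 'both' is the union of the single-orientation scans", {
  scene <- make_planted_scene(seed = 131)
  params <- scan_params(seed = 3)
  both <- scan_database(scene$query, scene$db, "both", params)$hits
  normal <- scan_database(scene$query, scene$db, "normal", params)$hits
  reversed <- scan_database(scene$query, scene$db, "reversed", params)$hits
  key <- function(df) {
    sort(paste(df$query_id, df$target_id, df$orientation, df$score))
  }
  expect_setequal(key(both), c(key(normal), key(reversed)))
})

test_that("identical inputs and seed give identical reports", {
  scene <- make_planted_scene(seed = 151)
  r1 <- scan_database(scene$query, scene$db, "both", scan_params(seed = 11))
  r2 <- scan_database(scene$query, scene$db, "both", scan_params(seed = 11))
  expect_identical(r1$hits, r2$hits)
  tsv1 <- withr::local_tempfile()
  tsv2 <- withr::local_tempfile()
  write_hits_tsv(r1, tsv1)
  write_hits_tsv(r2, tsv2)
  expect_identical(readLines(tsv1), readLines(tsv2))
})

test_that("re-reversing a reversed hit's aligned query recovers the fragment", {
  scene <- make_planted_scene(seed = 171)
  res <- scan_database(scene$query, scene$db, "reversed", scan_params(seed = 5))
  idx <- which(res$hits$target_id == "T1")
  expect_gte(length(idx), 1L)
  aln <- res$alignments[[idx[1L]]]
  matched <- gsub("-", "", aln$aligned_query, fixed = TRUE)
  unreversed <- paste(rev(strsplit(matched, "")[[1L]]), collapse = "")
  expect_true(grepl(unreversed, scene$query$residues, fixed = TRUE))
})

test_that("loosening the prescan E-value threshold yields a superset of hits", {
  scene <- make_planted_scene(seed = 191)
  strict <- scan_database(
    scene$query, scene$db, "both",
    scan_params(seed = 9, prescan_max_evalue = 0.5)
  )$hits
  loose <- scan_database(
    scene$query, scene$db, "both",
    scan_params(seed = 9, prescan_max_evalue = 4)
  )$hits
  key <- function(df) paste(df$query_id, df$target_id, df$orientation)
  expect_true(all(key(strict) %in% key(loose)))
  expect_gte(nrow(loose), nrow(strict))
})

test_that("hits are sorted by E-value then score", {
  scene <- make_planted_scene(seed = 211)
  hits <- scan_database(scene$query, scene$db, "both", scan_params(seed = 2))$hits
  if (nrow(hits) > 1L) {
    expect_true(all(diff(hits$evalue) >= 0))
    same_e <- which(diff(hits$evalue) == 0)
    expect_true(all(hits$score[same_e] >= hits$score[same_e + 1L]))
  }
})

test_that("run summaries conserve totals across breakdowns", {
  scene <- make_planted_scene(seed = 231)
  res <- scan_database(scene$query, scene$db, "both", scan_params(seed = 13))
  s <- summarize_run(res)
  expect_equal(sum(s$by_orientation$n_hits), s$n_hits)
  expect_equal(sum(s$by_orientation$n_positive), s$n_positive)
  expect_equal(sum(s$per_query$n_hits), s$n_hits)
  expect_equal(s$n_positive, sum(res$hits$label != "rejected"))

  empty <- summarize_run(res$hits[0, , drop = FALSE])
  expect_equal(empty$n_hits, 0L)
  expect_equal(empty$n_positive, 0L)
  expect_equal(nrow(empty$by_orientation), 0L)
})

test_that("verdict JSON export round-trips the hit table", {
  scene <- make_planted_scene(seed = 251)
  res <- scan_database(scene$query, scene$db, "both", scan_params(seed = 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_verdicts_json(res, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$seed, 4L)
  expect_equal(nrow(parsed$hits), nrow(res$hits))
  expect_equal(parsed$hits$label, res$hits$label)
})

test_that("YAML config overrides defaults and rejects unknown keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "prescan_max_evalue: 0.25",
    "window: 41",
    "ribs:",
    "  pattern_threshold: 0.7"
  ), path)
  cfg <- read_config(path)
  expect_equal(cfg$prescan_max_evalue, 0.25)
  expect_equal(cfg$window, 41L)
  expect_equal(cfg$ribs$pattern_threshold, 0.7)
  expect_equal(cfg$gap_open, 11) # untouched default

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("no_such_option: 1", bad)
  expect_error(read_config(bad), "unknown configuration key")
})
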