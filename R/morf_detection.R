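# Dip detection: structure-prone segments inside disordered regions.
#
# A dip is a maximal run of disorder scores below the threshold, bordered on
# both sides (or one side, for terminal tails) by disordered runs of
# sufficient length. Dips in a disorder profile are the classical signature
# of MoRFs: they carry a much higher content of hydrophobic residues than
# their flanking regions, which biases local composition toward structure.

#' Default dip-detection parameters
#'
#' @param threshold Order/disorder boundary (default 0.5).
#' @param min_dip_len,max_dip_len Dip length bounds (default 5-30: MoRFs are
#'   short segments, on the order of one to a few helical turns).
#' @param min_flank_len Minimum length of the adjacent disordered run(s)
#'   (default 10).
#' @param min_depth Minimum contrast `flank_mean - dip_mean` (default 0.2,
#'   separating sharp dips from profile noise).
#' @param allow_tail Also accept single-flank dips touching a terminus
#'   (default `TRUE`; binding segments can sit in disordered tails).
#' @return A named list of parameters for [detect_dips()].
#' @export
dip_params <- function(threshold = 0.5, min_dip_len = 5L, max_dip_len = 30L,
                       min_flank_len = 10L, min_depth = 0.2,
                       allow_tail = TRUE) {
  stopifnot(
    threshold > 0, threshold < 1,
    min_dip_len >= 1L, max_dip_len >= min_dip_len,
    min_flank_len >= 1L, min_depth >= 0
  )
  list(
    threshold = threshold,
    min_dip_len = as.integer(min_dip_len),
    max_dip_len = as.integer(max_dip_len),
    min_flank_len = as.integer(min_flank_len),
    min_depth = min_depth,
    allow_tail = isTRUE(allow_tail)
  )
}

#' Detect dips (MoRF candidates) in a disorder profile
#'
#' Scans the profile for maximal runs of scores below the threshold whose
#' length lies within the configured bounds, whose neighbouring
#' above-threshold runs are long enough, and whose contrast
#' (`flank_mean - dip_mean`) reaches `min_depth`. With
#' `params$allow_tail = TRUE`, a qualifying run touching a terminus with a
#' single qualifying flank is returned with `is_tail = TRUE`.
#'
#' @param profile A [disorder_profile()].
#' @param params See [dip_params()].
#' @return A data.frame of candidates, sorted by `start`, non-overlapping;
#'   columns: `seq_id`, `start`, `end` (1-based inclusive), `length`,
#'   `dip_mean`, `left_flank_len`, `right_flank_len`, `flank_mean`, `depth`,
#'   `is_tail`, `hydro_enrichment` (`NA` until annotated via
#'   [hydrophobic_enrichment()] or [annotate_candidates()]).
#' @export
detect_dips <- function(profile, params = dip_params()) {
  stopifnot(inherits(profile, "disorder_profile"))
  scores <- profile$scores
  runs <- logical_runs(scores < params$threshold)
  out <- list()
  for (i in seq_len(nrow(runs))) {
    if (!runs$value[i]) next # a disordered run, not a dip
    len <- runs$end[i] - runs$start[i] + 1L
    if (len < params$min_dip_len || len > params$max_dip_len) next
    left_len <- if (i > 1L) runs$end[i - 1L] - runs$start[i - 1L] + 1L else 0L
    right_len <- if (i < nrow(runs)) runs$end[i + 1L] - runs$start[i + 1L] + 1L else 0L
    left_ok <- left_len >= params$min_flank_len
    right_ok <- right_len >= params$min_flank_len
    at_start <- runs$start[i] == 1L
    at_end <- runs$end[i] == length(scores)
    is_tail <- FALSE
    if (left_ok && right_ok) {
      flank_idx <- c(
        runs$start[i - 1L]:runs$end[i - 1L],
        runs$start[i + 1L]:runs$end[i + 1L]
      )
    } else if (params$allow_tail && at_start && right_ok) {
      flank_idx <- runs$start[i + 1L]:runs$end[i + 1L]
      is_tail <- TRUE
    } else if (params$allow_tail && at_end && left_ok) {
      flank_idx <- runs$start[i - 1L]:runs$end[i - 1L]
      is_tail <- TRUE
    } else {
      next
    }
    dip_mean <- mean(scores[runs$start[i]:runs$end[i]])
    flank_mean <- mean(scores[flank_idx])
    depth <- flank_mean - dip_mean
    if (depth < params$min_depth) next
    out[[length(out) + 1L]] <- data.frame(
      seq_id = profile$seq_id,
      start = runs$start[i], end = runs$end[i], length = len,
      dip_mean = dip_mean,
      left_flank_len = if (left_ok) left_len else 0L,
      right_flank_len = if (right_ok) right_len else 0L,
      flank_mean = flank_mean, depth = depth, is_tail = is_tail,
      hydro_enrichment = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(
      seq_id = character(), start = integer(), end = integer(),
      length = integer(), dip_mean = numeric(), left_flank_len = integer(),
      right_flank_len = integer(), flank_mean = numeric(), depth = numeric(),
      is_tail = logical(), hydro_enrichment = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Default hydrophobic residue set
#'
#' The standard apolar set used for enrichment and pattern statistics.
#' @return Character vector `{A, C, F, I, L, M, V, W}`.
#' @export
hydrophobic_set <- function() c("A", "C", "F", "I", "L", "M", "V", "W")

#' Hydrophobic enrichment of a dip over its flanks
#'
#' Fraction of hydrophobic residues inside the dip minus the fraction over
#' its adjacent disordered runs; a difference (not a ratio) so that
#' hydrophobe-free flanks pose no division hazard. Range \[-1, 1\].
#'
#' @param seq The [protein_sequence()] the candidate was called on.
#' @param cand One row of the data.frame returned by [detect_dips()].
#' @param hydro_set Residue class treated as hydrophobic (default
#'   [hydrophobic_set()]).
#' @return A single numeric value.
#' @export
hydrophobic_enrichment <- function(seq, cand, hydro_set = hydrophobic_set()) {
  stopifnot(inherits(seq, "protein_sequence"), nrow(cand) == 1L)
  n <- nchar(seq$residues)
  if (cand$start < 1L || cand$end > n) {
    stop("candidate interval outside sequence", call. = FALSE)
  }
  chars <- seq_chars(seq)
  dip_frac <- mean(chars[cand$start:cand$end] %in% hydro_set)
  flank_idx <- integer()
  if (cand$left_flank_len > 0L) {
    flank_idx <- c(flank_idx, (cand$start - cand$left_flank_len):(cand$start - 1L))
  }
  if (cand$right_flank_len > 0L) {
    flank_idx <- c(flank_idx, (cand$end + 1L):(cand$end + cand$right_flank_len))
  }
  if (length(flank_idx) == 0L) {
    if (!isTRUE(cand$is_tail)) {
      stop("candidate has no flanks but is not a tail", call. = FALSE)
    }
    stop("tail candidate has zero-length flank record", call. = FALSE)
  }
  flank_frac <- mean(chars[flank_idx] %in% hydro_set)
  dip_frac - flank_frac
}

#' Annotate dip candidates with hydrophobic enrichment and rank them
#'
#' Fills the `hydro_enrichment` column for every candidate and sorts by
#' depth, then enrichment (both decreasing) — the package's ranking
#' convention for choosing which candidates to scan first.
#'
#' @param seq The [protein_sequence()] the candidates were called on.
#' @param candidates Data.frame from [detect_dips()].
#' @param hydro_set See [hydrophobic_enrichment()].
#' @return The annotated, re-ranked candidate data.frame.
#' @export
annotate_candidates <- function(seq, candidates,
                                hydro_set = hydrophobic_set()) {
  if (nrow(candidates) == 0L) return(candidates)
  for (i in seq_len(nrow(candidates))) {
    candidates$hydro_enrichment[i] <-
      hydrophobic_enrichment(seq, candidates[i, , drop = FALSE], hydro_set)
  }
  candidates[order(-candidates$depth, -candidates$hydro_enrichment), ,
    drop = FALSE
  ]
}

#' Extract candidate dip intervals as query fragments
#'
#' @param seq The source [protein_sequence()].
#' @param candidates Data.frame from [detect_dips()].
#' @return A list of [protein_sequence()] fragments (ids
#'   `<id>:<start>-<end>`), ready for [scan_database()].
#' @export
extract_candidate_fragments <- function(seq, candidates) {
  lapply(seq_len(nrow(candidates)), function(i) {
    subsequence(seq, candidates$start[i], candidates$end[i])
  })
}
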