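# The decision core: three criteria turn an alignment hit into a verdict.
#
#   (1) sequence identity strictly above 60%;
#   (2) conserved hydrophobic/charge pattern across the alignment, measured
#       as the fraction of columns whose residues fall in the same
#       biochemical class;
#   (3) the matched span on the target is disordered, disorder-flanked, or
#       in a disordered tail — short disordered runs wedged between ordered
#       domains are treated as linkers, not binding regions, and rejected.
#
# Amphipathicity (helical hydrophobic moment) and polyproline-II motif
# hits are supporting annotations, not gates: they flag segments that could
# present one face of an amphipathic helix or an SH3-binding PPII ligand,
# two geometries especially tolerant of sequence reversal.

#' Default residue class partition
#'
#' Every residue belongs to exactly one class: hydrophobic
#' `{A,C,F,I,L,M,V,W}`, polar `{G,N,Q,S,T,Y,P}`, positive `{K,R,H}`,
#' negative `{D,E}`. The `special` class is reserved for ambiguity codes.
#'
#' @return A named character vector mapping residue -> class name.
#' @export
residue_classes <- function() {
  map <- c(
    setNames(rep("hydrophobic", 8L), c("A", "C", "F", "I", "L", "M", "V", "W")),
    setNames(rep("polar", 7L), c("G", "N", "Q", "S", "T", "Y", "P")),
    setNames(rep("positive", 3L), c("K", "R", "H")),
    setNames(rep("negative", 2L), c("D", "E")),
    setNames(rep("special", 4L), c("X", "B", "Z", "U"))
  )
  map
}

#' Hydrophobic/charge pattern similarity of an alignment
#'
#' Fraction of alignment columns whose two residues are both non-gap and
#' fall in the same class of `classes`. Gap columns count as mismatches (in
#' the denominator), mirroring the identity convention. Because identical
#' residues always share a class, `pattern_similarity >= identity/100`.
#'
#' @param aln An [sw_align()] result (non-empty).
#' @param classes Residue -> class map (default [residue_classes()]).
#' @return Numeric in \[0, 1\].
#' @export
pattern_similarity <- function(aln, classes = residue_classes()) {
  stopifnot(inherits(aln, "sw_alignment"))
  if (!nzchar(aln$aligned_query)) {
    stop("pattern similarity is undefined for an empty alignment",
      call. = FALSE
    )
  }
  q <- strsplit(aln$aligned_query, "", fixed = TRUE)[[1L]]
  t <- strsplit(aln$aligned_target, "", fixed = TRUE)[[1L]]
  non_gap <- q != "-" & t != "-"
  same <- non_gap & classes[q] == classes[t]
  same[is.na(same)] <- FALSE
  sum(same) / length(q)
}

#' Helical hydrophobic moment of a residue window
#'
#' The classical helical-wheel amphipathicity measure: place residue k's
#' hydrophobicity H_k as a vector at angle k*delta and report the magnitude
#' of the vector sum divided by the window length,
#' `mu_H = |sum_k H_k (cos k*delta, sin k*delta)| / n`.
#' With delta = 100 degrees (the alpha-helix turn angle) a large mu_H means
#' hydrophobic residues cluster on one helix face. The measure is invariant
#' under window reversal — the quantitative face of the observation that
#' retro-sequences keep their hydrophobic/hydrophilic pattern.
#'
#' @param window A [protein_sequence()] or residue string, length >= 2.
#' @param delta_deg Angular step per residue in degrees (default 100 for an
#'   alpha-helix; use 120 for a PPII helix's three residues per turn).
#' @param hydropathy A `residue_scale` supplying per-residue hydrophobicity
#'   (default the shipped `hydrophobicity` scale, where I = 1 and R = 0).
#' @return A single non-negative numeric.
#' @export
hydrophobic_moment <- function(window, delta_deg = 100,
                               hydropathy = get_scale("hydrophobicity")) {
  chars <- strsplit(as_residue_string(window), "", fixed = TRUE)[[1L]]
  if (length(chars) < 2L) {
    stop("`window` must contain at least 2 residues", call. = FALSE)
  }
  h <- scale_lookup(hydropathy, chars)
  ang <- (seq_along(h) - 1L) * delta_deg * pi / 180
  sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / length(h)
}

#' Find polyproline-II SH3-binding motifs
#'
#' Reports every occurrence (including overlapping ones) of the SH3-ligand
#' consensus motifs: class I `R-x-x-P-x-x-P` and class II `P-x-x-P-x-R`.
#' The two classes bind SH3 domains in opposite orientations, which is why
#' PPII motifs are natural candidates for reversal-tolerant binding.
#'
#' @param seq A [protein_sequence()] or residue string.
#' @return A data.frame with columns `class` (`"I"` or `"II"`), `start`,
#'   `end` (1-based inclusive), `motif` (the matched substring); zero rows
#'   if none.
#' @export
find_ppii_motifs <- function(seq) {
  res <- as_residue_string(seq)
  scan_one <- function(pattern, width, label) {
    m <- gregexpr(paste0("(?=", pattern, ")"), res, perl = TRUE)[[1L]]
    if (m[1L] == -1L) {
      return(NULL)
    }
    starts <- as.integer(m)
    data.frame(
      class = rep(label, length(starts)),
      start = starts,
      end = starts + width - 1L,
      motif = substring(res, starts, starts + width - 1L),
      stringsAsFactors = FALSE
    )
  }
  hits <- rbind(
    scan_one("R..P..P", 7L, "I"),
    scan_one("P..P.R", 6L, "II")
  )
  if (is.null(hits)) {
    return(data.frame(
      class = character(), start = integer(), end = integer(),
      motif = character(), stringsAsFactors = FALSE
    ))
  }
  hits[order(hits$start, hits$class), , drop = FALSE]
}

#' Context-classification parameters
#'
#' @param threshold Order/disorder boundary (default 0.5).
#' @param min_flank_len Minimum length for a disordered run to count as a
#'   qualifying flank (default 10).
#' @param min_binding_region_len A disordered run fully containing the span
#'   but shorter than this, with ordered sequence on both sides, is called
#'   a linker rather than a binding region (default 50 residues; observed
#'   linker-like runs of ~25 and ~40 residues fall below, accepted binding
#'   contexts above).
#' @param flank_window Number of residues on each side of the span averaged
#'   for the "everything ordered" check (default 20).
#' @return Named list for [disorder_context()].
#' @export
context_params <- function(threshold = 0.5, min_flank_len = 10L,
                           min_binding_region_len = 50L,
                           flank_window = 20L) {
  list(
    threshold = threshold,
    min_flank_len = as.integer(min_flank_len),
    min_binding_region_len = as.integer(min_binding_region_len),
    flank_window = as.integer(flank_window)
  )
}

#' Classify the disorder context of a span
#'
#' Decides, for a matched span on a target sequence, which of four contexts
#' it sits in:
#' \describe{
#'   \item{`ordered`}{the span and both its flanking windows average below
#'     the disorder threshold — a structured region;}
#'   \item{`short_linker`}{the span lies inside a disordered run shorter
#'     than `min_binding_region_len` that connects two ordered regions —
#'     likely a flexible linker, not a binding region;}
#'   \item{`disordered_tail`}{the disordered run containing the span
#'     touches a terminus;}
#'   \item{`flanked_by_disorder`}{otherwise — the span is inside, or
#'     bordered by, qualifying disordered runs.}
#' }
#' Only the last two satisfy the disorder-context criterion of
#' [classify_ribs()].
#'
#' Because a windowed-mean profiler depresses scores up to half a window
#' beyond a structure-prone span, flank measurements and run-bordering
#' checks allow a margin of `profile$window %/% 2` residues around the
#' span.
#'
#' @param span Integer vector `c(start, end)`, 1-based inclusive, within
#'   the profile.
#' @param profile The target's [disorder_profile()].
#' @param segments Disordered segments of the target, from
#'   [call_disordered_segments()]; recomputed if missing.
#' @param params See [context_params()].
#' @return A single string: one of `"flanked_by_disorder"`,
#'   `"disordered_tail"`, `"short_linker"`, `"ordered"`.
#' @export
disorder_context <- function(span, profile, segments = NULL,
                             params = context_params()) {
  stopifnot(inherits(profile, "disorder_profile"), length(span) == 2L)
  n <- length(profile$scores)
  start <- as.integer(span[1L])
  end <- as.integer(span[2L])
  if (start < 1L || end > n || start > end) {
    stop("span [", start, ", ", end, "] outside profile (length ", n, ")",
      call. = FALSE
    )
  }
  if (is.null(segments)) {
    segments <- call_disordered_segments(profile,
      threshold = params$threshold,
      min_len = params$min_flank_len
    )
  }
  scores <- profile$scores
  thr <- params$threshold
  # a windowed-mean profiler depresses scores up to half a window beyond a
  # structure-prone span; flank measurements start past that margin
  margin <- profile$window %/% 2L
  l_hi <- start - margin - 1L
  r_lo <- end + margin + 1L
  span_mean <- mean(scores[start:end])
  left_mean <- if (l_hi < 1L) {
    NA_real_
  } else {
    mean(scores[seq.int(max(1L, l_hi - params$flank_window + 1L), l_hi)])
  }
  right_mean <- if (r_lo > n) {
    NA_real_
  } else {
    mean(scores[seq.int(r_lo, min(n, r_lo + params$flank_window - 1L))])
  }
  all_ordered <- span_mean < thr &&
    (is.na(left_mean) || left_mean < thr) &&
    (is.na(right_mean) || right_mean < thr)
  if (all_ordered) {
    return("ordered")
  }
  # disordered run fully containing the span, if any
  containing <- segments[segments$start <= start & segments$end >= end, ,
    drop = FALSE
  ]
  if (nrow(containing) >= 1L) {
    run <- containing[1L, ]
    touches_terminus <- run$start == 1L || run$end == n
    if (touches_terminus) {
      return("disordered_tail")
    }
    if (run$length < params$min_binding_region_len) {
      return("short_linker")
    }
    return("flanked_by_disorder")
  }
  # span not inside a single run: a structure-prone span bordered by
  # disordered runs, or a span straddling run boundaries
  qualifying <- segments[segments$length >= params$min_flank_len, ,
    drop = FALSE
  ]
  borders_left <- start <= margin + 1L ||
    any(qualifying$end >= start - 1L - margin & qualifying$start < start)
  borders_right <- end >= n - margin ||
    any(qualifying$start <= end + 1L + margin & qualifying$end > end)
  if (borders_left && borders_right) {
    return("flanked_by_disorder")
  }
  # one-sided disorder reaching a terminus around the span
  terminal <- qualifying[qualifying$start == 1L | qualifying$end == n, ,
    drop = FALSE
  ]
  near_terminal <- nrow(terminal) > 0L && any(
    terminal$end >= start - 1L - margin & terminal$start <= end + 1L + margin
  )
  if (near_terminal) {
    return("disordered_tail")
  }
  "ordered"
}

#' Verdict parameters for the three-criterion classifier
#'
#' @param identity_threshold Identity must be strictly greater than this
#'   (default 60, in percent).
#' @param pattern_threshold Minimum pattern similarity (default 0.6,
#'   mirroring the stringency of the identity criterion).
#' @return Named list for [classify_ribs()].
#' @export
ribs_params <- function(identity_threshold = 60, pattern_threshold = 0.6) {
  list(
    identity_threshold = identity_threshold,
    pattern_threshold = pattern_threshold
  )
}

#' Three-criterion verdict on an alignment hit
#'
#' A hit is a binding-site candidate only when all three criteria hold:
#' identity strictly above the threshold (criterion 1; exactly 60% is
#' rejected), pattern similarity at or above its threshold (criterion 2),
#' and a disordered or disorder-flanked/tail context (criterion 3). The
#' label is `"retro_morf_candidate"` for positive reversed-orientation
#' hits, `"morf_match"` for positive normal-orientation hits, and
#' `"rejected"` otherwise, with `reasons` enumerating the failed criteria.
#'
#' @param identity_pct Percent identity of the hit alignment.
#' @param pattern_sim Pattern similarity in \[0, 1\].
#' @param context A [disorder_context()] value.
#' @param orientation `"normal"` or `"reversed"` (controls the positive
#'   label).
#' @param params See [ribs_params()].
#' @return An object of class `ribs_verdict`: the inputs, booleans
#'   `criterion1`-`criterion3`, `label`, `reasons`.
#' @export
classify_ribs <- function(identity_pct, pattern_sim, context,
                          orientation = "reversed", params = ribs_params()) {
  context <- match.arg(
    context,
    c("flanked_by_disorder", "disordered_tail", "short_linker", "ordered")
  )
  orientation <- match.arg(orientation, c("normal", "reversed"))
  c1 <- identity_pct > params$identity_threshold # strict: 60.0 fails
  c2 <- pattern_sim >= params$pattern_threshold
  c3 <- context %in% c("flanked_by_disorder", "disordered_tail")
  reasons <- character()
  if (!c1) {
    reasons <- c(reasons, sprintf(
      "identity %.1f%% not above %g%%", identity_pct, params$identity_threshold
    ))
  }
  if (!c2) {
    reasons <- c(reasons, sprintf(
      "pattern similarity %.2f below %g", pattern_sim, params$pattern_threshold
    ))
  }
  if (!c3) {
    reasons <- c(reasons, paste0("context '", context, "' not disordered"))
  }
  positive <- c1 && c2 && c3
  label <- if (!positive) {
    "rejected"
  } else if (orientation == "reversed") {
    "retro_morf_candidate"
  } else {
    "morf_match"
  }
  structure(
    list(
      identity_pct = identity_pct, pattern_similarity = pattern_sim,
      context = context, orientation = orientation,
      criterion1 = c1, criterion2 = c2, criterion3 = c3,
      label = label, reasons = reasons
    ),
    class = "ribs_verdict"
  )
}

#' @export
print.ribs_verdict <- function(x, ...) {
  cat(
    "<ribs_verdict> ", x$label, " [", x$orientation, "]\n",
    "  identity ", sprintf("%.1f", x$identity_pct),
    "% (", x$criterion1, "), pattern ",
    sprintf("%.2f", x$pattern_similarity), " (", x$criterion2,
    "), context ", x$context, " (", x$criterion3, ")\n",
    sep = ""
  )
  if (length(x$reasons)) {
    cat("  reasons: ", paste(x$reasons, collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}
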