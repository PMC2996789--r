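# Scale-based disorder profiling.
#
# This is deliberately NOT a reimplementation of a trained disorder
# predictor (trained-model weights are proprietary). It is a transparent
# stand-in: a sliding-window mean of a published per-residue
# disorder-propensity scale, min-max normalised to [0,1] with higher values
# more disorder-promoting, and the conventional 0.5 order/disorder boundary.
# Downstream logic (dip calling, disorder context) only requires such a
# score track, not any particular predictor.

# TOP-IDP disorder propensity (Campen et al. 2008), raw values: the ranking
# of residues by the difference between their frequencies in disordered vs
# ordered regions. W is the most order-promoting, P the most
# disorder-promoting.
.TOP_IDP_RAW <- c(
  W = -0.884, F = -0.697, Y = -0.510, I = -0.486, M = -0.397,
  L = -0.326, V = -0.121, N = 0.007, C = 0.020, T = 0.059,
  A = 0.060, G = 0.166, R = 0.180, D = 0.192, H = 0.303,
  Q = 0.318, S = 0.341, K = 0.586, E = 0.736, P = 0.987
)

# Kyte-Doolittle hydropathy, raw values (positive = hydrophobic).
.KYTE_DOOLITTLE_RAW <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
  H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

normalize_scale <- function(values, flip = FALSE) {
  v <- values[AA_ALPHABET]
  if (anyNA(v)) stop("scale must cover all 20 residues", call. = FALSE)
  if (flip) v <- -v
  (v - min(v)) / (max(v) - min(v))
}

scale_registry <- function() {
  list(
    # higher = more disorder-promoting, by construction of TOP-IDP
    default_disorder = normalize_scale(.TOP_IDP_RAW),
    top_idp = normalize_scale(.TOP_IDP_RAW),
    # Kyte-Doolittle flipped so that hydrophilic (disorder-favouring)
    # residues score high; I/V/L sit at the 0 extreme, R at 1.
    hydropathy = normalize_scale(.KYTE_DOOLITTLE_RAW, flip = TRUE),
    # Kyte-Doolittle in its native direction (I/V/L at the 1 extreme);
    # the input expected by hydrophobic_moment().
    hydrophobicity = normalize_scale(.KYTE_DOOLITTLE_RAW)
  )
}

#' List the registered residue scales
#' @return Character vector of scale names usable with [get_scale()].
#' @export
list_scales <- function() names(scale_registry())

#' Retrieve a normalized per-residue propensity scale
#'
#' Scales map each of the 20 standard residues to a value min-max normalized
#' to \[0, 1\]. For the disorder scales, higher means more disorder-promoting.
#' Shipped scales:
#' \describe{
#'   \item{`default_disorder` / `top_idp`}{TOP-IDP disorder propensity
#'     (Campen et al. 2008); P scores 1 (most disorder-promoting), W scores
#'     0.}
#'   \item{`hydropathy`}{Kyte-Doolittle hydropathy, flipped so hydrophilic
#'     residues score high; the disorder-oriented face of hydropathy.}
#'   \item{`hydrophobicity`}{Kyte-Doolittle in its native direction
#'     (I = 1, R = 0); use this with [hydrophobic_moment()].}
#' }
#'
#' @param name Scale name; see [list_scales()].
#' @return An object of class `residue_scale`: fields `name` and `values`
#'   (named numeric vector over the 20 residues).
#' @export
get_scale <- function(name) {
  reg <- scale_registry()
  if (!name %in% names(reg)) {
    stop(
      "unknown scale '", name, "'; registered scales: ",
      paste(names(reg), collapse = ", "),
      call. = FALSE
    )
  }
  structure(list(name = name, values = reg[[name]]), class = "residue_scale")
}

#' Build a residue scale from raw values
#'
#' Min-max normalizes a user-supplied 20-residue propensity vector into a
#' `residue_scale` (higher = more disorder-promoting by package convention).
#'
#' @param name Scale name (free text).
#' @param values Named numeric vector covering all 20 standard residues.
#' @return A `residue_scale`.
#' @export
residue_scale <- function(name, values) {
  structure(
    list(name = name, values = normalize_scale(values)),
    class = "residue_scale"
  )
}

scale_lookup <- function(scale, chars) {
  v <- scale$values[chars]
  # ambiguity codes get the neutral midpoint score
  v[is.na(v)] <- 0.5
  unname(v)
}

#' Per-residue disorder profile of a sequence
#'
#' The score at position i is the mean scale value over a window centred at
#' i. Windows are clipped (shrunk) at the termini rather than padded, which
#' preserves the mirror symmetry `profile(reverse(s)) == reverse(profile(s))`
#' — the computable core of the premise that composition-level properties
#' survive sequence reversal.
#'
#' @param seq A [protein_sequence()].
#' @param scale A `residue_scale` (default the shipped disorder scale).
#' @param window Odd positive window width (default 21, approximating the
#'   smoothness of meta-predictor curves).
#' @param threshold Order/disorder boundary stored on the profile for
#'   downstream calls (default 0.5, the conventional boundary).
#' @return An object of class `disorder_profile`: fields `seq_id`,
#'   `residues`, `scores` (numeric in \[0,1\], one per residue), `window`,
#'   `scale_name`, `threshold`.
#' @export
disorder_profile <- function(seq, scale = get_scale("default_disorder"),
                             window = 21L, threshold = 0.5) {
  stopifnot(inherits(seq, "protein_sequence"), inherits(scale, "residue_scale"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be a positive odd integer", call. = FALSE)
  }
  chars <- seq_chars(seq)
  vals <- scale_lookup(scale, chars)
  n <- length(vals)
  half <- window %/% 2L
  cs <- c(0, cumsum(vals))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  scores <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  # guard against cumsum round-off at the [0,1] boundary
  scores <- pmin(pmax(scores, 0), 1)
  structure(
    list(
      seq_id = seq$id, residues = seq$residues, scores = scores,
      window = window, scale_name = scale$name, threshold = threshold
    ),
    class = "disorder_profile"
  )
}

#' @export
print.disorder_profile <- function(x, ...) {
  cat(
    "<disorder_profile> ", x$seq_id, ": ", length(x$scores),
    " residues, window ", x$window, ", scale '", x$scale_name,
    "', threshold ", x$threshold, "\n",
    sep = ""
  )
  cat(
    "  mean score ", sprintf("%.3f", mean(x$scores)),
    ", fraction >= threshold ",
    sprintf("%.3f", mean(x$scores >= x$threshold)), "\n",
    sep = ""
  )
  invisible(x)
}

# Maximal runs of a logical vector, as a data.frame of 1-based [start, end].
logical_runs <- function(keep) {
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts, end = ends, value = r$values)
}

#' Call disordered segments from a profile
#'
#' Maximal runs of scores at or above the threshold, retained if at least
#' `min_len` residues long. Segments are disjoint, sorted by start, and
#' cover exactly the positions passing the threshold after the length
#' filter.
#'
#' @param profile A [disorder_profile()].
#' @param threshold Order/disorder boundary (defaults to the profile's).
#' @param min_len Minimum segment length (default 4; suppresses
#'   single-residue flickers).
#' @return A data.frame with columns `seq_id`, `start`, `end` (1-based
#'   inclusive), `length`, `mean_score`.
#' @export
call_disordered_segments <- function(profile, threshold = profile$threshold,
                                     min_len = 4L) {
  stopifnot(inherits(profile, "disorder_profile"))
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  }
  runs <- logical_runs(profile$scores >= threshold)
  runs <- runs[runs$value & (runs$end - runs$start + 1L) >= min_len, ,
    drop = FALSE
  ]
  data.frame(
    seq_id = rep(profile$seq_id, nrow(runs)),
    start = runs$start,
    end = runs$end,
    length = runs$end - runs$start + 1L,
    mean_score = vapply(
      seq_len(nrow(runs)),
      function(i) mean(profile$scores[runs$start[i]:runs$end[i]]),
      numeric(1)
    ),
    stringsAsFactors = FALSE
  )
}

#' Export a disorder profile as TSV
#'
#' One row per residue: `position` (1-based), `residue`, `score`.
#'
#' @param profile A [disorder_profile()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "disorder_profile"))
  df <- data.frame(
    position = seq_along(profile$scores),
    residue = strsplit(profile$residues, "", fixed = TRUE)[[1L]],
    score = profile$scores
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export intervals as BED
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention.
#'
#' @param intervals A data.frame with columns `seq_id`, `start`, `end`
#'   (1-based inclusive), e.g. from [call_disordered_segments()] or
#'   [detect_dips()].
#' @param path Output path.
#' @param name_col Optional column used for the BED name field.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path, name_col = NULL) {
  name <- if (!is.null(name_col) && name_col %in% names(intervals)) {
    as.character(intervals[[name_col]])
  } else {
    paste0("region", seq_len(nrow(intervals)))
  }
  bed <- data.frame(
    chrom = intervals$seq_id,
    chromStart = intervals$start - 1L, # BED is 0-based half-open
    chromEnd = intervals$end,
    name = name
  )
  write.table(bed, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
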