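# Local alignment and empirical significance.
#
# The aligner is a full Smith-Waterman with affine gaps (Gotoh algorithm,
# implemented in C++ for speed) — an exhaustive local aligner, not a
# heuristic seeded search. Significance is empirical: the query is shuffled
# many times, re-scored against the target, and the add-one rank of the
# observed score gives a p-value; multiplying by the database size gives an
# E-value (expected chance hits at least this good). The add-one form keeps
# p strictly positive, so log-transforms are always safe.

#' Fetch a substitution matrix by name
#'
#' Resolves `"BLOSUM62"`, `"BLOSUM45"`, `"BLOSUM50"`, `"BLOSUM80"`,
#' `"BLOSUM100"`, `"PAM30"`, `"PAM40"`, `"PAM70"`, `"PAM120"`, `"PAM250"`
#' from the matrices shipped with Biostrings, or passes a numeric matrix
#' through unchanged.
#'
#' @param matrix Matrix name or a square numeric matrix with residue
#'   dimnames.
#' @return A numeric substitution matrix.
#' @export
substitution_matrix <- function(matrix = "BLOSUM62") {
  if (is.matrix(matrix)) {
    stopifnot(is.numeric(matrix), !is.null(rownames(matrix)))
    return(matrix)
  }
  stopifnot(is.character(matrix), length(matrix) == 1L)
  env <- new.env()
  ok <- tryCatch(
    {
      utils::data(list = matrix, package = "Biostrings", envir = env)
      TRUE
    },
    warning = function(w) FALSE
  )
  if (!ok || !exists(matrix, envir = env)) {
    stop("unknown substitution matrix '", matrix, "'", call. = FALSE)
  }
  get(matrix, envir = env)
}

# Encode residue characters as 0-based row indices of the matrix.
encode_residues <- function(chars, S, permissive = FALSE) {
  idx <- match(chars, rownames(S))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    if (permissive && "X" %in% rownames(S)) {
      idx[bad] <- match("X", rownames(S))
    } else {
      stop(
        "residue '", chars[bad[1L]], "' (position ", bad[1L],
        ") absent from the substitution matrix",
        call. = FALSE
      )
    }
  }
  as.integer(idx - 1L)
}

as_residue_string <- function(x) {
  if (inherits(x, "protein_sequence")) x$residues else as.character(x)
}

as_seq_id <- function(x, default) {
  if (inherits(x, "protein_sequence")) x$id else default
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Computes the optimal local alignment of `query` against `target` under a
#' substitution matrix and affine gap costs (a gap of length L costs
#' `gap_open + gap_extend * L`). The traceback uses a fixed tie-break
#' (diagonal over up over left) so a single deterministic optimal alignment
#' is returned; the empty alignment with score 0 is returned when no
#' positively scoring pairing exists.
#'
#' @param query,target [protein_sequence()] objects or plain residue
#'   strings.
#' @param matrix Substitution matrix or name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Positive gap penalties (defaults 11 and 1,
#'   the classical protein-search defaults).
#' @param orientation Label stored on the alignment (`"normal"` or
#'   `"reversed"`); bookkeeping only — the caller reverses the query itself.
#' @param permissive Map residues absent from the matrix to the neutral
#'   `X` column instead of erroring.
#' @return An object of class `sw_alignment`: `query_id`, `target_id`,
#'   `aligned_query`, `aligned_target` (equal-length gapped strings),
#'   `score`, `q_start`, `q_end`, `t_start`, `t_end` (1-based inclusive on
#'   the ungapped sequences), `identity_pct`, `orientation`.
#' @examples
#' aln <- sw_align("LLLL", "LLLL")
#' aln$score # 16 under BLOSUM62
#' @export
sw_align <- function(query, target, matrix = "BLOSUM62",
                     gap_open = 11, gap_extend = 1,
                     orientation = "normal", permissive = FALSE) {
  stopifnot(gap_open > 0, gap_extend > 0)
  orientation <- match.arg(orientation, c("normal", "reversed"))
  S <- substitution_matrix(matrix)
  q_res <- as_residue_string(query)
  t_res <- as_residue_string(target)
  if (!nzchar(q_res) || !nzchar(t_res)) {
    stop("both sequences must be non-empty", call. = FALSE)
  }
  q_chars <- strsplit(q_res, "", fixed = TRUE)[[1L]]
  t_chars <- strsplit(t_res, "", fixed = TRUE)[[1L]]
  qi <- encode_residues(q_chars, S, permissive)
  ti <- encode_residues(t_chars, S, permissive)
  raw <- sw_align_cpp(qi, ti, S, gap_open, gap_extend)
  if (length(raw$q_aln) == 0L) {
    aln_q <- aln_t <- ""
    q_start <- q_end <- t_start <- t_end <- NA_integer_
    identity <- NA_real_
  } else {
    gapped <- function(idx, chars) {
      out <- rep("-", length(idx))
      out[idx > 0L] <- chars[idx[idx > 0L]]
      paste(out, collapse = "")
    }
    aln_q <- gapped(raw$q_aln, q_chars)
    aln_t <- gapped(raw$t_aln, t_chars)
    q_start <- raw$q_start
    q_end <- raw$q_end
    t_start <- raw$t_start
    t_end <- raw$t_end
    identity <- NA_real_ # filled below via percent_identity()
  }
  aln <- structure(
    list(
      query_id = as_seq_id(query, "query"),
      target_id = as_seq_id(target, "target"),
      aligned_query = aln_q, aligned_target = aln_t,
      score = raw$score,
      q_start = q_start, q_end = q_end,
      t_start = t_start, t_end = t_end,
      identity_pct = identity,
      orientation = orientation
    ),
    class = "sw_alignment"
  )
  if (nzchar(aln_q)) aln$identity_pct <- percent_identity(aln)
  aln
}

#' @export
print.sw_alignment <- function(x, ...) {
  cat(
    "<sw_alignment> ", x$query_id, " vs ", x$target_id,
    " [", x$orientation, "]\n",
    "  score ", x$score,
    if (!is.na(x$identity_pct)) {
      paste0(", identity ", sprintf("%.1f", x$identity_pct), "%")
    } else {
      " (empty alignment)"
    },
    "\n",
    sep = ""
  )
  if (nzchar(x$aligned_query)) {
    cat(
      "  Q ", x$q_start, " ", x$aligned_query, " ", x$q_end, "\n",
      "  T ", x$t_start, " ", x$aligned_target, " ", x$t_end, "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Percent identity of a local alignment
#'
#' `100 * matching columns / total alignment columns`. Gapped columns count
#' in the denominator (a conservative convention: insertions dilute
#' identity), which makes the strict "above 60%" criterion unambiguous.
#'
#' @param aln An [sw_align()] result.
#' @return Numeric in \[0, 100\].
#' @export
percent_identity <- function(aln) {
  stopifnot(inherits(aln, "sw_alignment"))
  if (!nzchar(aln$aligned_query)) {
    stop("percent identity is undefined for an empty alignment",
      call. = FALSE
    )
  }
  q <- strsplit(aln$aligned_query, "", fixed = TRUE)[[1L]]
  t <- strsplit(aln$aligned_target, "", fixed = TRUE)[[1L]]
  100 * sum(q == t & q != "-") / length(q)
}

#' Empirical shuffle E-value for a local alignment score
#'
#' Shuffles the query `n_shuffles` times (seeded), re-scores each shuffle
#' against the target, and reports the add-one empirical p-value
#' `p_emp = (1 + #\{shuffle score >= score\}) / (n_shuffles + 1)` and the
#' E-value `p_emp * db_size`. Composition is held fixed by construction, so
#' the null preserves the query's residue usage. The smallest attainable
#' E-value is `db_size / (n_shuffles + 1)`; size `n_shuffles` accordingly
#' for the threshold in use.
#'
#' @param query,target [protein_sequence()] objects or residue strings.
#' @param score The observed alignment score to rank.
#' @param n_shuffles Number of shuffled decoys (>= 99).
#' @param db_size Number of database sequences the search spans (>= 1).
#' @param seed Integer seed; fixed seed gives a fully deterministic
#'   estimate.
#' @param matrix,gap_open,gap_extend Scoring parameters, as in
#'   [sw_align()].
#' @return An object of class `evalue_estimate`: `score`, `n_shuffles`,
#'   `n_ge`, `p_emp`, `evalue`, `seed`.
#' @export
empirical_evalue <- function(query, target, score, n_shuffles = 199L,
                             db_size = 1L, seed, matrix = "BLOSUM62",
                             gap_open = 11, gap_extend = 1) {
  n_shuffles <- as.integer(n_shuffles)
  if (n_shuffles < 99L) stop("`n_shuffles` must be at least 99", call. = FALSE)
  stopifnot(db_size >= 1)
  S <- substitution_matrix(matrix)
  q_chars <- strsplit(as_residue_string(query), "", fixed = TRUE)[[1L]]
  ti <- encode_residues(
    strsplit(as_residue_string(target), "", fixed = TRUE)[[1L]], S
  )
  qi <- encode_residues(q_chars, S)
  shuffles <- with_local_seed(seed, lapply(seq_len(n_shuffles), function(i) {
    qi[sample.int(length(qi))]
  }))
  decoy_scores <- sw_score_many_cpp(shuffles, ti, S, gap_open, gap_extend)
  n_ge <- sum(decoy_scores >= score)
  p_emp <- (1 + n_ge) / (n_shuffles + 1)
  structure(
    list(
      score = score, n_shuffles = n_shuffles, n_ge = n_ge,
      p_emp = p_emp, evalue = p_emp * db_size, seed = as.integer(seed)
    ),
    class = "evalue_estimate"
  )
}

#' @export
print.evalue_estimate <- function(x, ...) {
  cat(
    "<evalue_estimate> score ", x$score, ": p_emp ",
    signif(x$p_emp, 3), ", E ", signif(x$evalue, 3),
    " (", x$n_ge, "/", x$n_shuffles, " decoys >=, seed ", x$seed, ")\n",
    sep = ""
  )
  invisible(x)
}
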