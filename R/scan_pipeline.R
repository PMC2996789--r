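# End-to-end orchestration: align candidate fragments against a database in
# one or both orientations, prescan by empirical E-value, evaluate the
# three criteria on every survivor, and report.

#' Scan parameters
#'
#' Collects every knob of [scan_database()] with its default. The smallest
#' attainable E-value is `db_size / (prescan_n_shuffles + 1)`; the default
#' prescan threshold of `E <= 1` reads "fewer than one chance hit expected
#' per query over the whole database" and is attainable at any database
#' size. Users wanting classical cutoffs such as `1e-3` must raise
#' `prescan_n_shuffles` to at least `db_size / threshold`.
#'
#' @param matrix,gap_open,gap_extend Alignment scoring, as in [sw_align()].
#' @param prescan_n_shuffles Shuffles per query/target pair for the prescan
#'   E-value (default 199).
#' @param report_n_shuffles Shuffles used to re-estimate the E-value of
#'   prescan survivors (default 999).
#' @param prescan_max_evalue Survivor threshold on the prescan E-value
#'   (default 1).
#' @param window,threshold Disorder profiling of targets, as in
#'   [disorder_profile()].
#' @param scale_name Disorder scale for target profiling.
#' @param context See [context_params()].
#' @param ribs See [ribs_params()].
#' @param moment_delta_deg Helical angle for the hydrophobic-moment
#'   annotation (default 100).
#' @param seed Master seed; every shuffle stream is derived from it, so a
#'   fixed seed makes the whole scan deterministic.
#' @return Named list of parameters.
#' @export
scan_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                        prescan_n_shuffles = 199L, report_n_shuffles = 999L,
                        prescan_max_evalue = 1, window = 21L, threshold = 0.5,
                        scale_name = "default_disorder",
                        context = context_params(), ribs = ribs_params(),
                        moment_delta_deg = 100, seed = 1L) {
  list(
    matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
    prescan_n_shuffles = as.integer(prescan_n_shuffles),
    report_n_shuffles = as.integer(report_n_shuffles),
    prescan_max_evalue = prescan_max_evalue,
    window = as.integer(window), threshold = threshold,
    scale_name = scale_name, context = context, ribs = ribs,
    moment_delta_deg = moment_delta_deg, seed = as.integer(seed)
  )
}

#' Scan a protein database with candidate fragments
#'
#' For every query fragment and every database sequence (and the reversed
#' query when requested), computes the optimal local alignment, estimates an
#' empirical shuffle E-value, and — for prescan survivors — profiles the
#' target's disorder, classifies the disorder context of the matched span,
#' and applies the three-criterion verdict. Target profiles and segment
#' calls are computed once per target and cached across queries.
#'
#' @param queries A list of [protein_sequence()] fragments (e.g. from
#'   [extract_candidate_fragments()] or [generate_benchmark()] motifs), or a
#'   single one.
#' @param db A list of [protein_sequence()] records, e.g. from
#'   [read_fasta()].
#' @param orientation `"both"` (default), `"normal"`, or `"reversed"`.
#'   `"both"` returns the union of the normal and reversed scans.
#' @param params See [scan_params()].
#' @return An object of class `scan_result`: `hits` (a data.frame, one row
#'   per prescan survivor, sorted by E-value then score), `alignments`
#'   (the matching list of [sw_align()] objects), `n_pairs_evaluated`, and
#'   the parameter echo `params`.
#' @export
scan_database <- function(queries, db, orientation = c("both", "normal", "reversed"),
                          params = scan_params()) {
  orientation <- match.arg(orientation)
  if (inherits(queries, "protein_sequence")) queries <- list(queries)
  if (inherits(db, "protein_sequence")) db <- list(db)
  stopifnot(length(queries) > 0L, length(db) > 0L)
  S <- substitution_matrix(params$matrix)
  scale <- get_scale(params$scale_name)
  db_size <- length(db)

  oriented <- list()
  for (q in queries) {
    if (orientation %in% c("normal", "both")) {
      oriented[[length(oriented) + 1L]] <-
        list(seq = q, source_id = q$id, orient = "normal")
    }
    if (orientation %in% c("reversed", "both")) {
      oriented[[length(oriented) + 1L]] <-
        list(seq = reverse_sequence(q), source_id = q$id, orient = "reversed")
    }
  }
  n_pairs <- length(oriented) * db_size
  pair_seeds <- derive_seeds(params$seed, 2L * n_pairs)

  profile_cache <- new.env(parent = emptyenv())
  target_context <- function(tseq) {
    key <- tseq$id
    if (!exists(key, envir = profile_cache, inherits = FALSE)) {
      prof <- disorder_profile(tseq,
        scale = scale, window = params$window,
        threshold = params$threshold
      )
      segs <- call_disordered_segments(prof,
        threshold = params$context$threshold,
        min_len = params$context$min_flank_len
      )
      assign(key, list(profile = prof, segments = segs), envir = profile_cache)
    }
    get(key, envir = profile_cache, inherits = FALSE)
  }

  rows <- list()
  alignments <- list()
  pair <- 0L
  for (oq in oriented) {
    for (tseq in db) {
      pair <- pair + 1L
      aln <- sw_align(oq$seq, tseq,
        matrix = S, gap_open = params$gap_open,
        gap_extend = params$gap_extend, orientation = oq$orient
      )
      if (aln$score <= 0) next
      pre <- empirical_evalue(oq$seq, tseq, aln$score,
        n_shuffles = params$prescan_n_shuffles, db_size = db_size,
        seed = pair_seeds[2L * pair - 1L], matrix = S,
        gap_open = params$gap_open, gap_extend = params$gap_extend
      )
      if (pre$evalue > params$prescan_max_evalue) next
      ev <- empirical_evalue(oq$seq, tseq, aln$score,
        n_shuffles = params$report_n_shuffles, db_size = db_size,
        seed = pair_seeds[2L * pair], matrix = S,
        gap_open = params$gap_open, gap_extend = params$gap_extend
      )
      ctx_data <- target_context(tseq)
      ctx <- disorder_context(
        c(aln$t_start, aln$t_end), ctx_data$profile, ctx_data$segments,
        params$context
      )
      psim <- pattern_similarity(aln)
      verdict <- classify_ribs(aln$identity_pct, psim, ctx,
        orientation = oq$orient, params = params$ribs
      )
      span_seq <- substr(tseq$residues, aln$t_start, aln$t_end)
      mu_h <- if (nchar(span_seq) >= 2L) {
        hydrophobic_moment(span_seq, delta_deg = params$moment_delta_deg)
      } else {
        NA_real_
      }
      ppii <- find_ppii_motifs(span_seq)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = oq$source_id, target_id = tseq$id,
        orientation = oq$orient, score = aln$score,
        q_start = aln$q_start, q_end = aln$q_end,
        t_start = aln$t_start, t_end = aln$t_end,
        identity_pct = aln$identity_pct,
        p_emp = ev$p_emp, evalue = ev$evalue,
        prescan_evalue = pre$evalue,
        pattern_similarity = psim, context = ctx,
        criterion1 = verdict$criterion1, criterion2 = verdict$criterion2,
        criterion3 = verdict$criterion3, label = verdict$label,
        reasons = paste(verdict$reasons, collapse = "; "),
        hydrophobic_moment = mu_h, n_ppii_motifs = nrow(ppii),
        stringsAsFactors = FALSE
      )
      alignments[[length(alignments) + 1L]] <- aln
    }
  }

  if (length(rows) == 0L) {
    hits <- data.frame(
      query_id = character(), target_id = character(),
      orientation = character(), score = numeric(), q_start = integer(),
      q_end = integer(), t_start = integer(), t_end = integer(),
      identity_pct = numeric(), p_emp = numeric(), evalue = numeric(),
      prescan_evalue = numeric(), pattern_similarity = numeric(),
      context = character(), criterion1 = logical(), criterion2 = logical(),
      criterion3 = logical(), label = character(), reasons = character(),
      hydrophobic_moment = numeric(), n_ppii_motifs = integer(),
      stringsAsFactors = FALSE
    )
  } else {
    hits <- do.call(rbind, rows)
    ord <- order(hits$evalue, -hits$score)
    hits <- hits[ord, , drop = FALSE]
    alignments <- alignments[ord]
    rownames(hits) <- NULL
  }
  structure(
    list(
      hits = hits, alignments = alignments,
      n_pairs_evaluated = n_pairs, params = params
    ),
    class = "scan_result"
  )
}

#' @export
print.scan_result <- function(x, ...) {
  cat(
    "<scan_result> ", nrow(x$hits), " prescan survivor(s) of ",
    x$n_pairs_evaluated, " query-target pair(s)\n",
    sep = ""
  )
  if (nrow(x$hits) > 0L) {
    pos <- sum(x$hits$label != "rejected")
    cat("  positives: ", pos, "\n", sep = "")
    print(head(x$hits[, c(
      "query_id", "target_id", "orientation", "score",
      "identity_pct", "evalue", "label"
    )], 10L))
  }
  invisible(x)
}

#' Summarize a scan run
#'
#' Bookkeeping over the hits of a [scan_database()] run: how many prescan
#' survivors and how many positives, overall, per orientation, and per
#' query.
#'
#' @param x A `scan_result` or its `hits` data.frame.
#' @return An object of class `run_summary`: `n_hits`, `n_positive`,
#'   `by_orientation` (data.frame), `per_query` (data.frame).
#' @export
summarize_run <- function(x) {
  hits <- if (inherits(x, "scan_result")) x$hits else x
  positive <- hits$label != "rejected"
  count_by <- function(key) {
    if (nrow(hits) == 0L) {
      return(data.frame(
        key = character(), n_hits = integer(), n_positive = integer(),
        stringsAsFactors = FALSE
      )[, c("key", "n_hits", "n_positive")] |>
        setNames(c(key, "n_hits", "n_positive")))
    }
    counts <- stats::aggregate(
      data.frame(n_hits = rep(1L, nrow(hits)), n_positive = as.integer(positive)),
      by = setNames(list(hits[[key]]), key),
      FUN = sum
    )
    counts[order(counts[[key]]), , drop = FALSE]
  }
  by_orient <- count_by("orientation")
  per_query <- count_by("query_id")
  structure(
    list(
      n_hits = nrow(hits), n_positive = sum(positive),
      by_orientation = by_orient, per_query = per_query
    ),
    class = "run_summary"
  )
}

#' @export
print.run_summary <- function(x, ...) {
  cat(
    "<run_summary> ", x$n_positive, " positive(s) of ", x$n_hits,
    " hit(s)\n",
    sep = ""
  )
  if (nrow(x$by_orientation) > 0L) print(x$by_orientation)
  invisible(x)
}

#' Write scan hits as TSV
#'
#' Tabular hit format modelled on tabular protein-search output: one row
#' per hit with scores, coordinates, identity, E-value, orientation and the
#' verdict columns.
#'
#' @param x A `scan_result` or hits data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits_tsv <- function(x, path) {
  hits <- if (inherits(x, "scan_result")) x$hits else x
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write scan verdicts as JSON
#'
#' @param x A `scan_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_verdicts_json <- function(x, path) {
  stopifnot(inherits(x, "scan_result"))
  payload <- list(
    n_pairs_evaluated = x$n_pairs_evaluated,
    seed = x$params$seed,
    hits = x$hits
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA,
    dataframe = "rows"
  )
  invisible(path)
}

#' Read a YAML configuration of thresholds
#'
#' Reads a YAML file whose top-level keys override the defaults of
#' [scan_params()]; the nested keys `context` and `ribs` override
#' [context_params()] and [ribs_params()] entries.
#'
#' @param path Path to a YAML file.
#' @return A full `scan_params()` list with overrides applied.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- scan_params()
  for (key in names(cfg)) {
    if (!key %in% names(base)) {
      stop("unknown configuration key '", key, "'", call. = FALSE)
    }
    if (key %in% c("context", "ribs")) {
      for (sub in names(cfg[[key]])) {
        if (!sub %in% names(base[[key]])) {
          stop("unknown configuration key '", key, ".", sub, "'",
            call. = FALSE
          )
        }
        base[[key]][[sub]] <- cfg[[key]][[sub]]
      }
    } else {
      base[[key]] <- cfg[[key]]
    }
  }
  base
}
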