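# Seeded synthetic benchmarks: disorder-promoting background sequences with
# planted hydrophobic motifs in normal or reversed orientation, plus a
# truth table. These emulate the screening situation — a short
# structure-prone fragment recurring, sometimes backwards, inside the
# disordered regions of otherwise unrelated proteins — so every stage of
# the pipeline can be exercised without any external database.

#' Default disorder-promoting background composition
#'
#' 90% of the probability mass spread uniformly over the eight most
#' disorder-promoting residues of the shipped disorder scale, 10% over the
#' remaining twelve. Sequences drawn from it profile as disordered (mean
#' score well above 0.5), guaranteeing disordered context without
#' hand-tuning.
#'
#' @param scale A `residue_scale` ranking residues (default the shipped
#'   disorder scale).
#' @param top_mass Probability mass given to the top 8 residues
#'   (default 0.9).
#' @return Named numeric vector over the 20 residues, summing to 1.
#' @export
default_background_composition <- function(scale = get_scale("default_disorder"),
                                           top_mass = 0.9) {
  ranked <- names(sort(scale$values, decreasing = TRUE))
  top <- ranked[1:8]
  rest <- ranked[9:20]
  comp <- c(
    setNames(rep(top_mass / 8, 8L), top),
    setNames(rep((1 - top_mass) / 12, 12L), rest)
  )
  comp[AA_ALPHABET]
}

#' Generate a random background sequence
#'
#' Residues drawn i.i.d. from a composition; deterministic per seed.
#'
#' @param length Positive sequence length.
#' @param composition Named residue-frequency vector summing to 1 (within
#'   1e-6); default [default_background_composition()].
#' @param seed Integer seed.
#' @param id Record id (default `"bg"`).
#' @return A [protein_sequence()].
#' @export
generate_background <- function(length,
                                composition = default_background_composition(),
                                seed, id = "bg") {
  length <- as.integer(length)
  if (length < 1L) stop("`length` must be positive", call. = FALSE)
  if (is.null(names(composition)) ||
    !all(names(composition) %in% AA_ALPHABET) ||
    abs(sum(composition) - 1) > 1e-6 || any(composition < 0)) {
    stop("`composition` must be non-negative frequencies over the 20 ",
      "residues summing to 1",
      call. = FALSE
    )
  }
  chars <- with_local_seed(seed, sample(
    names(composition), length,
    replace = TRUE, prob = composition
  ))
  protein_sequence(id, paste(chars, collapse = ""))
}

#' Draw a random hydrophobic-rich motif
#'
#' Motifs are drawn uniformly from the hydrophobic residue class so that,
#' once planted in a disorder-promoting background, they carve a natural
#' dip into the disorder profile.
#'
#' @param length Motif length.
#' @param seed Integer seed.
#' @param id Record id.
#' @return A [protein_sequence()].
#' @export
random_motif <- function(length, seed, id = "motif") {
  chars <- with_local_seed(seed, sample(
    hydrophobic_set(), as.integer(length),
    replace = TRUE
  ))
  protein_sequence(id, paste(chars, collapse = ""))
}

#' Plant a motif into a target sequence
#'
#' Overwrites the span starting at `position` with the motif (reversed if
#' requested), then mutates each planted position independently with
#' probability `mutation_rate` to a uniformly chosen different residue.
#'
#' @param target A [protein_sequence()].
#' @param motif A [protein_sequence()] or residue string.
#' @param position 1-based start of the planted span; the motif must fit.
#' @param reversed Plant the reversed motif (default `FALSE`).
#' @param mutation_rate Per-position mutation probability in \[0, 1).
#' @param seed Integer seed for the mutation draws.
#' @param motif_id Identifier recorded in the truth table.
#' @return A list: `seq` (the modified `protein_sequence`) and `truth`
#'   (one-row data.frame: `target_id`, `start`, `end`, `orientation`,
#'   `motif_id`, `n_mutations`).
#' @export
plant_motif <- function(target, motif, position, reversed = FALSE,
                        mutation_rate = 0, seed, motif_id = "motif") {
  stopifnot(inherits(target, "protein_sequence"))
  if (mutation_rate < 0 || mutation_rate >= 1) {
    stop("`mutation_rate` must lie in [0, 1)", call. = FALSE)
  }
  motif_res <- as_residue_string(motif)
  m_len <- nchar(motif_res)
  n <- nchar(target$residues)
  position <- as.integer(position)
  if (position < 1L || position + m_len - 1L > n) {
    stop("motif does not fit at position ", position, " (target length ", n,
      ", motif length ", m_len, ")",
      call. = FALSE
    )
  }
  planted <- strsplit(motif_res, "", fixed = TRUE)[[1L]]
  if (reversed) planted <- rev(planted)
  original <- planted
  planted <- with_local_seed(seed, {
    mutate <- runif(m_len) < mutation_rate
    for (i in which(mutate)) {
      planted[i] <- sample(setdiff(AA_ALPHABET, planted[i]), 1L)
    }
    planted
  })
  n_mut <- sum(planted != original)
  chars <- seq_chars(target)
  chars[position:(position + m_len - 1L)] <- planted
  list(
    seq = protein_sequence(
      target$id, paste(chars, collapse = ""),
      target$description
    ),
    truth = data.frame(
      target_id = target$id, start = position, end = position + m_len - 1L,
      orientation = if (reversed) "reversed" else "normal",
      motif_id = motif_id, n_mutations = as.integer(n_mut),
      stringsAsFactors = FALSE
    )
  )
}

#' Specify a synthetic benchmark
#'
#' @param n_targets Number of database sequences (planted + decoy).
#' @param length_range Target length range, inclusive (default 300-600).
#' @param n_planted_normal,n_planted_reversed Number of targets carrying a
#'   planted motif in each orientation (defaults 0 and 10).
#' @param motif_length_range Motif length range (default 15-15).
#' @param mutation_rate Per-position mutation probability applied to
#'   planted copies (default 0).
#' @param composition Background composition (default
#'   [default_background_composition()]).
#' @param edge_margin Minimum distance of a planted span from either
#'   terminus (default 40, leaving ample disordered flanks).
#' @param seed Master seed.
#' @return A validated `benchmark_spec` list.
#' @export
benchmark_spec <- function(n_targets = 50L, length_range = c(300L, 600L),
                           n_planted_normal = 0L, n_planted_reversed = 10L,
                           motif_length_range = c(15L, 15L),
                           mutation_rate = 0,
                           composition = default_background_composition(),
                           edge_margin = 40L, seed = 1L) {
  spec <- list(
    n_targets = as.integer(n_targets),
    length_range = as.integer(length_range),
    n_planted_normal = as.integer(n_planted_normal),
    n_planted_reversed = as.integer(n_planted_reversed),
    motif_length_range = as.integer(motif_length_range),
    mutation_rate = mutation_rate,
    composition = composition,
    edge_margin = as.integer(edge_margin),
    seed = as.integer(seed)
  )
  n_planted <- spec$n_planted_normal + spec$n_planted_reversed
  if (spec$n_planted_normal < 0L || spec$n_planted_reversed < 0L ||
    n_planted > spec$n_targets) {
    stop("planted counts must be non-negative and fit in `n_targets`",
      call. = FALSE
    )
  }
  if (mutation_rate < 0 || mutation_rate >= 1) {
    stop("`mutation_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (spec$motif_length_range[2L] + 2L * spec$edge_margin >
    spec$length_range[1L]) {
    stop("motifs do not fit inside the shortest targets with the ",
      "requested edge margin",
      call. = FALSE
    )
  }
  structure(spec, class = "benchmark_spec")
}

#' Generate a synthetic benchmark database with truth table
#'
#' Builds `n_targets` background sequences; the first
#' `n_planted_normal + n_planted_reversed` each receive one planted motif
#' (a fresh hydrophobic motif per target) in the designated orientation at
#' a random interior position; the remainder are motif-free decoys. Fully
#' deterministic for a fixed spec seed.
#'
#' @param spec A [benchmark_spec()].
#' @return A list: `db` (list of [protein_sequence()]), `motifs` (list of
#'   `protein_sequence` query fragments, in source orientation), `truth`
#'   (data.frame with one row per planted motif), `spec` (echo).
#' @export
generate_benchmark <- function(spec = benchmark_spec()) {
  stopifnot(inherits(spec, "benchmark_spec"))
  n_planted <- spec$n_planted_normal + spec$n_planted_reversed
  seeds <- derive_seeds(spec$seed, 4L * spec$n_targets + 4L)
  # sample uniformly from lo:hi, immune to sample()'s scalar expansion
  sample_range <- function(lo, hi, n) {
    lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
  }
  lengths <- with_local_seed(seeds[1L], sample_range(
    spec$length_range[1L], spec$length_range[2L], spec$n_targets
  ))
  motif_lens <- with_local_seed(seeds[2L], sample_range(
    spec$motif_length_range[1L], spec$motif_length_range[2L],
    max(n_planted, 1L)
  ))
  db <- vector("list", spec$n_targets)
  motifs <- vector("list", n_planted)
  truth <- list()
  for (i in seq_len(spec$n_targets)) {
    tid <- sprintf("T%03d", i)
    bg <- generate_background(lengths[i], spec$composition,
      seed = seeds[2L + i], id = tid
    )
    if (i <= n_planted) {
      reversed <- i > spec$n_planted_normal
      mid <- sprintf("M%03d", i)
      motif <- random_motif(motif_lens[i],
        seed = seeds[2L + spec$n_targets + i], id = mid
      )
      pos <- with_local_seed(
        seeds[2L + 2L * spec$n_targets + i],
        sample_range(
          spec$edge_margin + 1L,
          lengths[i] - nchar(motif$residues) - spec$edge_margin, 1L
        )
      )
      planted <- plant_motif(bg, motif, pos,
        reversed = reversed,
        mutation_rate = spec$mutation_rate,
        seed = seeds[2L + 3L * spec$n_targets + i], motif_id = mid
      )
      db[[i]] <- planted$seq
      motifs[[i]] <- motif
      truth[[length(truth) + 1L]] <- planted$truth
    } else {
      db[[i]] <- bg
    }
  }
  truth <- if (length(truth)) {
    do.call(rbind, truth)
  } else {
    data.frame(
      target_id = character(), start = integer(), end = integer(),
      orientation = character(), motif_id = character(),
      n_mutations = integer(), stringsAsFactors = FALSE
    )
  }
  list(db = db, motifs = motifs, truth = truth, spec = spec)
}

#' Write a generated benchmark to disk
#'
#' FASTA database, TSV truth table, and a JSON echo of the spec (seed
#' included).
#'
#' @param bench A [generate_benchmark()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bench$db, file.path(dir, "database.fasta"))
  if (length(bench$motifs)) {
    write_fasta(bench$motifs, file.path(dir, "motifs.fasta"))
  }
  write.table(bench$truth, file.path(dir, "truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  spec <- bench$spec
  spec$composition <- as.list(spec$composition)
  jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Match scan hits against a benchmark truth table
#'
#' A truth row is recovered when some hit of the matching orientation on
#' the same target overlaps the planted span. Scanning is done with the
#' motif in its source orientation, so a motif planted reversed is
#' recovered by the reversed-orientation scan of that motif.
#'
#' @param hits Hits data.frame from [scan_database()] (or a `scan_result`).
#' @param truth Truth table from [generate_benchmark()].
#' @param positives_only Count only hits with a positive verdict label
#'   (default `TRUE`).
#' @return The truth data.frame with extra logical column `recovered` and,
#'   where recovered, `hit_identity` (best overlapping hit's identity).
#' @export
evaluate_recovery <- function(hits, truth, positives_only = TRUE) {
  if (inherits(hits, "scan_result")) hits <- hits$hits
  truth$recovered <- FALSE
  truth$hit_identity <- NA_real_
  if (nrow(hits) == 0L || nrow(truth) == 0L) {
    return(truth)
  }
  if (positives_only) hits <- hits[hits$label != "rejected", , drop = FALSE]
  for (i in seq_len(nrow(truth))) {
    m <- hits$target_id == truth$target_id[i] &
      hits$orientation == truth$orientation[i] &
      hits$t_start <= truth$end[i] & hits$t_end >= truth$start[i]
    if (any(m)) {
      truth$recovered[i] <- TRUE
      truth$hit_identity[i] <- max(hits$identity_pct[m])
    }
  }
  truth
}
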