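# FASTA input/output, sequence validation, reversal and shuffling.
# Coordinates throughout the package are 1-based inclusive (the convention of
# IRanges and of sequence feature tables); BED export converts on the way out.

#' The twenty standard amino-acid one-letter codes
#' @keywords internal
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Ambiguity codes tolerated in permissive mode.
AA_AMBIGUOUS <- c("X", "B", "Z", "U")

#' Construct a validated protein sequence record
#'
#' The basic record the whole package operates on: an identifier plus an
#' upper-case amino-acid string over the standard 20-letter alphabet.
#'
#' @param id Record identifier (unique within a database).
#' @param residues Amino-acid string; lower case is accepted and upper-cased,
#'   whitespace is stripped.
#' @param description Optional free-text description.
#' @param strict If `TRUE` (default) only the 20 standard residues are
#'   allowed; if `FALSE`, ambiguity codes X/B/Z/U are tolerated and the
#'   record is flagged via its `has_ambiguous` field.
#' @return An object of class `protein_sequence` with fields `id`,
#'   `residues`, `description`, `has_ambiguous`.
#' @examples
#' p <- protein_sequence("frag1", "mkv la")
#' p$residues # "MKVLA"
#' @export
protein_sequence <- function(id, residues, description = "", strict = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(gsub("[[:space:]]+", "", residues))
  if (!nzchar(residues)) {
    stop("sequence '", id, "': residues must be non-empty", call. = FALSE)
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  allowed <- if (strict) AA_ALPHABET else c(AA_ALPHABET, AA_AMBIGUOUS)
  bad <- which(!(chars %in% allowed))
  if (length(bad) > 0L) {
    stop(
      "sequence '", id, "': illegal residue '", chars[bad[1L]],
      "' at position ", bad[1L], call. = FALSE
    )
  }
  structure(
    list(
      id = id,
      residues = residues,
      description = description,
      has_ambiguous = any(chars %in% AA_AMBIGUOUS)
    ),
    class = "protein_sequence"
  )
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(
    "<protein_sequence> ", x$id, " (", nchar(x$residues), " aa)",
    if (x$has_ambiguous) " [ambiguous codes]" else "", "\n",
    sep = ""
  )
  res <- x$residues
  if (nchar(res) > 60) res <- paste0(substr(res, 1, 57), "...")
  cat("  ", res, "\n", sep = "")
  invisible(x)
}

#' @export
length.protein_sequence <- function(x) nchar(x$residues)

seq_chars <- function(seq) strsplit(seq$residues, "", fixed = TRUE)[[1L]]

#' Read a protein FASTA file
#'
#' Parses a multi-record FASTA file into a list of [protein_sequence()]
#' records. Residues are upper-cased and whitespace removed; record order is
#' preserved. The first whitespace-delimited token of each header becomes the
#' record id, the remainder (if any) the description. Ids must be unique.
#'
#' @param path Path to a FASTA file.
#' @param strict Passed to [protein_sequence()]; with `strict = TRUE` any
#'   non-standard residue raises an error naming the record and position.
#' @return A list of `protein_sequence` objects (empty, with a warning, for
#'   an empty file).
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in ", path, ": ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(list())
  }
  headers <- names(set)
  ids <- sub("[[:space:]].*$", "", headers)
  descs <- ifelse(
    grepl("[[:space:]]", headers),
    sub("^[^[:space:]]+[[:space:]]+", "", headers),
    ""
  )
  if (anyDuplicated(ids)) {
    stop(
      "duplicate record id(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  records <- vector("list", length(set))
  for (i in seq_along(set)) {
    records[[i]] <- protein_sequence(
      ids[i], as.character(set[[i]]), descs[i],
      strict = strict
    )
  }
  names(records) <- ids
  records
}

#' Write protein sequences to a FASTA file
#'
#' Round-trip safe with [read_fasta()]: ids and residues are reproduced
#' exactly.
#'
#' @param records A list of [protein_sequence()] records (or a single one).
#' @param path Output path.
#' @param width Maximum sequence-line width (positive integer, default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "protein_sequence")) records <- list(records)
  stopifnot(width >= 1L)
  set <- Biostrings::BStringSet(vapply(records, function(r) r$residues, ""))
  names(set) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, "")
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Reverse a protein sequence (retro-sequence)
#'
#' Reading a sequence backwards preserves its length, its amino-acid
#' composition, and the coarse hydrophobic/hydrophilic pattern — the premise
#' behind screening for retro-MoRFs. The returned record's id carries a
#' `|rev` suffix so hits stay traceable to their orientation; reversing a
#' reversed record removes the marker again (reversal is an involution).
#'
#' @param seq A [protein_sequence()].
#' @return A `protein_sequence` with residues in reverse order.
#' @examples
#' reverse_sequence(protein_sequence("f", "ACDE"))$residues # "EDCA"
#' @export
reverse_sequence <- function(seq) {
  stopifnot(inherits(seq, "protein_sequence"))
  rev_res <- paste(rev(seq_chars(seq)), collapse = "")
  new_id <- if (endsWith(seq$id, "|rev")) {
    sub("\\|rev$", "", seq$id)
  } else {
    paste0(seq$id, "|rev")
  }
  protein_sequence(new_id, rev_res, seq$description, strict = !seq$has_ambiguous)
}

#' Randomly shuffle the residues of a sequence
#'
#' A uniform random permutation of the residues, deterministic for a fixed
#' seed; composition and length are preserved. Shuffled copies of a query are
#' the decoys behind [empirical_evalue()].
#'
#' @param seq A [protein_sequence()].
#' @param seed Integer seed (required; the caller's RNG state is untouched).
#' @return A `protein_sequence` with id suffixed `|shuf`.
#' @export
shuffle_sequence <- function(seq, seed) {
  stopifnot(inherits(seq, "protein_sequence"))
  chars <- seq_chars(seq)
  perm <- with_local_seed(seed, sample.int(length(chars)))
  protein_sequence(
    paste0(seq$id, "|shuf"),
    paste(chars[perm], collapse = ""),
    seq$description,
    strict = !seq$has_ambiguous
  )
}

#' Extract a subsequence as a new record
#'
#' @param seq A [protein_sequence()].
#' @param start,end 1-based inclusive bounds.
#' @return A `protein_sequence` with id `<id>:<start>-<end>`.
#' @export
subsequence <- function(seq, start, end) {
  stopifnot(inherits(seq, "protein_sequence"))
  n <- nchar(seq$residues)
  if (start < 1L || end > n || start > end) {
    stop(
      "interval [", start, ", ", end, "] out of bounds for '", seq$id,
      "' (length ", n, ")",
      call. = FALSE
    )
  }
  protein_sequence(
    paste0(seq$id, ":", start, "-", end),
    substr(seq$residues, start, end),
    strict = !seq$has_ambiguous
  )
}

#' Amino-acid composition of a sequence
#'
#' @param seq A [protein_sequence()].
#' @return Named integer vector of counts over the 20-letter alphabet (plus
#'   any ambiguity codes present).
#' @export
composition <- function(seq) {
  chars <- seq_chars(seq)
  tab <- table(factor(chars, levels = union(AA_ALPHABET, unique(chars))))
  setNames(as.integer(tab), names(tab))
}
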