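# DRACH = [GAC][GA]AC[UAC], the methylated adenine at offset 3 of the 5-mer
DRACH_REGEX <- "[GAC][GA]AC[UAC]"

#' Scan a transcript for DRACH-motif candidate adenines
#'
#' Every adenine whose surrounding 5-mer matches the degenerate consensus
#' DRACH (\code{[G/A/C][G/A]AC[U/A/C]}) is a candidate m6A site.
#' Overlapping matches are all reported, ordered by position.
#'
#' @param sequence transcript sequence over \{A,C,G,U\} (normalised from
#'   DNA if needed).
#' @return a data.frame with columns `position` (1-based coordinate of
#'   the candidate adenine) and `motif_5mer`; zero rows when no match.
#' @export
scan_drach <- function(sequence) {
  sequence <- normalize_sequence(sequence)
  n <- nchar(sequence)
  if (n < 5L) {
    return(data.frame(position = integer(0), motif_5mer = character(0),
                      stringsAsFactors = FALSE))
  }
  # lookahead makes overlapping motif instances all visible
  starts <- gregexpr(paste0("(?=", DRACH_REGEX, ")"), sequence,
                     perl = TRUE)[[1L]]
  if (starts[1L] == -1L) {
    return(data.frame(position = integer(0), motif_5mer = character(0),
                      stringsAsFactors = FALSE))
  }
  starts <- as.integer(starts)
  data.frame(position = starts + 2L,
             motif_5mer = substring(sequence, starts, starts + 4L),
             stringsAsFactors = FALSE)
}

#' Extract a fixed-size window around a transcript position
#'
#' The window is centred at `position` and spans `flank` nucleotides on
#' each side; cells falling outside the transcript are padded with 'N'.
#'
#' @param sequence transcript sequence.
#' @param position 1-based centre position.
#' @param flank number of flanking nucleotides per side (default 25,
#'   giving 51-nt windows).
#' @return a window string of length `2 * flank + 1`.
#' @export
extract_window <- function(sequence, position, flank = 25L) {
  sequence <- normalize_sequence(sequence)
  n <- nchar(sequence)
  position <- as.integer(position)
  if (position < 1L || position > n) {
    stop(sprintf("position %d outside transcript of length %d", position, n))
  }
  lo <- position - flank
  hi <- position + flank
  core <- substr(sequence, max(lo, 1L), min(hi, n))
  paste0(strrep("N", max(0L, 1L - lo)), core, strrep("N", max(0L, hi - n)))
}

#' Build a sample table from transcripts and known positive sites
#'
#' Every DRACH candidate on every transcript becomes one row; rows whose
#' (transcript, position) appears in `positive_sites` are labelled
#' positive, all remaining candidates negative.  A supplied positive site
#' that does not sit on a DRACH match is retained with a warning.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param positive_sites data.frame with columns `transcript_id` and
#'   `position`, or NULL for an all-negative table.
#' @param flank window half-width (default 25).
#' @return a validated sample table.
#' @export
build_samples <- function(transcripts, positive_sites = NULL, flank = 25L) {
  stopifnot(!is.null(names(transcripts)))
  pieces <- lapply(names(transcripts), function(id) {
    seq <- normalize_sequence(transcripts[[id]])
    hits <- scan_drach(seq)
    if (nrow(hits) == 0L) return(NULL)
    data.frame(transcript_id = id, position = hits$position,
               transcript_length = nchar(seq), stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, pieces)
  extra <- NULL
  if (!is.null(positive_sites) && nrow(positive_sites) > 0L) {
    key <- function(d) paste(d$transcript_id, d$position)
    pos_key <- key(positive_sites)
    cand_key <- if (is.null(rows)) character(0) else key(rows)
    off_motif <- !(pos_key %in% cand_key)
    if (any(off_motif)) {
      warning(sprintf(
        "%d positive site(s) do not match DRACH (first: %s:%d); retained",
        sum(off_motif), positive_sites$transcript_id[which(off_motif)[1L]],
        positive_sites$position[which(off_motif)[1L]]))
      miss <- positive_sites[off_motif, , drop = FALSE]
      extra <- data.frame(
        transcript_id = miss$transcript_id,
        position = as.integer(miss$position),
        transcript_length = nchar(transcripts[miss$transcript_id]),
        stringsAsFactors = FALSE)
    }
  } else {
    pos_key <- character(0)
  }
  rows <- rbind(rows, extra)
  if (is.null(rows) || nrow(rows) == 0L) {
    return(sample_table(character(0), integer(0), integer(0), character(0),
                        character(0)))
  }
  windows <- vapply(seq_len(nrow(rows)), function(i) {
    extract_window(transcripts[[rows$transcript_id[i]]], rows$position[i],
                   flank)
  }, "")
  label <- ifelse(paste(rows$transcript_id, rows$position) %in% pos_key,
                  "positive", "negative")
  sample_table(rows$transcript_id, rows$position, rows$transcript_length,
               windows, label)
}
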