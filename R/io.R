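#' @importFrom stats fisher.test rnorm rlnorm runif setNames predict complete.cases
#' @importFrom utils read.delim read.csv write.table head
NULL

RNA_LETTERS <- c("A", "C", "G", "U")

normalize_sequence <- function(x) {
  x <- toupper(x)
  gsub("T", "U", x, fixed = TRUE)
}

#' Construct and validate a sample table
#'
#' A sample table holds one row per candidate adenine: the transcript it
#' sits on, its 1-based position, the transcript length, the flanking
#' window sequence (odd length, 'A' at the centre, 'N' allowed only as
#' edge padding) and a binary label.
#'
#' @param transcript_id character vector of transcript identifiers.
#' @param position 1-based site positions on the mature transcript.
#' @param transcript_length transcript lengths in nucleotides.
#' @param window flanking window sequences over \{A,C,G,U,N\} (lower case
#'   and DNA 'T' are normalised).
#' @param label class labels, `"positive"` or `"negative"`.
#' @return a validated `data.frame` with those five columns.
#' @export
sample_table <- function(transcript_id, position, transcript_length, window,
                         label) {
  tab <- data.frame(
    transcript_id = as.character(transcript_id),
    position = as.integer(position),
    transcript_length = as.integer(transcript_length),
    window = normalize_sequence(as.character(window)),
    label = as.character(label),
    stringsAsFactors = FALSE
  )
  validate_sample_table(tab)
}

#' Validate a sample table against its invariants
#'
#' @param tab a data.frame with columns transcript_id, position,
#'   transcript_length, window, label.
#' @return the table, invisibly unchanged, or an error naming the first
#'   offending row.
#' @export
validate_sample_table <- function(tab) {
  required <- c("transcript_id", "position", "transcript_length", "window",
                "label")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("sample table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(tab) == 0L) {
    return(tab)
  }
  bad_lab <- which(!tab$label %in% c("positive", "negative"))
  if (length(bad_lab) > 0L) {
    stop(sprintf("row %d (%s): label '%s' is not 'positive'/'negative'",
                 bad_lab[1L], tab$transcript_id[bad_lab[1L]],
                 tab$label[bad_lab[1L]]))
  }
  bad_chr <- which(grepl("[^ACGUN]", tab$window))
  if (length(bad_chr) > 0L) {
    stop(sprintf("row %d (%s): window contains characters outside {A,C,G,U,N}",
                 bad_chr[1L], tab$transcript_id[bad_chr[1L]]))
  }
  len <- nchar(tab$window)
  bad_len <- which(len %% 2L == 0L)
  if (length(bad_len) > 0L) {
    stop(sprintf("row %d (%s): window length %d is even; windows must be odd",
                 bad_len[1L], tab$transcript_id[bad_len[1L]], len[bad_len[1L]]))
  }
  centre <- substr(tab$window, (len + 1L) %/% 2L, (len + 1L) %/% 2L)
  bad_ctr <- which(centre != "A")
  if (length(bad_ctr) > 0L) {
    stop(sprintf("row %d (%s): window centre is '%s', expected 'A'",
                 bad_ctr[1L], tab$transcript_id[bad_ctr[1L]],
                 centre[bad_ctr[1L]]))
  }
  bad_pos <- which(tab$position < 1L | tab$position > tab$transcript_length)
  if (length(bad_pos) > 0L) {
    stop(sprintf("row %d (%s): position %d outside 1..%d",
                 bad_pos[1L], tab$transcript_id[bad_pos[1L]],
                 tab$position[bad_pos[1L]], tab$transcript_length[bad_pos[1L]]))
  }
  tab
}

#' Read a sample table from TSV, CSV or XLSX
#'
#' Columns are resolved by header name (`transcript_id`, `position`,
#' `transcript_length`, `window`, `label`).  Sequences are upper-cased and
#' 'T' is transliterated to 'U'; any other repair is refused.
#'
#' @param path file path.
#' @param dialect one of `"tsv"`, `"csv"`, `"xlsx"` (xlsx needs readxl).
#' @return a validated sample table.
#' @export
read_sample_table <- function(path, dialect = c("tsv", "csv", "xlsx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- switch(dialect,
    tsv = read.delim(path, stringsAsFactors = FALSE, colClasses = "character"),
    csv = read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading xlsx requires the 'readxl' package")
      }
      as.data.frame(readxl::read_xlsx(path, col_types = "text"),
                    stringsAsFactors = FALSE)
    }
  )
  required <- c("transcript_id", "position", "transcript_length", "window",
                "label")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(raw$position))
  tlen <- suppressWarnings(as.integer(raw$transcript_length))
  bad <- which(is.na(pos) | is.na(tlen))
  if (length(bad) > 0L) {
    stop(sprintf("row %d: non-integer position or transcript_length", bad[1L]))
  }
  sample_table(raw$transcript_id, pos, tlen, raw$window, raw$label)
}

#' Write a sample table to TSV or CSV
#'
#' Re-reading the written file yields an equal table; 'N' padding is
#' preserved verbatim.
#'
#' @param tab a valid sample table.
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return the path, invisibly.
#' @export
write_sample_table <- function(tab, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  validate_sample_table(tab)
  sep <- if (dialect == "tsv") "\t" else ","
  write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' Identifiers are taken from the header up to the first whitespace;
#' sequences are upper-cased and 'T' transliterated to 'U'.
#'
#' @param path FASTA file.
#' @return a named character vector of transcript sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- normalize_sequence(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (any(nchar(seqs) == 0L)) {
    stop("empty record in ", path, ": ", ids[which(nchar(seqs) == 0L)[1L]])
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate transcript id in ", path, ": ", dup[1L])
  }
  names(seqs) <- ids
  seqs
}

#' Write transcript sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a SNP position table
#'
#' Accepts a two-column tab-delimited file (transcript_id, 1-based
#' position) or a minimal VCF where CHROM is interpreted as the
#' transcript id and POS as the transcript coordinate.  Duplicate entries
#' collapse to one (set semantics).
#'
#' @param path input file; VCF is detected by a `##fileformat` header or
#'   a `.vcf` extension.
#' @return a data.frame with columns `transcript_id`, `position`.
#' @export
read_snp_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_vcf <- grepl("\\.vcf$", path, ignore.case = TRUE) ||
    (length(lines) > 0L && startsWith(lines[1L], "##fileformat"))
  lines_kept <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines_kept) == 0L) {
    return(snp_table(character(0), integer(0)))
  }
  fields <- strsplit(lines_kept, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", 1L)
  pos_chr <- vapply(fields, `[[`, "", 2L)
  pos <- suppressWarnings(as.integer(pos_chr))
  bad <- which(is.na(pos))
  if (length(bad) > 0L) {
    line_no <- which(lines == lines_kept[bad[1L]])[1L]
    stop(sprintf("line %d of %s: non-integer position '%s'",
                 line_no, path, pos_chr[bad[1L]]))
  }
  if (is_vcf && any(pos < 1L)) {
    stop("VCF positions must be >= 1")
  }
  snp_table(ids, pos)
}

#' Construct a SNP table from vectors
#'
#' @param transcript_id character vector.
#' @param position 1-based integer positions.
#' @return deduplicated data.frame (`transcript_id`, `position`).
#' @export
snp_table <- function(transcript_id, position) {
  position <- as.integer(position)
  if (any(position < 1L, na.rm = TRUE)) stop("SNP positions must be >= 1")
  tab <- unique(data.frame(transcript_id = as.character(transcript_id),
                           position = position, stringsAsFactors = FALSE))
  rownames(tab) <- NULL
  tab
}

#' Write a SNP table as two-column TSV
#'
#' @param snp a SNP table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_snp_table <- function(snp, path) {
  write.table(snp, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

MODEL_FORMAT_VERSION <- 1L

#' Save a fitted model to disk
#'
#' The artifact is versioned; `load_model(save_model(m))` reproduces
#' bitwise-identical predictions.
#'
#' @param model an object of class `m6acs`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "m6acs"))
  if (dir.exists(path)) stop("path is a directory: ", path)
  artifact <- list(
    format_version = MODEL_FORMAT_VERSION,
    booster_raw = xgboost::xgb.save.raw(model$booster),
    config = model$config,
    ranking = model$ranking,
    feature_names = model$feature_names,
    n_train = model$n_train,
    class_counts = model$class_counts
  )
  saveRDS(artifact, path)
  invisible(path)
}

#' Load a fitted model saved by [save_model()]
#'
#' @param path artifact path.
#' @return an object of class `m6acs`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  artifact <- readRDS(path)
  if (!is.list(artifact) || is.null(artifact$format_version)) {
    stop("not a recognised model artifact: ", path)
  }
  if (artifact$format_version != MODEL_FORMAT_VERSION) {
    stop(sprintf("model artifact version %s; this package reads version %d",
                 artifact$format_version, MODEL_FORMAT_VERSION))
  }
  model <- list(
    booster = xgboost::xgb.load.raw(artifact$booster_raw),
    config = artifact$config,
    ranking = artifact$ranking,
    feature_names = artifact$feature_names,
    n_train = artifact$n_train,
    class_counts = artifact$class_counts
  )
  class(model) <- "m6acs"
  model
}
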