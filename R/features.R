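# Per-nucleotide encodings.  Binary: one-hot in order A,C,G,U.
# CPD: ring number / hydrogen bond / functional group, overlapping code
# A-(1,1,1) C-(0,0,1) G-(1,0,0) U-(0,1,0).  'N' (edge padding) maps to
# all-zero codes in both and is excluded from composition frequencies.
BINARY_CODE <- rbind(A = c(1, 0, 0, 0), C = c(0, 1, 0, 0),
                     G = c(0, 0, 1, 0), U = c(0, 0, 0, 1),
                     N = c(0, 0, 0, 0))
CPD_CODE <- rbind(A = c(1, 1, 1), C = c(0, 0, 1),
                  G = c(1, 0, 0), U = c(0, 1, 0),
                  N = c(0, 0, 0))
CPD_BIT_NAMES <- c("ring", "hbond", "amino")

window_chars <- function(window) {
  chars <- strsplit(window, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c(RNA_LETTERS, "N"))
  if (length(bad) > 0L) {
    stop(sprintf("illegal character '%s' at window position %d",
                 chars[bad[1L]], bad[1L]))
  }
  chars
}

window_offsets <- function(L) seq_len(L) - (L + 1L) %/% 2L

#' One-hot binary encoding of a window
#'
#' Each position becomes 4 bits in the order A,C,G,U ('N' padding gives
#' all zeros), so a 51-nt window yields 204 values.
#'
#' @param window window sequence over \{A,C,G,U,N\}.
#' @return named numeric vector of length `4 * nchar(window)`.
#' @export
encode_binary <- function(window) {
  chars <- window_chars(window)
  m <- BINARY_CODE[chars, , drop = FALSE]
  off <- window_offsets(length(chars))
  setNames(as.vector(t(m)),
           paste0("binary_", rep(off, each = 4L), "_", RNA_LETTERS))
}

#' Chemical-property encoding of a window
#'
#' Each position becomes 3 bits (ring number, hydrogen bonding,
#' functional group): A-(1,1,1), C-(0,0,1), G-(1,0,0), U-(0,1,0);
#' 'N' gives (0,0,0).
#'
#' @inheritParams encode_binary
#' @return named numeric vector of length `3 * nchar(window)`.
#' @export
encode_cpd <- function(window) {
  chars <- window_chars(window)
  m <- CPD_CODE[chars, , drop = FALSE]
  off <- window_offsets(length(chars))
  setNames(as.vector(t(m)),
           paste0("cpd_", rep(off, each = 3L), "_", CPD_BIT_NAMES))
}

#' Cumulative nucleotide density along a window
#'
#' Position i gets the frequency of its own nucleotide among positions
#' 1..i: `d_i = #\{j <= i : s_j = s_i\} / i`.  'N' positions get density
#' 0 and do not count toward any letter; the denominator stays the
#' prefix length i.
#'
#' @inheritParams encode_binary
#' @return named numeric vector of length `nchar(window)`.
#' @export
nucleotide_density <- function(window) {
  chars <- window_chars(window)
  L <- length(chars)
  counts <- setNames(integer(4L), RNA_LETTERS)
  d <- numeric(L)
  for (i in seq_len(L)) {
    ci <- chars[i]
    if (ci != "N") {
      counts[ci] <- counts[ci] + 1L
      d[i] <- counts[ci] / i
    }
  }
  setNames(d, paste0("density_", window_offsets(L)))
}

all_kmers <- function(k) {
  grids <- rev(rep(list(RNA_LETTERS), k))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

#' k-mer frequencies of a window
#'
#' Counts every length-k substring over the `L - k + 1` sliding windows
#' and divides by the number of valid (N-free) windows; k-mers containing
#' 'N' are skipped from numerator and denominator.  Output order is
#' lexicographic with A < C < G < U.
#'
#' @inheritParams encode_binary
#' @param k substring length.
#' @return named numeric vector of length `4^k`.
#' @export
kmer_frequencies <- function(window, k) {
  chars <- window_chars(window)
  L <- length(chars)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > L) stop(sprintf("k = %d exceeds window length %d", k, L))
  kmers <- all_kmers(k)
  counts <- setNames(numeric(length(kmers)), kmers)
  n_valid <- 0L
  for (i in seq_len(L - k + 1L)) {
    sub <- chars[i:(i + k - 1L)]
    if (any(sub == "N")) next
    mer <- paste(sub, collapse = "")
    counts[mer] <- counts[mer] + 1
    n_valid <- n_valid + 1L
  }
  if (n_valid > 0L) counts <- counts / n_valid
  setNames(counts, paste0("kmer", k, "_", kmers))
}

#' Entropy and composition features of a window
#'
#' Nucleotide frequencies are taken over non-'N' characters.  Shannon
#' entropy is `En = -sum p_i log2 p_i` (with `0 log 0 := 0`); relative
#' entropy against the uniform reference p0 = 1/4 is
#' `REn = -sum p_i log2(p_i / p0)`, and the information gain score is
#' `IGS = En - REn`.  With this sign convention REn equals `En - 2` and
#' IGS is identically 2 bits; the encoding is kept as defined, and the
#' identity is asserted in the test suite.
#'
#' @inheritParams encode_binary
#' @return named numeric vector `(p_A, p_G, p_U, p_C, En, REn, IGS)`.
#' @export
entropy_features <- function(window) {
  chars <- window_chars(window)
  chars <- chars[chars != "N"]
  if (length(chars) == 0L) stop("window is all 'N'; entropy undefined")
  p <- setNames(numeric(4L), c("A", "G", "U", "C"))
  tab <- table(chars) / length(chars)
  p[names(tab)] <- as.numeric(tab)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  en <- -sum(plogp)
  ren <- -sum(ifelse(p > 0, p * log2(p / 0.25), 0))
  c(p_A = unname(p["A"]), p_G = unname(p["G"]), p_U = unname(p["U"]),
    p_C = unname(p["C"]), En = en, REn = ren, IGS = en - ren)
}

#' Site location features
#'
#' Absolute location is the distance from the transcript start site
#' (position 1 maps to 0); relative location is that distance divided by
#' the transcript length, in [0, 1).
#'
#' @param position 1-based site position.
#' @param transcript_length transcript length in nucleotides.
#' @return named numeric vector `(loc_abs, loc_rel)`.
#' @export
location_features <- function(position, transcript_length) {
  if (any(transcript_length < 1L)) stop("transcript_length must be >= 1")
  if (any(position < 1L | position > transcript_length)) {
    stop("position outside 1..transcript_length")
  }
  absolute <- position - 1
  c(loc_abs = absolute, loc_rel = absolute / transcript_length)
}

#' SNP variant state vector over a sample window
#'
#' Bit j is 1 iff the transcript coordinate of window offset j
#' (-flank..+flank around the site) carries a SNP variant; coordinates
#' outside the transcript (padding) are 0.
#'
#' @param transcript_id transcript the sample sits on.
#' @param position 1-based site position.
#' @param transcript_length transcript length.
#' @param snp SNP table (see [snp_table()]).
#' @param flank window half-width.
#' @return named 0/1 integer vector of length `2 * flank + 1`.
#' @export
snp_state_vector <- function(transcript_id, position, transcript_length, snp,
                             flank = 25L) {
  off <- (-flank):flank
  coords <- position + off
  tx_pos <- snp$position[snp$transcript_id == transcript_id]
  bits <- as.integer(coords >= 1L & coords <= transcript_length &
                       coords %in% tx_pos)
  setNames(bits, paste0("snp_", off))
}

#' Assemble the full feature vector for one sample
#'
#' Concatenates the blocks in fixed order: binary (4 per position), CPD
#' (3 per position), density, k-mer, entropy/composition, location, SNP.
#' The SNP block keeps only the selected window offsets in their ranked
#' order.  At the defaults (51-nt window, k = 2 and 3, 12 SNP positions)
#' the vector has 509 dimensions.
#'
#' @param sample one-row sample table (or a list with the same fields).
#' @param snp SNP table, or NULL to disable the SNP block.
#' @param selected_positions integer window offsets for the SNP block,
#'   in ranked order (e.g. `ranking$offset[ranking$selected]`).
#' @param config run configuration, see [m6acs_config()].
#' @return named numeric feature vector.
#' @export
assemble_features <- function(sample, snp = NULL, selected_positions = NULL,
                              config = m6acs_config()) {
  w <- sample$window
  out <- c(
    encode_binary(w),
    encode_cpd(w),
    nucleotide_density(w),
    unlist(lapply(config$kmer_sizes, function(k) kmer_frequencies(w, k))),
    entropy_features(w),
    location_features(sample$position, sample$transcript_length)
  )
  if (!is.null(snp) && !is.null(selected_positions) &&
      length(selected_positions) > 0L) {
    states <- snp_state_vector(sample$transcript_id, sample$position,
                               sample$transcript_length, snp, config$flank)
    sel <- states[paste0("snp_", selected_positions)]
    out <- c(out, sel)
  }
  out
}

#' Feature matrix for a sample table
#'
#' Vectorised assembly of [assemble_features()] over all rows.
#'
#' @param samples a validated sample table.
#' @param snp SNP table, or NULL to disable the SNP block.
#' @param selected_positions SNP window offsets in ranked order.
#' @param config run configuration.
#' @return numeric matrix, one row per sample, block-qualified column
#'   names.
#' @export
feature_matrix <- function(samples, snp = NULL, selected_positions = NULL,
                           config = m6acs_config()) {
  validate_sample_table(samples)
  n <- nrow(samples)
  L <- 2L * config$flank + 1L
  if (n == 0L) stop("empty sample table")
  wlen <- unique(nchar(samples$window))
  if (!identical(wlen, L)) {
    stop(sprintf("window length(s) %s do not match configured 2*flank+1 = %d",
                 paste(wlen, collapse = ","), L))
  }
  cm <- matrix(unlist(strsplit(samples$window, "", fixed = TRUE), use.names = FALSE),
               nrow = n, byrow = TRUE)
  bad <- !cm %in% c(RNA_LETTERS, "N")
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("row %d: illegal character at window position %d",
                 idx[1L], idx[2L]))
  }
  off <- window_offsets(L)

  # binary and cpd blocks, position-major
  bin <- matrix(0, n, 4L * L,
                dimnames = list(NULL, paste0("binary_", rep(off, each = 4L),
                                             "_", RNA_LETTERS)))
  cpd <- matrix(0, n, 3L * L,
                dimnames = list(NULL, paste0("cpd_", rep(off, each = 3L),
                                             "_", CPD_BIT_NAMES)))
  for (i in seq_len(L)) {
    bin[, (4L * (i - 1L) + 1L):(4L * i)] <- BINARY_CODE[cm[, i], , drop = FALSE]
    cpd[, (3L * (i - 1L) + 1L):(3L * i)] <- CPD_CODE[cm[, i], , drop = FALSE]
  }

  # density: running per-letter prefix counts, shared across rows
  dens <- matrix(0, n, L, dimnames = list(NULL, paste0("density_", off)))
  counts <- matrix(0L, n, 4L, dimnames = list(NULL, RNA_LETTERS))
  for (i in seq_len(L)) {
    for (letter in RNA_LETTERS) {
      hit <- cm[, i] == letter
      counts[hit, letter] <- counts[hit, letter] + 1L
      dens[hit, i] <- counts[hit, letter] / i
    }
  }

  # k-mer frequencies
  kmer_blocks <- lapply(config$kmer_sizes, function(k) {
    mers <- all_kmers(k)
    nwin <- L - k + 1L
    win <- cm[, 1:nwin, drop = FALSE]
    valid <- !(cm[, 1:nwin, drop = FALSE] == "N")
    for (j in seq_len(k - 1L)) {
      win <- matrix(paste0(win, cm[, (1L + j):(nwin + j), drop = FALSE]),
                    nrow = n)
      valid <- valid & !(cm[, (1L + j):(nwin + j), drop = FALSE] == "N")
    }
    n_valid <- rowSums(valid)
    blk <- matrix(0, n, length(mers),
                  dimnames = list(NULL, paste0("kmer", k, "_", mers)))
    for (m in seq_along(mers)) {
      blk[, m] <- rowSums(win == mers[m] & valid)
    }
    blk[n_valid > 0L, ] <- blk[n_valid > 0L, , drop = FALSE] / n_valid[n_valid > 0L]
    blk
  })

  # entropy / composition
  non_n <- rowSums(cm != "N")
  if (any(non_n == 0L)) {
    stop(sprintf("row %d: window is all 'N'; entropy undefined",
                 which(non_n == 0L)[1L]))
  }
  freq <- sapply(c("A", "G", "U", "C"),
                 function(letter) rowSums(cm == letter) / non_n)
  freq <- matrix(freq, nrow = n,
                 dimnames = list(NULL, c("A", "G", "U", "C")))
  plogp <- ifelse(freq > 0, freq * log2(freq), 0)
  en <- -rowSums(plogp)
  ren <- en - 2
  ent <- cbind(p_A = freq[, "A"], p_G = freq[, "G"], p_U = freq[, "U"],
               p_C = freq[, "C"], En = en, REn = ren, IGS = en - ren)

  loc_abs <- samples$position - 1
  loc <- cbind(loc_abs = loc_abs,
               loc_rel = loc_abs / samples$transcript_length)

  out <- do.call(cbind, c(list(bin, cpd, dens), kmer_blocks,
                          list(ent, loc)))

  if (!is.null(snp) && !is.null(selected_positions) &&
      length(selected_positions) > 0L) {
    states <- snp_state_matrix(samples, snp, config$flank)
    out <- cbind(out, states[, paste0("snp_", selected_positions),
                             drop = FALSE])
  }
  out
}

#' SNP state matrix for a sample table
#'
#' Row-wise [snp_state_vector()]: one 0/1 column per window offset
#' -flank..+flank.
#'
#' @inheritParams feature_matrix
#' @param flank window half-width.
#' @return integer matrix `n x (2 * flank + 1)`.
#' @export
snp_state_matrix <- function(samples, snp, flank = 25L) {
  off <- (-flank):flank
  n <- nrow(samples)
  out <- matrix(0L, n, length(off),
                dimnames = list(NULL, paste0("snp_", off)))
  key <- paste(snp$transcript_id, snp$position)
  for (j in seq_along(off)) {
    coords <- samples$position + off[j]
    inside <- coords >= 1L & coords <= samples$transcript_length
    out[, j] <- as.integer(inside &
                             paste(samples$transcript_id, coords) %in% key)
  }
  out
}
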