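# Independent oracles used to check package operations.  These are
# deliberately written as naive brute-force routines on a different code
# path from the implementation.

# all 18 concrete DRACH 5-mers, by explicit enumeration
drach_5mers <- function() {
  g <- expand.grid(d = c("G", "A", "C"), r = c("G", "A"), a = "A", c = "C",
                   h = c("U", "A", "C"), stringsAsFactors = FALSE)
  paste0(g$d, g$r, g$a, g$c, g$h)
}

# positional substring comparison against the enumerated motif set
oracle_scan_drach <- function(sequence) {
  mers <- drach_5mers()
  n <- nchar(sequence)
  pos <- integer(0)
  if (n >= 5L) {
    for (i in seq_len(n - 4L)) {
      if (substr(sequence, i, i + 4L) %in% mers) pos <- c(pos, i + 2L)
    }
  }
  pos
}

# exhaustive two-sided Fisher p: sum of hypergeometric probabilities of
# all margin-fixed tables no more probable than the observed one
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + c_          # positives
  n <- b + d           # negatives
  k <- a + b           # variants
  lo <- max(0L, k - n)
  hi <- min(k, m)
  dens <- stats::dhyper(lo:hi, m, n, k)
  sum(dens[dens <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

# entropy-based mutual information in bits (different formula route)
oracle_mi <- function(x, y) {
  h <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  h(x) + h(y) - h(paste(x, y))
}

# direct greedy MID evaluation over all candidates at every step
oracle_mrmr <- function(states, labels) {
  p <- ncol(states)
  offsets <- as.integer(sub("^snp_", "", colnames(states)))
  constant <- apply(states, 2L, function(x) length(unique(x)) == 1L)
  active <- which(!constant)
  selected <- integer(0)
  while (length(active) > 0L) {
    score <- vapply(active, function(j) {
      rel <- oracle_mi(states[, j], labels)
      if (length(selected) == 0L) return(rel)
      red <- mean(vapply(selected, function(s) {
        oracle_mi(states[, j], states[, s])
      }, 0))
      rel - red
    }, 0)
    cand <- active[score == max(score)]
    best <- cand[order(abs(offsets[cand]), offsets[cand])][1L]
    selected <- c(selected, best)
    active <- setdiff(active, best)
  }
  const_idx <- which(constant)
  unname(c(selected, const_idx[order(offsets[const_idx])]))
}

# dictionary-count k-mer oracle
oracle_kmers <- function(window, k) {
  chars <- strsplit(window, "")[[1L]]
  mers <- character(0)
  for (i in seq_len(length(chars) - k + 1L)) {
    m <- paste(chars[i:(i + k - 1L)], collapse = "")
    if (!grepl("N", m)) mers <- c(mers, m)
  }
  lex <- ""
  for (i in seq_len(k)) {
    lex <- as.vector(outer(lex, c("A", "C", "G", "U"), paste0))
  }
  lex <- sort(lex)
  counts <- vapply(lex, function(m) sum(mers == m), 0)
  if (length(mers) > 0L) counts <- counts / length(mers)
  unname(counts)
}

# prefix-count density oracle
oracle_density <- function(window) {
  chars <- strsplit(window, "")[[1L]]
  vapply(seq_along(chars), function(i) {
    if (chars[i] == "N") return(0)
    sum(chars[1:i] == chars[i] & chars[1:i] != "N") / i
  }, 0)
}

random_window <- function(len = 51L, letters = c("A", "C", "G", "U")) {
  w <- sample(letters, len, replace = TRUE)
  w[(len + 1L) %/% 2L] <- "A"
  paste(w, collapse = "")
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
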