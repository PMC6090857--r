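# Synthetic-corpus generator.  Emulates the statistical structure the
# predictor exploits: DRACH candidate sites on random-background
# transcripts, positives concentrated near a nominal stop-codon
# position (m6A enrichment in the 3'UTR), negatives spread over the
# whole transcript, class-conditional SNP variant rates at a chosen set
# of window offsets, and a configurable negative:positive imbalance.

#' Simulation configuration
#'
#' Defaults mirror the study conditions of the predictor: lognormal
#' transcript lengths with median ~2000 nt, a stop codon at 80% of the
#' length, positives drawn around the stop codon with sd 10% of the
#' length, ~10:1 negative:positive imbalance, background SNP rate 0.05
#' per position and planted window offsets \{-2, -1, 2\} where positives
#' carry variants at rate 0.30.
#'
#' @param n_transcripts number of transcripts to simulate.
#' @param length_meanlog,length_sdlog lognormal length parameters
#'   (defaults log(2000) and 0.3).
#' @param stop_codon_rel relative position of the nominal stop codon.
#' @param enrichment_sd sd of the positive-site location bump, as a
#'   fraction of transcript length; NA disables the location bias.
#' @param imbalance_ratio target negative:positive ratio.
#' @param snp_background_rate per-position background SNP rate.
#' @param planted_offsets window offsets with elevated positive-class
#'   variant rate.
#' @param planted_rate variant rate at planted offsets in positive
#'   samples.
#' @param flank window half-width.
#' @param seed integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 100L, length_meanlog = log(2000),
                       length_sdlog = 0.3, stop_codon_rel = 0.8,
                       enrichment_sd = 0.1, imbalance_ratio = 10,
                       snp_background_rate = 0.05,
                       planted_offsets = c(-2L, -1L, 2L),
                       planted_rate = 0.30, flank = 25L, seed = 1L) {
  stopifnot(n_transcripts >= 1L, imbalance_ratio >= 1,
            snp_background_rate >= 0, snp_background_rate <= 1,
            planted_rate >= 0, planted_rate <= 1,
            all(abs(planted_offsets) <= flank))
  structure(list(n_transcripts = as.integer(n_transcripts),
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 stop_codon_rel = stop_codon_rel,
                 enrichment_sd = enrichment_sd,
                 imbalance_ratio = imbalance_ratio,
                 snp_background_rate = snp_background_rate,
                 planted_offsets = as.integer(planted_offsets),
                 planted_rate = planted_rate, flank = as.integer(flank),
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_transcript <- function(len) {
  paste(sample(RNA_LETTERS, len, replace = TRUE), collapse = "")
}

#' Simulate a labelled m6A corpus
#'
#' Generates random transcripts, enumerates their DRACH candidate
#' adenines, labels a location-biased subset positive so the corpus hits
#' the configured imbalance ratio, and draws a SNP table with
#' class-conditional variant rates at the planted window offsets.
#' Fully seeded: the same config reproduces the same corpus.
#'
#' @param config a [sim_config()].
#' @return list with `transcripts` (named character vector), `samples`
#'   (sample table), `snp` (SNP table) and `truth` (planted structure:
#'   offsets, rates, positive site keys, config).
#' @export
simulate_corpus <- function(config = sim_config()) {
  set.seed(config$seed)
  lens <- pmax(200L, as.integer(round(rlnorm(config$n_transcripts,
                                             config$length_meanlog,
                                             config$length_sdlog))))
  transcripts <- setNames(vapply(lens, random_transcript, ""),
                          sprintf("SYNTX%04d", seq_len(config$n_transcripts)))

  hits_by_tx <- lapply(names(transcripts), function(id) {
    scan_drach(transcripts[[id]])
  })
  names(hits_by_tx) <- names(transcripts)
  n_hits <- vapply(hits_by_tx, nrow, 0L)
  total <- sum(n_hits)
  target_pos <- round(total / (config$imbalance_ratio + 1))
  if (total < 2L || target_pos < 1L) {
    stop("too few DRACH candidates for the requested imbalance ratio")
  }
  # largest-remainder allocation of the positive quota across transcripts
  quota <- n_hits * target_pos / total
  n_pos <- pmin(floor(quota), n_hits)
  short <- target_pos - sum(n_pos)
  if (short > 0L) {
    spare <- which(n_pos < n_hits)
    bump <- spare[order(-(quota[spare] - n_pos[spare]))][seq_len(short)]
    n_pos[bump] <- n_pos[bump] + 1L
  }

  pos_sites <- list()
  for (id in names(transcripts)) {
    k <- n_pos[[id]]
    if (k == 0L) next
    hits <- hits_by_tx[[id]]
    len <- nchar(transcripts[[id]])
    if (is.na(config$enrichment_sd)) {
      w <- rep(1, nrow(hits))
    } else {
      stop_pos <- config$stop_codon_rel * len
      w <- stats::dnorm(hits$position, stop_pos, config$enrichment_sd * len)
      w <- w + 1e-12
    }
    take <- sample(seq_len(nrow(hits)), k, prob = w)
    pos_sites[[id]] <- data.frame(transcript_id = id,
                                  position = hits$position[take],
                                  stringsAsFactors = FALSE)
  }
  positives <- do.call(rbind, pos_sites)
  samples <- build_samples(transcripts, positives, config$flank)

  # background SNPs: sprinkle over every transcript position
  snp_id <- character(0); snp_pos <- integer(0)
  for (id in names(transcripts)) {
    len <- nchar(transcripts[[id]])
    hit <- which(runif(len) < config$snp_background_rate)
    snp_id <- c(snp_id, rep(id, length(hit)))
    snp_pos <- c(snp_pos, hit)
  }
  # planted offsets: top up positives to the planted rate
  extra <- (config$planted_rate - config$snp_background_rate) /
    (1 - config$snp_background_rate)
  pos_rows <- samples[samples$label == "positive", , drop = FALSE]
  for (off in config$planted_offsets) {
    coords <- pos_rows$position + off
    ok <- coords >= 1L & coords <= pos_rows$transcript_length
    add <- ok & runif(nrow(pos_rows)) < extra
    snp_id <- c(snp_id, pos_rows$transcript_id[add])
    snp_pos <- c(snp_pos, coords[add])
  }
  snp <- snp_table(snp_id, snp_pos)

  truth <- list(planted_offsets = config$planted_offsets,
                planted_rate = config$planted_rate,
                background_rate = config$snp_background_rate,
                positive_sites = paste(positives$transcript_id,
                                       positives$position),
                config = config)
  list(transcripts = transcripts, samples = samples, snp = snp,
       truth = truth)
}

#' Synthetic worked-case fixtures
#'
#' Builds a small labelled sample table with the class sizes of the two
#' published single-transcript case studies (c-Jun: 25 positives + 47
#' negatives; HIV-1/CBFB: 12 positives + 50 negatives) and an injected
#' prediction vector realising the reported confusion counts (c-Jun:
#' 18 TP, 3 FP; HIV-1: 5 TP, 3 FP).  The sequence content is synthetic;
#' only the evaluation arithmetic is exercised.
#'
#' @param preset `"cjun"` or `"hiv1"`.
#' @param seed integer seed for the synthetic sequence content.
#' @return list with `samples` (sample table) and `predicted`
#'   (character labels aligned with the rows).
#' @export
simulate_worked_case <- function(preset = c("cjun", "hiv1"), seed = 1L) {
  preset <- match.arg(preset)
  spec <- switch(preset,
    cjun = list(n_pos = 25L, n_neg = 47L, tp = 18L, fp = 3L,
                tx = "SYNCJUN"),
    hiv1 = list(n_pos = 12L, n_neg = 50L, tp = 5L, fp = 3L,
                tx = "SYNCBFB"))
  set.seed(seed)
  n <- spec$n_pos + spec$n_neg
  # one synthetic transcript long enough to host n well-separated sites
  len <- 60L * (n + 2L)
  flank <- 25L
  positions <- 60L * seq_len(n)
  drach <- function() {
    paste0(sample(c("G", "A", "C"), 1), sample(c("G", "A"), 1), "AC",
           sample(c("U", "A", "C"), 1))
  }
  windows <- vapply(seq_len(n), function(i) {
    w <- sample(RNA_LETTERS, 2L * flank + 1L, replace = TRUE)
    w[(flank - 1L):(flank + 3L)] <- strsplit(drach(), "")[[1L]]
    paste(w, collapse = "")
  }, "")
  label <- c(rep("positive", spec$n_pos), rep("negative", spec$n_neg))
  samples <- sample_table(rep(spec$tx, n), positions, len, windows, label)
  predicted <- rep("negative", n)
  predicted[seq_len(spec$tp)] <- "positive"                 # true positives
  predicted[spec$n_pos + seq_len(spec$fp)] <- "positive"    # false positives
  list(samples = samples, predicted = predicted)
}
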