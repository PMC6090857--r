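test_that("binary and CPD encoders follow the published nucleotide codes", {
  expect_equal(unname(encode_binary("A")), c(1, 0, 0, 0))
  expect_equal(unname(encode_binary("C")), c(0, 1, 0, 0))
  expect_equal(unname(encode_binary("G")), c(0, 0, 1, 0))
  expect_equal(unname(encode_binary("U")), c(0, 0, 0, 1))
  expect_equal(unname(encode_cpd("A")), c(1, 1, 1))
  expect_equal(unname(encode_cpd("C")), c(0, 0, 1))
  expect_equal(unname(encode_cpd("G")), c(1, 0, 0))
  expect_equal(unname(encode_cpd("U")), c(0, 1, 0))
  w <- random_window(51)
  expect_length(encode_binary(w), 204L)
  expect_length(encode_cpd(w), 153L)
  expect_true(all(encode_binary(strrep("N", 51)) == 0))
  expect_true(all(encode_cpd(strrep("N", 51)) == 0))
  expect_error(encode_binary("AXA"), "position 2")
})

test_that("density matches hand evaluation and the prefix-count oracle", {
  expect_equal(unname(nucleotide_density("AACG")), c(1, 1, 1 / 3, 1 / 4))
  expect_equal(unname(nucleotide_density("AAAA")), c(1, 1, 1, 1))
  set.seed(31)
  for (i in 1:50) {
    w <- random_window(sample(c(11, 21, 51), 1),
                       letters = c("A", "C", "G", "U", "N"))
    expect_equal(unname(nucleotide_density(w)), oracle_density(w))
  }
})

test_that("k-mer frequencies match the dictionary-count oracle", {
  v <- kmer_frequencies("AAAA", 2)
  expect_equal(unname(v["kmer2_AA"]), 1)
  expect_equal(sum(v), 1)
  expect_length(c(kmer_frequencies(random_window(51), 2),
                  kmer_frequencies(random_window(51), 3)), 80L)
  expect_error(kmer_frequencies("ACA", 4), "exceeds")
  set.seed(32)
  for (i in 1:30) {
    w <- random_window(51, letters = c("A", "C", "G", "U", "N"))
    for (k in 2:3) {
      expect_equal(unname(kmer_frequencies(w, k)), oracle_kmers(w, k))
    }
  }
})

test_that("entropy features obey the printed identities", {
  ent <- entropy_features(paste(rep(c("A", "G", "U", "C"), 10), collapse = ""))
  expect_equal(unname(ent[c("En", "REn", "IGS")]), c(2, 0, 2))
  homo <- entropy_features(strrep("A", 51))
  expect_equal(unname(homo[c("En", "REn", "IGS")]), c(0, -2, 2))
  expect_equal(unname(homo[c("p_A", "p_G", "p_U", "p_C")]), c(1, 0, 0, 0))
  expect_error(entropy_features(strrep("N", 5)), "all 'N'")
  # frequencies exclude padding
  padded <- entropy_features(paste0(strrep("N", 10), strrep("A", 41)))
  expect_equal(unname(padded[["p_A"]]), 1)
})

test_that("location features measure distance from the transcript start", {
  expect_equal(unname(location_features(101, 1000)), c(100, 0.1))
  expect_equal(unname(location_features(1, 500)), c(0, 0))
  rel <- vapply(1:100, function(p) location_features(p, 100)[["loc_rel"]], 0)
  expect_true(all(diff(rel) > 0))
  expect_error(location_features(5, 0), ">= 1")
})

test_that("SNP state vectors map transcript coordinates onto window offsets", {
  snp <- snp_table(c("tx", "tx", "other"), c(100, 80, 100))
  v <- snp_state_vector("tx", 100, 500, snp, flank = 25)
  expect_length(v, 51L)
  expect_equal(unname(v[["snp_0"]]), 1L)
  expect_equal(unname(v[["snp_-20"]]), 1L)
  expect_equal(sum(v), 2L)
  expect_true(all(snp_state_vector("tx", 100, 500, snp_table(character(0),
                                                             integer(0))) == 0L))
  # padded offsets (outside the transcript) stay 0 even if listed
  snp_edge <- snp_table("tx", 1)
  expect_equal(sum(snp_state_vector("tx", 10, 500, snp_edge, 25)), 1L)
  set.seed(33)
  for (i in 1:20) {
    pos <- sample(30:470, 1)
    pts <- sample(500, 20)
    snp_i <- snp_table(rep("tx", 20), pts)
    v <- snp_state_vector("tx", pos, 500, snp_i, 25)
    off <- -25:25
    expect_equal(unname(v), as.integer((pos + off) %in% pts &
                                         (pos + off) >= 1 &
                                         (pos + off) <= 500))
  }
})

test_that("assembled vectors have the documented 509-dimension layout", {
  set.seed(34)
  s <- list(transcript_id = "tx", position = 100L, transcript_length = 400L,
            window = random_window(51))
  snp <- snp_table(rep("tx", 5), c(98, 99, 102, 150, 60))
  ranked <- c(-2L, -1L, 2L, 5L, -5L, 10L, -10L, 15L, -15L, 20L, -20L, 25L)
  v <- assemble_features(s, snp, ranked)
  expect_length(v, 509L)
  expect_length(assemble_features(s), 497L)  # SNP block disabled
  # block boundaries: binary 204 | cpd 153 | density 51 | kmer 80 |
  # entropy 7 | location 2 | snp 12
  expect_equal(names(v)[1], "binary_-25_A")
  expect_equal(names(v)[205], "cpd_-25_ring")
  expect_equal(names(v)[358], "density_-25")
  expect_equal(names(v)[409], "kmer2_AA")
  expect_equal(names(v)[489], "p_A")
  expect_equal(names(v)[496], "loc_abs")
  expect_equal(names(v)[498:509], paste0("snp_", ranked))
  # sentinel probe: a known window drives known block values
  probe <- list(transcript_id = "tx", position = 2L, transcript_length = 8L,
                window = "GGACU")
  pv <- assemble_features(probe, config = m6acs_config(flank = 2L,
                                                       kmer_sizes = 2L,
                                                       snp_top_k = 5L))
  expect_equal(unname(pv[1:4]), c(0, 0, 1, 0))          # G one-hot
  expect_equal(unname(pv["loc_abs"]), 1)
  expect_equal(unname(pv["kmer2_AC"]), 0.25)
})

test_that("the vectorised feature matrix equals per-sample assembly", {
  set.seed(35)
  sim <- simulate_corpus(sim_config(n_transcripts = 6, seed = 35))
  samples <- sim$samples[sample(nrow(sim$samples), 25), ]
  ranked <- c(-2L, -1L, 2L, 0L, 7L, -7L, 12L, -12L, 18L, -18L, 24L, -24L)
  x <- feature_matrix(samples, sim$snp, ranked)
  expect_equal(dim(x), c(25L, 509L))
  for (i in c(1, 7, 25)) {
    v <- assemble_features(samples[i, ], sim$snp, ranked)
    expect_equal(x[i, ], v)
  }
  expect_true(all(x[, grepl("^kmer", colnames(x))] >= 0 &
                    x[, grepl("^kmer", colnames(x))] <= 1))
  expect_true(all(x[, "loc_rel"] >= 0 & x[, "loc_rel"] < 1))
})

test_that("motif-forced window offsets are constant across samples", {
  set.seed(36)
  sim <- simulate_corpus(sim_config(n_transcripts = 10, seed = 36))
  x <- feature_matrix(sim$samples)
  # centre A (offset 0) and the motif C at offset +1 are invariant
  expect_true(all(x[, "binary_0_A"] == 1))
  expect_true(all(x[, "binary_1_C"] == 1))
  expect_true(all(x[, "cpd_1_amino"] == 1))
  expect_equal(unname(apply(x[, c("binary_0_C", "binary_0_G", "binary_0_U",
                                  "binary_1_A")], 2, stats::var)),
               rep(0, 4))
})
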