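test_that("genome simulation is deterministic and gap-insertion reversible", {
  a <- simulate_genomes(3, 2000, seed = 60)
  b <- simulate_genomes(3, 2000, seed = 60)
  expect_identical(a$catalog$sequences, b$catalog$sequences)
  expect_identical(a$segments, b$segments)

  # gaps are additions: normalization recovers the stated length exactly
  gapped <- simulate_genomes(3, 10000, seed = 61, gap_fraction = 0.1)
  expect_true(all(gapped$catalog$manifest$length == 10000L))
  expect_true(all(gapped$catalog$manifest$segment_count >= 2L))
  n_inserted <- vapply(gapped$segments, function(segs)
    sum(nchar(segs)) - 10000L, integer(1))
  expect_true(all(n_inserted >= 999L))  # ~gap_fraction * length added as N
  for (segs in gapped$segments)
    expect_equal(sum(vapply(strsplit(segs, ""), function(ch) sum(ch == "N"),
                            numeric(1))),
                 sum(nchar(segs)) - 10000L)

  expect_error(simulate_genomes(0, 2000, seed = 1),
               class = "cohortref_invalid_input")
  expect_error(simulate_genomes(2, 500, seed = 1),
               class = "cohortref_invalid_input")
})

test_that("independent random genomes share almost no exact 21-mers", {
  sim <- simulate_genomes(2, 20000, seed = 62)
  kmers <- function(s) {
    start <- seq_len(nchar(s) - 20L)
    unique(substring(s, start, start + 20L))
  }
  shared <- length(intersect(kmers(sim$catalog$sequences[[1]]),
                             kmers(sim$catalog$sequences[[2]])))
  expect_lt(shared / (20000 - 20), 0.01)
})

test_that("sampled profiles are valid, sorted, and skew grows with sigma", {
  p1 <- sample_profile(1, seed = 63)
  expect_equal(p1$abundance, 1.0)

  p <- sample_profile(25, sigma = 1.5, seed = 64)
  expect_equal(sum(p$abundance), 1, tolerance = 1e-9)
  expect_true(all(diff(p$abundance) <= 0))
  expect_true(all(p$abundance >= 0))

  # Monte-Carlo: larger sigma concentrates mass in fewer species
  mean_prop <- function(sigma) {
    mean(vapply(1:100, function(i)
      abundant_species_proportion(sample_profile(30, sigma, seed = 1000 + i)),
      numeric(1)))
  }
  expect_gt(mean_prop(0.5), mean_prop(2.0))
})

test_that("abundant-species proportion follows the top-80% prefix rule", {
  prof <- community_profile(paste0("s", 1:5), c(0.5, 0.3, 0.1, 0.05, 0.05))
  expect_equal(abundant_species_proportion(prof), 0.4)  # 2 of 5 reach 0.8

  expect_equal(abundant_species_proportion(
    community_profile("s1", 1.0)), 1.0)

  uniform <- community_profile(paste0("s", 1:5), rep(0.2, 5))
  expect_equal(abundant_species_proportion(uniform), 0.8)  # 4 of 5

  # invariant to input order and to uniform rescaling before normalization
  shuffled <- community_profile(paste0("s", 1:5),
                                c(0.05, 0.3, 0.5, 0.05, 0.1))
  expect_equal(abundant_species_proportion(shuffled), 0.4)
  rescaled <- community_profile(paste0("s", 1:5),
                                (c(0.5, 0.3, 0.1, 0.05, 0.05) * 7) / 7)
  expect_equal(abundant_species_proportion(rescaled), 0.4)

  expect_error(community_profile(character(0), numeric(0)),
               class = "cohortref_invalid_input")
  expect_error(abundant_species_proportion(prof, threshold = 0),
               class = "cohortref_invalid_input")
})

test_that("noiseless reads are exact substrings at their truth coordinates", {
  com <- tiny_community(n_genomes = 4, genome_len = 3000, seed = 65)
  cfg <- read_sim_config(n_read_pairs = 200, insert_mean = 250, insert_sd = 20,
                         sub_error_rate = 0, seed = 66)
  sim <- simulate_reads(com$catalog, com$profile, cfg)
  reads <- c(sim$reads1, sim$reads2)
  truth <- sim$truth
  for (i in seq_len(nrow(truth))) {
    g <- com$catalog$sequences[[truth$genome_id[i]]]
    expected <- substr(g, truth$pos[i], truth$pos[i] + cfg$read_length - 1L)
    if (truth$strand[i] == "-") expected <- revcomp(expected)
    expect_identical(unname(reads[[truth$read_id[i]]]), expected)
  }
})

test_that("per-genome read fractions track the abundance profile", {
  com <- tiny_community(n_genomes = 6, genome_len = 5000, seed = 67)
  cfg <- read_sim_config(n_read_pairs = 100000, sub_error_rate = 0, seed = 68)
  sim <- simulate_reads(com$catalog, com$profile, cfg)
  frac <- table(factor(sim$truth$genome_id[seq_len(cfg$n_read_pairs)],
                       levels = com$profile$species)) / cfg$n_read_pairs
  se <- sqrt(com$profile$abundance * (1 - com$profile$abundance) /
               cfg$n_read_pairs)
  expect_true(all(abs(as.numeric(frac) - com$profile$abundance) <= 3 * se + 1e-12))
})

test_that("simulation is deterministic and validates its inputs", {
  com <- tiny_community(n_genomes = 3, genome_len = 3000, seed = 69)
  cfg <- read_sim_config(n_read_pairs = 50, seed = 70)
  s1 <- simulate_reads(com$catalog, com$profile, cfg)
  s2 <- simulate_reads(com$catalog, com$profile, cfg)
  expect_identical(s1$reads1, s2$reads1)
  expect_identical(s1$reads2, s2$reads2)

  alien <- community_profile(c("g001", "gXXX"), c(0.5, 0.5))
  expect_error(simulate_reads(com$catalog, alien, cfg),
               "gXXX", class = "cohortref_invalid_input")
  expect_error(read_sim_config(n_read_pairs = 10, sub_error_rate = 1),
               class = "cohortref_invalid_input")
})

test_that("N injection feeds the QC filter as designed", {
  com <- tiny_community(n_genomes = 3, genome_len = 3000, seed = 71)
  cfg <- read_sim_config(n_read_pairs = 100, n_base_fraction = 0.999,
                         seed = 72)
  sim <- simulate_reads(com$catalog, com$profile, cfg)
  keep <- qc_read(c(sim$reads1, sim$reads2))
  expect_equal(sum(keep), 0L)  # every read carries an N; fastp-style QC drops all
})

test_that("indel-bearing reads are never silently accepted", {
  com <- tiny_community(n_genomes = 3, genome_len = 3000, seed = 73)
  # indel-aware CIGARs are rejected by the post-alignment filter outright
  rec <- alignment_records("r1", "g001", 10L, 60L, "50M1I49M", 1L)
  expect_false(passes_filters(rec))
  rec_d <- alignment_records("r1", "g001", 10L, 60L, "50M1D50M", 1L)
  expect_false(passes_filters(rec_d))

  # a mid-read 1-base indel shifts the tail: the ungapped aligner either
  # loses the locus or reports a mismatch pile-up, so the read cannot
  # REF-encode within the 3-substitution budget
  g <- com$catalog$sequences[["g002"]]
  reads <- character(0)
  for (i in 1:20) {
    start <- 100 + 37 * i
    frag <- substr(g, start, start + 100L)  # 101 bases
    with_del <- paste0(substr(frag, 1, 45), substr(frag, 47, 101))  # 100 b
    reads[sprintf("del%02d", i)] <- with_del
  }
  stream <- encode_reads(reads, com$catalog, max_diffs = 3)
  modes <- vapply(stream$reads, `[[`, character(1), "mode")
  expect_true(all(modes == "RAW"))
  # and the round trip still restores them losslessly
  expect_identical(unname(decode_reads(stream, com$catalog)), unname(reads))
})
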