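make_counts <- function(counts, total) {
  count_result(counts, total_reads = total)
}

test_that("pooling sums numerators and denominators, then re-ranks", {
  one <- make_counts(c(g1 = 10L, g2 = 5L), 100)
  t1 <- pool_samples(list(s1 = one))
  expect_s3_class(t1, "mapping_rate_table")
  expect_equal(t1$mapping_rate, c(0.10, 0.05))
  expect_equal(attr(t1, "total_reads"), 100)

  two <- make_counts(c(g1 = 30L, g2 = 0L), 100)
  pooled <- pool_samples(list(a = one, b = two))
  expect_equal(pooled$mapped_reads[pooled$genome_id == "g1"], 40)
  expect_equal(pooled$mapping_rate[pooled$genome_id == "g1"], 40 / 200)

  # order invariance
  flipped <- pool_samples(list(b = two, a = one))
  expect_equal(as.data.frame(pooled), as.data.frame(flipped))

  expect_error(pool_samples(list(one, make_counts(c(g1 = 1L, g3 = 1L), 10))),
               "g3", class = "cohortref_invalid_input")
  expect_error(pool_samples(list()), class = "cohortref_invalid_input")
})

test_that("pooling is linear over any partition of the samples", {
  set.seed(31)
  ids <- sprintf("g%02d", 1:6)
  samples <- lapply(1:6, function(i)
    make_counts(stats::setNames(as.integer(rpois(6, 40)), ids),
                total = 500 + 100 * i))
  all_at_once <- pool_samples(samples)
  part <- pool_samples(list(
    p1 = make_counts(Reduce(`+`, lapply(samples[1:2], `[[`, "per_genome_mapped")),
                     sum(vapply(samples[1:2], `[[`, numeric(1), "total_reads"))),
    p2 = make_counts(Reduce(`+`, lapply(samples[3:6], `[[`, "per_genome_mapped")),
                     sum(vapply(samples[3:6], `[[`, numeric(1), "total_reads")))))
  expect_equal(as.data.frame(all_at_once), as.data.frame(part))
})

test_that("rate table invariants: exact rates, deterministic ordering", {
  tab <- mapping_rate_table(c("b", "a", "c"), c(5, 5, 20), 100)
  expect_equal(tab$genome_id, c("c", "a", "b"))  # rate desc, id asc on ties
  expect_equal(tab$mapping_rate, tab$mapped_reads / 100, tolerance = 1e-12)
  expect_lte(sum(tab$mapping_rate), 1)
})

test_that("top-N selection honors ranking, boundary ties and padding", {
  tab <- mapping_rate_table(c("g1", "g2", "g3"), c(30, 20, 10), 100)
  all3 <- top_n_genomes(tab, 10)
  expect_equal(all3$genome_ids, c("g1", "g2", "g3"))

  top2 <- top_n_genomes(tab, 2)
  expect_equal(top2$genome_ids, c("g1", "g2"))
  expect_equal(top2$cumulative_rate, 0.5)

  # tie at the boundary resolved by genome_id ascending
  tie <- mapping_rate_table(c("gB", "gA", "gC"), c(10, 10, 30), 100)
  expect_equal(top_n_genomes(tie, 2)$genome_ids, c("gC", "gA"))

  # zero-count genomes only pad, in genome_id order, with a message
  zeros <- mapping_rate_table(c("g1", "gZ", "gM"), c(7, 0, 0), 100)
  expect_message(padded <- top_n_genomes(zeros, 2), "padding")
  expect_equal(padded$genome_ids, c("g1", "gM"))

  empty <- mapping_rate_table(character(0), numeric(0), 10)
  expect_error(top_n_genomes(empty, 1), class = "cohortref_invalid_input")
})

test_that("saturation curve accumulates rates monotonically", {
  single <- mapping_rate_table("g1", 40, 100)
  expect_equal(saturation_curve(single),
               data.frame(k = 1L, cumulative_rate = 0.4))

  tab <- mapping_rate_table(c("g1", "g2", "g3"), c(30, 20, 10), 100)
  expect_equal(saturation_curve(tab)$cumulative_rate, c(0.3, 0.5, 0.6))

  set.seed(8)
  for (i in 1:10) {
    n <- sample(1:30, 1)
    tab <- mapping_rate_table(sprintf("g%02d", seq_len(n)),
                              rpois(n, 10), 1000)
    curve <- saturation_curve(tab)
    expect_true(all(diff(curve$cumulative_rate) >= 0))
    expect_equal(curve$cumulative_rate[n], sum(tab$mapped_reads) / 1000)
  }
})

test_that("sub-database integration equals the monolithic run", {
  com <- tiny_community(n_genomes = 9, genome_len = 3000, seed = 21)
  pr <- planted_reads(com$catalog, 150, max_subs = 3, seed = 22)
  cfg <- filter_config()

  mono_hits <- builtin_align(pr$reads, com$catalog)
  mono <- count_mapped(mono_hits, catalog_ids(com$catalog), cfg,
                       total_reads = length(pr$reads))

  subs <- split_catalog(com$catalog, 3)
  per_subdb <- lapply(subs, function(sc)
    best_records(builtin_align(pr$reads, sc), cfg, catalog_ids(sc)))
  merged <- merge_subdb(per_subdb, cfg, total_reads = length(pr$reads))

  expect_equal(merged$per_genome_mapped[names(mono$per_genome_mapped)],
               mono$per_genome_mapped)
  expect_equal(merged$reads_kept, mono$reads_kept)

  # cross-sub-database winner: higher score wins regardless of sub-db
  a <- alignment_records("r1", "gA", 5L, 60L, "100M", 2L, align_score = 90L)
  attr(a, "catalog_ids") <- "gA"
  b <- alignment_records("r1", "gB", 9L, 60L, "100M", 1L, align_score = 95L)
  attr(b, "catalog_ids") <- "gB"
  res <- merge_subdb(list(a, b), cfg, total_reads = 1)
  expect_equal(unname(res$per_genome_mapped["gB"]), 1L)

  # a read present in only one sub-db is simply counted there
  solo <- alignment_records("r2", "gA", 3L, 60L, "100M", 0L, align_score = 100L)
  attr(solo, "catalog_ids") <- "gA"
  empty_b <- b[0, ]
  attr(empty_b, "catalog_ids") <- "gB"
  res2 <- merge_subdb(list(solo, empty_b), cfg, total_reads = 1)
  expect_equal(unname(res2$per_genome_mapped["gA"]), 1L)

  attr(b, "catalog_ids") <- "gA"  # overlap
  expect_error(merge_subdb(list(a, b), cfg, total_reads = 1),
               "shared", class = "cohortref_invalid_input")
})

test_that("emitted reference preserves ranked order and sequences", {
  tmp <- withr::local_tempdir()
  com <- tiny_community(n_genomes = 4, genome_len = 2000, seed = 23)
  tab <- mapping_rate_table(catalog_ids(com$catalog), c(5, 50, 20, 1), 100)
  ref <- top_n_genomes(tab, 3)
  fa <- file.path(tmp, "ref.fasta")
  emit_reference(com$catalog, ref, fa)

  back <- load_reference_fasta(fa)
  expect_equal(catalog_ids(back), ref$genome_ids)
  expect_equal(unname(back$sequences),
               unname(com$catalog$sequences[ref$genome_ids]))

  sidecar <- read.delim(paste0(fa, ".tsv"))
  expect_equal(sidecar$rank, 1:3)
  expect_equal(sidecar$genome_id, ref$genome_ids)

  bogus <- ref
  bogus$genome_ids <- c(ref$genome_ids, "gnope")
  expect_error(emit_reference(com$catalog, bogus, fa),
               "gnope", class = "cohortref_invalid_input")
})

test_that("rate tables round-trip through TSV", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  tab <- mapping_rate_table(sprintf("g%02d", 1:5), c(9, 3, 3, 0, 25), 400,
                            sample_ids = c("s1", "s2"))
  write_rate_table(tab, tmp)
  back <- read_rate_table(tmp)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_equal(attr(back, "total_reads"), 400)
  expect_equal(attr(back, "sample_ids"), c("s1", "s2"))
})
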