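# Shared fixtures: all inputs are generated in code at test time.

# Small truth community: catalog + skewed profile.
tiny_community <- function(n_genomes = 5, genome_len = 5000, seed = 42,
                           sigma = 1.5) {
  sim <- simulate_genomes(n_genomes, genome_len, seed = seed)
  profile <- sample_profile(n_genomes, sigma = sigma, seed = seed + 1,
                            species = catalog_ids(sim$catalog))
  list(catalog = sim$catalog, profile = profile)
}

# Random substring reads with planted substitutions; returns named reads plus
# the truth (genome_id, pos, strand, n_subs).
planted_reads <- function(catalog, n, read_len = 100, max_subs = 0,
                          revcomp_frac = 0.5, seed = 1) {
  set.seed(seed)
  ids <- catalog_ids(catalog)
  glen <- stats::setNames(catalog$manifest$length, ids)
  gid <- ids[sample.int(length(ids), n, replace = TRUE)]
  start <- floor(stats::runif(n) * (glen[gid] - read_len + 1)) + 1L
  seqs <- substring(catalog$sequences[gid], start, start + read_len - 1L)
  nsub <- if (max_subs > 0) sample.int(max_subs + 1L, n, replace = TRUE) - 1L
          else rep(0L, n)
  for (i in which(nsub > 0)) {
    ch <- strsplit(seqs[i], "")[[1L]]
    at <- sample.int(read_len, nsub[i])
    for (p in at) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[sample.int(3L, 1L)]
    seqs[i] <- paste(ch, collapse = "")
  }
  rev <- stats::runif(n) < revcomp_frac
  seqs[rev] <- revcomp(seqs[rev])
  names(seqs) <- sprintf("p%05d", seq_len(n))
  list(reads = seqs,
       truth = data.frame(read_id = names(seqs), genome_id = gid, pos = start,
                          strand = ifelse(rev, "-", "+"), n_subs = nsub,
                          stringsAsFactors = FALSE))
}

# Random alignment-record table spanning all CIGAR ops, MAPQ and NM values.
random_sam_records <- function(n, seed = 1) {
  set.seed(seed)
  rand_cigar <- function() {
    k <- sample.int(3L, 1L)
    ops <- sample(c("M", "=", "X", "I", "D", "N", "S", "H"), k, replace = TRUE,
                  prob = c(8, 2, 2, 1, 1, 1, 1, 1))
    if (!any(ops %in% c("M", "=", "X"))) ops <- c("M", ops)
    paste0(sample.int(100L, length(ops), replace = TRUE), ops, collapse = "")
  }
  alignment_records(
    read_id = sprintf("q%05d", seq_len(n)),
    genome_id = sample(sprintf("g%03d", 1:8), n, replace = TRUE),
    pos = sample.int(5000L, n, replace = TRUE),
    mapq = sample(c(0:10, 20L, 42L, 60L, 255L), n, replace = TRUE),
    cigar = vapply(seq_len(n), function(i) rand_cigar(), character(1)),
    mismatches = sample(0:6, n, replace = TRUE),
    align_score = ifelse(stats::runif(n) < 0.8,
                         sample(0:100, n, replace = TRUE), NA_integer_))
}

# Run the installed CLI script in a child Rscript process.
run_cli <- function(args) {
  script <- system.file("cli", "cohortref.R", package = "cohortref")
  stopifnot(nzchar(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(shQuote(script), shQuote(args)),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
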